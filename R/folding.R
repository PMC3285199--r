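#' Dual-cutoff specification for fold/unfold detection
#'
#' A folding event requires the C-alpha RMSD of every segment to drop below
#' its (strict) fold threshold in the same frame; an unfolding event
#' requires all segments to rise above their (looser) unfold thresholds
#' simultaneously. The gap between the two thresholds provides hysteresis
#' that suppresses spurious recrossings near a single cutoff.
#'
#' @param segments data.frame with columns `first`, `last` (inclusive
#'   residue range, author numbering; NA means "all residues"),
#'   `fold_threshold` and `unfold_threshold` in Angstrom.
#' @param reference label of the reference experimental structure.
#' @return list of class `dual_cutoff_spec`.
#' @export
dual_cutoff_spec <- function(segments, reference = "reference") {
  need <- c("first", "last", "fold_threshold", "unfold_threshold")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    stop("`segments` needs columns ", paste(need, collapse = ", "))
  if (!nrow(segments)) stop("at least one segment is required")
  if (any(segments$fold_threshold >= segments$unfold_threshold))
    stop("fold_threshold must be < unfold_threshold for every segment")
  structure(list(segments = segments, reference = reference),
            class = "dual_cutoff_spec")
}

#' Built-in dual-cutoff presets
#'
#' Thresholds for the three systems analyzed with this scheme: the villin
#' headpiece subdomain (reference PDB 2F4K; three segments), the FiP35 WW
#' domain GTT variant (reference PDB 2F21; four segments) and the CLN025
#' beta-hairpin peptide (single segment over the whole chain, 1.0 / 4.0
#' Angstrom against its NMR structure).
#'
#' @param name one of `"villin-2F4K"`, `"ww-2F21"`, `"cln025"`.
#' @return a [dual_cutoff_spec].
#' @export
dual_cutoff_preset <- function(name = c("villin-2F4K", "ww-2F21", "cln025")) {
  name <- match.arg(name)
  switch(name,
    "villin-2F4K" = dual_cutoff_spec(data.frame(
      first = c(3L, 3L, 14L), last = c(31L, 18L, 31L),
      fold_threshold = c(1.2, 0.9, 0.9),
      unfold_threshold = c(5.0, 4.6, 2.5)), reference = "2F4K"),
    "ww-2F21" = dual_cutoff_spec(data.frame(
      first = c(2L, 8L, 12L, 19L), last = c(33L, 22L, 18L, 30L),
      fold_threshold = c(2.0, 1.1, 0.6, 0.9),
      unfold_threshold = c(7.0, 5.8, 1.8, 3.8)), reference = "2F21"),
    "cln025" = dual_cutoff_spec(data.frame(
      first = NA_integer_, last = NA_integer_,
      fold_threshold = 1.0, unfold_threshold = 4.0),
      reference = "cln025-nmr"))
}

#' Dual-cutoff state assignment of an RMSD trace
#'
#' Walks the per-segment RMSD series frame by frame: a frame where every
#' segment is strictly below its fold threshold triggers the folded state;
#' a frame where every segment is strictly above its unfold threshold
#' triggers the unfolded state; otherwise the previous state persists
#' (hysteresis). Frames before the first trigger are `"undetermined"`. An
#' event is recorded at each folded <-> unfolded transition; the first
#' crossing out of `"undetermined"` establishes the state without counting
#' as an event.
#'
#' @param rmsd_series numeric matrix (frames x segments), or a vector /
#'   list of equal-length vectors; column order must match
#'   `spec$segments`.
#' @param spec a [dual_cutoff_spec].
#' @return object of class `state_trajectory`: list with `states` (factor
#'   levels unfolded/folded/undetermined) and `events` (data.frame
#'   `frame`, `kind`).
#' @export
dual_cutoff_states <- function(rmsd_series, spec) {
  stopifnot(inherits(spec, "dual_cutoff_spec"))
  if (is.list(rmsd_series) && !is.data.frame(rmsd_series)) {
    if (length(unique(lengths(rmsd_series))) != 1)
      stop("per-segment RMSD series have unequal lengths")
    rmsd_series <- do.call(cbind, rmsd_series)
  }
  m <- as.matrix(rmsd_series)
  if (ncol(m) != nrow(spec$segments))
    stop("got ", ncol(m), " RMSD series for ", nrow(spec$segments),
         " segments")
  n <- nrow(m)
  fold_trig <- rowSums(sweep(m, 2, spec$segments$fold_threshold, "<")) == ncol(m)
  unfold_trig <- rowSums(sweep(m, 2, spec$segments$unfold_threshold, ">")) == ncol(m)
  states <- character(n)
  events <- list()
  cur <- "undetermined"
  for (f in seq_len(n)) {
    if (fold_trig[f] && cur != "folded") {
      if (cur == "unfolded")
        events[[length(events) + 1L]] <- data.frame(frame = f, kind = "fold")
      cur <- "folded"
    } else if (unfold_trig[f] && cur != "unfolded") {
      if (cur == "folded")
        events[[length(events) + 1L]] <- data.frame(frame = f, kind = "unfold")
      cur <- "unfolded"
    }
    states[f] <- cur
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(frame = integer(0), kind = character(0))
  structure(list(states = states, events = events),
            class = "state_trajectory")
}

#' Count folding and unfolding events
#'
#' @param traj a `state_trajectory` from [dual_cutoff_states()].
#' @return named integer vector `c(n_fold, n_unfold)`.
#' @export
count_events <- function(traj) {
  stopifnot(inherits(traj, "state_trajectory"))
  c(n_fold = sum(traj$events$kind == "fold"),
    n_unfold = sum(traj$events$kind == "unfold"))
}

#' Fraction of determined frames assigned folded
#'
#' Undetermined frames (before the first threshold crossing) are excluded
#' from the denominator; their count is reported as an attribute.
#'
#' @param traj a `state_trajectory`.
#' @return fraction in [0, 1] with attribute `"n_undetermined"`.
#' @export
fraction_folded <- function(traj) {
  stopifnot(inherits(traj, "state_trajectory"))
  det <- traj$states != "undetermined"
  if (!any(det)) stop("all frames are undetermined")
  out <- sum(traj$states == "folded") / sum(det)
  attr(out, "n_undetermined") <- sum(!det)
  out
}

#' Dual-cutoff analysis of an ensemble against a reference structure
#'
#' Convenience wrapper: computes the per-segment C-alpha RMSD series of an
#' ensemble against a reference and runs [dual_cutoff_states()].
#'
#' @param ensemble a [conf_ensemble].
#' @param reference a one-frame [conf_ensemble] (the experimental
#'   structure).
#' @param spec a [dual_cutoff_spec]; NA segment bounds span all shared
#'   residues.
#' @return a `state_trajectory` with the RMSD matrix attached as attribute
#'   `"rmsd"`.
#' @export
detect_folding_events <- function(ensemble, reference, spec) {
  seg <- spec$segments
  m <- vapply(seq_len(nrow(seg)), function(i) {
    rng <- if (is.na(seg$first[i]) || is.na(seg$last[i])) NULL
           else residue_range(seg$first[i], seg$last[i])
    ca_rmsd_series(ensemble, reference, rng)
  }, numeric(n_frames(ensemble)))
  if (n_frames(ensemble) == 1L) m <- matrix(m, 1)
  traj <- dual_cutoff_states(m, spec)
  attr(traj, "rmsd") <- m
  traj
}
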