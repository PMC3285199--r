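#' Per-frame, per-residue helicity assignment
#'
#' A residue is marked helical in a frame iff its (phi, psi) falls in the
#' helical rectangle and it belongs to a run of at least `min_run`
#' consecutive in-box residues (helices are cooperative; isolated in-box
#' residues are not counted). Terminal residues with undefined phi or psi
#' are never helical and break runs.
#'
#' @param ensemble a [conf_ensemble].
#' @param phi_box,psi_box numeric length-2 bounds in degrees; defaults are
#'   a standard alpha-helical basin, phi in [-100, -30], psi in [-67, -7].
#' @param min_run minimum run length of consecutive in-box residues.
#' @return object of class `helix_assignment`: logical matrix
#'   (frames x residues) with residue indices as column names.
#' @export
assign_helical <- function(ensemble, phi_box = c(-100, -30),
                           psi_box = c(-67, -7), min_run = 3L) {
  stopifnot(min_run >= 1L)
  phi <- phi_psi_matrix(ensemble, "phi")
  psi <- phi_psi_matrix(ensemble, "psi")
  inbox <- !is.na(phi) & !is.na(psi) &
    phi >= phi_box[1] & phi <= phi_box[2] &
    psi >= psi_box[1] & psi <= psi_box[2]
  helical <- matrix(FALSE, nrow(inbox), ncol(inbox),
                    dimnames = dimnames(phi))
  for (f in seq_len(nrow(inbox)))
    helical[f, ] <- runs_at_least(inbox[f, ], min_run)
  attr(helical, "assignable") <- colSums(is.na(phi) | is.na(psi)) == 0
  attr(helical, "phi_box") <- phi_box
  attr(helical, "psi_box") <- psi_box
  attr(helical, "min_run") <- min_run
  class(helical) <- c("helix_assignment", class(helical))
  helical
}

# TRUE where x is TRUE and lies in a run of >= min_run consecutive TRUEs.
runs_at_least <- function(x, min_run) {
  r <- rle(x)
  keep <- r$values & r$lengths >= min_run
  inverse.rle(list(lengths = r$lengths, values = keep))
}

#' Mean helical fraction of an assignment
#'
#' Mean of the helical indicator over frames and assignable residues
#' (residues whose dihedrals are defined in every frame).
#'
#' @param assignment a `helix_assignment` from [assign_helical()], or any
#'   logical matrix (frames x residues).
#' @return fraction in [0, 1].
#' @export
helical_fraction <- function(assignment) {
  if (!length(assignment)) stop("empty helicity assignment")
  keep <- attr(assignment, "assignable")
  m <- unclass(assignment)
  if (!is.null(keep) && any(keep)) m <- m[, keep, drop = FALSE]
  mean(m)
}

#' Melting curve from per-temperature indicator series
#'
#' Computes, per temperature, the mean of a folded/helical indicator and
#' its standard error from contiguous block averaging, and returns the
#' curve sorted by temperature.
#'
#' @param per_temperature list of entries, each a list with `temperature`
#'   (K) and `indicator` (per-frame 0/1 vector, or a frames x residues
#'   logical/numeric matrix which is averaged over residues per frame).
#' @param n_blocks number of contiguous blocks for the SEM.
#' @return data.frame of class `melting_curve` with columns `temperature`,
#'   `fraction`, `sem`, `n_frames`.
#' @export
melting_curve <- function(per_temperature, n_blocks = 5) {
  if (length(per_temperature) < 2)
    stop("melting curve needs at least 2 temperatures")
  temps <- vapply(per_temperature, function(e) as.numeric(e$temperature),
                  numeric(1))
  if (anyDuplicated(temps))
    stop("duplicate temperatures: ",
         paste(unique(temps[duplicated(temps)]), collapse = ", "))
  rows <- lapply(per_temperature, function(e) {
    ind <- e$indicator
    per_frame <- if (is.matrix(ind)) rowMeans(ind) else as.numeric(ind)
    if (any(per_frame < 0 | per_frame > 1))
      stop("indicator values must lie in [0, 1]")
    blocks <- frame_blocks(length(per_frame), n_blocks)
    bl <- vapply(blocks, function(idx) mean(per_frame[idx]), numeric(1))
    data.frame(temperature = as.numeric(e$temperature),
               fraction = mean(per_frame), sem = block_sem(bl),
               n_frames = length(per_frame))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$temperature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("melting_curve", "data.frame")
  out
}
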