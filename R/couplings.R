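#' Karplus parameter set
#'
#' Coefficients of the Karplus relation
#' \deqn{J(\phi) = A \cos^2(\phi + \delta) + B \cos(\phi + \delta) + C}
#' relating a three-bond scalar coupling to the backbone dihedral phi.
#'
#' @param coupling_type one of `"HNHA"`, `"HNCO"`, `"HNCB"`, `"HACO"`.
#' @param A,B,C coefficients in Hz.
#' @param delta phase offset in degrees (the angle between phi and the
#'   dihedral spanned by the coupled nuclei).
#' @return list of class `karplus_parameters`.
#' @export
karplus_parameters <- function(coupling_type, A, B, C, delta) {
  coupling_type <- match.arg(coupling_type,
                             c("HNHA", "HNCO", "HNCB", "HACO"))
  vals <- c(A = A, B = B, C = C, delta = delta)
  if (!all(is.finite(vals))) stop("Karplus parameters must be finite")
  structure(list(coupling_type = coupling_type,
                 A = A, B = B, C = C, delta = delta),
            class = "karplus_parameters")
}

#' Default Karplus parameter sets
#'
#' Coefficients for the four backbone couplings, transcribed from commonly
#' used published calibrations against ubiquitin/GB3 data. They are config
#' data, not constants of the method: pass your own sets to
#' [karplus_coupling()] / [observable_agreement_panel()] to use a different
#' calibration, and note that reports record the parameter set used.
#'
#' @return named list of [karplus_parameters], one per coupling type.
#' @export
default_karplus <- function() {
  list(
    HNHA = karplus_parameters("HNHA", 7.97, -1.26, 0.63, -60),
    HNCO = karplus_parameters("HNCO", 4.12, -1.10, 0.11, 180),
    HNCB = karplus_parameters("HNCB", 3.39, -0.94, 0.07, 60),
    HACO = karplus_parameters("HACO", 3.72, -2.18, 1.28, 120))
}

#' Ensemble-averaged scalar coupling from a phi series
#'
#' Evaluates the Karplus relation frame by frame and returns the ensemble
#' mean. (Because J is evaluated per frame and averaged, and the relation is
#' linear in its cos/cos^2 terms, averaging the trigonometric terms first
#' gives the identical result.)
#'
#' @param phi_series per-frame phi angles in degrees.
#' @param params a [karplus_parameters] object.
#' @return mean coupling in Hz.
#' @export
karplus_coupling <- function(phi_series, params) {
  if (!length(phi_series)) stop("empty phi series")
  stopifnot(inherits(params, "karplus_parameters"))
  th <- (phi_series + params$delta) * pi / 180
  mean(params$A * cos(th)^2 + params$B * cos(th) + params$C)
}

#' Scalar coupling table
#'
#' @param residue_index integer residues.
#' @param coupling_type character vector of coupling types.
#' @param value_hz measured or calculated couplings in Hz.
#' @param uncertainty_hz optional per-row uncertainty in Hz.
#' @return data.frame of class `coupling_table` with unique
#'   (residue, type) keys.
#' @export
coupling_table <- function(residue_index, coupling_type, value_hz,
                           uncertainty_hz = NULL) {
  df <- data.frame(residue_index = as.integer(residue_index),
                   coupling_type = as.character(coupling_type),
                   value_hz = as.numeric(value_hz),
                   stringsAsFactors = FALSE)
  if (!is.null(uncertainty_hz)) df$uncertainty_hz <- as.numeric(uncertainty_hz)
  if (!all(is.finite(df$value_hz))) stop("coupling values must be finite")
  if (anyDuplicated(df[c("residue_index", "coupling_type")]))
    stop("duplicate (residue, coupling_type) rows")
  class(df) <- c("coupling_table", "data.frame")
  df
}

#' Read a scalar-coupling table from delimited text
#'
#' Expects columns `residue`, `type`, `value_hz` (and optionally
#' `uncertainty_hz`); the delimiter is sniffed from the file extension
#' (.csv vs .tsv/.txt).
#'
#' @param path file path.
#' @return a [coupling_table].
#' @export
read_coupling_table <- function(path) {
  df <- read_delim_auto(path, c("residue", "type", "value_hz"))
  coupling_table(df$residue, df$type, df$value_hz,
                 if ("uncertainty_hz" %in% names(df)) df$uncertainty_hz)
}

read_delim_auto <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, " lacks required column(s): ", paste(miss, collapse = ", "))
  df
}

#' RMS deviation between calculated and experimental couplings
#'
#' Rows are matched on (residue, coupling type); unmatched rows on either
#' side are reported, not silently dropped.
#'
#' @param calc,exp [coupling_table]s.
#' @return list with `rmsd` (Hz over matched rows), `n_matched`, and
#'   `unmatched` (data.frame of rows present on only one side).
#' @export
coupling_agreement <- function(calc, exp) {
  m <- merge(calc, exp, by = c("residue_index", "coupling_type"),
             suffixes = c("_calc", "_exp"))
  if (!nrow(m)) stop("no matched (residue, coupling_type) rows")
  key <- function(d) paste(d$residue_index, d$coupling_type)
  only_calc <- calc[!key(calc) %in% key(exp), c("residue_index", "coupling_type")]
  only_exp <- exp[!key(exp) %in% key(calc), c("residue_index", "coupling_type")]
  unmatched <- rbind(
    if (nrow(only_calc)) cbind(only_calc, side = "calc_only"),
    if (nrow(only_exp)) cbind(only_exp, side = "exp_only"))
  list(rmsd = sqrt(mean((m$value_hz_calc - m$value_hz_exp)^2)),
       n_matched = nrow(m),
       unmatched = unmatched)
}

#' Back-calculate a scalar-coupling table from an ensemble
#'
#' Computes the phi series of each requested residue and applies the
#' Karplus relation for each requested coupling type. Residues whose phi is
#' undefined (chain N-terminus) are skipped and reported via attribute
#' `"skipped_residues"`.
#'
#' @param ensemble a [conf_ensemble].
#' @param residues residues to evaluate (default: all with a defined phi).
#' @param karplus named list of [karplus_parameters] (default
#'   [default_karplus()]).
#' @return a [coupling_table] of ensemble-mean couplings.
#' @export
calc_couplings <- function(ensemble, residues = NULL,
                           karplus = default_karplus()) {
  if (is.null(residues))
    residues <- sort(unique(ensemble$atoms$residue_index))
  rows <- list(); skipped <- integer(0)
  for (r in residues) {
    phi <- tryCatch(backbone_dihedral(ensemble, r, "phi"),
                    error = function(e) NULL)
    if (is.null(phi)) { skipped <- c(skipped, r); next }
    for (p in karplus)
      rows[[length(rows) + 1L]] <- data.frame(
        residue_index = r, coupling_type = p$coupling_type,
        value_hz = karplus_coupling(phi, p))
  }
  if (!length(rows)) stop("no residue had a defined phi angle")
  out <- do.call(rbind, rows)
  out <- coupling_table(out$residue_index, out$coupling_type, out$value_hz)
  attr(out, "skipped_residues") <- skipped
  attr(out, "karplus") <- karplus
  out
}
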