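#' Internal orientational autocorrelation functions
#'
#' For each residue's bond vector (default backbone N-H), computes
#' \deqn{C(t) = \langle P_2(\mu(\tau)\cdot\mu(\tau+t)) \rangle}
#' averaged over all overlapping time origins, where
#' `P2(x) = (3 x^2 - 1) / 2`. Frames are superposed onto a reference first
#' so that overall tumbling is removed and only internal motion remains.
#'
#' @param ensemble a [conf_ensemble] with known `frame_interval` (ns).
#' @param max_lag_ns largest lag evaluated, in ns; must be shorter than the
#'   trajectory.
#' @param vector_spec two atom names defining the per-residue vector
#'   (default `c("N", "H")`).
#' @param residues residues to analyze (default: all that carry both
#'   atoms).
#' @param superpose superpose frames onto `reference` before extracting
#'   vectors (set `FALSE` if the ensemble is already in one molecular
#'   frame).
#' @param reference,selection passed to [superpose_frames()].
#' @return object of class `internal_acf`: list with `lags_ns`, `values`
#'   (matrix lag x residue) and `residues`.
#' @export
internal_acf <- function(ensemble, max_lag_ns, vector_spec = c("N", "H"),
                         residues = NULL, superpose = TRUE,
                         reference = NULL, selection = NULL) {
  dt <- ensemble$frame_interval
  if (is.null(dt)) stop("frame_interval (ns) must be set on the ensemble")
  nfr <- n_frames(ensemble)
  max_k <- floor(max_lag_ns / dt + 1e-9)
  if (max_k >= nfr)
    stop("max_lag_ns (", max_lag_ns, " ns) must be shorter than the ",
         "trajectory (", (nfr - 1) * dt, " ns)")
  if (superpose)
    ensemble <- superpose_frames(ensemble, reference, selection)
  at <- ensemble$atoms
  if (is.null(residues)) {
    res_all <- sort(unique(at$residue_index))
    residues <- res_all[!is.na(atom_rows(at, res_all, vector_spec[1])) &
                        !is.na(atom_rows(at, res_all, vector_spec[2]))]
  }
  if (!length(residues)) stop("no residue carries both vector atoms (",
                              paste(vector_spec, collapse = "-"), ")")
  i1 <- atom_rows(at, residues, vector_spec[1])
  i2 <- atom_rows(at, residues, vector_spec[2])
  if (anyNA(i1) || anyNA(i2))
    stop("missing vector atoms for residues: ",
         paste(residues[is.na(i1) | is.na(i2)], collapse = ", "))
  lags <- 0:max_k
  vals <- matrix(NA_real_, length(lags), length(residues),
                 dimnames = list(NULL, residues))
  for (j in seq_along(residues)) {
    v <- t(ensemble$coords[i2[j], , , drop = TRUE] -
           ensemble$coords[i1[j], , , drop = TRUE])   # frames x 3
    v <- v / sqrt(rowSums(v^2))
    for (k in lags) {
      n <- nfr - k
      dot <- rowSums(v[seq_len(n), , drop = FALSE] *
                     v[seq_len(n) + k, , drop = FALSE])
      vals[k + 1L, j] <- mean((3 * dot^2 - 1) / 2)
    }
  }
  structure(list(lags_ns = lags * dt, values = vals, residues = residues),
            class = "internal_acf")
}

#' Order parameters from autocorrelation plateaus
#'
#' Reads the generalized order parameter S^2 off the internal
#' autocorrelation function as its mean over a lag window centred on the
#' experimental rotational correlation time tau_c (the plateau the
#' Lipari-Szabo model identifies with S^2). Values are clipped to [0, 1]
#' with a warning, since the estimator can stray marginally outside.
#'
#' @param acf an [internal_acf] object.
#' @param tau_c_ns rotational correlation time in ns (user input from
#'   experiment; not estimated from the ensemble).
#' @param window relative half-width of the lag window (default 0.2, i.e.
#'   lags within tau_c * (1 +/- 0.2)).
#' @return data.frame of class `order_parameter_table` with columns
#'   `residue_index`, `s2`.
#' @export
order_parameter <- function(acf, tau_c_ns, window = 0.2) {
  stopifnot(inherits(acf, "internal_acf"))
  lo <- tau_c_ns * (1 - window); hi <- tau_c_ns * (1 + window)
  sel <- acf$lags_ns >= lo & acf$lags_ns <= hi
  if (!any(sel))
    stop("no lags inside the window [", signif(lo, 4), ", ", signif(hi, 4),
         "] ns; available lags end at ", max(acf$lags_ns), " ns")
  s2 <- colMeans(acf$values[sel, , drop = FALSE])
  if (any(s2 < -1e-6 | s2 > 1 + 1e-6))
    warning("S^2 estimates outside [0, 1] were clipped")
  s2 <- pmin(pmax(s2, 0), 1)
  out <- data.frame(residue_index = acf$residues, s2 = as.numeric(s2))
  class(out) <- c("order_parameter_table", "data.frame")
  out
}

#' Read an order-parameter table from delimited text
#'
#' Expects columns `residue` and `s2`.
#' @param path file path.
#' @return `order_parameter_table` data.frame.
#' @export
read_s2_table <- function(path) {
  df <- read_delim_auto(path, c("residue", "s2"))
  if (any(df$s2 < 0 | df$s2 > 1)) stop("s2 values must lie in [0, 1]")
  out <- data.frame(residue_index = as.integer(df$residue), s2 = df$s2)
  class(out) <- c("order_parameter_table", "data.frame")
  out
}
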