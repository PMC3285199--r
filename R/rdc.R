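#' Alignment (Saupe) tensor
#'
#' Traceless symmetric 3x3 order tensor describing partial molecular
#' alignment; an RDC for internuclear unit vector b is
#' `scale * t(b) %*% saupe %*% b`. The pair-specific maximal coupling
#' (gyromagnetic ratios and bond length) is absorbed into `scale`.
#'
#' @param saupe 3x3 symmetric traceless matrix (dimensionless).
#' @param scale coupling scale in Hz (default 1: the Saupe entries then
#'   carry Hz units directly).
#' @return list of class `alignment_tensor`.
#' @export
alignment_tensor <- function(saupe, scale = 1) {
  saupe <- as.matrix(saupe)
  if (!all(dim(saupe) == c(3, 3))) stop("saupe must be 3x3")
  if (max(abs(saupe - t(saupe))) > 1e-9) stop("saupe must be symmetric")
  if (abs(sum(diag(saupe))) > 1e-9) stop("saupe must be traceless")
  saupe <- (saupe + t(saupe)) / 2
  diag(saupe) <- diag(saupe) - sum(diag(saupe)) / 3
  structure(list(saupe = saupe, scale = scale), class = "alignment_tensor")
}

#' Residual dipolar coupling table
#'
#' @param residue_index integer residues.
#' @param atom_pair pair labels such as `"N-H"`.
#' @param value_hz couplings in Hz.
#' @param medium_id label of the alignment medium.
#' @return data.frame of class `rdc_table`.
#' @export
rdc_table <- function(residue_index, atom_pair, value_hz, medium_id = "medium1") {
  df <- data.frame(residue_index = as.integer(residue_index),
                   atom_pair = as.character(atom_pair),
                   value_hz = as.numeric(value_hz),
                   stringsAsFactors = FALSE)
  if (!all(is.finite(df$value_hz))) stop("RDC values must be finite")
  if (anyDuplicated(df[c("residue_index", "atom_pair")]))
    stop("duplicate (residue, atom_pair) rows")
  attr(df, "medium_id") <- medium_id
  class(df) <- c("rdc_table", "data.frame")
  df
}

#' Read an RDC table from delimited text
#'
#' Expects columns `residue`, `pair`, `value_hz` and optionally `medium`.
#' @param path file path.
#' @return an [rdc_table].
#' @export
read_rdc_table <- function(path) {
  df <- read_delim_auto(path, c("residue", "pair", "value_hz"))
  rdc_table(df$residue, df$pair, df$value_hz,
            if ("medium" %in% names(df)) df$medium[1] else "medium1")
}

#' Ensemble-averaged bond dyadics for RDC back-calculation
#'
#' For each (residue, atom pair), normalizes the internuclear vector in
#' every frame of the (superposed) ensemble and averages the outer product
#' `b %*% t(b)`. A single alignment tensor contracted with this averaged
#' dyadic yields the ensemble-averaged RDC, keeping the tensor fit linear.
#'
#' @param ensemble a [conf_ensemble]; superpose it first (see
#'   [superpose_frames()]) unless frames share one molecular frame already.
#' @param pairs data.frame with columns `residue_index`, `atom_pair`
#'   (e.g. `"N-H"`).
#' @return array `n_pairs x 3 x 3` with dimnames on the first margin
#'   `"residue:pair"`, plus attribute `"pairs"`.
#' @export
bond_dyadics <- function(ensemble, pairs) {
  nfr <- n_frames(ensemble)
  out <- array(0, dim = c(nrow(pairs), 3, 3))
  for (k in seq_len(nrow(pairs))) {
    nm <- strsplit(pairs$atom_pair[k], "-", fixed = TRUE)[[1]]
    if (length(nm) != 2) stop("atom_pair must look like \"N-H\": ",
                              pairs$atom_pair[k])
    i1 <- atom_rows(ensemble$atoms, pairs$residue_index[k], nm[1])
    i2 <- atom_rows(ensemble$atoms, pairs$residue_index[k], nm[2])
    if (anyNA(c(i1, i2)))
      stop("missing atom for pair ", pairs$atom_pair[k],
           " of residue ", pairs$residue_index[k])
    acc <- matrix(0, 3, 3)
    for (f in seq_len(nfr)) {
      b <- normalize(ensemble$coords[i2, , f] - ensemble$coords[i1, , f])
      acc <- acc + tcrossprod(b)
    }
    out[k, , ] <- acc / nfr
  }
  dimnames(out) <- list(paste0(pairs$residue_index, ":", pairs$atom_pair),
                        NULL, NULL)
  attr(out, "pairs") <- pairs[c("residue_index", "atom_pair")]
  out
}

# Accept unit-vector matrix (n x 3) or dyadic array (n x 3 x 3); return
# dyadic array.
as_dyadics <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("expected n x 3 unit vectors or n x 3 x 3 dyadics")
  out <- array(0, dim = c(nrow(x), 3, 3))
  for (k in seq_len(nrow(x))) {
    b <- normalize(x[k, ])
    out[k, , ] <- tcrossprod(b)
  }
  out
}

# Design matrix over the 5 independent traceless-symmetric components
# (Sxx, Syy, Sxy, Sxz, Syz), with Szz = -Sxx - Syy.
rdc_design <- function(dy) {
  cbind(dy[, 1, 1] - dy[, 3, 3],
        dy[, 2, 2] - dy[, 3, 3],
        2 * dy[, 1, 2],
        2 * dy[, 1, 3],
        2 * dy[, 2, 3])
}

#' Fit an alignment tensor to measured RDCs
#'
#' Least-squares solution of the linear system
#' `D_i = scale * tr(S %*% dyadic_i)` over the 5 independent components of
#' the traceless symmetric Saupe matrix S.
#'
#' @param coords bond geometry: an `n x 3` matrix of internuclear unit
#'   vectors, an `n x 3 x 3` dyadic array from [bond_dyadics()], or a
#'   [conf_ensemble] (then `rdcs`' pairs are resolved against it).
#' @param rdcs an [rdc_table]; rows must correspond to the rows of `coords`
#'   when geometry is given explicitly.
#' @param scale coupling scale in Hz absorbed out of the fitted Saupe
#'   matrix.
#' @return an [alignment_tensor] with attributes `"residuals_hz"` and
#'   `"rms_residual_hz"`.
#' @export
fit_alignment_tensor <- function(coords, rdcs, scale = 1) {
  if (inherits(coords, "conf_ensemble"))
    coords <- bond_dyadics(coords, rdcs)
  dy <- as_dyadics(coords)
  if (dim(dy)[1] != nrow(rdcs))
    stop("geometry rows (", dim(dy)[1], ") and RDC rows (", nrow(rdcs),
         ") differ")
  if (nrow(rdcs) < 5)
    stop("under-determined: need >= 5 RDCs to fit a Saupe tensor, got ",
         nrow(rdcs))
  X <- rdc_design(dy) * scale
  qx <- qr(X)
  if (qx$rank < 5)
    stop("under-determined: rank-deficient design matrix ",
         "(degenerate bond directions)")
  beta <- qr.coef(qx, rdcs$value_hz)
  S <- matrix(c(beta[1], beta[3], beta[4],
                beta[3], beta[2], beta[5],
                beta[4], beta[5], -beta[1] - beta[2]), 3, 3)
  out <- alignment_tensor(S, scale)
  res <- rdcs$value_hz - X %*% beta
  attr(out, "residuals_hz") <- as.numeric(res)
  attr(out, "rms_residual_hz") <- sqrt(mean(res^2))
  out
}

#' Back-calculate RDCs from a tensor and bond geometry
#'
#' @param coords geometry as in [fit_alignment_tensor()].
#' @param tensor an [alignment_tensor].
#' @param pairs data.frame with `residue_index`, `atom_pair` labelling the
#'   rows (required when `coords` is not a `conf_ensemble`).
#' @param medium_id medium label for the output table.
#' @return an [rdc_table] with `D = scale * tr(S %*% dyadic)` per row.
#' @export
back_calculate_rdc <- function(coords, tensor, pairs = NULL,
                               medium_id = "medium1") {
  stopifnot(inherits(tensor, "alignment_tensor"))
  if (inherits(coords, "conf_ensemble")) {
    if (is.null(pairs)) stop("`pairs` required with an ensemble")
    coords <- bond_dyadics(coords, pairs)
  }
  dy <- as_dyadics(coords)
  if (is.null(pairs)) pairs <- attr(dy, "pairs")
  if (is.null(pairs))
    pairs <- data.frame(residue_index = seq_len(dim(dy)[1]),
                        atom_pair = "N-H")
  d <- vapply(seq_len(dim(dy)[1]),
              function(k) tensor$scale * sum(tensor$saupe * dy[k, , ]),
              numeric(1))
  rdc_table(pairs$residue_index, pairs$atom_pair, d, medium_id)
}

#' RDC quality (Q) factor
#'
#' `Q = rms(D_calc - D_exp) / rms(D_exp)` over rows matched on
#' (residue, atom pair); 0 means perfect agreement.
#'
#' @param calc,exp [rdc_table]s.
#' @return dimensionless Q (attributes record the match count).
#' @export
q_score <- function(calc, exp) {
  m <- merge(as.data.frame(calc), as.data.frame(exp),
             by = c("residue_index", "atom_pair"),
             suffixes = c("_calc", "_exp"))
  if (!nrow(m)) stop("no matched (residue, atom_pair) rows")
  denom <- sum(m$value_hz_exp^2)
  if (denom == 0) stop("undefined Q: experimental RDCs are all zero")
  q <- sqrt(sum((m$value_hz_calc - m$value_hz_exp)^2) / denom)
  attr(q, "n_matched") <- nrow(m)
  q
}
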