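#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimize the RMSD between
#' a mobile and a reference set of coordinates over a selected atom subset,
#' using the SVD of the cross-covariance matrix with the determinant
#' correction that excludes reflections.
#'
#' @param mobile,reference `n x 3` coordinate matrices with matching rows.
#' @param selection integer row indices used for the fit (default: all rows).
#' @return list with `rotation` (3x3, proper: det = +1), `translation`
#'   (length 3) and `rmsd` (Angstrom over the selection). The fitted mobile
#'   coordinates are `mobile %*% rotation + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3)
    stop("coordinates must be n x 3 matrices")
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3)
    stop("superposition needs at least 3 selected atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("selection size mismatch between frames")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv_geom <- svd(Ac)$d
  if (sv_geom[2] < 1e-8 * max(sv_geom[1], 1))
    stop("degenerate geometry: selected atoms are (near-)collinear")
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Ac %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Bc)^2)))
  list(rotation = R, translation = as.numeric(cb - ca %*% R), rmsd = rmsd)
}

#' Inclusive residue range in author numbering
#' @param first,last first and last residue index (inclusive, 1-based).
#' @return list of class `residue_range`.
#' @export
residue_range <- function(first, last) {
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || first > last)
    stop("residue_range requires first <= last")
  structure(list(first = first, last = last), class = "residue_range")
}

#' Per-frame C-alpha RMSD to a reference structure
#'
#' For each frame, superposes the C-alpha atoms of the residues in `range`
#' onto the corresponding reference C-alphas and returns the minimized RMSD.
#' This is the quantity the dual-cutoff fold/unfold detector thresholds.
#'
#' @param ensemble a [conf_ensemble].
#' @param reference a one-frame `conf_ensemble` (or any ensemble; frame 1 is
#'   used) sharing residue numbering with `ensemble`.
#' @param range a [residue_range]; default spans all residues common to both.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
ca_rmsd_series <- function(ensemble, reference, range = NULL) {
  if (is.null(range)) {
    shared <- intersect(ensemble$atoms$residue_index,
                        reference$atoms$residue_index)
    range <- residue_range(min(shared), max(shared))
  }
  res <- seq(range$first, range$last)
  ie <- atom_rows(ensemble$atoms, res, "CA")
  ir <- atom_rows(reference$atoms, res, "CA")
  missing <- res[is.na(ie) | is.na(ir)]
  if (length(missing))
    stop("missing CA atoms for residues: ", paste(missing, collapse = ", "))
  ref <- reference$coords[ir, , 1, drop = TRUE]
  vapply(seq_len(n_frames(ensemble)), function(f) {
    kabsch_superpose(ensemble$coords[ie, , f, drop = TRUE], ref)$rmsd
  }, numeric(1))
}

# Vectorized torsion angle (degrees, IUPAC sign, range (-180, 180]) for
# four n x 3 point sets.
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross3(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- 180
  ang
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Backbone dihedral angle series
#'
#' phi(i) is defined by C(i-1), N(i), CA(i), C(i); psi(i) by N(i), CA(i),
#' C(i), N(i+1). Angles follow the IUPAC sign convention, in degrees, in the
#' range (-180, 180].
#'
#' @param ensemble a [conf_ensemble].
#' @param residue_index residue (author numbering).
#' @param angle `"phi"` or `"psi"`.
#' @return numeric vector, one angle per frame.
#' @export
backbone_dihedral <- function(ensemble, residue_index, angle = c("phi", "psi")) {
  angle <- match.arg(angle)
  at <- ensemble$atoms
  idx <- if (angle == "phi") {
    c(atom_rows(at, residue_index - 1L, "C"),
      atom_rows(at, residue_index, "N"),
      atom_rows(at, residue_index, "CA"),
      atom_rows(at, residue_index, "C"))
  } else {
    c(atom_rows(at, residue_index, "N"),
      atom_rows(at, residue_index, "CA"),
      atom_rows(at, residue_index, "C"),
      atom_rows(at, residue_index + 1L, "N"))
  }
  if (anyNA(idx))
    stop(angle, " undefined for residue ", residue_index,
         ": missing defining atom(s)")
  p <- lapply(idx, function(i) t(ensemble$coords[i, , , drop = TRUE]))
  if (n_frames(ensemble) == 1L) p <- lapply(p, function(m) matrix(m, 1, 3))
  dihedral_deg(p[[1]], p[[2]], p[[3]], p[[4]])
}

# phi/psi matrices (frames x residues) with NA where undefined.
phi_psi_matrix <- function(ensemble, angle) {
  res <- sort(unique(ensemble$atoms$residue_index))
  out <- matrix(NA_real_, n_frames(ensemble), length(res),
                dimnames = list(NULL, res))
  for (j in seq_along(res)) {
    ang <- tryCatch(backbone_dihedral(ensemble, res[j], angle),
                    error = function(e) NULL)
    if (!is.null(ang)) out[, j] <- ang
  }
  out
}

#' Superpose every frame of an ensemble onto a reference frame
#'
#' Removes overall rotation and translation (molecular tumbling) before
#' internal motions are analyzed, by least-squares fitting each frame onto
#' the reference over a selection of atoms (default: all backbone heavy
#' atoms N, CA, C).
#'
#' @param ensemble a [conf_ensemble].
#' @param reference coordinates to fit to: a `conf_ensemble` (frame 1) or an
#'   `n_atoms x 3` matrix; default is the ensemble's own first frame.
#' @param selection integer atom row indices for the fit; default all
#'   N/CA/C atoms.
#' @return a new `conf_ensemble` with every frame superposed.
#' @export
superpose_frames <- function(ensemble, reference = NULL, selection = NULL) {
  if (is.null(selection))
    selection <- which(ensemble$atoms$atom_name %in% c("N", "CA", "C"))
  ref <- if (is.null(reference)) frame_coords(ensemble, 1L)
         else if (inherits(reference, "conf_ensemble")) frame_coords(reference, 1L)
         else as.matrix(reference)
  out <- ensemble
  for (f in seq_len(n_frames(ensemble))) {
    m <- ensemble$coords[, , f, drop = TRUE]
    fit <- kabsch_superpose(m, ref, selection)
    out$coords[, , f] <- sweep(m %*% fit$rotation, 2, fit$translation, "+")
  }
  out
}
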