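#' Conformational ensemble container
#'
#' An ordered set of frames (conformations) of one molecule, stored as an
#' atom table plus a coordinate array. This is the substrate every
#' back-calculation in the package operates on: frames may come from a
#' multi-model PDB file, from a trajectory reader, or from one of the
#' synthetic generators.
#'
#' @param atoms data.frame with columns `atom_name` (PDB atom naming, e.g.
#'   "CA", "N", "H"), `residue_index` (1-based author numbering),
#'   `residue_name` (3-letter code) and `element`.
#' @param coords numeric array of dimension `n_atoms x 3 x n_frames` (in
#'   Angstrom), or a list of `n_atoms x 3` matrices, or a single matrix for a
#'   one-frame ensemble.
#' @param frame_interval optional time between consecutive frames, in ns.
#' @param temperature optional temperature label, in kelvin.
#'
#' @return An object of class `conf_ensemble`: a list with elements `atoms`,
#'   `coords` (always a 3-d array), `frame_interval` and `temperature`.
#' @export
conf_ensemble <- function(atoms, coords, frame_interval = NULL,
                          temperature = NULL) {
  required <- c("atom_name", "residue_index", "residue_name", "element")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms)))
    stop("`atoms` must be a data.frame with columns ",
         paste(required, collapse = ", "))
  atoms$residue_index <- as.integer(atoms$residue_index)
  if (any(atoms$residue_index < 1L))
    stop("residue_index must be >= 1 (author numbering)")
  if (any(!nzchar(atoms$atom_name)))
    stop("atom_name must be non-empty")
  key <- paste(atoms$residue_index, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (residue_index, atom_name) in topology: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))

  if (is.matrix(coords)) coords <- list(coords)
  if (is.list(coords)) {
    n <- length(coords)
    for (i in seq_len(n)) {
      if (!is.matrix(coords[[i]]) || ncol(coords[[i]]) != 3 ||
          nrow(coords[[i]]) != nrow(atoms))
        stop("frame ", i, " does not have one coordinate triple per atom")
    }
    coords <- array(unlist(coords), dim = c(nrow(atoms), 3, n))
  }
  if (!is.array(coords) || length(dim(coords)) != 3 ||
      dim(coords)[1] != nrow(atoms) || dim(coords)[2] != 3)
    stop("`coords` must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[3] < 1) stop("ensemble must contain at least one frame")
  if (!all(is.finite(coords))) stop("coordinates must be finite")

  structure(
    list(atoms = atoms, coords = coords,
         frame_interval = frame_interval, temperature = temperature),
    class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat("Conformational ensemble:", n_frames(x), "frame(s),",
      nrow(x$atoms), "atoms,",
      length(unique(x$atoms$residue_index)), "residues\n")
  if (!is.null(x$frame_interval))
    cat("  frame interval:", x$frame_interval, "ns\n")
  if (!is.null(x$temperature))
    cat("  temperature:", x$temperature, "K\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `conf_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Extract one frame's coordinates
#' @param ensemble a `conf_ensemble`.
#' @param frame frame index (1-based).
#' @return `n_atoms x 3` coordinate matrix in Angstrom.
#' @export
frame_coords <- function(ensemble, frame = 1L) {
  stopifnot(frame >= 1L, frame <= n_frames(ensemble))
  ensemble$coords[, , frame, drop = TRUE]
}

# Row indices of named atoms; NA where absent.
atom_rows <- function(atoms, residue_index, atom_name) {
  match(paste(residue_index, atom_name),
        paste(atoms$residue_index, atoms$atom_name))
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' Each MODEL in the file becomes one frame; atom ordering and author
#' (PDB) residue numbering are preserved. Alternate locations other than
#' blank or 'A' are dropped; insertion codes are rejected because they make
#' the 1-based author numbering ambiguous.
#'
#' @param path path to a PDB file (single- or multi-model).
#' @param frame_interval optional time between models, in ns.
#' @param temperature optional temperature label, in kelvin.
#' @return a [conf_ensemble].
#' @export
read_ensemble <- function(path, frame_interval = NULL, temperature = NULL) {
  if (!file.exists(path)) stop("cannot read ensemble: no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  atom <- pdb$atom
  keep <- is.na(atom$alt) | atom$alt %in% c("", "A")
  if (any(!is.na(atom$insert) & nzchar(atom$insert)))
    stop("insertion codes present in ", path,
         "; renumber the structure before reading")
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  idx <- which(keep)
  atoms <- data.frame(
    atom_name = trimws(atom$elety[idx]),
    residue_index = as.integer(atom$resno[idx]),
    residue_name = trimws(atom$resid[idx]),
    element = trimws(ifelse(is.na(atom$elesy[idx]), "", atom$elesy[idx])),
    stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(length(idx), 3, nfr))
  for (f in seq_len(nfr)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    if (anyNA(m))
      stop("frame ", f, " in ", path, " has inconsistent atom records")
    coords[, , f] <- m[idx, , drop = FALSE]
  }
  conf_ensemble(atoms, coords, frame_interval = frame_interval,
                temperature = temperature)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a [conf_ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  at <- ensemble$atoms
  nfr <- n_frames(ensemble)
  xyz <- t(apply(ensemble$coords, 3, function(m) as.vector(t(m))))
  if (nfr == 1L) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(at)),
    eleno = seq_len(nrow(at)),
    elety = at$atom_name,
    resid = at$residue_name,
    resno = at$residue_index,
    chain = rep("A", nrow(at)),
    elesy = at$element)
  invisible(path)
}

#' Reconstruct backbone amide hydrogens from heavy-atom geometry
#'
#' Experimental structures often lack hydrogens, but N-H bond vectors are
#' needed for RDC back-calculation and order parameters. The amide H of
#' residue i is placed 1.01 Angstrom from N along the direction opposite the
#' bisector of the N-CA(i) and N-C(i-1) bonds (ideal planar amide geometry).
#' Residues that already have an H, and residues without a preceding C
#' (chain N-terminus), are left untouched.
#'
#' @param ensemble a [conf_ensemble].
#' @param bond_length N-H bond length in Angstrom.
#' @return a new `conf_ensemble` including the reconstructed "H" atoms;
#'   reconstructed residues are recorded in attribute `"reconstructed_h"`.
#' @export
reconstruct_amide_h <- function(ensemble, bond_length = 1.01) {
  at <- ensemble$atoms
  res <- sort(unique(at$residue_index))
  added <- integer(0)
  new_rows <- list(); new_xyz <- list()
  for (r in res) {
    if (!is.na(atom_rows(at, r, "H")[1])) next
    i_n <- atom_rows(at, r, "N"); i_ca <- atom_rows(at, r, "CA")
    i_cp <- atom_rows(at, r - 1L, "C")
    if (anyNA(c(i_n, i_ca, i_cp))) next
    nfr <- n_frames(ensemble)
    h <- matrix(NA_real_, nfr, 3)
    for (f in seq_len(nfr)) {
      pn <- ensemble$coords[i_n, , f]
      u1 <- normalize(ensemble$coords[i_ca, , f] - pn)
      u2 <- normalize(ensemble$coords[i_cp, , f] - pn)
      h[f, ] <- pn - bond_length * normalize(u1 + u2)
    }
    added <- c(added, r)
    new_rows[[length(new_rows) + 1L]] <- data.frame(
      atom_name = "H", residue_index = r,
      residue_name = at$residue_name[i_n], element = "H",
      stringsAsFactors = FALSE)
    new_xyz[[length(new_xyz) + 1L]] <- h
  }
  if (!length(added)) {
    attr(ensemble, "reconstructed_h") <- integer(0)
    return(ensemble)
  }
  atoms2 <- rbind(at, do.call(rbind, new_rows))
  nfr <- n_frames(ensemble)
  coords2 <- array(NA_real_, dim = c(nrow(atoms2), 3, nfr))
  coords2[seq_len(nrow(at)), , ] <- ensemble$coords
  for (k in seq_along(added))
    coords2[nrow(at) + k, , ] <- t(new_xyz[[k]])
  out <- conf_ensemble(atoms2, coords2,
                       frame_interval = ensemble$frame_interval,
                       temperature = ensemble$temperature)
  attr(out, "reconstructed_h") <- added
  out
}

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}
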