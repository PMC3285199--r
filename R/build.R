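#' Build an idealized polypeptide backbone from internal coordinates
#'
#' Constructs a single-frame backbone (N, CA, C, and amide H) for `n_res`
#' residues with the given phi/psi angles and trans peptide bonds, using
#' standard bond lengths and angles. Used as a reference geometry by the
#' synthetic generators and as a known-answer fixture for dihedral and
#' helicity code.
#'
#' @param n_res number of residues.
#' @param phi,psi backbone dihedrals in degrees; recycled to `n_res`.
#'   Defaults are ideal alpha-helical values (-57, -47).
#' @param residue_name 3-letter code used for every residue.
#' @return a one-frame [conf_ensemble].
#' @export
build_backbone <- function(n_res, phi = -57, psi = -47,
                           residue_name = "ALA") {
  stopifnot(n_res >= 1)
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  # standard backbone geometry (Engh-Huber-like values)
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_n_h <- 1.01
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7
  a_c_n_h <- 119.5
  omega <- 180

  # seed the first three atoms
  pos <- list()
  pos[["1 N"]] <- c(0, 0, 0)
  pos[["1 CA"]] <- c(b_n_ca, 0, 0)
  th <- (180 - a_n_ca_c) * pi / 180
  pos[["1 C"]] <- pos[["1 CA"]] + b_ca_c * c(cos(th), sin(th), 0)

  for (i in seq_len(n_res)) {
    nm <- function(res, a) paste(res, a)
    if (i > 1) {
      pos[[nm(i, "N")]] <- place_atom(pos[[nm(i - 1, "CA")]],
                                      pos[[nm(i - 1, "C")]], NULL,
                                      prev = pos[[nm(i - 1, "N")]],
                                      bond = b_c_n, angle = a_ca_c_n,
                                      torsion = psi[i - 1])
      pos[[nm(i, "CA")]] <- place_atom(pos[[nm(i - 1, "C")]],
                                       pos[[nm(i, "N")]], NULL,
                                       prev = pos[[nm(i - 1, "CA")]],
                                       bond = b_n_ca, angle = a_c_n_ca,
                                       torsion = omega)
      pos[[nm(i, "C")]] <- place_atom(pos[[nm(i, "N")]],
                                      pos[[nm(i, "CA")]], NULL,
                                      prev = pos[[nm(i - 1, "C")]],
                                      bond = b_ca_c, angle = a_n_ca_c,
                                      torsion = phi[i])
      # amide H in the peptide plane, opposite CA(i) across the C-N bond
      pos[[nm(i, "H")]] <- place_atom(pos[[nm(i - 1, "C")]],
                                      pos[[nm(i, "N")]], NULL,
                                      prev = pos[[nm(i - 1, "CA")]],
                                      bond = b_n_h, angle = a_c_n_h,
                                      torsion = 0)
    }
  }

  order_names <- unlist(lapply(seq_len(n_res), function(i) {
    a <- c("N", "H", "CA", "C")
    if (i == 1) a <- c("N", "CA", "C")  # no preceding C for H placement
    paste(i, a)
  }))
  coords <- do.call(rbind, pos[order_names])
  parts <- strsplit(order_names, " ")
  atoms <- data.frame(
    atom_name = vapply(parts, `[`, "", 2),
    residue_index = as.integer(vapply(parts, `[`, "", 1)),
    residue_name = residue_name,
    element = substr(vapply(parts, `[`, "", 2), 1, 1),
    stringsAsFactors = FALSE)
  conf_ensemble(atoms, coords)
}

# Natural-extension-reference-frame atom placement: position d such that
# |d - pc| = bond, angle(pb, pc, d) = angle and torsion(prev, pb, pc, d) =
# torsion (degrees). `a` unused slot kept for call-site readability.
place_atom <- function(pb, pc, a = NULL, prev, bond, angle, torsion) {
  angle <- angle * pi / 180; torsion <- torsion * pi / 180
  bc <- normalize(pc - pb)
  n <- normalize(cross3(matrix(pb - prev, 1, 3), matrix(bc, 1, 3))[1, ])
  m <- cross3(matrix(n, 1, 3), matrix(bc, 1, 3))[1, ]
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion),
                 sin(angle) * sin(torsion))
  pc + d2[1] * bc + d2[2] * m + d2[3] * n
}
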