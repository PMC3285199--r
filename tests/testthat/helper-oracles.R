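# Independent oracles used to validate the implementation by a second route.

# Horn's quaternion method for least-squares superposition RMSD: the optimal
# rotation is encoded in the largest eigenvalue of a 4x4 matrix built from
# the cross-covariance; no SVD involved.
quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  B <- sweep(as.matrix(reference), 2, colMeans(reference))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)
  sqrt(max(msd, 0))
}

# Scalar (non-vectorized) torsion oracle built on bio3d, plus explicit
# cis/trans conventions checked in the tests.
torsion_oracle <- function(p1, p2, p3, p4) {
  bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)
}

# Brute-force mean helicity of the nucleation-propagation chain by
# enumerating all 2^n residue-state strings.
enumerate_helicity <- function(n_res, w, sigma) {
  z <- 0; acc <- 0
  for (k in 0:(2^n_res - 1)) {
    s <- as.integer(intToBits(k))[seq_len(n_res)]
    nh <- sum(s)
    n_runs <- sum(diff(c(0L, s)) == 1L)
    wt <- w^nh * sigma^n_runs
    z <- z + wt
    acc <- acc + wt * nh / n_res
  }
  acc / z
}

# Random rigid motion applied to an n x 3 coordinate matrix.
apply_random_rigid <- function(x) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; a <- q[2]; b <- q[3]; cc <- q[4]
  R <- matrix(c(1 - 2 * (b^2 + cc^2), 2 * (a * b - w * cc), 2 * (a * cc + w * b),
                2 * (a * b + w * cc), 1 - 2 * (a^2 + cc^2), 2 * (b * cc - w * a),
                2 * (a * cc - w * b), 2 * (b * cc + w * a), 1 - 2 * (a^2 + b^2)),
              3, 3, byrow = TRUE)
  sweep(x %*% R, 2, runif(3, -20, 20), "+")
}

# A random symmetric traceless Saupe-like matrix of typical magnitude.
random_saupe <- function(magnitude = 1e-3) {
  m <- matrix(rnorm(9, sd = magnitude), 3, 3)
  m <- (m + t(m)) / 2
  diag(m) <- diag(m) - sum(diag(m)) / 3
  m
}
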