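test_that("karplus_coupling averages the Karplus curve over frames", {
  const <- karplus_parameters("HNHA", 0, 0, 3.0, 0)
  expect_equal(karplus_coupling(c(-120, 33, 7), const), 3.0)
  a_only <- karplus_parameters("HNHA", 1, 0, 0, 0)
  expect_equal(karplus_coupling(0, a_only), 1.0)
  abc <- karplus_parameters("HNHA", 1, 1, 1, 0)
  expect_equal(karplus_coupling(c(0, 180), abc), 2.0)  # mean of 3 and 1
  # phase offset shifts the curve
  shifted <- karplus_parameters("HNHA", 1, 0, 0, -60)
  expect_equal(karplus_coupling(60, shifted), 1.0)
  expect_error(karplus_coupling(numeric(0), abc), "empty")
})

test_that("coupling_agreement computes matched-row RMSD and reports unmatched rows", {
  calc <- coupling_table(1:3, "HNHA", c(5, 6, 7))
  expect_equal(coupling_agreement(calc, calc)$rmsd, 0)
  exp1 <- coupling_table(1:3, "HNHA", c(4, 5, 6))
  expect_equal(coupling_agreement(calc, exp1)$rmsd, 1)
  exp2 <- coupling_table(1:3, "HNHA", c(5, 3, 3))   # diffs 0, 3, 4
  expect_equal(coupling_agreement(calc, exp2)$rmsd, 5 / sqrt(3))
  # permutation invariance in row order
  perm <- exp2[c(3, 1, 2), ]
  expect_equal(coupling_agreement(calc, perm)$rmsd, 5 / sqrt(3))
  # unmatched rows reported, not dropped
  exp3 <- coupling_table(c(2, 3, 9), "HNHA", c(6, 7, 1))
  ag <- coupling_agreement(calc, exp3)
  expect_equal(ag$n_matched, 2)
  expect_setequal(ag$unmatched$side, c("calc_only", "exp_only"))
  expect_error(coupling_agreement(calc, coupling_table(9, "HNCO", 1)),
               "no matched")
})

test_that("alignment tensor fits recover generating tensors and respect rank limits", {
  set.seed(5)
  S <- alignment_tensor(random_saupe(), scale = 21700)
  v <- matrix(rnorm(60), 20, 3)
  rdcs <- generate_rdc_dataset(v, S, noise_sd = 0, seed = 9)
  fit <- fit_alignment_tensor(v, rdcs, scale = 21700)
  expect_lt(max(abs(fit$saupe - S$saupe)), 1e-8)
  expect_lt(abs(sum(diag(fit$saupe))), 1e-12)
  expect_equal(fit$saupe, t(fit$saupe))
  # round-trip identity: refit then back-calculate reproduces inputs
  back <- back_calculate_rdc(v, fit)
  expect_lt(max(abs(back$value_hz - rdcs$value_hz)), 1e-8)
  expect_lt(q_score(back, rdcs), 1e-10)

  zero <- rdc_table(1:20, "N-H", rep(0, 20))
  fit0 <- fit_alignment_tensor(v, zero)
  expect_equal(max(abs(fit0$saupe)), 0, tolerance = 1e-12)

  expect_error(fit_alignment_tensor(v[1:4, ], rdc_table(1:4, "N-H", rnorm(4))),
               "under-determined")
  # >= 5 rows but degenerate directions
  degen <- matrix(rep(c(0, 0, 1), each = 6), 6, 3)
  expect_error(fit_alignment_tensor(degen, rdc_table(1:6, "N-H", rnorm(6))),
               "under-determined")
})

test_that("back_calculate_rdc honours axial geometry", {
  s <- 1e-3
  Sax <- alignment_tensor(diag(c(-s / 2, -s / 2, s)), scale = 100)
  z <- back_calculate_rdc(matrix(c(0, 0, 1), 1, 3), Sax)
  expect_equal(z$value_hz, 100 * s)
  x <- back_calculate_rdc(matrix(c(1, 0, 0), 1, 3), Sax)
  expect_equal(x$value_hz, -100 * s / 2)
  # isotropic bonds average to ~0
  set.seed(8)
  iso <- matrix(rnorm(3 * 5000), 5000, 3)
  iso <- iso / sqrt(rowSums(iso^2))
  dy <- array(0, c(1, 3, 3))
  for (k in seq_len(nrow(iso))) dy[1, , ] <- dy[1, , ] + tcrossprod(iso[k, ])
  dy <- dy / nrow(iso)
  d <- back_calculate_rdc(dy, Sax, pairs = data.frame(residue_index = 1,
                                                      atom_pair = "N-H"))
  expect_lt(abs(d$value_hz), 100 * s * 0.05)
})

test_that("q_score matches hand arithmetic and is rotation-invariant under refit", {
  exp_t <- rdc_table(1:3, "N-H", c(1, -1, 2))
  expect_equal(as.numeric(q_score(exp_t, exp_t)), 0)
  zeros <- rdc_table(1:3, "N-H", c(0, 0, 0))
  expect_equal(as.numeric(q_score(zeros, exp_t)), 1)
  doubled <- rdc_table(1:3, "N-H", c(2, -2, 4))
  expect_equal(as.numeric(q_score(doubled, exp_t)), 1)
  expect_error(q_score(exp_t, zeros), "undefined Q")
  # permutation invariance
  expect_equal(as.numeric(q_score(doubled[c(2, 3, 1), ], exp_t)), 1)

  # Q after tensor refit is invariant to a global rotation of the bonds
  set.seed(13)
  v <- matrix(rnorm(36), 12, 3)
  S <- alignment_tensor(random_saupe(), scale = 21700)
  noisy <- generate_rdc_dataset(v, S, noise_sd = 0.5, seed = 2)
  q1 <- q_score(back_calculate_rdc(v, fit_alignment_tensor(v, noisy, 21700)),
                noisy)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  vr <- apply_random_rigid(v)  # rotation+translation; vectors: rotate only
  vr <- sweep(vr, 2, colMeans(vr) - colMeans(v))  # translation irrelevant
  # rebuild unit vectors by rotating directly
  R <- kabsch_superpose(v, vr)$rotation
  vrot <- v %*% R
  q2 <- q_score(back_calculate_rdc(vrot,
                                   fit_alignment_tensor(vrot, noisy, 21700)),
                noisy)
  expect_equal(as.numeric(q1), as.numeric(q2), tolerance = 1e-6)

  # Q grows linearly in small calc-side perturbations
  eps <- c(0.01, 0.02, 0.04)
  qs <- vapply(eps, function(e) {
    pert <- exp_t; pert$value_hz <- pert$value_hz + e * c(1, 1, -1)
    as.numeric(q_score(pert, exp_t))
  }, numeric(1))
  expect_equal(qs[2] / qs[1], 2, tolerance = 1e-6)
  expect_equal(qs[3] / qs[2], 2, tolerance = 1e-6)
})

test_that("internal ACF reproduces closed-form cases", {
  ref <- build_backbone(5)
  rigid <- conf_ensemble(ref$atoms,
                         array(rep(frame_coords(ref), 40),
                               c(nrow(ref$atoms), 3, 40)),
                         frame_interval = 0.1)
  acf_r <- internal_acf(rigid, max_lag_ns = 2)
  expect_equal(max(abs(acf_r$values - 1)), 0, tolerance = 1e-9)

  # two orientations 90 degrees apart, alternating frames:
  # C(odd lags) = P2(0) = -0.5, C(even lags) = 1
  at <- data.frame(atom_name = c("N", "H", "CA", "C"),
                   residue_index = c(1, 1, 1, 1),
                   residue_name = "ALA", element = c("N", "H", "C", "C"))
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0), c(4.5, 1, 0))
  flip <- base; flip[2, ] <- c(0, 1, 0)
  frames <- rep(list(base, flip), 10)
  ens <- conf_ensemble(at, frames, frame_interval = 1)
  acf_a <- internal_acf(ens, max_lag_ns = 5, superpose = FALSE)
  expect_equal(as.numeric(acf_a$values[c(1, 3, 5), 1]), c(1, 1, 1),
               tolerance = 1e-9)
  expect_equal(as.numeric(acf_a$values[c(2, 4, 6), 1]), c(-0.5, -0.5, -0.5),
               tolerance = 1e-9)

  # i.i.d. isotropic vectors decorrelate
  set.seed(17)
  n <- 10000
  iso_frames <- lapply(seq_len(n), function(f) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    m <- base; m[2, ] <- m[1, ] + u
    m
  })
  iso <- conf_ensemble(at, iso_frames, frame_interval = 1)
  acf_i <- internal_acf(iso, max_lag_ns = 5, superpose = FALSE)
  expect_lt(max(abs(acf_i$values[-1, 1])), 0.02)

  expect_error(internal_acf(ens, max_lag_ns = 100), "shorter")
})

test_that("order_parameter reads the plateau over the tau_c window", {
  fake <- structure(list(lags_ns = seq(0, 10, by = 0.5),
                         values = matrix(1, 21, 1, dimnames = list(NULL, 4)),
                         residues = 4L),
                    class = "internal_acf")
  expect_equal(order_parameter(fake, tau_c_ns = 5)$s2, 1)
  fake$values[] <- 0.8
  expect_equal(order_parameter(fake, tau_c_ns = 5)$s2, 0.8)
  expect_error(order_parameter(fake, tau_c_ns = 50), "no lags")
  fake$values[] <- 1.1
  expect_warning(out <- order_parameter(fake, tau_c_ns = 5), "clipped")
  expect_equal(out$s2, 1)
})

test_that("cone ensembles recover the analytic order parameter", {
  ref <- build_backbone(6)
  for (th in c(20, 60)) {
    ens <- generate_cone_ensemble(ref, theta0_deg = th, n_frames = 4000,
                                  frame_interval_ns = 0.01, tumble = TRUE,
                                  seed = 100 + th)
    acf <- internal_acf(ens, max_lag_ns = 0.36,
                        residues = attr(ens, "s2_true")$residue_index)
    s2 <- order_parameter(acf, tau_c_ns = 0.3)
    expect_lt(max(abs(s2$s2 - cone_s2(th))), 0.03)
  }
})

test_that("agreement panel returns point estimates with block SEMs", {
  # repeated single structure: metrics equal single-structure values, SEM 0
  ref <- build_backbone(8, phi = -63, psi = -42)
  ens <- conf_ensemble(ref$atoms,
                       array(rep(frame_coords(ref), 50),
                             c(nrow(ref$atoms), 3, 50)),
                       frame_interval = 0.1)
  couplings <- calc_couplings(conf_ensemble(ref$atoms, frame_coords(ref)),
                              residues = 3:6)
  set.seed(23)
  S <- alignment_tensor(random_saupe(), scale = 21700)
  pairs <- data.frame(residue_index = 2:8, atom_pair = "N-H")
  rdcs <- generate_rdc_dataset(superpose_frames(ens), S, pairs,
                               noise_sd = 0, seed = 3)
  s2_exp <- data.frame(residue_index = 2:8, s2 = 1)
  class(s2_exp) <- c("order_parameter_table", "data.frame")
  panel <- observable_agreement_panel(
    ens, list(couplings = couplings, rdcs = rdcs, s2 = s2_exp),
    tau_c_ns = 0.5, label = "rigid-helix")
  expect_equal(panel$value[panel$observable == "scalar_couplings"], 0,
               tolerance = 1e-8)
  expect_equal(panel$value[panel$observable == "rdcs"], 0, tolerance = 1e-8)
  expect_equal(panel$value[panel$observable == "order_parameters"], 0,
               tolerance = 1e-6)
  expect_equal(panel$sem, rep(0, 3), tolerance = 1e-7)

  # SEM from hand-chosen block estimates
  expect_equal(block_sem(c(1, 2, 3, 4, 5)), sd(1:5) / sqrt(5))
  expect_equal(block_sem(rep(0.7, 5)), 0)
})
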