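make_indicator_ensemble <- function(phi, psi, n_res = 7) {
  build_backbone(n_res, phi = phi, psi = psi)
}

test_that("helicity assignment applies the dihedral box and run condition", {
  helix <- make_indicator_ensemble(-65, -40)
  a <- assign_helical(helix, min_run = 3)
  assignable <- attr(a, "assignable")
  expect_true(all(a[, assignable]))
  expect_false(any(a[, !assignable]))   # terminals never helical
  expect_equal(helical_fraction(a), 1)

  sheet <- make_indicator_ensemble(-120, 130)
  b <- assign_helical(sheet, min_run = 3)
  expect_false(any(b))
  expect_equal(helical_fraction(b), 0)

  # alternating in-box / out-of-box residues: no run of 3
  phis <- rep(c(-65, -120), length.out = 8)
  psis <- rep(c(-40, 130), length.out = 8)
  alt <- make_indicator_ensemble(phis, psis, 8)
  expect_false(any(assign_helical(alt, min_run = 3)))
  # but runs of 1 are allowed when min_run = 1
  expect_true(any(assign_helical(alt, min_run = 1)))
})

test_that("helical_fraction counts frames x residues", {
  m <- matrix(FALSE, 2, 5)
  m[1, 2:3] <- TRUE; m[2, 4] <- TRUE
  expect_equal(helical_fraction(m), 0.3)
  expect_equal(helical_fraction(matrix(TRUE, 3, 4)), 1)
})

test_that("dual-cutoff state machine matches the worked single-segment example", {
  spec <- dual_cutoff_preset("cln025")
  traj <- dual_cutoff_states(c(5.0, 3.0, 0.8, 2.0, 5.0), spec)
  expect_equal(traj$states,
               c("unfolded", "unfolded", "folded", "folded", "unfolded"))
  expect_equal(traj$events$frame, c(3L, 5L))
  expect_equal(traj$events$kind, c("fold", "unfold"))
  expect_equal(unname(count_events(traj)), c(1L, 1L))
  expect_equal(as.numeric(fraction_folded(traj)), 0.4)

  # hysteresis: series stays between cutoffs after the fold
  traj2 <- dual_cutoff_states(c(5, 0.5, rep(2.5, 20)), spec)
  expect_equal(nrow(traj2$events), 1L)
  expect_true(all(traj2$states[-1] == "folded"))

  # frames before any trigger are undetermined and excluded from fractions
  traj3 <- dual_cutoff_states(c(2, 3, 0.5, 2), spec)
  expect_equal(traj3$states[1:2], c("undetermined", "undetermined"))
  expect_equal(nrow(traj3$events), 0L)  # undetermined -> folded: no event
  expect_equal(as.numeric(fraction_folded(traj3)), 1)
  expect_equal(attr(fraction_folded(traj3), "n_undetermined"), 2L)
  expect_error(fraction_folded(dual_cutoff_states(c(2, 3), spec)),
               "undetermined")
})

test_that("multi-segment folds require simultaneity across all segments", {
  spec <- dual_cutoff_preset("villin-2F4K")
  # segment 3 folds one frame later than the others
  m <- rbind(c(6, 6, 6),
             c(1.0, 0.5, 2.0),   # segs 1-2 below, seg 3 not
             c(1.0, 0.5, 0.5),   # all below -> fold
             c(6, 6, 2.0),       # seg 3 below unfold cutoff -> no unfold
             c(6, 6, 6))         # all above -> unfold
  traj <- dual_cutoff_states(m, spec)
  expect_equal(traj$events$frame, c(3L, 5L))
  expect_equal(traj$events$kind, c("fold", "unfold"))
  expect_error(dual_cutoff_states(m[, 1:2], spec), "segments")
  expect_error(dual_cutoff_states(list(1:3, 1:4), dual_cutoff_preset("cln025")),
               "unequal")
})

test_that("events alternate and counts are balanced on generated traces", {
  spec <- dual_cutoff_preset("cln025")
  for (s in 1:25) {
    g <- generate_two_state_trace(0.8, 1.2, 20, 0.02, seed = 4000 + s)
    traj <- dual_cutoff_states(g$rmsd, spec)
    k <- traj$events$kind
    if (length(k) > 1) expect_true(all(k[-1] != k[-length(k)]))
    ev <- count_events(traj)
    expect_lte(abs(ev["n_fold"] - ev["n_unfold"]), 1)
  }
})

test_that("raising the unfold threshold never increases the event count", {
  set.seed(55)
  base <- dual_cutoff_spec(data.frame(first = NA, last = NA,
                                      fold_threshold = 1,
                                      unfold_threshold = 3))
  loose <- dual_cutoff_spec(data.frame(first = NA, last = NA,
                                       fold_threshold = 1,
                                       unfold_threshold = 4.5))
  for (i in 1:20) {
    trace <- abs(cumsum(rnorm(400, 0, 0.6)))
    n_base <- sum(count_events(dual_cutoff_states(trace, base)))
    n_loose <- sum(count_events(dual_cutoff_states(trace, loose)))
    expect_lte(n_loose, n_base)
  }
})

test_that("fraction_folded is invariant to frame duplication", {
  spec <- dual_cutoff_preset("cln025")
  trace <- c(5, 0.5, 2, 5, 0.5, 2)
  f1 <- as.numeric(fraction_folded(dual_cutoff_states(trace, spec)))
  f3 <- as.numeric(fraction_folded(dual_cutoff_states(rep(trace, each = 3),
                                                      spec)))
  expect_equal(f1, f3)
})

test_that("detect_folding_events thresholds real RMSD series", {
  ref <- build_backbone(10)
  unfolded <- build_backbone(10, phi = -140, psi = 140)  # extended decoy
  frames <- list(frame_coords(unfolded), frame_coords(ref),
                 frame_coords(unfolded))
  ens <- conf_ensemble(ref$atoms, frames)
  spec <- dual_cutoff_spec(data.frame(first = 2L, last = 9L,
                                      fold_threshold = 1,
                                      unfold_threshold = 4),
                           reference = "ideal-helix")
  traj <- detect_folding_events(ens, ref, spec)
  expect_equal(unname(count_events(traj)), c(1L, 1L))
  expect_equal(traj$states, c("unfolded", "folded", "unfolded"))
})

test_that("melting_curve sorts temperatures and propagates block SEMs", {
  pt <- list(list(temperature = 320, indicator = rep(0, 50)),
             list(temperature = 280, indicator = rep(1, 50)))
  mc <- melting_curve(pt)
  expect_equal(mc$temperature, c(280, 320))
  expect_equal(mc$fraction, c(1, 0))
  expect_equal(mc$sem, c(0, 0))
  expect_error(melting_curve(pt[1]), "at least 2")
  expect_error(melting_curve(c(pt, list(list(temperature = 280,
                                             indicator = rep(1, 50))))),
               "duplicate")
  # matrix indicators are averaged over residues per frame
  ind <- matrix(c(1, 0), 50, 4)
  mc2 <- melting_curve(list(list(temperature = 300, indicator = ind),
                            list(temperature = 350, indicator = ind * 0)))
  expect_equal(mc2$fraction, c(0.5, 0))
})

test_that("sampled helix-coil melting curves track the analytic helicity", {
  temps <- c(275, 290, 305, 320, 335)
  w <- helix_propagation_weight(temps)
  hc <- generate_helix_coil_ensemble(15, w, sigma = 0.003, n_frames = 3000,
                                     seed = 77)
  mc <- melting_curve(hc)
  analytic <- vapply(hc, function(e) e$analytic_helicity, numeric(1))
  analytic <- analytic[order(vapply(hc, function(e) e$temperature,
                                    numeric(1)))]
  # monotone decreasing analytic curve for decreasing w(T)
  expect_true(all(diff(analytic) < 0))
  sem <- pmax(mc$sem, 1e-4)
  expect_true(all(abs(mc$fraction - analytic) <= 3.5 * sem))
})
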