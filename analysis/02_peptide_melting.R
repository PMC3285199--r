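#!/usr/bin/env Rscript
# Temperature-dependent secondary-structure propensities.
#
# (a) Helical melting of a 15-residue alanine-like peptide: exact
#     Zimm-Bragg sampling at seven temperatures, compared with the
#     analytic transfer-matrix helicity.
# (b) Two-state hairpin melting: per-temperature two-state traces whose
#     equilibrium constant follows a van't Hoff law; the dual-cutoff
#     detector assigns folded/unfolded states and the fraction folded
#     traces out the melting curve.

suppressMessages(library(ffvalidate))
set.seed(201)
dir.create("results", showWarnings = FALSE)

## (a) helix-coil melting
temps <- seq(275, 335, by = 10)
w <- helix_propagation_weight(temps)   # van't Hoff, dh = -0.9 kcal/mol
hc <- generate_helix_coil_ensemble(15, w, sigma = 0.003, n_frames = 5000,
                                   seed = 202)
helix_curve <- melting_curve(hc)
helix_curve$analytic <- vapply(
  hc[order(vapply(hc, `[[`, 0, "temperature"))],
  `[[`, 0, "analytic_helicity")

cat("Helix-coil melting (15-mer, sigma = 0.003):\n")
print(helix_curve, row.names = FALSE)
cat("\nSampled fractions track the analytic transfer-matrix helicity;",
    "helicity falls steeply with temperature, as designed for an",
    "alanine-rich helical peptide.\n\n")

## (b) two-state hairpin melting via the dual-cutoff detector
spec <- dual_cutoff_preset("cln025")
t_melt <- 340; dh <- -20  # kcal/mol van't Hoff enthalpy of folding
R <- 0.0019872
per_t <- lapply(seq_along(temps), function(i) {
  keq <- exp(-(dh / R) * (1 / temps[i] - 1 / t_melt))
  g <- generate_two_state_trace(
    k_fold = sqrt(keq), k_unfold = 1 / sqrt(keq),
    duration_ns = 50, frame_interval_ns = 0.02,
    folded_level = 0.3, unfolded_level = 6, level_sd = 0.05,
    seed = 203 + i)
  traj <- dual_cutoff_states(g$rmsd, spec)
  list(temperature = temps[i],
       indicator = as.numeric(traj$states == "folded"))
})
fold_curve <- melting_curve(per_t)
cat("Two-state hairpin melting (dual-cutoff fraction folded):\n")
print(fold_curve, row.names = FALSE)
cat("\nFraction folded decreases towards the 340 K midpoint, mirroring",
    "the hairpin melting analysis.\n")

render_report("results/melting",
              curves = list(`helix-15mer` = helix_curve[-5],
                            `hairpin-two-state` = fold_curve))
cat("wrote results/melting/\n")
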