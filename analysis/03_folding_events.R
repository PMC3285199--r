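#!/usr/bin/env Rscript
# Folding-event detection with the multi-segment dual-cutoff scheme.
#
# Emulates the fold/unfold benchmark: for each synthetic "force field"
# scenario we generate two-state traces for a villin-like (3-segment) and a
# WW-like (4-segment) system over a horizon ten times the mean dwell time,
# run the detector with the corresponding preset, and render the event
# grid in the check-mark (n_fold/n_unfold) convention.

suppressMessages(library(ffvalidate))
set.seed(301)
dir.create("results", showWarnings = FALSE)

scenarios <- list(
  # balanced: folds and unfolds reversibly at the melting point
  balanced = list(k_fold = 1, k_unfold = 1),
  # overstabilized: folds once, native state too stable to leave
  overstabilized = list(k_fold = 1, k_unfold = 0.02),
  # non-folder: never reaches the native basin on this horizon
  nonfolder = list(k_fold = 0.001, k_unfold = 1))

systems <- list(
  villin = dual_cutoff_preset("villin-2F4K"),
  ww = dual_cutoff_preset("ww-2F21"))

rows <- list()
for (sc in names(scenarios)) {
  for (sys in names(systems)) {
    spec <- systems[[sys]]
    nseg <- nrow(spec$segments)
    g <- generate_two_state_trace(
      k_fold = scenarios[[sc]]$k_fold, k_unfold = scenarios[[sc]]$k_unfold,
      duration_ns = 10, frame_interval_ns = 0.005,
      folded_level = pmax(spec$segments$fold_threshold - 0.4, 0.05),
      unfolded_level = spec$segments$unfold_threshold + 2,
      level_sd = 0.05, n_segments = nseg,
      seed = 1000 + match(sc, names(scenarios)) * 10 + match(sys, names(systems)))
    traj <- dual_cutoff_states(g$rmsd, spec)
    ev <- count_events(traj)
    stopifnot(identical(traj$events, g$events_true))  # detector vs truth
    rows[[length(rows) + 1L]] <- data.frame(
      force_field = sc, system = sys,
      n_fold = unname(ev["n_fold"]), n_unfold = unname(ev["n_unfold"]))
  }
}
events <- do.call(rbind, rows)
cat("Detected folding/unfolding events (detector equals generator truth):\n")
print(events, row.names = FALSE)
cat("\nA balanced scenario shows reversible folding (~5/5 expected at\n",
    "equal rates over a 10T horizon); the overstabilized one folds and\n",
    "stays folded; the non-folder earns an X in the grid.\n", sep = "")

render_report("results/folding", events = events)
cat("wrote results/folding/\n")
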