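#!/usr/bin/env Rscript
# Native-state NMR benchmark on a synthetic folded protein.
#
# Emulates the folded-protein test: an ensemble with restricted-amplitude
# N-H motion (known per-residue order parameters), plus synthetic
# "experimental" tables of scalar couplings, RDCs and S2 generated from the
# same ground truth with measurement noise. The agreement panel then plays
# the role of the per-protein comparison bars: coupling RMSD (Hz), RDC Q
# factor, and S2 RMSD, each with a block-averaged standard error.

suppressMessages(library(ffvalidate))
set.seed(101)
dir.create("results", showWarnings = FALSE)

n_res <- 16
ref <- build_backbone(n_res, phi = -63, psi = -42)

# restricted internal motion: stiffer core, mobile termini
res_h <- 2:n_res
theta0 <- c(seq(40, 12, length.out = 7),
            rep(12, length(res_h) - 14),
            seq(12, 45, length.out = 7))
ens <- generate_cone_ensemble(ref, theta0_deg = theta0, n_frames = 4000,
                              frame_interval_ns = 0.01, tumble = TRUE,
                              seed = 102)
truth <- attr(ens, "s2_true")

# synthetic experimental S2 table: ground truth + measurement noise
s2_exp <- data.frame(
  residue_index = truth$residue_index,
  s2 = pmin(pmax(truth$s2 + rnorm(nrow(truth), 0, 0.01), 0), 1))
class(s2_exp) <- c("order_parameter_table", "data.frame")

# synthetic experimental couplings: back-calculated from the rigid
# reference phi angles + 0.3 Hz noise (heavy atoms do not move, so the
# ensemble phi distribution is sharp around the reference values)
kp <- default_karplus()
coup_ref <- calc_couplings(ref, residues = 2:(n_res - 1), karplus = kp)
coup_exp <- coupling_table(coup_ref$residue_index, coup_ref$coupling_type,
                           coup_ref$value_hz +
                             rnorm(nrow(coup_ref), 0, 0.3))

# synthetic experimental RDCs from a known alignment tensor + 0.3 Hz noise
saupe <- matrix(c(4e-4, 1e-4, -8e-5,
                  1e-4, -1e-4, 5e-5,
                  -8e-5, 5e-5, -3e-4), 3, 3)
tensor <- alignment_tensor(saupe, scale = 21700)
pairs <- data.frame(residue_index = res_h, atom_pair = "N-H")
rdc_exp <- generate_rdc_dataset(superpose_frames(ens), tensor, pairs,
                                noise_sd = 0.3, seed = 103)

panel <- observable_agreement_panel(
  ens,
  list(couplings = coup_exp, rdcs = rdc_exp, s2 = s2_exp),
  karplus = kp, tau_c_ns = 0.3, label = "synthetic-helix-16")

cat("Native-state agreement panel (synthetic folded protein):\n")
print(panel, row.names = FALSE)
cat("\nInterpretation: coupling RMSD and Q are small but nonzero because\n",
    "the 'experimental' tables carry injected measurement noise; the S2\n",
    "RMSD reflects finite sampling of the cone motion plus table noise.\n",
    sep = "")

render_report("results/native_state", panels = panel)
utils::write.csv(cbind(truth, s2_exp = s2_exp$s2),
                 "results/native_state/s2_truth_vs_exp.csv",
                 row.names = FALSE)
cat("wrote results/native_state/\n")
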