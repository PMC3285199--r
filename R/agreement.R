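# Block averaging: split frame indices into n contiguous blocks and return
# the list of index vectors. Used for standard errors of ensemble-averaged
# observables, which are strongly autocorrelated along the trajectory.
frame_blocks <- function(n_frames, n_blocks) {
  if (n_blocks < 2) stop("need at least 2 blocks for a standard error")
  if (n_frames < n_blocks) stop("fewer frames than blocks")
  cut_ids <- ceiling(seq_len(n_frames) / (n_frames / n_blocks))
  split(seq_len(n_frames), pmin(cut_ids, n_blocks))
}

#' Standard error of the mean from contiguous block estimates
#'
#' @param block_values one estimate per block.
#' @return `sd(block_values) / sqrt(n_blocks)`; 0 for constant blocks.
#' @export
block_sem <- function(block_values) {
  n <- length(block_values)
  if (n < 2) stop("need at least 2 block estimates")
  s <- stats::sd(block_values)
  if (!is.finite(s)) s <- 0
  s / sqrt(n)
}

subset_frames <- function(ensemble, idx) {
  conf_ensemble(ensemble$atoms,
                ensemble$coords[, , idx, drop = FALSE],
                frame_interval = ensemble$frame_interval,
                temperature = ensemble$temperature)
}

#' Per-observable agreement panel with block standard errors
#'
#' Runs the full native-state comparison for one protein: back-calculates
#' scalar couplings, RDCs (refitting the alignment tensor) and order
#' parameters from the ensemble, quantifies agreement with the experimental
#' tables (coupling RMSD in Hz, RDC Q factor, S^2 RMSD), and attaches a
#' standard error of the mean for each metric from contiguous block
#' averaging (each block re-analyzed independently, including its own
#' tensor refit).
#'
#' @param ensemble a [conf_ensemble]; frames are superposed internally
#'   where the observable requires a common molecular frame.
#' @param experiments list with any of `couplings` ([coupling_table]),
#'   `rdcs` ([rdc_table]), `s2` (`order_parameter_table`).
#' @param karplus named list of [karplus_parameters].
#' @param tau_c_ns rotational correlation time for S^2 extraction (ns);
#'   required when `experiments$s2` is given.
#' @param s2_window relative half-width of the S^2 lag window.
#' @param rdc_scale coupling scale passed to the tensor fit.
#' @param n_blocks number of contiguous blocks for the SEM.
#' @param label protein/system label copied into the output.
#' @return data.frame of class `agreement_panel`: one row per observable
#'   with columns `system`, `observable`, `metric`, `value`, `sem`, `n`.
#' @export
observable_agreement_panel <- function(ensemble, experiments,
                                       karplus = default_karplus(),
                                       tau_c_ns = NULL, s2_window = 0.2,
                                       rdc_scale = 1, n_blocks = 5,
                                       label = "system") {
  rows <- list()
  blocks <- frame_blocks(n_frames(ensemble), n_blocks)
  add_row <- function(observable, metric, value, sem, n)
    rows[[length(rows) + 1L]] <<- data.frame(
      system = label, observable = observable, metric = metric,
      value = value, sem = sem, n = n, stringsAsFactors = FALSE)

  if (!is.null(experiments$couplings)) {
    res <- unique(experiments$couplings$residue_index)
    full <- coupling_agreement(calc_couplings(ensemble, res, karplus),
                               experiments$couplings)
    per_block <- vapply(blocks, function(idx)
      coupling_agreement(calc_couplings(subset_frames(ensemble, idx),
                                        res, karplus),
                         experiments$couplings)$rmsd, numeric(1))
    add_row("scalar_couplings", "rmsd_hz", full$rmsd,
            block_sem(per_block), full$n_matched)
  }

  if (!is.null(experiments$rdcs)) {
    sup <- superpose_frames(ensemble)
    q_of <- function(ens) {
      dy <- bond_dyadics(ens, experiments$rdcs)
      tensor <- fit_alignment_tensor(dy, experiments$rdcs, rdc_scale)
      calc <- back_calculate_rdc(dy, tensor)
      as.numeric(q_score(calc, experiments$rdcs))
    }
    per_block <- vapply(blocks, function(idx) q_of(subset_frames(sup, idx)),
                        numeric(1))
    add_row("rdcs", "q_factor", q_of(sup), block_sem(per_block),
            nrow(experiments$rdcs))
  }

  if (!is.null(experiments$s2)) {
    if (is.null(tau_c_ns)) stop("tau_c_ns required for S^2 agreement")
    s2_rmsd <- function(ens) {
      acf <- internal_acf(ens, max_lag_ns = tau_c_ns * (1 + s2_window),
                          residues = experiments$s2$residue_index)
      calc <- order_parameter(acf, tau_c_ns, s2_window)
      m <- merge(calc, experiments$s2, by = "residue_index",
                 suffixes = c("_calc", "_exp"))
      if (!nrow(m)) stop("no matched S^2 residues")
      sqrt(mean((m$s2_calc - m$s2_exp)^2))
    }
    per_block <- vapply(blocks, function(idx)
      s2_rmsd(subset_frames(ensemble, idx)), numeric(1))
    add_row("order_parameters", "s2_rmsd", s2_rmsd(ensemble),
            block_sem(per_block), nrow(experiments$s2))
  }

  if (!length(rows)) stop("`experiments` supplied no observable tables")
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_panel", "data.frame")
  out
}
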