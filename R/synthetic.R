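#' Two-state folding/unfolding trace generator
#'
#' Samples a continuous-time two-state Markov chain (exponential dwell
#' times with rates `k_fold` out of the unfolded state and `k_unfold` out
#' of the folded state), discretizes it at the frame interval, and emits a
#' per-segment C-alpha-RMSD-like trace as the state's mean level plus
#' Gaussian noise. Ground truth (the discretized state sequence and its
#' transition events) is returned alongside, so detector output can be
#' compared exactly.
#'
#' With equal rates `1/T` and a horizon of `10 T` -- the design of a
#' folding benchmark run ten times longer than the experimental folding
#' time at the melting temperature -- one expects roughly five folding and
#' five unfolding events per trace.
#'
#' @param k_fold,k_unfold rates in 1/ns (>= 0; 0 makes the state
#'   absorbing).
#' @param duration_ns trace length in ns.
#' @param frame_interval_ns time per frame in ns.
#' @param folded_level,unfolded_level per-segment mean RMSD levels in
#'   Angstrom (recycled to `n_segments`); separable traces need
#'   `folded_level < fold thresholds < unfold thresholds < unfolded_level`.
#' @param level_sd Gaussian noise s.d. in Angstrom.
#' @param n_segments number of RMSD series to emit.
#' @param start initial state.
#' @param seed integer seed (mandatory: generators must be reproducible).
#' @return list with `rmsd` (frames x segments matrix), `states_true`
#'   (character per frame), `events_true` (data.frame `frame`, `kind`) and
#'   `params`.
#' @export
generate_two_state_trace <- function(k_fold, k_unfold, duration_ns,
                                     frame_interval_ns,
                                     folded_level = 0.4,
                                     unfolded_level = 6.0,
                                     level_sd = 0.1, n_segments = 1L,
                                     start = c("unfolded", "folded"),
                                     seed) {
  start <- match.arg(start)
  stopifnot(k_fold >= 0, k_unfold >= 0, duration_ns >= 0,
            frame_interval_ns > 0)
  set.seed(as.integer(seed))
  folded_level <- rep_len(folded_level, n_segments)
  unfolded_level <- rep_len(unfolded_level, n_segments)

  n <- floor(duration_ns / frame_interval_ns + 1e-9)
  params <- list(k_fold = k_fold, k_unfold = k_unfold,
                 duration_ns = duration_ns,
                 frame_interval_ns = frame_interval_ns,
                 folded_level = folded_level,
                 unfolded_level = unfolded_level,
                 level_sd = level_sd, start = start, seed = seed)
  if (n == 0)
    return(list(rmsd = matrix(numeric(0), 0, n_segments),
                states_true = character(0),
                events_true = data.frame(frame = integer(0),
                                         kind = character(0)),
                params = params))

  # continuous-time state path
  trans_times <- numeric(0)
  state <- start; t_now <- 0
  repeat {
    rate <- if (state == "unfolded") k_fold else k_unfold
    if (rate == 0) break
    t_now <- t_now + stats::rexp(1, rate)
    if (t_now >= duration_ns) break
    trans_times <- c(trans_times, t_now)
    state <- if (state == "unfolded") "folded" else "unfolded"
  }
  frame_times <- seq_len(n) * frame_interval_ns
  n_before <- findInterval(frame_times, trans_times)
  seq_states <- if (start == "unfolded") c("unfolded", "folded")
                else c("folded", "unfolded")
  states <- seq_states[(n_before %% 2) + 1L]

  chg <- which(states[-1] != states[-n]) + 1L
  events <- data.frame(
    frame = chg,
    kind = as.character(ifelse(states[chg] == "folded", "fold", "unfold")),
    stringsAsFactors = FALSE)

  level <- function(st, seg) ifelse(st == "folded",
                                    folded_level[seg], unfolded_level[seg])
  rmsd <- vapply(seq_len(n_segments), function(seg)
    pmax(level(states, seg) + stats::rnorm(n, 0, level_sd), 0),
    numeric(n))
  if (n == 1L) rmsd <- matrix(rmsd, 1L)

  list(rmsd = rmsd, states_true = states, events_true = events,
       params = params)
}

# ---- Zimm-Bragg helix-coil chain ------------------------------------------

# Transfer matrix with states ordered (coil, helix): propagation weight w
# per helical residue, nucleation penalty sigma on each coil->helix (or
# chain-start) helix.
zb_matrix <- function(w, sigma) {
  matrix(c(1, 1, sigma * w, w), 2, 2,
         dimnames = list(c("c", "h"), c("c", "h")))
}

# Backward vectors b[i, s] = sum over completions from residue i+1..n given
# state s at residue i; b[n, ] = 1.
zb_backward <- function(n_res, w, sigma) {
  M <- zb_matrix(w, sigma)
  b <- matrix(1, n_res, 2, dimnames = list(NULL, c("c", "h")))
  for (i in rev(seq_len(n_res - 1)))
    b[i, ] <- as.numeric(M %*% b[i + 1, ])
  b
}

#' Analytic mean helicity of the nucleation-propagation chain
#'
#' Exact per-chain mean fraction of helical residues under the
#' Zimm-Bragg-type distribution with propagation weight `w` and nucleation
#' penalty `sigma`, computed by the transfer-matrix forward-backward
#' recursion.
#'
#' @param n_res chain length.
#' @param w helix propagation weight (> 0); may be temperature dependent.
#' @param sigma nucleation penalty in (0, 1].
#' @return mean helicity in [0, 1].
#' @export
helix_coil_helicity <- function(n_res, w, sigma) {
  stopifnot(n_res >= 1, w > 0, sigma > 0, sigma <= 1)
  M <- zb_matrix(w, sigma)
  b <- zb_backward(n_res, w, sigma)
  f <- matrix(0, n_res, 2, dimnames = list(NULL, c("c", "h")))
  f[1, ] <- c(1, sigma * w)
  if (n_res > 1)
    for (i in 2:n_res) f[i, ] <- as.numeric(f[i - 1, ] %*% M)
  Z <- sum(f[n_res, ])
  p_h <- vapply(seq_len(n_res), function(i) f[i, "h"] * b[i, "h"] / Z,
                numeric(1))
  mean(p_h)
}

#' Exact sampler for the helix-coil chain
#'
#' Draws residue state strings from the exact Zimm-Bragg-type distribution
#' by conditional (backward-weighted) sampling, one temperature at a time,
#' and returns the analytic mean helicity from the same transfer matrix so
#' estimators can be validated against ground truth.
#'
#' @param n_res chain length.
#' @param w_by_temperature named numeric vector: helix propagation weight
#'   at each temperature (names are temperatures in K, or pass
#'   `temperatures`).
#' @param sigma nucleation penalty in (0, 1].
#' @param n_frames chains sampled per temperature.
#' @param temperatures numeric temperatures (K); defaults to the names of
#'   `w_by_temperature`.
#' @param seed integer seed.
#' @return list with one entry per temperature: `temperature`, `indicator`
#'   (n_frames x n_res logical matrix), `analytic_helicity`.
#' @export
generate_helix_coil_ensemble <- function(n_res, w_by_temperature, sigma,
                                         n_frames, temperatures = NULL,
                                         seed) {
  if (is.null(temperatures))
    temperatures <- as.numeric(names(w_by_temperature))
  stopifnot(length(temperatures) == length(w_by_temperature),
            !anyNA(temperatures))
  set.seed(as.integer(seed))
  out <- vector("list", length(temperatures))
  for (t in seq_along(temperatures)) {
    w <- as.numeric(w_by_temperature[t])
    b <- zb_backward(n_res, w, sigma)
    M <- zb_matrix(w, sigma)
    ind <- matrix(FALSE, n_frames, n_res)
    w1 <- c(1, sigma * w) * b[1, ]
    for (f in seq_len(n_frames)) {
      s <- integer(n_res)  # 1 = coil, 2 = helix
      s[1] <- sample.int(2, 1, prob = w1)
      if (n_res > 1) for (i in 2:n_res) {
        pw <- M[s[i - 1], ] * b[i, ]
        s[i] <- sample.int(2, 1, prob = pw)
      }
      ind[f, ] <- s == 2L
    }
    out[[t]] <- list(temperature = temperatures[t], indicator = ind,
                     analytic_helicity = helix_coil_helicity(n_res, w, sigma))
  }
  names(out) <- temperatures
  out
}

#' Temperature-dependent helix propagation weights
#'
#' A van't Hoff parameterization `w(T) = exp(-(dh/R) * (1/T - 1/T_m))`
#' giving `w = 1` at the per-residue melting temperature `T_m`. The default
#' enthalpy (-0.9 kcal/mol per residue) and nucleation penalty used with it
#' elsewhere in the package (sigma ~ 0.003) are in the range classically
#' fitted for short alanine-rich helical peptides.
#'
#' @param temperatures_k temperatures in K.
#' @param dh_kcal helix propagation enthalpy in kcal/mol (negative:
#'   helicity decreases with temperature).
#' @param t_melt_k per-residue melting temperature in K.
#' @return named numeric vector of weights.
#' @export
helix_propagation_weight <- function(temperatures_k, dh_kcal = -0.9,
                                     t_melt_k = 295) {
  R <- 0.0019872  # kcal / (mol K)
  w <- exp(-(dh_kcal / R) * (1 / temperatures_k - 1 / t_melt_k))
  names(w) <- temperatures_k
  w
}

# ---- Diffusion-in-a-cone bond-vector motion -------------------------------

#' Analytic order parameter of the uniform-cone model
#'
#' For a bond vector uniformly distributed inside a cone of half-angle
#' theta0 about a fixed axis, `S^2 = (cos(theta0) (1 + cos(theta0)) / 2)^2`.
#'
#' @param theta0_deg cone half-angle in degrees, in [0, 90].
#' @return S^2 in [0, 1].
#' @export
cone_s2 <- function(theta0_deg) {
  stopifnot(all(theta0_deg >= 0), all(theta0_deg <= 90))
  ct <- cos(theta0_deg * pi / 180)
  (ct * (1 + ct) / 2)^2
}

#' Cone-motion ensemble generator
#'
#' Builds an ensemble in which each residue's amide N-H vector is redrawn
#' every frame uniformly within a cone about its reference orientation
#' while all heavy atoms stay at the reference geometry -- restricted
#' internal motion with a known order parameter per residue. Optionally a
#' random global rotation and translation is applied to every frame so
#' that tumbling-removal code can be exercised; with `tumble = FALSE`
#' frames share the molecular frame.
#'
#' @param reference a one-frame [conf_ensemble] containing N, H (and
#'   backbone heavy atoms); default [build_backbone()] helix. Residues
#'   without an H (chain start) are held rigid.
#' @param theta0_deg cone half-angle(s) in degrees, recycled across
#'   residues carrying an H.
#' @param n_frames frames to generate.
#' @param frame_interval_ns time per frame (ns), stored on the ensemble.
#' @param tumble apply a random global rigid motion per frame.
#' @param seed integer seed.
#' @return a `conf_ensemble` with attribute `"s2_true"` (data.frame
#'   `residue_index`, `theta0_deg`, `s2`).
#' @export
generate_cone_ensemble <- function(reference = NULL, theta0_deg = 20,
                                   n_frames = 1000,
                                   frame_interval_ns = 0.01,
                                   tumble = FALSE, seed) {
  set.seed(as.integer(seed))
  if (is.null(reference)) reference <- build_backbone(8)
  at <- reference$atoms
  res_h <- sort(unique(at$residue_index[at$atom_name == "H"]))
  if (!length(res_h)) stop("reference carries no amide H atoms")
  theta0_deg <- rep_len(theta0_deg, length(res_h))
  ref <- frame_coords(reference, 1L)

  i_n <- atom_rows(at, res_h, "N")
  i_h <- atom_rows(at, res_h, "H")
  bond <- sqrt(rowSums((ref[i_h, , drop = FALSE] -
                        ref[i_n, , drop = FALSE])^2))
  axes <- (ref[i_h, , drop = FALSE] - ref[i_n, , drop = FALSE]) / bond

  coords <- array(rep(ref, n_frames), dim = c(nrow(at), 3, n_frames))
  for (j in seq_along(res_h)) {
    u <- axes[j, ]
    basis <- orthonormal_basis(u)
    ct0 <- cos(theta0_deg[j] * pi / 180)
    ct <- stats::runif(n_frames, ct0, 1)
    ph <- stats::runif(n_frames, 0, 2 * pi)
    st <- sqrt(pmax(1 - ct^2, 0))
    dirs <- outer(ct, u) +
      outer(st * cos(ph), basis$e1) + outer(st * sin(ph), basis$e2)
    for (f in seq_len(n_frames))
      coords[i_h[j], , f] <- coords[i_n[j], , f] + bond[j] * dirs[f, ]
  }
  if (tumble) {
    for (f in seq_len(n_frames)) {
      R <- random_rotation()
      shift <- stats::runif(3, -10, 10)
      coords[, , f] <- sweep(coords[, , f] %*% R, 2, shift, "+")
    }
  }
  out <- conf_ensemble(at, coords, frame_interval = frame_interval_ns,
                       temperature = reference$temperature)
  attr(out, "s2_true") <- data.frame(residue_index = res_h,
                                     theta0_deg = theta0_deg,
                                     s2 = cone_s2(theta0_deg))
  out
}

orthonormal_basis <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize(a - sum(a * u) * u)
  e2 <- cross3(matrix(u, 1, 3), matrix(e1, 1, 3))[1, ]
  list(e1 = e1, e2 = e2)
}

# Uniform random rotation via quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# ---- Observable datasets with known generating truth ----------------------

#' RDC dataset generator
#'
#' Back-calculates couplings from a known alignment tensor over the given
#' bond geometry and adds Gaussian noise; the generating tensor and the
#' noiseless values are recorded so tensor refits and Q factors can be
#' checked against truth.
#'
#' @param coords bond geometry (unit-vector matrix, dyadic array, or
#'   `conf_ensemble`) as in [fit_alignment_tensor()].
#' @param tensor an [alignment_tensor].
#' @param pairs data.frame `residue_index`, `atom_pair` labelling rows.
#' @param noise_sd Gaussian noise s.d. in Hz.
#' @param seed integer seed.
#' @return an [rdc_table] with attributes `"tensor_true"` and
#'   `"value_true_hz"`.
#' @export
generate_rdc_dataset <- function(coords, tensor, pairs = NULL,
                                 noise_sd = 0, seed) {
  set.seed(as.integer(seed))
  clean <- back_calculate_rdc(coords, tensor, pairs)
  noisy <- clean
  noisy$value_hz <- clean$value_hz + stats::rnorm(nrow(clean), 0, noise_sd)
  attr(noisy, "tensor_true") <- tensor
  attr(noisy, "value_true_hz") <- clean$value_hz
  noisy
}

#' Scalar-coupling dataset generator
#'
#' Draws per-residue phi samples from the supplied distributions, forms
#' ensemble-mean Karplus couplings, adds Gaussian noise, and records the
#' noiseless means as ground truth.
#'
#' @param phi_samples list (one entry per residue) of per-frame phi angles
#'   in degrees, or a frames x residues matrix with residue indices as
#'   column names.
#' @param params a [karplus_parameters] object.
#' @param noise_sd Gaussian noise s.d. in Hz.
#' @param seed integer seed.
#' @return a [coupling_table] with attribute `"value_true_hz"`.
#' @export
generate_coupling_dataset <- function(phi_samples, params, noise_sd = 0,
                                      seed) {
  set.seed(as.integer(seed))
  if (is.matrix(phi_samples)) {
    res <- as.integer(colnames(phi_samples))
    if (anyNA(res)) res <- seq_len(ncol(phi_samples))
    phi_samples <- lapply(seq_len(ncol(phi_samples)),
                          function(j) phi_samples[, j])
  } else {
    res <- as.integer(names(phi_samples))
    if (!length(res) || anyNA(res)) res <- seq_along(phi_samples)
  }
  truth <- vapply(phi_samples, karplus_coupling, numeric(1),
                  params = params)
  out <- coupling_table(res, params$coupling_type,
                        truth + stats::rnorm(length(truth), 0, noise_sd))
  attr(out, "value_true_hz") <- truth
  out
}
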