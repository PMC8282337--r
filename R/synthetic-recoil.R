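#' Parameters for a synthetic recoil trajectory
#'
#' Bundles the Kelvin-Voigt generative parameters for one ablated junction.
#' The simulated interface starts at length `L0`; after ablation the
#' vertex-to-vertex distance follows `L0 + D * (1 - exp(-t / tau))`, with t
#' measured from the last pre-ablation frame, and isotropic Gaussian tracking
#' noise added to each vertex coordinate at every frame.
#'
#' Defaults mirror the reference acquisition: one frame every 4 s, 9
#' post-ablation frames covering 36 s.
#'
#' @param L0 Pre-ablation interface length, micrometres (> 0).
#' @param D Asymptotic recoil amplitude, micrometres (>= 0).
#' @param tau Relaxation time, seconds (> 0); the viscosity-to-elasticity
#'   ratio of the tissue.
#' @param frame_interval Seconds between frames (default 4).
#' @param n_pre Number of pre-ablation frames (>= 1).
#' @param n_post Number of post-ablation frames (default 9, i.e. 36 s).
#' @param noise_sd Gaussian positional noise s.d. per vertex coordinate per
#'   frame, micrometres (default 0.05, a manual-tracking jitter proxy).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `recoil_sim_params`.
#' @export
recoil_sim_params <- function(L0 = 3, D = 1.2, tau = 10, frame_interval = 4,
                              n_pre = 1L, n_post = 9L, noise_sd = 0.05,
                              seed = 1L) {
  check_positive(L0, "L0")
  check_nonneg(D, "D")
  check_positive(tau, "tau")
  check_positive(frame_interval, "frame_interval")
  check_nonneg(noise_sd, "noise_sd")
  n_pre <- check_count(n_pre, "n_pre", 1L)
  n_post <- check_count(n_post, "n_post", 2L)
  structure(list(L0 = L0, D = D, tau = tau, frame_interval = frame_interval,
                 n_pre = n_pre, n_post = n_post, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "recoil_sim_params")
}

#' Simulate the recoil trajectory of one ablated junction
#'
#' Places the two tricellular vertices symmetrically on the x axis and moves
#' them apart after ablation according to the Kelvin-Voigt recoil
#' `L(t) = L0 + D * (1 - exp(-t / tau))`, the damped recoil of an elastic
#' fibre under parallel spring-dashpot mechanics. Time t = 0 is the last
#' pre-ablation frame; the first post-ablation frame is imaged one frame
#' interval later. Independent Gaussian noise of s.d. `noise_sd` is added to
#' every vertex coordinate at every frame.
#'
#' The generating parameters are attached as attribute `"truth"` so recovery
#' tests can compare estimates against ground truth.
#'
#' @param params A [recoil_sim_params()] object.
#' @param track_id Identifier for the simulated track.
#' @return A [vertex_track()] with attribute `truth` (the generating
#'   parameters).
#' @examples
#' tr <- simulate_recoil_track(recoil_sim_params(L0 = 2, D = 1.5, tau = 10, noise_sd = 0))
#' interface_length(tr)$L
#' @export
simulate_recoil_track <- function(params, track_id = "sim") {
  if (!inherits(params, "recoil_sim_params")) {
    stop("'params' must be a recoil_sim_params object", call. = FALSE)
  }
  p <- params
  n <- p$n_pre + p$n_post
  times <- (seq_len(n) - 1L) * p$frame_interval
  t_rel <- times - times[p$n_pre]
  L <- ifelse(t_rel <= 0, p$L0, p$L0 + p$D * (1 - exp(-t_rel / p$tau)))
  half <- L / 2
  v1 <- cbind(-half, rep(0, n))
  v2 <- cbind(half, rep(0, n))
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed, matrix(stats::rnorm(4L * n, sd = p$noise_sd), n, 4L))
    v1 <- v1 + noise[, 1:2]
    v2 <- v2 + noise[, 3:4]
  }
  tr <- vertex_track(track_id, times, v1, v2, ablation_frame = p$n_pre - 1L)
  attr(tr, "truth") <- list(L0 = p$L0, D = p$D, tau = p$tau,
                            noise_sd = p$noise_sd, seed = p$seed)
  tr
}

#' Specification of a per-condition ensemble of recoil experiments
#'
#' Describes a condition as a set of replicate junctions (one per embryo),
#' whose generating parameters (L0, D, tau) vary between replicates following
#' lognormal distributions parameterised by arithmetic mean and coefficient of
#' variation. Lognormal variability keeps all parameters positive.
#'
#' Default means and CVs emulate the control regime of embryonic epidermis
#' ablations: mean tau 10 s with ~10% spread, recoil amplitudes giving initial
#' retraction velocities around 0.1 um/s.
#'
#' @param n_replicates Number of junctions/embryos in the condition.
#' @param L0_mean,D_mean,tau_mean Arithmetic means of the per-replicate
#'   generating parameters (micrometres, micrometres, seconds).
#' @param L0_cv,D_cv,tau_cv Coefficients of variation (>= 0) of the
#'   inter-replicate lognormal variability.
#' @param noise_sd Per-frame vertex tracking noise, micrometres.
#' @param frame_interval,n_pre,n_post Acquisition layout, as in
#'   [recoil_sim_params()].
#' @param seed Integer seed; replicate-level seeds are derived
#'   deterministically from it.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_replicates = 17L, L0_mean = 3, D_mean = 1.2,
                          tau_mean = 10, L0_cv = 0.2, D_cv = 0.25,
                          tau_cv = 0.1, noise_sd = 0.05, frame_interval = 4,
                          n_pre = 1L, n_post = 9L, seed = 1L) {
  n_replicates <- check_count(n_replicates, "n_replicates", 1L)
  check_positive(L0_mean, "L0_mean"); check_nonneg(D_mean, "D_mean")
  check_positive(tau_mean, "tau_mean")
  check_nonneg(L0_cv, "L0_cv"); check_nonneg(D_cv, "D_cv"); check_nonneg(tau_cv, "tau_cv")
  check_nonneg(noise_sd, "noise_sd")
  structure(list(n_replicates = n_replicates,
                 L0_mean = L0_mean, D_mean = D_mean, tau_mean = tau_mean,
                 L0_cv = L0_cv, D_cv = D_cv, tau_cv = tau_cv,
                 noise_sd = noise_sd, frame_interval = frame_interval,
                 n_pre = n_pre, n_post = n_post, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Simulate an ensemble of recoil tracks for one condition
#'
#' Draws per-replicate (L0, D, tau) from the lognormal distributions in the
#' spec, then simulates one track per replicate with
#' [simulate_recoil_track()]. Replicate seeds are derived deterministically
#' from `spec$seed` (fixed prime stride), so every element of the ensemble is
#' individually reproducible.
#'
#' @param spec An [ensemble_spec()].
#' @param id_prefix Prefix for track identifiers.
#' @return A list of [vertex_track()]s, with attribute `truth`: a data frame
#'   of the generating parameters per replicate.
#' @export
simulate_condition_ensemble <- function(spec, id_prefix = "junction") {
  if (!inherits(spec, "ensemble_spec")) {
    stop("'spec' must be an ensemble_spec object", call. = FALSE)
  }
  n <- spec$n_replicates
  pars <- with_seed(spec$seed, data.frame(
    L0 = rlnorm_mean_cv(n, spec$L0_mean, spec$L0_cv),
    D = rlnorm_mean_cv(n, spec$D_mean, spec$D_cv),
    tau = rlnorm_mean_cv(n, spec$tau_mean, spec$tau_cv)
  ))
  tracks <- lapply(seq_len(n), function(i) {
    simulate_recoil_track(
      recoil_sim_params(L0 = pars$L0[i], D = pars$D[i], tau = pars$tau[i],
                        frame_interval = spec$frame_interval,
                        n_pre = spec$n_pre, n_post = spec$n_post,
                        noise_sd = spec$noise_sd,
                        seed = replicate_seed(spec$seed, i)),
      track_id = sprintf("%s%02d", id_prefix, i))
  })
  pars$track_id <- vapply(tracks, `[[`, character(1), "track_id")
  attr(tracks, "truth") <- pars
  tracks
}
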