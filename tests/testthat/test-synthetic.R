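test_that("noiseless recoil tracks follow the Kelvin-Voigt closed form", {
  tr <- simulate_recoil_track(recoil_sim_params(L0 = 2, D = 1.5, tau = 10,
                                                noise_sd = 0))
  s <- interface_length(tr)
  expect_equal(s$L[s$ablation_index + 1], 2 + 1.5 * (1 - exp(-0.4)),
               tolerance = 1e-12)
  # every frame, several parameter combinations
  for (D in c(0.5, 1, 2)) {
    for (tau in c(5, 10, 20)) {
      tr <- simulate_recoil_track(recoil_sim_params(L0 = 3, D = D, tau = tau,
                                                    noise_sd = 0, n_pre = 2))
      s <- interface_length(tr)
      expect_equal(s$L, kv_length(s$t, 3, D, tau), tolerance = 1e-9)
    }
  }
})

test_that("zero-amplitude recoil leaves the interface length constant", {
  tr <- simulate_recoil_track(recoil_sim_params(L0 = 2.5, D = 0, tau = 7,
                                                noise_sd = 0))
  expect_equal(interface_length(tr)$L, rep(2.5, 10), tolerance = 1e-12)
})

test_that("generators are deterministic given the seed", {
  p <- recoil_sim_params(noise_sd = 0.1, seed = 99L)
  expect_identical(simulate_recoil_track(p), simulate_recoil_track(p))
  sp <- ensemble_spec(n_replicates = 4L, seed = 7L)
  expect_identical(simulate_condition_ensemble(sp), simulate_condition_ensemble(sp))
  expect_identical(synth_epithelium_image(n_cells = 4L, seed = 3L),
                   synth_epithelium_image(n_cells = 4L, seed = 3L))
  expect_identical(synth_clone_widths(seed = 11L), synth_clone_widths(seed = 11L))
  # generators do not disturb the session RNG
  set.seed(123); before <- .Random.seed
  invisible(simulate_recoil_track(p))
  expect_identical(.Random.seed, before)
})

test_that("invalid simulation parameters are rejected naming the field", {
  expect_error(recoil_sim_params(L0 = -1), "L0")
  expect_error(recoil_sim_params(tau = 0), "tau")
  expect_error(recoil_sim_params(noise_sd = -0.1), "noise_sd")
  expect_error(recoil_sim_params(n_post = 1), "n_post")
  expect_error(synth_epithelium_image(punctateness = -0.5), "punctateness")
  expect_error(synth_clone_widths(clone_fraction = 1.2), "clone_fraction")
})

test_that("degenerate ensembles collapse to identical replicates", {
  sp <- ensemble_spec(n_replicates = 17L, L0_cv = 0, D_cv = 0, tau_cv = 0,
                      noise_sd = 0, seed = 1L)
  tracks <- simulate_condition_ensemble(sp)
  expect_length(tracks, 17L)
  L <- lapply(tracks, function(tr) interface_length(tr)$L)
  for (i in 2:17) expect_equal(L[[i]], L[[1]], tolerance = 0)
})

test_that("ensemble variability matches the requested lognormal moments", {
  sp <- ensemble_spec(n_replicates = 12L, tau_mean = 10, tau_cv = 0.1, seed = 5L)
  truth <- attr(simulate_condition_ensemble(sp), "truth")
  expect_equal(nrow(truth), 12L)
  expect_lt(abs(mean(truth$tau) - 10) / 10, 0.10)
  # law of large numbers at larger n
  sp2 <- ensemble_spec(n_replicates = 400L, tau_mean = 10, tau_cv = 0.1, seed = 6L)
  truth2 <- attr(simulate_condition_ensemble(sp2), "truth")
  expect_lt(abs(mean(truth2$tau) - 10) / 10, 0.02)
  expect_lt(abs(sd(truth2$tau) / mean(truth2$tau) - 0.1), 0.02)
})

test_that("synthetic epithelium honours its contracts", {
  epi <- synth_epithelium_image(n_cells = 9L, seed = 2L)
  expect_true(all(epi$stack$data >= 0))
  expect_identical(dim(epi$junction_mask), dim(epi$stack$data)[2:3])
  expect_gt(sum(epi$junction_mask), 0)
  # uniform junctions, no noise, regular lattice: junction linescan is constant
  epi0 <- synth_epithelium_image(n_cells = 9L, punctateness = 0,
                                 background_noise_sd = 0, jitter = 0, seed = 2L)
  ends <- junction_linescan_endpoints(epi0)
  prof <- extract_linescan(max_project(epi0$stack), ends$p0, ends$p1,
                           epi0$stack$pixel_size)
  expect_equal(linescan_stats(prof)$heterogeneity, 0, tolerance = 1e-12)
})

test_that("punctate junctions score higher heterogeneity than uniform ones", {
  for (seed in 1:5) {
    epi_u <- synth_epithelium_image(n_cells = 9L, punctateness = 0,
                                    background_noise_sd = 0, seed = seed)
    epi_p <- synth_epithelium_image(n_cells = 9L, punctateness = 0.5,
                                    background_noise_sd = 0, seed = seed)
    ends <- junction_linescan_endpoints(epi_u)
    ps <- epi_u$stack$pixel_size
    h_u <- linescan_stats(extract_linescan(max_project(epi_u$stack),
                                           ends$p0, ends$p1, ps))$heterogeneity
    h_p <- linescan_stats(extract_linescan(max_project(epi_p$stack),
                                           ends$p0, ends$p1, ps))$heterogeneity
    expect_gt(h_p, h_u)
  }
})

test_that("clone width generator recovers the programmed constriction", {
  s1 <- synth_clone_widths(constriction_factor = 1, width_cv = 0, seed = 1L)
  expect_equal(clone_ratio(s1)$ratio, 1, tolerance = 1e-12)
  s2 <- synth_clone_widths(constriction_factor = 0.6, width_cv = 0, seed = 1L)
  expect_equal(clone_ratio(s2)$ratio, 0.6, tolerance = 1e-12)
  truth <- attr(s2, "truth")
  expect_equal(truth$constriction_factor, 0.6)
})
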