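make_track <- function(v1, v2, times = (0:9) * 4, abl = 0L) {
  vertex_track("t1", times, v1, v2, ablation_frame = abl)
}

test_that("interface length is the vertex-to-vertex Euclidean distance", {
  n <- 10
  tr <- make_track(matrix(0, n, 2), cbind(rep(3, n), rep(4, n)))
  s <- interface_length(tr)
  expect_equal(s$L, rep(5, n), tolerance = 1e-12)
  # time axis: 1 pre frame + 9 post at 4 s spacing -> t = 0, 4, ..., 36
  expect_equal(s$t, seq(0, 36, by = 4))
  expect_equal(s$ablation_index, 1L)
})

test_that("vertex tracks validate their contracts", {
  n <- 10
  v <- matrix(0, n, 2)
  expect_error(vertex_track("a", (0:9) * 4, v, v, ablation_frame = 8L),
               "post-ablation")
  expect_error(vertex_track("a", c(0, 4, 8, 12.5, 16, 20, 24, 28, 32, 36),
                            v, v, ablation_frame = 0L), "uniformly spaced")
  expect_error(vertex_track("a", (9:0) * 4, v, v, ablation_frame = 0L),
               "increasing")
  vbad <- v; vbad[3, 1] <- NA
  expect_error(vertex_track("a", (0:9) * 4, vbad, v, ablation_frame = 0L),
               "finite")
})

test_that("retraction velocity follows the stated first-frame definition", {
  n <- 10
  tr <- make_track(matrix(0, n, 2), cbind(rep(2, n), rep(0, n)))
  expect_equal(retraction_velocity(tr), 0)
  # L(0) = 2.0, L(4) = 2.6 -> 0.15 um/s
  s <- structure(list(t = c(0, 4, 8), L = c(2.0, 2.6, 2.9), ablation_index = 1L),
                 class = "interface_length_series")
  expect_equal(retraction_velocity(s), 0.15, tolerance = 1e-12)
  # closed form on noiseless Kelvin-Voigt tracks
  for (D in c(0.5, 1.5)) {
    for (tau in c(5, 10)) {
      tr <- simulate_recoil_track(recoil_sim_params(D = D, tau = tau, noise_sd = 0))
      expect_equal(retraction_velocity(interface_length(tr)),
                   D * (1 - exp(-4 / tau)) / 4, tolerance = 1e-9)
    }
  }
})

test_that("noiseless series are recovered exactly by the fit", {
  for (D in c(0.5, 2)) {
    for (tau in c(5, 8, 20)) {
      f <- kelvin_voigt(kv_series(3, D, tau))
      expect_true(f$converged)
      expect_lt(abs(f$D - D) / D, 1e-6)
      expect_lt(abs(f$tau - tau) / tau, 1e-6)
    }
  }
})

test_that("the optimizer never loses to the exhaustive grid oracle", {
  for (seed in 1:10) {
    tr <- simulate_recoil_track(recoil_sim_params(noise_sd = 0.05, seed = seed))
    s <- interface_length(tr)
    f <- kelvin_voigt(s)
    post <- s$t > 0
    dL <- s$L[post] - s$L[s$ablation_index]
    tt <- s$t[post]
    oracle <- grid_oracle(tt, dL, D_max = max(3 * max(dL), 1e-6),
                          tau_lo = 0.4, tau_hi = 360)
    expect_lte(f$rss, oracle + 1e-9)
  }
})

test_that("zero-recoil series are flagged, not errored", {
  tr <- simulate_recoil_track(recoil_sim_params(D = 0, noise_sd = 0))
  r <- analyze_track(tr)
  expect_equal(r$retraction_velocity, 0)
  expect_false(r$fit$converged)
  expect_match(r$fit$method, "degenerate")
  # non-finite input is an error
  bad <- data.frame(t = c(0, 4, 8, 12), L = c(2, NA, 2.5, 2.6))
  expect_error(kelvin_voigt(bad), "finite")
})

test_that("measurements are invariant under rigid motions of the tissue", {
  p <- recoil_sim_params(noise_sd = 0.05, seed = 17L)
  tr <- simulate_recoil_track(p)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shift <- c(12.3, -4.5)
  tr2 <- vertex_track(tr$track_id, tr$times,
                      sweep(tr$vertex1 %*% t(R), 2, -shift),
                      sweep(tr$vertex2 %*% t(R), 2, -shift),
                      ablation_frame = tr$ablation_frame)
  s1 <- interface_length(tr); s2 <- interface_length(tr2)
  expect_equal(s1$L, s2$L, tolerance = 1e-9)
  expect_equal(retraction_velocity(s1), retraction_velocity(s2), tolerance = 1e-9)
  expect_equal(coef(kelvin_voigt(s1)), coef(kelvin_voigt(s2)), tolerance = 1e-9)
})

test_that("larger recoil amplitude gives strictly faster retraction", {
  v <- vapply(c(0.5, 1, 1.5, 2), function(D) {
    retraction_velocity(interface_length(
      simulate_recoil_track(recoil_sim_params(D = D, tau = 10, noise_sd = 0))))
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("fit options behave as documented", {
  s <- kv_series(3, 1.5, 10, n_pre = 3)
  f_last <- kelvin_voigt(s, L_ref = "last")
  f_mean <- kelvin_voigt(s, L_ref = "mean")
  expect_equal(f_last$L_ref, 3)
  expect_equal(f_mean$L_ref, 3)  # noiseless: all pre frames equal
  f_t0 <- kelvin_voigt(s, include_t0 = TRUE)
  expect_equal(f_t0$n_points, f_last$n_points + 1L)
  expect_lt(abs(f_t0$tau - 10) / 10, 1e-6)  # anchor is on the model curve
})

test_that("model methods are mutually consistent", {
  tr <- simulate_recoil_track(recoil_sim_params(noise_sd = 0.03, seed = 4L))
  f <- kelvin_voigt(interface_length(tr))
  expect_equal(unname(coef(f)), c(f$D, f$tau))
  expect_equal(fitted(f) + residuals(f), f$dL, tolerance = 1e-12)
  expect_equal(sum(residuals(f)^2), f$rss, tolerance = 1e-12)
  expect_equal(predict(f, t = f$t), fitted(f), tolerance = 1e-12)
  expect_equal(predict(f, t = 0, type = "length"), f$L_ref, tolerance = 1e-12)
  sims <- simulate(f, nsim = 2, seed = 8L, noise_sd = 0)
  expect_length(sims, 2L)
  refit <- kelvin_voigt(interface_length(sims[[1]]))
  expect_equal(coef(refit), coef(f), tolerance = 1e-6)
  expect_output(print(summary(f)), "relaxation time")
})

test_that("ensemble analysis keeps non-converged fits flagged", {
  tracks <- c(
    simulate_condition_ensemble(ensemble_spec(n_replicates = 5L, seed = 2L)),
    list(simulate_recoil_track(recoil_sim_params(D = 0, noise_sd = 0), "flat"))
  )
  tab <- analyze_tracks(tracks)
  expect_equal(nrow(tab), 6L)
  expect_equal(sum(!tab$converged), 1L)
  expect_equal(attr(tab, "n_excluded"), 1L)
  expect_true(is.na(tab$tau_s[!tab$converged]))
})
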