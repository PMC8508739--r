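test_that("noiseless single-exponential trace is recovered to 4 significant digits", {
  tr <- single_exp_trace(tau = 2, amp = 5000)
  fit <- fit_single_decay(tr, delta_irf(nrow(tr)), n_components = 1)
  expect_true(fit$converged)
  expect_equal(fit$lifetimes$lifetime_ns, 2, tolerance = 5e-4)
})

test_that("an all-zero trace raises an insufficient-counts error", {
  tr <- tibble::tibble(channel = 0:127, counts = rep(0, 128))
  expect_error(fit_single_decay(tr, delta_irf(128)), "[Ii]nsufficient")
})

test_that("lifetimes are recovered from Poisson-noised three-component decays", {
  errs <- vapply(1:3, function(s) {
    sim <- simulate_decays(decay_sim_spec(wavelengths = seq(330, 390, 15),
                                          n_channels = 900, seed = s))
    fit <- fit_decays(sim$decays, sim$irf, n_components = 3, n_starts = 3)
    tau <- fit$lifetimes$lifetime_ns
    c(abs(tau[1] - 5.1) / 5.1, abs(tau[2] - 1.9) / 1.9)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("global fit shares one lifetime set across wavelengths and matches single-trace fits", {
  sim <- simulate_decays(decay_sim_spec(lifetimes = c(4, 1.5),
                                        wavelengths = c(340, 370),
                                        n_channels = 700, seed = 11,
                                        background_rate = 0),
                         noise = FALSE)
  fit <- fit_decays(sim$decays, sim$irf, n_components = 2, n_starts = 3)
  # linkage: the lifetime table is one shared set, identical for every trace
  expect_equal(unique(fit$amplitudes$lifetime_ns[fit$amplitudes$component == 1]),
               fit$lifetimes$lifetime_ns[1])
  # consistency: a single-trace fit of either wavelength gives the same taus
  one <- fit_decays(dplyr::filter(sim$decays, wavelength_nm == 340),
                    sim$irf, n_components = 2, n_starts = 3)
  expect_equal(one$lifetimes$lifetime_ns, fit$lifetimes$lifetime_ns,
               tolerance = 1e-3)
})

test_that("reduced chi-square is near one for correctly specified synthetic data", {
  chi2 <- vapply(1:4, function(s) {
    sim <- simulate_decays(decay_sim_spec(wavelengths = c(340, 360, 380),
                                          n_channels = 800, seed = 100 + s))
    fit_decays(sim$decays, sim$irf, n_components = 3,
               n_starts = 2)$chi2_reduced
  }, numeric(1))
  expect_true(all(chi2 > 0.8 & chi2 < 1.2))
})

test_that("fit is invariant under integer rescaling of the counts", {
  sim <- simulate_decays(decay_sim_spec(lifetimes = c(4, 1.5),
                                        wavelengths = 350,
                                        n_channels = 700, seed = 21,
                                        background_rate = 0),
                         noise = FALSE)
  fit1 <- fit_decays(sim$decays, sim$irf, n_components = 2, n_starts = 2)
  scaled <- dplyr::mutate(sim$decays, counts = counts * 4L)
  fit4 <- fit_decays(scaled, sim$irf, n_components = 2, n_starts = 2)
  expect_equal(fit4$lifetimes$lifetime_ns, fit1$lifetimes$lifetime_ns,
               tolerance = 2e-3)
  expect_equal(
    fit4$amplitudes$amplitude / fit1$amplitudes$amplitude,
    rep(4, nrow(fit1$amplitudes)), tolerance = 0.02)
})

test_that("sub-resolution lifetimes are flagged unreliable", {
  sim <- simulate_decays(decay_sim_spec(seed = 31, n_channels = 900,
                                        wavelengths = c(340, 360)))
  fit <- fit_decays(sim$decays, sim$irf, n_components = 3, n_starts = 3)
  expect_true(all(fit$lifetimes$reliable[1:2]))
  # tau3 = 0.1 ns is ~3.7 channels, above 1.5 channel widths: reliable;
  # the flag trips below 1.5 * 0.027 ns
  expect_identical(fit$lifetimes$reliable,
                   fit$lifetimes$lifetime_ns >= 1.5 * 0.027)
})

test_that("nearly equal lifetimes trigger a degeneracy warning", {
  tr <- single_exp_trace(tau = 2, amp = 8000, n = 400)
  expect_warning(
    fit_single_decay(tr, delta_irf(400), n_components = 2,
                     init_lifetimes = c(2.02, 2), n_starts = 1),
    "degenerate")
})

test_that("traces on different grids are rejected", {
  a <- tibble::tibble(wavelength_nm = 340, channel = 0:99,
                      counts = rpois(100, 50))
  b <- tibble::tibble(wavelength_nm = 360, channel = 0:49,
                      counts = rpois(50, 50))
  expect_error(fit_decays(dplyr::bind_rows(a, b), delta_irf(100)),
               "grid")
})
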