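test_that("double-Boltzmann evaluates its closed form", {
  # sigmoid midpoint: u = c1 with p = 1 gives y0 + A/2
  expect_equal(double_boltzmann(1.5, y0 = 2, A = 3, p = 1, c1 = 1.5,
                                c2 = 4, k1 = 0.3), 2 + 1.5)
  # asymptotes
  expect_equal(double_boltzmann(1e3, 2, 3, 0.5, 1.5, 4, 0.3), 5,
               tolerance = 1e-12)
  expect_equal(double_boltzmann(-1e3, 2, 3, 0.5, 1.5, 4, 0.3), 2,
               tolerance = 1e-12)
  # direct substitution, computed independently inline
  manual <- 6.0 + (-2.5) * (0.5 / (1 + exp((1.5 - 1.5) / 0.3)) +
                            0.5 / (1 + exp((4.0 - 1.5) / 0.3)))
  expect_equal(double_boltzmann(1.5, 6.0, -2.5, 0.5, 1.5, 4.0, 0.3, 0.3),
               manual)
  # p = 1 reduces exactly to a single Boltzmann
  u <- seq(0, 8, 0.25)
  single <- 1 + 2 / (1 + exp((3 - u) / 0.4))
  expect_equal(double_boltzmann(u, 1, 2, 1, 3, 7, 0.4, 0.9), single)
})

test_that("noiseless double-Boltzmann curves are recovered to 4 significant digits", {
  truth <- list(y0 = 6, A = -2.5, p = 0.45, c1 = 1.5, c2 = 4, k1 = 0.3,
                k2 = 0.35)
  cv <- simulate_transition_curve(truth, noise_sd = 0, seed = 1)
  fit <- fit_transition(cv)
  est <- setNames(fit$params$estimate, fit$params$term)
  for (nm in names(truth)) {
    expect_equal(unname(est[nm]), truth[[nm]], tolerance = 5e-4)
  }
})

test_that("midpoints are recovered within 0.1 M under 1% noise", {
  hits <- vapply(1:8, function(s) {
    cv <- simulate_transition_curve(seed = s)
    fit <- fit_transition(cv)
    est <- setNames(fit$params$estimate, fit$params$term)
    abs(est["c1"] - 1.5) <= 0.1 && abs(est["c2"] - 4.0) <= 0.1
  }, logical(1))
  expect_gte(sum(hits), 7)
})

test_that("swapped midpoint initialization returns the same ordered estimates", {
  cv <- simulate_transition_curve(seed = 5)
  f1 <- fit_transition(cv, init = list(c1 = 1.5, c2 = 4))
  f2 <- fit_transition(cv, init = list(c1 = 4, c2 = 1.5))
  expect_equal(f1$params$estimate, f2$params$estimate, tolerance = 1e-6)
  est <- setNames(f1$params$estimate, f1$params$term)
  expect_lt(est["c1"], est["c2"])
})

test_that("degenerate inputs are flagged, not fatal", {
  flat <- tibble::tibble(urea_M = seq(0, 8, length.out = 20), signal = 3)
  fit <- fit_transition(flat)
  expect_false(fit$converged)
  # single-transition data force-fit with two transitions warns via p-hat
  single <- tibble::tibble(
    urea_M = seq(0, 8, length.out = 30),
    signal = double_boltzmann(seq(0, 8, length.out = 30), 1, 2, 1, 3, 6,
                              0.4, 0.4))
  expect_warning(fit_transition(single, n_transitions = 2), "single")
})

test_that("thermodynamics follow the linear-extrapolation mapping", {
  R <- 8.314462618e-3
  th <- thermo_from_fit(list(p = 1, c1 = 2, c2 = NA, k1 = 0.4, k2 = NA),
                        temperature = 298.15)
  expect_equal(th$m_kJ_per_mol_M, R * 298.15 / 0.4, tolerance = 1e-12)
  expect_equal(th$dG_H2O_kJ_per_mol, R * 298.15 / 0.4 * 2, tolerance = 1e-12)
  # halving k doubles m and dG at fixed c
  th2 <- thermo_from_fit(list(p = 1, c1 = 2, c2 = NA, k1 = 0.2, k2 = NA))
  expect_equal(th2$m_kJ_per_mol_M, 2 * th$m_kJ_per_mol_M)
  expect_equal(th2$dG_H2O_kJ_per_mol, 2 * th$dG_H2O_kJ_per_mol)
  # dG scales linearly with temperature at fixed k, c
  th_hot <- thermo_from_fit(list(p = 1, c1 = 2, c2 = NA, k1 = 0.4, k2 = NA),
                            temperature = 2 * 298.15)
  expect_equal(th_hot$dG_H2O_kJ_per_mol, 2 * th$dG_H2O_kJ_per_mol)
  # p = 1 with two transitions present -> second fraction 0
  th_p1 <- thermo_from_fit(list(p = 1, c1 = 2, c2 = 5, k1 = 0.4, k2 = 0.4))
  expect_equal(th_p1$fraction, c(1, 0))
  expect_error(thermo_from_fit(list(p = 1, c1 = 2, c2 = NA, k1 = -1,
                                    k2 = NA)), "positive")
})

test_that("fitted transition objects expose thermodynamics per transition", {
  cv <- simulate_transition_curve(seed = 9)
  fit <- fit_transition(cv)
  expect_equal(nrow(fit$thermo), 2)
  expect_equal(sum(fit$thermo$fraction), 1)
  expect_true(all(fit$thermo$m_kJ_per_mol_M > 0))
})

test_that("intensity ratio interpolates the spectrum at 320 and 360 nm", {
  ss <- tibble::tibble(wavelength_nm = seq(300, 420, 20),
                       intensity = rep(200, 7))
  expect_equal(intensity_ratio(ss), 1)
  ss2 <- tibble::tibble(wavelength_nm = c(300, 320, 360, 420),
                        intensity = c(120, 150, 100, 80))
  expect_equal(intensity_ratio(ss2), 1.5)
  # a blue-shifted band has the larger ratio
  wl <- seq(305, 450, 1)
  band <- function(mu) tibble::tibble(
    wavelength_nm = wl, intensity = exp(-(wl - mu)^2 / (2 * 25^2)))
  expect_gt(intensity_ratio(band(330)), intensity_ratio(band(350)))
  # zero denominator -> missing with a warning
  ss3 <- tibble::tibble(wavelength_nm = c(310, 360, 400),
                        intensity = c(100, 0, 0))
  expect_warning(r <- intensity_ratio(ss3), "zero")
  expect_true(is.na(r))
})
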