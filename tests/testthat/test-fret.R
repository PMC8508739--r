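test_that("indole centers are equivariant and match a hand-computed mean", {
  st <- build_toy_structure(pairs = list(list(r = 9)))
  ring <- model_atoms_for_test(st)
  ring1 <- ring[ring$resno == 1, ]
  expect_equal(indole_center(st, "A", 1),
               unname(colMeans(as.matrix(ring1[, c("x", "y", "z")]))))
  moved <- transform_structure(st, diag(3), c(1, 2, 3))
  expect_equal(indole_center(moved, "A", 1),
               indole_center(st, "A", 1) + c(1, 2, 3))
  # mass-weighted and geometric centers of an idealized ring nearly coincide
  d <- sqrt(sum((indole_center(st, "A", 1, center = "mass") -
                   indole_center(st, "A", 1))^2))
  expect_lt(d, 0.2)
})

test_that("missing ring atoms raise an incomplete-residue error", {
  st <- build_toy_structure()
  a <- model_atoms_for_test(st)
  st2 <- as_protein_structure(a[!(a$resno == 1 & a$atom == "NE1"), ])
  expect_error(indole_geometry(st2, "A", 1), "NE1")
})

test_that("the transition dipole lies in the ring plane and rotates rigidly", {
  st <- build_toy_structure()
  g0 <- indole_geometry(st, "A", 1, dipole_angle_deg = 0)
  expect_equal(sum(g0$dipole * g0$normal), 0, tolerance = 1e-9)
  expect_equal(g0$dipole, g0$long_axis)  # angle 0 = projected long axis
  g <- indole_geometry(st, "A", 1)
  expect_equal(sum(g$dipole * g$normal), 0, tolerance = 1e-9)
  expect_equal(sqrt(sum(g$dipole^2)), 1)
  rot <- euler_matrix_for_test(0.7, -0.3, 1.9)
  gr <- indole_geometry(transform_structure(st, rot, c(5, 5, 5)), "A", 1)
  expect_equal(gr$dipole, drop(rot %*% g$dipole), tolerance = 1e-9)
})

test_that("kappa squared hits its limiting geometries exactly", {
  mk <- function(center, dipole) list(center = center, dipole = dipole)
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  # collinear head-to-tail: kappa2 = 4
  expect_equal(kappa_squared(mk(c(0, 0, 0), ex), mk(c(5, 0, 0), ex)), 4)
  # parallel, both perpendicular to the separation: kappa2 = 1
  expect_equal(kappa_squared(mk(c(0, 0, 0), ez), mk(c(5, 0, 0), ez)), 1)
  # one along separation, other orthogonal to both: kappa2 = 0
  expect_equal(kappa_squared(mk(c(0, 0, 0), ex), mk(c(5, 0, 0), ey)), 0)
  # symmetric under donor/acceptor exchange
  set.seed(1)
  for (i in 1:20) {
    d <- mk(rnorm(3), unit_for_test(rnorm(3)))
    a <- mk(rnorm(3) + 3, unit_for_test(rnorm(3)))
    expect_equal(kappa_squared(d, a), kappa_squared(a, d), tolerance = 1e-12)
    expect_gte(kappa_squared(d, a), 0)
    expect_lte(kappa_squared(d, a), 4)
  }
  expect_error(kappa_squared(mk(c(0, 0, 0), ex), mk(c(0, 0, 0), ey)),
               "coincide")
})

test_that("kappa squared is invariant under rigid motion of the pair", {
  st <- build_toy_structure(pairs = list(list(r = 7, rotate = c(30, 40, 10))))
  k0 <- kappa_squared(indole_geometry(st, "A", 1), indole_geometry(st, "A", 2))
  rot <- euler_matrix_for_test(-0.5, 0.2, 0.9)
  stm <- transform_structure(st, rot, c(-3, 8, 2))
  k1 <- kappa_squared(indole_geometry(stm, "A", 1),
                      indole_geometry(stm, "A", 2))
  expect_equal(k1, k0, tolerance = 1e-9)
})

test_that("the isotropic orientation average is 2/3", {
  # the vectorized sampler is first validated against kappa_squared, then
  # used as the high-throughput oracle
  set.seed(99)
  d <- random_unit_rows(50); a <- random_unit_rows(50)
  r <- random_unit_rows(50)
  kv <- kappa2_vectorized(d, a, r)
  ks <- vapply(1:50, function(i) {
    kappa_squared(list(center = c(0, 0, 0), dipole = d[i, ]),
                  list(center = 5 * r[i, ], dipole = a[i, ]))
  }, numeric(1))
  expect_equal(kv, ks, tolerance = 1e-12)
  set.seed(7)
  n <- 1e6
  k <- kappa2_vectorized(random_unit_rows(n), random_unit_rows(n),
                         random_unit_rows(n))
  expect_equal(mean(k), 2 / 3, tolerance = 0.01)
})

test_that("transfer efficiency follows the orientation-weighted Forster form", {
  expect_equal(fret_efficiency(2 / 3, 7.8, 7.8), 0.5)
  expect_equal(fret_efficiency(2 / 3, 1e-6, 7.8), 1, tolerance = 1e-9)
  expect_equal(fret_efficiency(2 / 3, 1e3, 7.8), 0, tolerance = 1e-9)
  expect_equal(fret_efficiency(0, 5, 7.8), 0)
  # strictly decreasing in R, increasing in kappa2
  r <- seq(2, 15, 0.5)
  expect_true(all(diff(fret_efficiency(1, r, 7.8)) < 0))
  k <- seq(0.1, 4, 0.1)
  expect_true(all(diff(fret_efficiency(k, 7, 7.8)) > 0))
  # kappa2 = 2/3 reduces to the classic 1/(1+(R/R0)^6)
  expect_equal(fret_efficiency(2 / 3, r, 7.8), 1 / (1 + (r / 7.8)^6))
  expect_error(fret_efficiency(1, -1), ">")
})

test_that("fret_pair reports geometry for a constructed pair", {
  st <- build_toy_structure(pairs = list(list(r = 7.8)))
  fp <- fret_pair(st, "A:1", "A:2")
  expect_equal(fp$r, 7.8, tolerance = 1e-9)
  expect_equal(fp$kappa2, 1, tolerance = 1e-9)   # translated copy: parallel
  expect_equal(fp$efficiency, fret_efficiency(1, 7.8, 7.8))
  expect_true(fp$kappa2_range[1] <= fp$kappa2 &&
                fp$kappa2 <= fp$kappa2_range[2])
  td <- tidy(fp)
  expect_equal(td$kappa2, fp$kappa2)
})

test_that("distance distributions bin every frame and recover the truth", {
  st <- build_toy_structure(pairs = list(list(r = 6)))
  one <- distance_distribution(st, "A:1", "A:2")
  expect_equal(one$summary$n_frames, 1)
  expect_equal(sum(one$histogram$count), 1)
  n <- 200
  traj <- simulate_trajectory(st, n_frames = n, jitter_sd = 0.3, seed = 12)
  dd <- distance_distribution(traj, "A:1", "A:2")
  expect_equal(sum(dd$histogram$count), n)
  # jitter on all atoms perturbs each center by ~sd/3 per axis; the mean
  # distance stays within 3 standard errors of the construction distance
  se <- dd$summary$sd / sqrt(n)
  expect_lt(abs(dd$summary$mean - 6), 3 * se + 0.05)
  # missing residue in a frame is a frame-indexed error
  a <- traj$atoms
  broken <- as_protein_structure(a[!(a$model == 3 & a$resno == 2), ])
  expect_error(distance_distribution(broken, "A:1", "A:2"), "Frame 3")
})
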