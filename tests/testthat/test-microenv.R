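test_that("neighbor counting respects the cutoff boundary", {
  st <- build_toy_structure(pairs = list(list(r = 30)))
  a <- model_atoms_for_test(st)
  trp <- a[a$resno == 1, ]
  # one foreign atom exactly 6.9 A from the nearest Trp atom along +x
  edge <- trp[which.max(trp$x), ]
  probe <- atom_row("Z", 99, "GLY", "CA", "C", edge$x + 6.9, edge$y, edge$z)
  st1 <- as_protein_structure(dplyr::bind_rows(a, probe))
  expect_equal(count_neighbors(st1, "A", 1, cutoff = 7), 1)
  probe$x <- edge$x + 7.1
  st2 <- as_protein_structure(dplyr::bind_rows(a, probe))
  expect_equal(count_neighbors(st2, "A", 1, cutoff = 7), 0)
})

test_that("neighbor counts agree with the all-pairs oracle on random structures", {
  for (s in 1:12) {
    st <- build_toy_structure(pairs = list(list(r = 8)),
                              n_background_atoms = 120, box = 24, seed = s)
    got <- count_neighbors(st, "A", 1, cutoff = 7)
    expect_identical(got, neighbor_oracle(st, "A", 1, cutoff = 7))
  }
})

test_that("polar counts never exceed the total and respect the filter", {
  for (s in 1:5) {
    st <- build_toy_structure(pairs = list(list(r = 5)),
                              n_background_atoms = 60, box = 18, seed = s)
    n_tot <- count_neighbors(st, "A", 1, cutoff = 7)
    n_pol <- count_neighbors(st, "A", 1, cutoff = 7, selection = "polar")
    expect_lte(n_pol, n_tot)
  }
  # the partner ring's single nitrogen is the only polar atom nearby
  st <- build_toy_structure(pairs = list(list(r = 4)))
  expect_equal(count_neighbors(st, "A", 1, cutoff = 10, selection = "polar"),
               1)
})

test_that("isolated-atom SASA matches the analytic sphere", {
  for (el in c("C", "N", "O", "S")) {
    iso <- as_protein_structure(atom_row("A", 1, "GLY", "X", el, 0, 0, 0))
    r <- unname(c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[el])
    expect_equal(compute_sasa(iso)$area, 4 * pi * (r + 1.4)^2,
                 tolerance = 0.01)
  }
})

test_that("a caged atom has zero accessible area", {
  # surround a carbon with a tight octahedral + cubic cage of large spheres
  shells <- rbind(expand.grid(x = c(-2, 2), y = c(-2, 2), z = c(-2, 2)),
                  data.frame(x = c(2.6, -2.6, 0, 0, 0, 0),
                             y = c(0, 0, 2.6, -2.6, 0, 0),
                             z = c(0, 0, 0, 0, 2.6, -2.6)))
  cage <- purrr::pmap_dfr(shells, function(x, y, z) {
    atom_row("B", 50 + x * 7 + y * 3 + z, "GLY", "CA", "S", x, y, z)
  })
  cage$resno <- 100L + seq_len(nrow(cage))
  st <- as_protein_structure(
    dplyr::bind_rows(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0), cage))
  area <- compute_sasa(st)$area
  expect_equal(area[1], 0)
})

test_that("two-sphere SASA matches a dense point-sampling oracle", {
  st <- as_protein_structure(dplyr::bind_rows(
    atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
    atom_row("A", 2, "GLY", "CA", "O", 2.2, 0, 0)))
  got <- compute_sasa(st, n_points = 960)$area
  # oracle: same construction at much higher angular resolution
  dense <- compute_sasa(st, n_points = 20000)$area
  expect_lt(max(abs(got - dense) / dense), 0.02)
  # accessible area never exceeds the isolated-sphere value
  expect_lt(got[1], 4 * pi * (1.70 + 1.4)^2)
  expect_lt(got[2], 4 * pi * (1.52 + 1.4)^2)
})

test_that("adding surrounding atoms monotonically buries a residue", {
  core <- atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0)
  angles <- seq(0, 2 * pi, length.out = 13)[-13]
  areas <- vapply(c(2, 6, 12), function(k) {
    nb <- purrr::map_dfr(seq_len(k), function(i) {
      atom_row("B", 1 + i, "GLY", "CA", "C",
               3 * cos(angles[i]), 3 * sin(angles[i]), 0)
    })
    st <- as_protein_structure(dplyr::bind_rows(core, nb))
    compute_sasa(st)$area[1]
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("descriptors are invariant under rigid-body motion", {
  st <- build_toy_structure(pairs = list(list(r = 6)),
                            n_background_atoms = 80, box = 20, seed = 7)
  rot <- euler_matrix_for_test(0.4, -1.1, 2.2)
  moved <- transform_structure(st, rot, c(11, -4, 3))
  expect_identical(count_neighbors(st, "A", 1),
                   count_neighbors(moved, "A", 1))
  expect_identical(count_neighbors(st, "A", 1, selection = "polar"),
                   count_neighbors(moved, "A", 1, selection = "polar"))
  q1 <- screen_quenchers(st, "A", 1)
  q2 <- screen_quenchers(moved, "A", 1)
  expect_equal(q1$distance, q2$distance, tolerance = 1e-9)
  # SASA is quadrature-based: rotation invariance holds to sampling accuracy
  s1 <- residue_sasa(st, "A", 1)
  s2 <- residue_sasa(moved, "A", 1)
  expect_equal(s2$sasa_abs, s1$sasa_abs, tolerance = 0.01)
  expect_equal(s2$sasa_rel, s1$sasa_rel, tolerance = 0.01)
})

test_that("a shielded indole ranks as buried against a surface one", {
  st <- build_toy_structure(pairs = list(list(r = 25)))
  a <- model_atoms_for_test(st)
  ring1 <- a[a$resno == 1, ]
  # cage residue 1 in carbons on a sphere of radius 4.5 around its center
  ctr <- colMeans(as.matrix(ring1[, c("x", "y", "z")]))
  pts <- 4.5 * fib_points_for_test(80)
  cage <- tibble::tibble(chain = "C", resno = 200L + seq_len(nrow(pts)),
                         resname = "GLY", atom = "CA", element = "C",
                         x = ctr[1] + pts[, 1], y = ctr[2] + pts[, 2],
                         z = ctr[3] + pts[, 3])
  st2 <- as_protein_structure(dplyr::bind_rows(a, cage))
  buried <- residue_sasa(st2, "A", 1)
  exposed <- residue_sasa(st2, "A", 2)
  expect_lt(buried$sasa_rel, 17)
  expect_gt(exposed$sasa_rel, 40)
  expect_true(all(c(buried$sasa_rel, exposed$sasa_rel) >= 0))
  expect_true(all(c(buried$sasa_rel, exposed$sasa_rel) <= 100))
})

test_that("secondary-structure fraction counts helix/strand neighbors", {
  st <- build_toy_structure(pairs = list(list(r = 5)),
                            n_background_atoms = 10, box = 14, seed = 5)
  # label partner Trp as helix, all background coil
  st <- set_secondary_structure(
    st, tibble::tibble(chain = c("A", "A"), resno = 1:2, ss = c("C", "H")))
  nb <- microenv_atoms(st, "A", 1, cutoff = 7)
  expected <- 100 * sum(nb$chain == "A" & nb$resno == 2) / nrow(nb)
  expect_equal(secondary_structure_fraction(st, "A", 1, cutoff = 7,
                                            fallback = FALSE),
               expected)
  # all neighbors in helices -> 100%
  st_h <- build_toy_structure(pairs = list(list(r = 5)))
  st_h <- set_secondary_structure(
    st_h, tibble::tibble(chain = "A", resno = 1:2, ss = "H"))
  expect_equal(secondary_structure_fraction(st_h, "A", 1, cutoff = 10,
                                            fallback = FALSE), 100)
  # no annotation, fallback disabled -> missing with a warning
  st_n <- build_toy_structure(pairs = list(list(r = 5)))
  expect_warning(
    v <- secondary_structure_fraction(st_n, "A", 1, fallback = FALSE),
    "disabled")
  expect_true(is.na(v))
})

test_that("quencher screening tags mechanisms and respects the cutoff", {
  st <- build_toy_structure(pairs = list(list(r = 40)))
  a <- model_atoms_for_test(st)
  ring <- a[a$resno == 1, ]
  edge <- ring[which.max(ring$x), ]
  asp <- atom_row("B", 10, "ASP", c("CG", "OD1", "OD2"), c("C", "O", "O"),
                  edge$x + c(4.6, 4.0, 4.3), edge$y, edge$z)
  cys <- atom_row("B", 11, "CYS", "SG", "S", edge$x + 4.4, edge$y + 1, edge$z)
  far <- atom_row("B", 12, "LYS", "NZ", "N", edge$x + 9, edge$y, edge$z)
  st2 <- as_protein_structure(dplyr::bind_rows(a, asp, cys, far))
  q <- screen_quenchers(st2, "A", 1, cutoff = 5.5)
  expect_true(any(q$mechanism == "electron-transfer-carboxyl" &
                    q$atom == "OD1"))
  expect_true(any(q$mechanism == "electron-transfer-sulfur"))
  expect_false(any(q$resname == "LYS"))
  expect_true(all(q$distance <= 5.5))
  # nothing in range -> empty tibble, no error
  st3 <- build_toy_structure(pairs = list(list(r = 40)))
  expect_equal(nrow(screen_quenchers(st3, "A", 1, cutoff = 2)), 0)
})

test_that("the microenvironment report covers every tryptophan and model", {
  st <- build_toy_structure(pairs = list(list(r = 6)),
                            n_background_atoms = 40, box = 18, seed = 9)
  st$chain_roles <- c(A = "alpha", Z = "beta")
  traj <- simulate_trajectory(st, n_frames = 2, jitter_sd = 0.1, seed = 4)
  rep <- microenv_report(traj, cterm = list(chain = "A", from = 2, to = 2))
  expect_equal(nrow(rep), 4)  # 2 tryptophans x 2 models
  expect_true(all(rep$n_polar <= rep$n_total))
  expect_true(all(rep$sasa_rel >= 0 & rep$sasa_rel <= 100))
  smry <- summarise_microenv(rep)
  expect_equal(nrow(smry), 2)
})
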