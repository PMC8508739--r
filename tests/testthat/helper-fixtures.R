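# shared fixture builders; everything generated in code, seeded

delta_irf <- function(n = 256) {
  tibble::tibble(channel = 0:(n - 1), counts = c(1, rep(0, n - 1)))
}

# single exponential trace with a delta IRF, optionally noiseless
single_exp_trace <- function(tau = 2, amp = 5000, n = 512, cw = 0.027,
                             background = 0) {
  mu <- convolve_decay(tau, amp, delta_irf(n), n, channel_width = cw,
                       background = background)
  tibble::tibble(channel = 0:(n - 1), counts = round(mu))
}

# an atom tibble row for hand-built structures
atom_row <- function(chain, resno, resname, atom, element, x, y, z) {
  tibble::tibble(chain = chain, resno = as.integer(resno), resname = resname,
                 atom = atom, element = element, x = x, y = y, z = z)
}

# all-pairs neighbor-count oracle: atoms within `cutoff` of any reference
# atom, own residue excluded
neighbor_oracle <- function(structure, chain, resno, cutoff = 7,
                            model = 1) {
  a <- structure$atoms[structure$atoms$model == model &
                         structure$atoms$element != "H", ]
  own <- a[a$chain == chain & a$resno == resno, ]
  oth <- a[!(a$chain == chain & a$resno == resno), ]
  cnt <- 0L
  for (i in seq_len(nrow(oth))) {
    dmin <- Inf
    for (j in seq_len(nrow(own))) {
      d <- sqrt((oth$x[i] - own$x[j])^2 + (oth$y[i] - own$y[j])^2 +
                  (oth$z[i] - own$z[j])^2)
      if (d < dmin) dmin <- d
    }
    if (dmin <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# rigid-body transform of a protein_structure
transform_structure <- function(structure, rot = diag(3), shift = c(0, 0, 0)) {
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  s2 <- structure
  s2$atoms <- a
  s2
}

# vectorized kappa^2 for the Monte-Carlo isotropic-average oracle
kappa2_vectorized <- function(d, a, rhat) {
  ct <- rowSums(d * a)
  cd <- rowSums(d * rhat)
  ca <- rowSums(a * rhat)
  (ct - 3 * ca * cd)^2
}

random_unit_rows <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

model_atoms_for_test <- function(structure, model = 1) {
  structure$atoms[structure$atoms$model == model, ]
}

# independent rotation matrix (ZYX Euler) for invariance tests
euler_matrix_for_test <- function(ax, ay, az) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# roughly uniform unit-sphere points (golden-spiral construction)
fib_points_for_test <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

unit_for_test <- function(v) v / sqrt(sum(v^2))

# complete on-disk synthetic input bundle + matching pipeline config
make_full_bundle <- function(dir, seed = 1) {
  sim <- simulate_decays(decay_sim_spec(
    lifetimes = c(5.1, 1.9), wavelengths = seq(330, 390, 20),
    n_channels = 700, seed = seed))
  write_decay_bundle(sim, dir)
  wl <- seq(305, 450, 5)
  readr::write_tsv(tibble::tibble(
    wavelength_nm = wl, intensity = 1000 * exp(-(wl - 340)^2 / 1800)),
    file.path(dir, "spectrum.tsv"))
  cv <- simulate_transition_curve(seed = seed)
  readr::write_tsv(tibble::tibble(urea_M = cv$urea_M, signal = cv$signal),
                   file.path(dir, "tau1.tsv"))
  st <- build_toy_structure(pairs = list(list(r = 6.5)),
                            n_background_atoms = 30, box = 20, seed = seed)
  write_pdb(st, file.path(dir, "structure.pdb"))
  run_config(
    decays_manifest = file.path(dir, "manifest.tsv"),
    irf = file.path(dir, "irf.tsv"),
    spectrum = file.path(dir, "spectrum.tsv"),
    transition_curves = list(tau1_ns = file.path(dir, "tau1.tsv")),
    pdb = file.path(dir, "structure.pdb"),
    chain_roles = list(A = "alpha"),
    fret_pairs = list(list(donor = "A:1", acceptor = "A:2")),
    n_components = 2, seed = seed,
    out_dir = file.path(dir, "out"))
}
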