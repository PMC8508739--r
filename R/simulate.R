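#' Specification for a synthetic multi-wavelength TCSPC data set
#'
#' Defaults emulate the study conditions of a multi-tryptophan protein
#' measured on a diode-excited TCSPC instrument: three lifetime components
#' (5.1, 1.9, 0.1 ns), emission sampled 320-410 nm in 5 nm steps, 0.027
#' ns/channel, a Gaussian IRF of 1.2 ns FWHM, and a peak of 10^4 counts.
#' Component amplitude spectra are Gaussian emission bands with the long-lived
#' component centered redder than the mid one, so per-wavelength spectral
#' fractions vary with wavelength; band heights put roughly 40/50/10% of the
#' steady-state intensity into the three components.
#'
#' @param lifetimes Lifetimes in ns (default `c(5.1, 1.9, 0.1)`).
#' @param wavelengths Emission wavelengths in nm (default `seq(320, 410, 5)`).
#' @param amplitude_bands Tibble with one row per component: `peak`,
#'   `center_nm`, `sd_nm` describing Gaussian amplitude spectra.
#' @param irf_center_ns,irf_fwhm_ns Gaussian IRF position and width
#'   (defaults 1.35 and 1.2 ns).
#' @param peak_counts Expected maximum count over all traces (default 1e4).
#' @param background_rate Background counts/channel (default 2).
#' @param channel_width Channel width in ns (default 0.027).
#' @param n_channels Number of channels (default 1024).
#' @param seed Integer seed (default 1).
#' @return A list of class `decay_sim_spec`.
#' @export
decay_sim_spec <- function(lifetimes = c(5.1, 1.9, 0.1),
                           wavelengths = seq(320, 410, by = 5),
                           amplitude_bands = NULL,
                           irf_center_ns = 1.35, irf_fwhm_ns = 1.2,
                           peak_counts = 1e4, background_rate = 2,
                           channel_width = 0.027, n_channels = 1024,
                           seed = 1) {
  if (any(lifetimes <= 0)) abort("All lifetimes must be > 0.")
  if (peak_counts <= 0) abort("`peak_counts` must be > 0.")
  p <- length(lifetimes)
  if (is.null(amplitude_bands)) {
    # heights chosen so the time-integrated (alpha*tau) contributions are
    # about 40/50/10% at the band centers, exercising the 3-component fit
    defaults <- tibble(
      peak = c(0.40, 0.50, 0.10)[seq_len(p)] / lifetimes,
      center_nm = c(350, 335, 330)[seq_len(p)],
      sd_nm = c(30, 25, 25)[seq_len(p)])
    amplitude_bands <- defaults
  }
  if (nrow(amplitude_bands) != p) {
    abort("`amplitude_bands` needs one row per lifetime component.")
  }
  structure(list(lifetimes = lifetimes, wavelengths = wavelengths,
                 amplitude_bands = as_tibble(amplitude_bands),
                 irf_center_ns = irf_center_ns, irf_fwhm_ns = irf_fwhm_ns,
                 peak_counts = peak_counts, background_rate = background_rate,
                 channel_width = channel_width, n_channels = n_channels,
                 seed = seed),
            class = "decay_sim_spec")
}

#' Simulate a multi-wavelength TCSPC decay bundle
#'
#' Generates the expected decay of each trace with [convolve_decay()] (the
#' same forward model the fit assumes), scales the bundle so the brightest
#' channel has expectation `peak_counts`, and draws per-channel Poisson
#' counts. The IRF histogram itself is a scaled Gaussian profile, rounded to
#' integer counts. Everything is reproducible per seed: the same seed gives
#' identical counts, a different seed changes only the noise.
#'
#' @param spec A [decay_sim_spec()] (or arguments for it, via `...`).
#' @param noise Draw Poisson noise (default `TRUE`); with `FALSE` the rounded
#'   expectations are returned.
#' @param ... Used to build a spec when `spec` is missing.
#' @return List with `decays` (tibble `wavelength_nm`, `channel`, `counts`),
#'   `irf` (tibble `channel`, `counts`), `expected` (tibble of expectations),
#'   `truth` (tibble `wavelength_nm`, `component`, `lifetime_ns`, `amplitude`,
#'   scaled to count units), and `spec`.
#' @export
simulate_decays <- function(spec = decay_sim_spec(...), noise = TRUE, ...) {
  stopifnot(inherits(spec, "decay_sim_spec"))
  nc <- spec$n_channels
  cw <- spec$channel_width
  t_ch <- (seq_len(nc) - 1) * cw
  sigma <- spec$irf_fwhm_ns / (2 * sqrt(2 * log(2)))
  irf_profile <- exp(-(t_ch - spec$irf_center_ns)^2 / (2 * sigma^2))
  irf_counts_v <- round(irf_profile / max(irf_profile) * spec$peak_counts)
  irf_tbl <- tibble(channel = seq_len(nc) - 1, counts = irf_counts_v)

  p <- length(spec$lifetimes)
  amp <- vapply(seq_len(p), function(i) {
    b <- spec$amplitude_bands[i, ]
    b$peak * exp(-(spec$wavelengths - b$center_nm)^2 / (2 * b$sd_nm^2))
  }, numeric(length(spec$wavelengths)))
  amp <- matrix(amp, nrow = length(spec$wavelengths))

  expected_raw <- vapply(seq_along(spec$wavelengths), function(wi) {
    convolve_decay(spec$lifetimes, amp[wi, ], irf_counts_v, nc,
                   channel_width = cw, background = 0)
  }, numeric(nc))
  scale <- spec$peak_counts / max(expected_raw)
  expected <- expected_raw * scale + spec$background_rate

  counts <- withr::with_seed(spec$seed, {
    if (noise) {
      matrix(stats::rpois(length(expected), lambda = expected), nrow = nc)
    } else {
      round(expected)
    }
  })
  decays <- purrr::map_dfr(seq_along(spec$wavelengths), function(wi) {
    tibble(wavelength_nm = spec$wavelengths[wi], channel = seq_len(nc) - 1,
           counts = as.numeric(counts[, wi]))
  })
  expected_tbl <- purrr::map_dfr(seq_along(spec$wavelengths), function(wi) {
    tibble(wavelength_nm = spec$wavelengths[wi], channel = seq_len(nc) - 1,
           expected = expected[, wi])
  })
  truth <- purrr::map_dfr(seq_along(spec$wavelengths), function(wi) {
    tibble(wavelength_nm = spec$wavelengths[wi], component = seq_len(p),
           lifetime_ns = spec$lifetimes, amplitude = amp[wi, ] * scale)
  })
  list(decays = decays, irf = irf_tbl, expected = expected_tbl,
       truth = truth, spec = spec)
}

#' Simulate a denaturant transition curve
#'
#' Evaluates [double_boltzmann()] on a urea grid and applies multiplicative
#' Gaussian noise. Defaults emulate a two-step unfolding with midpoints at
#' 1.5 and 4.0 M urea and widths of 0.3 M, sampled at 24 urea points over
#' 0-8 M with 1% noise.
#'
#' @param truth Named list of double-Boltzmann parameters
#'   (`y0`, `A`, `p`, `c1`, `c2`, `k1`, `k2`).
#' @param urea Urea grid in M (default 24 points over 0-8).
#' @param noise_sd Relative (multiplicative) Gaussian noise sd (default 0.01).
#' @param seed Integer seed (default 1).
#' @param signal_name Label for the simulated observable.
#' @return Tibble with columns `urea_M`, `signal` and attributes `truth`,
#'   `signal_name`.
#' @export
simulate_transition_curve <- function(truth = list(y0 = 6, A = -2.5, p = 0.5,
                                                   c1 = 1.5, c2 = 4,
                                                   k1 = 0.3, k2 = 0.3),
                                      urea = seq(0, 8, length.out = 24),
                                      noise_sd = 0.01, seed = 1,
                                      signal_name = "tau1_ns") {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  y <- double_boltzmann(urea, truth$y0, truth$A, truth$p, truth$c1,
                        truth$c2, truth$k1, truth$k2)
  y_obs <- withr::with_seed(seed, {
    y * (1 + stats::rnorm(length(y), sd = noise_sd))
  })
  out <- tibble(urea_M = urea, signal = y_obs)
  attr(out, "truth") <- truth
  attr(out, "signal_name") <- signal_name
  out
}

# idealized planar indole ring template in the xy-plane: a regular benzene
# hexagon (1.39 A sides) fused along the CD2-CE2 bond with a regular pentagon
# (pyrrole). Bond lengths are literature-like, not crystallographic.
indole_template <- function() {
  s <- 1.39
  rh <- s  # circumradius of a regular hexagon equals its side
  hex_names <- c("CD2", "CE3", "CZ3", "CH2", "CZ2", "CE2")
  ang <- (seq_len(6) - 1) * pi / 3 + pi / 6
  hex <- cbind(rh * cos(ang), rh * sin(ang))
  rownames(hex) <- hex_names
  # shared edge CD2 (row 1) -> CE2 (row 6); build a regular pentagon on the
  # far side of that edge
  p1 <- hex["CE2", ]; p2 <- hex["CD2", ]
  e <- p2 - p1
  elen <- sqrt(sum(e^2))
  ex <- e / elen
  ey <- c(-ex[2], ex[1])
  mid <- (p1 + p2) / 2
  if (sum((mid + ey) ^ 2) < sum((mid - ey)^2)) ey <- -ey  # point away from hexagon center
  rp <- elen / (2 * sin(pi / 5))       # pentagon circumradius
  apo <- rp * cos(pi / 5)              # apothem
  ctr <- mid + ey * apo
  penta_ang <- atan2((p1 - ctr)[2], (p1 - ctr)[1])
  step <- 2 * pi / 5
  # walk around: CE2 -> NE1 -> CD1 -> CG -> CD2
  dir <- if (abs(sum((ctr + rp * c(cos(penta_ang - step), sin(penta_ang - step)) - p2)^2)) <
             abs(sum((ctr + rp * c(cos(penta_ang + step), sin(penta_ang + step)) - p2)^2))) 1 else -1
  idx <- penta_ang + dir * step * 1:3
  pent <- cbind(ctr[1] + rp * cos(idx), ctr[2] + rp * sin(idx))
  rownames(pent) <- c("NE1", "CD1", "CG")
  xyz <- rbind(hex, pent)
  xyz <- cbind(xyz, 0)
  xyz <- sweep(xyz, 2, c(colMeans(xyz[, 1:2]), 0))
  colnames(xyz) <- c("x", "y", "z")
  tibble(atom = rownames(xyz),
         element = ifelse(substr(rownames(xyz), 1, 1) == "N", "N", "C"),
         x = xyz[, "x"], y = xyz[, "y"], z = xyz[, "z"])
}

#' Build a toy structure with placed indole pairs and background atoms
#'
#' Places idealized planar indole rings (as TRP residues on chain "A") at
#' controlled separations and orientations, plus optional random single-atom
#' background residues (chain "Z") inside a cubic box, with bookkeeping valid
#' for the PDB writer/reader. Used to exercise the geometry and
#' microenvironment code against constructions with known answers.
#'
#' Each element of `pairs` is a list with `r` (center-center distance,
#' Angstrom), `direction` (unit-ish vector from donor center to acceptor
#' center in the donor frame; default `c(0, 0, 1)`, i.e. along the donor ring
#' normal, giving parallel dipoles perpendicular to the separation), and
#' `rotate` (Euler angles in degrees applied to the acceptor ring about its
#' center; default no rotation).
#'
#' @param pairs List of pair specifications (see Details). Default: one pair
#'   at 7.8 Angstrom along the ring normal.
#' @param n_background_atoms Number of random background atoms (default 0).
#' @param box Edge length of the placement cube, Angstrom (default 40).
#' @param seed Integer seed (default 1).
#' @param min_separation Minimum distance between a background atom and any
#'   existing atom (default 1.5 Angstrom); placements closer than this are
#'   re-sampled up to 200 times, then an error is raised.
#' @return A `protein_structure`.
#' @export
build_toy_structure <- function(pairs = list(list(r = 7.8)),
                                n_background_atoms = 0, box = 40, seed = 1,
                                min_separation = 1.5) {
  tmpl <- indole_template()
  atoms <- NULL
  resno <- 0
  spacing <- box / max(1, length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    if (is.null(pr$r) || pr$r <= 0) abort("Each pair needs a distance r > 0.")
    dir <- unit(pr$direction %||% c(0, 0, 1))
    rot <- pr$rotate %||% c(0, 0, 0)
    offset <- c((i - 1) * spacing, 0, 0)
    donor <- tmpl
    donor[, c("x", "y", "z")] <- sweep(as.matrix(tmpl[, c("x", "y", "z")]),
                                       2, offset, "+")
    rotm <- euler_matrix(rot[1] * pi / 180, rot[2] * pi / 180,
                         rot[3] * pi / 180)
    acc_xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(rotm)
    acc_xyz <- sweep(acc_xyz, 2, offset + pr$r * dir, "+")
    acceptor <- tmpl
    acceptor[, c("x", "y", "z")] <- acc_xyz
    donor <- mutate(donor, chain = "A", resno = resno + 1L, resname = "TRP")
    acceptor <- mutate(acceptor, chain = "A", resno = resno + 2L,
                       resname = "TRP")
    resno <- resno + 2
    atoms <- bind_rows(atoms, donor, acceptor)
  }
  if (n_background_atoms > 0) {
    bg <- withr::with_seed(seed, {
      placed <- matrix(NA_real_, n_background_atoms, 3)
      existing <- as.matrix(atoms[, c("x", "y", "z")])
      for (i in seq_len(n_background_atoms)) {
        ok <- FALSE
        for (try in seq_len(200)) {
          cand <- stats::runif(3, -box / 2, box / 2)
          all_xyz <- rbind(existing, placed[seq_len(i - 1), , drop = FALSE])
          if (nrow(all_xyz) == 0 ||
              min(sqrt(rowSums(sweep(all_xyz, 2, cand)^2))) >= min_separation) {
            ok <- TRUE; break
          }
        }
        if (!ok) abort("Could not place background atoms without overlap.")
        placed[i, ] <- cand
      }
      placed
    })
    atoms <- bind_rows(atoms, tibble(
      atom = "CA", element = "C", x = bg[, 1], y = bg[, 2], z = bg[, 3],
      chain = "Z", resno = seq_len(n_background_atoms) + resno,
      resname = "GLY"))
  }
  as_protein_structure(atoms)
}

#' Simulate a jittered trajectory from a base structure
#'
#' Replicates the base coordinates over `n_frames` models and adds i.i.d.
#' Gaussian displacement per atom per frame: a stand-in for thermal frame
#' scatter when testing frame-wise analyses. Not a physical dynamics model.
#'
#' @param base A single-model `protein_structure`.
#' @param n_frames Number of frames (>= 1).
#' @param jitter_sd Displacement sd in Angstrom per coordinate (default 0.3).
#' @param seed Integer seed (default 1).
#' @return A multi-model `protein_structure` with `n_frames` models.
#' @export
simulate_trajectory <- function(base, n_frames, jitter_sd = 0.3, seed = 1) {
  if (n_frames < 1) abort("`n_frames` must be >= 1.")
  a <- model_atoms(base, 1)
  frames <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_frames), function(f) {
      fa <- a
      fa$model <- f
      if (jitter_sd > 0) {
        fa$x <- fa$x + stats::rnorm(nrow(fa), sd = jitter_sd)
        fa$y <- fa$y + stats::rnorm(nrow(fa), sd = jitter_sd)
        fa$z <- fa$z + stats::rnorm(nrow(fa), sd = jitter_sd)
      }
      fa
    })
  })
  as_protein_structure(frames, sec = base$sec, chain_roles = base$chain_roles)
}
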