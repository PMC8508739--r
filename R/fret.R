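# the 9 indole ring atoms of tryptophan, PDB naming
indole_ring_atoms <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                       "CZ2", "CZ3", "CH2")

# atomic masses for mass-weighted ring centers
atom_masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)

#' Indole ring geometry of a tryptophan residue
#'
#' Extracts the 9-atom indole ring, its center (geometric or mass-weighted),
#' the best-fit ring plane normal, and the emission transition-dipole
#' direction. The dipole is modelled as an in-plane unit vector obtained by
#' rotating the ring's long-axis reference (the CE3-to-NE1 direction projected
#' into the plane) about the plane normal by `dipole_angle_deg`; the default
#' of -38 degrees approximates the commonly assumed orientation of the
#' environment-sensitive (1La) transition moment of indole. The normal's sign
#' is fixed from the ring atom order so the rotation is reproducible.
#'
#' @param structure A `protein_structure`.
#' @param chain,resno Residue identity (must be a tryptophan with all 9 ring
#'   atoms present).
#' @param model Model index (default 1).
#' @param center `"geometric"` (default) or `"mass"`.
#' @param dipole_angle_deg In-plane rotation from the projected long axis,
#'   degrees (default -38).
#' @return Object of class `indole_geometry`: list with `ring` (atom tibble),
#'   `center`, `normal`, `long_axis`, `dipole`, `dipole_angle_deg`.
#' @export
indole_geometry <- function(structure, chain, resno, model = 1,
                            center = c("geometric", "mass"),
                            dipole_angle_deg = -38) {
  center <- match.arg(center)
  res <- residue_atoms(structure, chain, resno, model)
  ring <- res[match(indole_ring_atoms, res$atom), ]
  if (any(is.na(ring$atom))) {
    missing <- setdiff(indole_ring_atoms, res$atom)
    abort(sprintf("Residue %s:%s is missing indole ring atom(s): %s",
                  chain, resno, paste(missing, collapse = ", ")))
  }
  xyz <- unname(as.matrix(ring[, c("x", "y", "z")]))
  ctr <- ring_center(xyz, ring$element, center)
  geo_ctr <- colMeans(xyz)
  centered <- sweep(xyz, 2, geo_ctr)
  sv <- svd(centered)
  if (sv$d[2] < 1e-6) abort("Degenerate ring geometry: atoms are collinear.")
  normal <- sv$v[, 3]
  # deterministic sign from the ring atom order
  ref <- cross3(xyz[indole_ring_atoms == "NE1", ] - xyz[indole_ring_atoms == "CE3", ],
                xyz[indole_ring_atoms == "CD1", ] - xyz[indole_ring_atoms == "CE3", ])
  if (sum(ref * normal) < 0) normal <- -normal
  long_raw <- xyz[indole_ring_atoms == "NE1", ] - xyz[indole_ring_atoms == "CE3", ]
  long_axis <- unit(long_raw - sum(long_raw * normal) * normal)
  dipole <- rotate_about(long_axis, normal, dipole_angle_deg * pi / 180)
  structure(list(ring = ring, center = ctr, normal = normal,
                 long_axis = long_axis, dipole = unit(dipole),
                 dipole_angle_deg = dipole_angle_deg),
            class = "indole_geometry")
}

ring_center <- function(xyz, elements, center = "geometric") {
  if (center == "mass") {
    w <- atom_masses[elements]
    w[is.na(w)] <- mean(atom_masses[c("C", "N")])
    colSums(xyz * w) / sum(w)
  } else {
    colMeans(xyz)
  }
}

#' Indole ring center of a tryptophan
#'
#' @inheritParams indole_geometry
#' @return Numeric length-3 vector (Angstrom).
#' @export
indole_center <- function(structure, chain, resno, model = 1,
                          center = c("geometric", "mass")) {
  indole_geometry(structure, chain, resno, model = model,
                  center = center)$center
}

#' FRET orientation factor kappa squared
#'
#' \eqn{\kappa^2 = (\cos\theta - 3\cos\theta_A\cos\theta_D)^2}, where
#' \eqn{\theta} is the angle between donor and acceptor transition dipoles and
#' \eqn{\theta_D}, \eqn{\theta_A} the angles each dipole makes with the vector
#' joining the two ring centers. Ranges from 0 to 4; the isotropic dynamic
#' average is 2/3. Symmetric under donor/acceptor exchange.
#'
#' @param donor,acceptor `indole_geometry` objects, or lists with unit
#'   `dipole` and `center` elements.
#' @return kappa squared (dimensionless).
#' @export
kappa_squared <- function(donor, acceptor) {
  r <- acceptor$center - donor$center
  if (sqrt(sum(r^2)) < 1e-9) abort("Donor and acceptor centers coincide.")
  rhat <- unit(r)
  d <- unit(donor$dipole)
  a <- unit(acceptor$dipole)
  (sum(d * a) - 3 * sum(a * rhat) * sum(d * rhat))^2
}

#' FRET efficiency from distance and orientation
#'
#' \eqn{E = \left[1 + \frac{2/3}{\kappa^2}\left(\frac{R}{R_0}\right)^6\right]^{-1}}.
#' The Forster radius \eqn{R_0} is defined for the isotropic orientation
#' average, so the orientation factor enters relative to 2/3. For
#' \eqn{\kappa^2 = 0} the efficiency is 0 (continuity limit). The default
#' \eqn{R_0 = 7.8} Angstrom is the accepted value for the Trp-Trp
#' (indole-indole) donor-acceptor pair.
#'
#' @param kappa2 Orientation factor(s), >= 0.
#' @param r Donor-acceptor distance(s), Angstrom, > 0.
#' @param r0 Forster radius, Angstrom (default 7.8).
#' @return Efficiency in \[0, 1\] (vectorized).
#' @export
fret_efficiency <- function(kappa2, r, r0 = 7.8) {
  if (any(r <= 0) || any(r0 <= 0)) abort("`r` and `r0` must be > 0.")
  if (any(kappa2 < 0)) abort("`kappa2` must be >= 0.")
  # kappa2 = 0 gives (2/3)/0 = Inf and hence E = 0, the continuity limit
  1 / (1 + (2 / 3) / kappa2 * (r / r0)^6)
}

#' Full FRET geometry report for a tryptophan pair
#'
#' Computes the center-center distance, orientation factor and transfer
#' efficiency for a donor/acceptor tryptophan pair in a structure, plus a
#' sensitivity range of kappa squared and efficiency over a grid of in-plane
#' dipole angles around the assumed one (the transition-moment direction
#' within the ring plane is a modelling choice, so its impact is surfaced).
#'
#' @param structure A `protein_structure`.
#' @param donor,acceptor Residue selectors, `"chain:resno"` strings (see
#'   [parse_residue_selector()]).
#' @param r0 Forster radius, Angstrom (default 7.8).
#' @param dipole_angle_deg In-plane dipole angle, degrees (default -38).
#' @param sensitivity_deg Half-width of the angle scan (default 15; 0 turns
#'   the scan off).
#' @param model Model index (default 1).
#' @param center Ring center convention (default `"geometric"`).
#' @return Object of class `fret_pair`: list with `r`, `kappa2`, `efficiency`,
#'   `r0`, `dipole_angle_deg`, `kappa2_range`, `efficiency_range`, `donor`,
#'   `acceptor`.
#' @export
fret_pair <- function(structure, donor, acceptor, r0 = 7.8,
                      dipole_angle_deg = -38, sensitivity_deg = 15,
                      model = 1, center = c("geometric", "mass")) {
  center <- match.arg(center)
  dsel <- parse_residue_selector(donor)
  asel <- parse_residue_selector(acceptor)
  geo <- function(sel, angle) {
    indole_geometry(structure, sel$chain, sel$resno, model = model,
                    center = center, dipole_angle_deg = angle)
  }
  dg <- geo(dsel, dipole_angle_deg)
  ag <- geo(asel, dipole_angle_deg)
  r <- sqrt(sum((ag$center - dg$center)^2))
  k2 <- kappa_squared(dg, ag)
  eff <- fret_efficiency(k2, r, r0)
  k2_range <- eff_range <- NULL
  if (sensitivity_deg > 0) {
    angles <- dipole_angle_deg + seq(-sensitivity_deg, sensitivity_deg,
                                     length.out = 7)
    grid <- expand.grid(da = angles, aa = angles)
    k2s <- purrr::map2_dbl(grid$da, grid$aa, function(da, aa) {
      kappa_squared(geo(dsel, da), geo(asel, aa))
    })
    k2_range <- range(k2s)
    eff_range <- range(fret_efficiency(k2s, r, r0))
  }
  structure(list(r = r, kappa2 = k2, efficiency = eff, r0 = r0,
                 dipole_angle_deg = dipole_angle_deg,
                 sensitivity_deg = sensitivity_deg,
                 kappa2_range = k2_range, efficiency_range = eff_range,
                 donor = dg, acceptor = ag,
                 donor_id = dsel, acceptor_id = asel),
            class = "fret_pair")
}

#' @export
print.fret_pair <- function(x, ...) {
  cat(sprintf("Trp-Trp FRET pair %s:%d -> %s:%d\n",
              x$donor_id$chain, x$donor_id$resno,
              x$acceptor_id$chain, x$acceptor_id$resno))
  cat(sprintf("  R = %.2f A, kappa2 = %.3f, E = %.1f%% (R0 = %.1f A)\n",
              x$r, x$kappa2, 100 * x$efficiency, x$r0))
  if (!is.null(x$kappa2_range)) {
    cat(sprintf("  dipole angle %g deg +/- %g: kappa2 in [%.3f, %.3f], E in [%.1f%%, %.1f%%]\n",
                x$dipole_angle_deg, x$sensitivity_deg,
                x$kappa2_range[1], x$kappa2_range[2],
                100 * x$efficiency_range[1], 100 * x$efficiency_range[2]))
  }
  invisible(x)
}

#' Inter-tryptophan distance distribution over trajectory frames
#'
#' Center-to-center distances between two tryptophan indole rings in every
#' model (frame) of a multi-model structure, histogrammed with a fixed bin
#' width. Mass-weighted ring centers are the default here, matching how such
#' distributions are computed from MD trajectories.
#'
#' @param structure A (multi-model) `protein_structure`.
#' @param a,b Residue selectors (`"chain:resno"`).
#' @param bin_width Histogram bin width in Angstrom (default 0.25).
#' @param center Ring-center convention (default `"mass"`).
#' @return Object of class `distance_distribution`: list with `distances`
#'   (tibble `model`, `distance`), `histogram` (tibble `lower`, `upper`,
#'   `mid`, `count`), and `summary` (mean/sd/min/max/n_frames).
#' @export
distance_distribution <- function(structure, a, b, bin_width = 0.25,
                                  center = c("mass", "geometric")) {
  center <- match.arg(center)
  sa <- parse_residue_selector(a)
  sb <- parse_residue_selector(b)
  frames <- seq_len(n_models(structure))
  d <- vapply(frames, function(m) {
    ca <- tryCatch(indole_center(structure, sa$chain, sa$resno, model = m,
                                 center = center),
                   error = function(e) abort(sprintf(
                     "Frame %d: %s", m, conditionMessage(e))))
    cb <- tryCatch(indole_center(structure, sb$chain, sb$resno, model = m,
                                 center = center),
                   error = function(e) abort(sprintf(
                     "Frame %d: %s", m, conditionMessage(e))))
    sqrt(sum((cb - ca)^2))
  }, numeric(1))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (max(breaks) < hi) breaks <- c(breaks, max(breaks) + bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE, right = FALSE)
  structure(list(
    distances = tibble(model = frames, distance = d),
    histogram = tibble(lower = h$breaks[-length(h$breaks)],
                       upper = h$breaks[-1], mid = h$mids, count = h$counts),
    summary = tibble(n_frames = length(d), mean = mean(d),
                     sd = stats::sd(d), min = min(d), max = max(d)),
    bin_width = bin_width, center = center,
    pair = list(a = sa, b = sb)
  ), class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Indole-indole distance over %d frame(s): mean %.2f A (sd %.2f), range [%.2f, %.2f]\n",
    s$n_frames, s$mean, s$sd, s$min, s$max))
  invisible(x)
}
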