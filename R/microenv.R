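# van der Waals radii (Angstrom) used for SASA; a fixed published table
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
polar_elements_default <- c("N", "O")

#' Microenvironment atoms of a tryptophan
#'
#' Returns every protein atom whose minimum distance to the reference atom set
#' of the given tryptophan (all of its atoms, or its side-chain atoms only) is
#' within `cutoff`. Atoms of the tryptophan's own residue are excluded;
#' hydrogens are excluded by default so crystal structures and MD frames are
#' comparable.
#'
#' @param structure A `protein_structure`.
#' @param chain,resno Residue identity of the tryptophan.
#' @param cutoff Distance cutoff in Angstrom (default 7).
#' @param reference `"all"` (default) or `"sidechain"` (atoms beyond the
#'   backbone N, CA, C, O).
#' @param model Model index (default 1).
#' @param include_hydrogens Count hydrogens too (default `FALSE`).
#' @return Tibble of neighboring atoms with an extra column `min_dist`.
#' @export
microenv_atoms <- function(structure, chain, resno, cutoff = 7,
                           reference = c("all", "sidechain"), model = 1,
                           include_hydrogens = FALSE) {
  reference <- match.arg(reference)
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  a <- model_atoms(structure, model)
  own <- a[a$chain == chain & a$resno == resno, ]
  if (nrow(own) == 0) {
    abort(sprintf("No residue %s:%s in model %d.", chain, resno, model))
  }
  ref <- own
  if (reference == "sidechain") {
    ref <- ref[!ref$atom %in% c("N", "CA", "C", "O", "OXT"), ]
  }
  others <- a[!(a$chain == chain & a$resno == resno), ]
  if (!include_hydrogens) {
    ref <- ref[ref$element != "H", ]
    others <- others[others$element != "H", ]
  }
  if (nrow(ref) == 0 || nrow(others) == 0) {
    return(mutate(others[0, ], min_dist = numeric(0)))
  }
  rm_ <- as.matrix(ref[, c("x", "y", "z")])
  om <- as.matrix(others[, c("x", "y", "z")])
  # min distance from each candidate atom to the reference set
  d2 <- outer(rowSums(om^2), rowSums(rm_^2), "+") - 2 * om %*% t(rm_)
  others$min_dist <- sqrt(pmax(apply(d2, 1, min), 0))
  filter(others, .data$min_dist <= cutoff)
}

#' Count atoms in a tryptophan's microenvironment
#'
#' The neighbor-count descriptors: all protein atoms within the cutoff of any
#' tryptophan atom (total packing density), only polar atoms, only atoms of a
#' given domain or subunit, etc.
#'
#' @inheritParams microenv_atoms
#' @param selection `"all"` (default), `"polar"` (N/O atoms; add S via
#'   `polar_sulfur`), or a predicate function taking the neighbor-atom tibble
#'   and returning a logical vector.
#' @param polar_sulfur Count sulfur as polar (default `FALSE`).
#' @return Integer atom count.
#' @export
count_neighbors <- function(structure, chain, resno, cutoff = 7,
                            reference = c("all", "sidechain"),
                            selection = "all", model = 1,
                            include_hydrogens = FALSE, polar_sulfur = FALSE) {
  nb <- microenv_atoms(structure, chain, resno, cutoff = cutoff,
                       reference = reference, model = model,
                       include_hydrogens = include_hydrogens)
  if (is.function(selection)) {
    sum(selection(nb))
  } else if (identical(selection, "polar")) {
    pol <- polar_elements_default
    if (polar_sulfur) pol <- c(pol, "S")
    sum(nb$element %in% pol)
  } else if (identical(selection, "all")) {
    nrow(nb)
  } else {
    abort("`selection` must be \"all\", \"polar\", or a function.")
  }
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom solvent-accessible surface area by probe-sphere point sampling:
#' each atom's van der Waals sphere is inflated by the probe radius and covered
#' with a deterministic Fibonacci point lattice; the accessible area is the
#' fraction of points not buried inside any neighboring inflated sphere.
#'
#' @param structure A `protein_structure`.
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Sample points per atom (default 960).
#' @param model Model index (default 1).
#' @param include_hydrogens Include hydrogens (default `FALSE`).
#' @param default_radius Radius used (with a warning) for elements missing
#'   from the van der Waals table (default 1.70).
#' @return The model's atom tibble with an added column `area` (Angstrom^2).
#' @export
compute_sasa <- function(structure, probe = 1.4, n_points = 960, model = 1,
                         include_hydrogens = FALSE, default_radius = 1.70) {
  a <- model_atoms(structure, model)
  if (!include_hydrogens) a <- a[a$element != "H", ]
  if (nrow(a) == 0) abort("No atoms to compute SASA for.")
  radii <- unname(vdw_radii[a$element])
  if (any(is.na(radii))) {
    warn(paste("Unknown element(s)",
               paste(unique(a$element[is.na(radii)]), collapse = ", "),
               "- using default radius", default_radius))
    radii[is.na(radii)] <- default_radius
  }
  pts <- fibonacci_sphere(n_points)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r_ext <- radii + probe
  n <- nrow(a)
  area <- numeric(n)
  # neighbor prefilter: spheres can only intersect within the sum of radii
  maxr <- max(r_ext)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r_ext[i] + r_ext)^2 & seq_len(n) != i)
    p <- sweep(pts * r_ext[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, nrow(p))
      for (j in nb) {
        if (!any(free)) break
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        free <- free & (dj2 > r_ext[j]^2)
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    area[i] <- 4 * pi * r_ext[i]^2 * frac
  }
  a$area <- area
  a
}

# deterministic, nearly uniform points on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Absolute and relative SASA of one residue
#'
#' Relative SASA compares the residue's surface in the context of the whole
#' structure against the same residue with every other residue deleted
#' (residue-in-isolation reference), as a percentage.
#'
#' @inheritParams compute_sasa
#' @param chain,resno Residue identity.
#' @return Tibble with columns `sasa_abs` (Angstrom^2) and `sasa_rel` (%).
#' @export
residue_sasa <- function(structure, chain, resno, probe = 1.4,
                         n_points = 960, model = 1) {
  ctx <- compute_sasa(structure, probe = probe, n_points = n_points,
                      model = model)
  in_ctx <- sum(ctx$area[ctx$chain == chain & ctx$resno == resno])
  a <- model_atoms(structure, model)
  own <- a[a$chain == chain & a$resno == resno, ]
  own$model <- 1L
  iso <- as_protein_structure(own)
  iso_area <- sum(compute_sasa(iso, probe = probe, n_points = n_points)$area)
  tibble(sasa_abs = in_ctx,
         sasa_rel = if (iso_area > 0) 100 * in_ctx / iso_area else NA_real_)
}

#' Fraction of microenvironment atoms in regular secondary structure
#'
#' Percentage of a tryptophan's neighboring atoms that belong to residues
#' labelled helix or strand. Uses the structure's secondary-structure
#' annotation; when absent, the dihedral fallback [assign_secondary_structure()]
#' is applied (or a missing value returned if `fallback = FALSE`).
#'
#' @inheritParams microenv_atoms
#' @param fallback Assign secondary structure heuristically when no
#'   annotation is present (default `TRUE`).
#' @return Percentage in \[0, 100\], or `NA` when undefined.
#' @export
secondary_structure_fraction <- function(structure, chain, resno, cutoff = 7,
                                         model = 1, fallback = TRUE) {
  if (is.null(structure$sec)) {
    if (!fallback) {
      warn("No secondary-structure annotation and fallback disabled.")
      return(NA_real_)
    }
    structure <- assign_secondary_structure(structure, model = model)
  }
  nb <- microenv_atoms(structure, chain, resno, cutoff = cutoff, model = model)
  if (nrow(nb) == 0) {
    warn("Empty microenvironment; secondary-structure fraction undefined.")
    return(NA_real_)
  }
  lab <- nb |>
    left_join(structure$sec, by = c("chain", "resno"))
  100 * sum(lab$ss %in% c("H", "E")) / nrow(nb)
}

# quencher atom catalogue: mechanism -> residue/atom selectors
quencher_catalogue <- list(
  list(mechanism = "proton-transfer-amino", resname = "LYS", atoms = "NZ"),
  list(mechanism = "proton-transfer-hydroxyl", resname = "TYR", atoms = "OH"),
  list(mechanism = "electron-transfer-sulfur", resname = "CYS", atoms = "SG"),
  list(mechanism = "electron-transfer-amide", resname = "GLN",
       atoms = c("CD", "OE1", "NE2")),
  list(mechanism = "electron-transfer-amide", resname = "ASN",
       atoms = c("CG", "OD1", "ND2")),
  list(mechanism = "electron-transfer-amide", resname = "HIS",
       atoms = c("ND1", "NE2", "CE1")),
  list(mechanism = "electron-transfer-carboxyl", resname = "ASP",
       atoms = c("CG", "OD1", "OD2")),
  list(mechanism = "electron-transfer-carboxyl", resname = "GLU",
       atoms = c("CD", "OE1", "OE2"))
)

#' Screen for potential fluorescence quenchers around a tryptophan
#'
#' Reports side-chain groups known to quench indole fluorescence that lie
#' within the cutoff of the tryptophan's indole ring: amino/hydroxyl groups
#' capable of excited-state proton transfer (Lys, Tyr), electron-accepting
#' sulfur, amide and carboxyl groups (Cys; His/Gln/Asn; Asp/Glu), and backbone
#' carbonyl carbons near the ring's CE3 atom (backbone electron transfer; the
#' tryptophan's own carbonyl is considered for this mechanism).
#'
#' @inheritParams microenv_atoms
#' @param cutoff Contact cutoff in Angstrom (default 5.5).
#' @return Tibble with columns `chain`, `resno`, `resname`, `atom`,
#'   `distance`, `mechanism` (possibly empty), sorted by distance.
#' @export
screen_quenchers <- function(structure, chain, resno, cutoff = 5.5,
                             model = 1) {
  a <- model_atoms(structure, model)
  ring <- residue_atoms(structure, chain, resno, model)
  ring <- ring[ring$atom %in% indole_ring_atoms, ]
  if (nrow(ring) == 0) {
    abort(sprintf("Residue %s:%s has no indole ring atoms.", chain, resno))
  }
  ring_xyz <- as.matrix(ring[, c("x", "y", "z")])
  min_dist_to_ring <- function(tb) {
    m <- as.matrix(tb[, c("x", "y", "z")])
    d2 <- outer(rowSums(m^2), rowSums(ring_xyz^2), "+") -
      2 * m %*% t(ring_xyz)
    sqrt(pmax(apply(d2, 1, min), 0))
  }
  hits <- purrr::map_dfr(quencher_catalogue, function(q) {
    cand <- a[a$resname == q$resname & a$atom %in% q$atoms &
                !(a$chain == chain & a$resno == resno), ]
    if (nrow(cand) == 0) return(NULL)
    cand$distance <- min_dist_to_ring(cand)
    cand$mechanism <- q$mechanism
    cand[cand$distance <= cutoff,
         c("chain", "resno", "resname", "atom", "distance", "mechanism")]
  })
  # backbone carbonyl carbons near the benzene-ring CE3 atom (own residue too)
  ce3 <- ring[ring$atom == "CE3", ]
  if (nrow(ce3) == 1) {
    carb <- a[a$atom == "C", ]
    if (nrow(carb)) {
      carb$distance <- sqrt((carb$x - ce3$x)^2 + (carb$y - ce3$y)^2 +
                              (carb$z - ce3$z)^2)
      carb$mechanism <- "backbone-carbonyl"
      hits <- bind_rows(hits, carb[carb$distance <= cutoff,
        c("chain", "resno", "resname", "atom", "distance", "mechanism")])
    }
  }
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble(chain = character(), resno = integer(),
                  resname = character(), atom = character(),
                  distance = numeric(), mechanism = character()))
  }
  arrange(as_tibble(hits), .data$distance)
}

#' Per-tryptophan microenvironment descriptor table
#'
#' Computes, for every tryptophan and every coordinate model, the descriptor
#' set used to rationalize per-residue fluorescence behavior: total and polar
#' neighbor counts within `cutoff`, absolute and relative SASA, the number of
#' neighbors belonging to a designated C-terminal domain, the percentage of
#' neighbors in helix/strand residues, the number of neighbors from
#' other-subunit chains (side-chain reference), and the number of quencher
#' contacts within `quencher_cutoff`.
#'
#' @param structure A `protein_structure` (set `chain_roles` to enable the
#'   other-subunit count).
#' @param cutoff Microenvironment cutoff in Angstrom (default 7).
#' @param quencher_cutoff Quencher-contact cutoff in Angstrom (default 5.5).
#' @param cterm Optional domain definition: a list with `chain`, `from`, `to`
#'   (residue range, default range 236-355 on the alpha-subunit chain when
#'   roles are set).
#' @param probe,n_points SASA parameters, see [compute_sasa()].
#' @param models Model indices to analyze (default: all).
#' @return Tibble, one row per tryptophan per model, with columns
#'   `chain`, `resno`, `model`, `n_total`, `n_polar`, `sasa_abs`, `sasa_rel`,
#'   `n_cterm`, `pct_sec`, `n_other_subunit`, `n_quencher_contacts`.
#' @export
microenv_report <- function(structure, cutoff = 7, quencher_cutoff = 5.5,
                            cterm = NULL, probe = 1.4, n_points = 960,
                            models = NULL) {
  trps <- find_tryptophans(structure)
  if (nrow(trps) == 0) abort("Structure contains no tryptophans.")
  if (is.null(models)) models <- seq_len(n_models(structure))
  if (is.null(cterm) && !is.null(structure$chain_roles)) {
    alpha <- names(structure$chain_roles)[structure$chain_roles == "alpha"]
    if (length(alpha) == 1) cterm <- list(chain = alpha, from = 236, to = 355)
  }
  purrr::map_dfr(models, function(m) {
    purrr::pmap_dfr(trps, function(chain, resno) {
      nb <- microenv_atoms(structure, chain, resno, cutoff = cutoff, model = m)
      n_total <- nrow(nb)
      n_polar <- sum(nb$element %in% polar_elements_default)
      sasa <- residue_sasa(structure, chain, resno, probe = probe,
                           n_points = n_points, model = m)
      n_cterm <- if (!is.null(cterm)) {
        sum(nb$chain == cterm$chain & nb$resno >= cterm$from &
              nb$resno <= cterm$to)
      } else NA_integer_
      pct_sec <- suppressWarnings(
        secondary_structure_fraction(structure, chain, resno,
                                     cutoff = cutoff, model = m))
      n_other <- if (!is.null(structure$chain_roles)) {
        own_role <- structure$chain_roles[chain]
        nb_sc <- microenv_atoms(structure, chain, resno, cutoff = cutoff,
                                reference = "sidechain", model = m)
        roles <- structure$chain_roles[nb_sc$chain]
        sum(!is.na(roles) & roles != own_role)
      } else NA_integer_
      nq <- nrow(screen_quenchers(structure, chain, resno,
                                  cutoff = quencher_cutoff, model = m))
      tibble(chain = chain, resno = resno, model = m,
             n_total = n_total, n_polar = n_polar,
             sasa_abs = sasa$sasa_abs, sasa_rel = sasa$sasa_rel,
             n_cterm = n_cterm, pct_sec = pct_sec,
             n_other_subunit = n_other, n_quencher_contacts = nq)
    })
  })
}

#' Summarise a multi-model microenvironment report
#'
#' Mean and standard deviation of each descriptor over models, mirroring how
#' descriptor variability over trajectory frames is usually reported.
#'
#' @param report Output of [microenv_report()].
#' @return Tibble with one row per tryptophan and `<descriptor>_mean` /
#'   `<descriptor>_sd` columns.
#' @export
summarise_microenv <- function(report) {
  report |>
    group_by(.data$chain, .data$resno) |>
    summarise(across(c("n_total", "n_polar", "sasa_abs", "sasa_rel",
                       "n_cterm", "pct_sec", "n_other_subunit",
                       "n_quencher_contacts"),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~stats::sd(.x, na.rm = TRUE))),
              .groups = "drop")
}
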