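#' Protein structure container
#'
#' A light tidy container for (possibly multi-model) protein coordinates:
#' a tibble of atoms plus optional per-residue secondary-structure labels and
#' a chain-to-subunit role map. All analysis functions in the package accept
#' this object.
#'
#' @param atoms Tibble with columns `model` (integer, >= 1), `chain`,
#'   `resno` (integer), `insert` (character or NA), `resname`, `atom`
#'   (atom name, PDB convention), `element`, `x`, `y`, `z` (Angstrom).
#'   Missing `model`/`insert`/`element` columns are filled in (`element` is
#'   derived from the atom name).
#' @param sec Optional tibble with columns `chain`, `resno`, `ss`
#'   (labels `"H"`, `"E"`, `"C"`).
#' @param chain_roles Optional named character vector mapping chain id to a
#'   subunit label, e.g. `c(A = "alpha", B = "beta")`.
#' @return An object of class `protein_structure`.
#' @export
as_protein_structure <- function(atoms, sec = NULL, chain_roles = NULL) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    abort(paste("`atoms` needs columns:", paste(need, collapse = ", ")))
  }
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  atoms$model[is.na(atoms$model)] <- 1L
  if (!"insert" %in% names(atoms)) atoms$insert <- NA_character_
  if (!"element" %in% names(atoms)) {
    atoms$element <- guess_element(atoms$atom)
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("All coordinates must be finite.")
  }
  atoms$model <- as.integer(atoms$model)
  atoms$resno <- as.integer(atoms$resno)
  if (!is.null(chain_roles)) {
    missing_ch <- setdiff(names(chain_roles), unique(atoms$chain))
    if (length(missing_ch)) {
      abort(paste("chain_roles refers to absent chain(s):",
                  paste(missing_ch, collapse = ", ")))
    }
  }
  structure(list(atoms = atoms, sec = sec, chain_roles = chain_roles),
            class = "protein_structure")
}

# element symbol from a PDB atom name ("CA" -> C, "NE1" -> N, "1HB" -> H)
guess_element <- function(atom_name) {
  nm <- toupper(gsub("[0-9' ]", "", atom_name))
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  metals <- c("FE", "ZN", "MG", "MN", "SE", "CL", "BR")
  el[two %in% metals] <- two[two %in% metals]
  el
}

#' @export
print.protein_structure <- function(x, ...) {
  nm <- max(x$atoms$model)
  cat(sprintf("<protein_structure> %d atoms, %d model(s), chains: %s\n",
              nrow(x$atoms[x$atoms$model == 1, ]), nm,
              paste(sort(unique(x$atoms$chain)), collapse = " ")))
  if (!is.null(x$chain_roles)) {
    cat("  roles:", paste(names(x$chain_roles), x$chain_roles, sep = "=",
                          collapse = ", "), "\n")
  }
  if (!is.null(x$sec)) cat("  secondary structure: annotated\n")
  invisible(x)
}

#' Number of coordinate models in a structure
#' @param structure A `protein_structure`.
#' @return Integer count of models (trajectory frames).
#' @export
n_models <- function(structure) max(structure$atoms$model)

# atoms of one model (or all)
model_atoms <- function(structure, model = NULL) {
  a <- structure$atoms
  if (is.null(model)) a else a[which(a$model == model), ]
}

residue_atoms <- function(structure, chain, resno, model = 1) {
  a <- model_atoms(structure, model)
  a[a$chain == chain & a$resno == resno, ]
}

#' Read a PDB file into a protein_structure
#'
#' Parses ATOM/HETATM records (single- or multi-MODEL) plus HELIX/SHEET
#' annotations. Alternate locations are resolved by keeping, per residue, the
#' altloc with the highest occupancy; insertion codes are preserved as part of
#' residue identity. Hydrogens are kept in the atom table (analysis functions
#' exclude them by default).
#'
#' @param path Path to a PDB file.
#' @param chain_roles Optional named character vector, see
#'   [as_protein_structure()].
#' @return A `protein_structure`.
#' @export
read_pdb <- function(path, chain_roles = NULL) {
  if (!file.exists(path)) abort(paste("No such file:", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(paste0("PDB parse error in '", path, "': ",
                                     conditionMessage(e))))
  at <- as_tibble(pdb$atom)
  at$row_idx <- seq_len(nrow(at))
  # altloc: keep NA or, per residue, the highest-occupancy altloc letter
  if (any(!is.na(at$alt))) {
    pick <- at |>
      filter(!is.na(.data$alt)) |>
      group_by(.data$chain, .data$resno, .data$insert) |>
      summarise(keep_alt = .data$alt[which.max(.data$o)], .groups = "drop")
    at <- at |>
      left_join(pick, by = c("chain", "resno", "insert")) |>
      filter(is.na(.data$alt) | .data$alt == .data$keep_alt) |>
      select(-"keep_alt")
  }
  n_mod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  col_idx <- as.vector(rbind(3 * at$row_idx - 2, 3 * at$row_idx - 1,
                             3 * at$row_idx))
  base <- tibble(
    chain = at$chain, resno = as.integer(at$resno),
    insert = as.character(at$insert), resname = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     guess_element(at$elety), toupper(at$elesy)))
  atoms <- purrr::map_dfr(seq_len(n_mod), function(m) {
    xyz_all <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else as.numeric(pdb$xyz)
    xyz <- xyz_all[col_idx]
    mm <- base
    mm$model <- m
    mm$x <- xyz[seq(1, length(xyz), by = 3)]
    mm$y <- xyz[seq(2, length(xyz), by = 3)]
    mm$z <- xyz[seq(3, length(xyz), by = 3)]
    mm
  })
  sec <- pdb_sec_annotations(pdb)
  as_protein_structure(atoms, sec = sec, chain_roles = chain_roles)
}

pdb_sec_annotations <- function(pdb) {
  expand <- function(rec, label) {
    if (is.null(rec) || length(rec$start) == 0) return(NULL)
    purrr::pmap_dfr(
      list(as.numeric(rec$start), as.numeric(rec$end), rec$chain),
      function(s, e, ch) tibble(chain = ch, resno = seq(s, e), ss = label))
  }
  sec <- bind_rows(expand(pdb$helix, "H"), expand(pdb$sheet, "E"))
  if (is.null(sec) || nrow(sec) == 0) NULL else distinct(sec)
}

#' Write a protein_structure to a PDB file
#'
#' Fixed-width PDB writer covering ATOM, MODEL/ENDMDL, and HELIX/SHEET
#' records (from the structure's secondary-structure annotation, if any).
#' Coordinates are written at 3-decimal precision, so a write/read round trip
#' preserves the atom table at that precision.
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  lines <- character()
  if (!is.null(structure$sec)) {
    lines <- c(lines, sec_records(structure$sec))
  }
  nmod <- n_models(structure)
  for (m in seq_len(nmod)) {
    a <- model_atoms(structure, m)
    if (nmod > 1) lines <- c(lines, sprintf("MODEL     %4d", m))
    nm <- ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom)
    rec <- sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000, nm, " ", a$resname, a$chain, a$resno,
      ifelse(is.na(a$insert), " ", a$insert), a$x, a$y, a$z, 1, 0, a$element)
    lines <- c(lines, rec)
    if (nmod > 1) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

sec_records <- function(sec) {
  runs <- sec |>
    arrange(.data$chain, .data$resno) |>
    group_by(.data$chain, .data$ss) |>
    mutate(run = cumsum(c(1, diff(.data$resno) != 1))) |>
    group_by(.data$chain, .data$ss, .data$run) |>
    summarise(start = min(.data$resno), end = max(.data$resno),
              .groups = "drop")
  out <- character()
  hel <- runs[runs$ss == "H", ]
  if (nrow(hel)) {
    out <- c(out, sprintf(
      "HELIX  %3d %3s ALA %1s %4d  ALA %1s %4d  1%30s",
      seq_len(nrow(hel)), seq_len(nrow(hel)), hel$chain, hel$start,
      hel$chain, hel$end, ""))
  }
  sht <- runs[runs$ss == "E", ]
  if (nrow(sht)) {
    out <- c(out, sprintf(
      "SHEET  %3d   S 1 ALA %1s%4d  ALA %1s%4d  0",
      seq_len(nrow(sht)), sht$chain, sht$start, sht$chain, sht$end))
  }
  out
}

#' Locate tryptophan residues in a structure or sequence
#'
#' For a `protein_structure`, returns all TRP residues of the first model; for
#' character amino-acid sequences (optionally a named vector, one entry per
#' chain), returns the positions of `W`. Non-standard residue codes are
#' skipped with a warning.
#'
#' @param x A `protein_structure`, or a (named) character vector of one-letter
#'   amino-acid sequences. `Biostrings` string sets are accepted via
#'   `as.character()`.
#' @return Tibble with columns `chain`, `resno`, ordered by chain then number.
#' @export
find_tryptophans <- function(x) {
  if (inherits(x, "protein_structure")) {
    a <- model_atoms(x, 1)
    std <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
    unknown <- setdiff(unique(a$resname), std)
    if (length(unknown)) {
      warn(paste("Skipping non-standard residue code(s):",
                 paste(unknown, collapse = ", ")))
    }
    out <- a |>
      filter(.data$resname == "TRP") |>
      distinct(.data$chain, .data$resno) |>
      arrange(.data$chain, .data$resno)
    return(out)
  }
  if (!is.character(x)) x <- as.character(x)
  if (is.null(names(x))) {
    names(x) <- if (length(x) == 1) "A" else as.character(seq_along(x))
  }
  aa <- "ACDEFGHIKLMNPQRSTVWY"
  purrr::imap_dfr(x, function(seq, nm) {
    chars <- strsplit(toupper(seq), "")[[1]]
    bad <- setdiff(unique(chars), strsplit(aa, "")[[1]])
    if (length(bad)) {
      warn(paste0("Sequence '", nm, "': skipping unknown residue code(s) ",
                  paste(bad, collapse = ", ")))
    }
    pos <- which(chars == "W")
    if (!length(pos)) return(tibble(chain = character(), resno = integer()))
    tibble(chain = nm, resno = as.integer(pos))
  }) |>
    arrange(.data$chain, .data$resno)
}

#' Attach secondary-structure labels to a structure
#'
#' @param structure A `protein_structure`.
#' @param sec Tibble with columns `chain`, `resno`, `ss` (`"H"`/`"E"`/`"C"`).
#' @return The structure with `sec` replaced.
#' @export
set_secondary_structure <- function(structure, sec) {
  structure$sec <- as_tibble(sec)
  structure
}

#' Heuristic backbone secondary-structure assignment
#'
#' Fallback used when a file carries no HELIX/SHEET records: residues whose
#' backbone dihedrals fall in the canonical alpha-helix or beta-strand regions
#' of the Ramachandran map, in runs of at least `min_run` consecutive
#' residues, are labelled `"H"` or `"E"`; everything else is `"C"`. This is a
#' coarse stand-in for a full hydrogen-bond-based assignment.
#'
#' @param structure A `protein_structure` with backbone N, CA, C atoms.
#' @param min_run Minimum run length (default 3).
#' @param model Model to use (default 1).
#' @return The structure with its `sec` annotation set.
#' @export
assign_secondary_structure <- function(structure, min_run = 3, model = 1) {
  a <- model_atoms(structure, model)
  sec <- purrr::map_dfr(unique(a$chain), function(ch) {
    ca <- a[a$chain == ch & a$atom %in% c("N", "CA", "C"), ]
    resnos <- sort(unique(ca$resno))
    get <- function(rn, nm) {
      r <- ca[ca$resno == rn & ca$atom == nm, ]
      if (nrow(r) != 1) return(NULL)
      c(r$x, r$y, r$z)
    }
    lab <- rep("C", length(resnos))
    for (i in seq_along(resnos)) {
      rn <- resnos[i]
      prev_c <- if (i > 1 && resnos[i - 1] == rn - 1) get(rn - 1, "C") else NULL
      next_n <- if (i < length(resnos) && resnos[i + 1] == rn + 1)
        get(rn + 1, "N") else NULL
      nn <- get(rn, "N"); cca <- get(rn, "CA"); cc <- get(rn, "C")
      if (is.null(prev_c) || is.null(next_n) || is.null(nn) ||
          is.null(cca) || is.null(cc)) next
      phi <- dihedral_angle(prev_c, nn, cca, cc)
      psi <- dihedral_angle(nn, cca, cc, next_n)
      if (phi > -100 && phi < -30 && psi > -80 && psi < -5) lab[i] <- "H"
      else if (phi > -170 && phi < -70 && (psi > 90 || psi < -170)) lab[i] <- "E"
    }
    # suppress runs shorter than min_run
    r <- rle(lab)
    r$values[r$lengths < min_run & r$values != "C"] <- "C"
    tibble(chain = ch, resno = resnos, ss = inverse.rle(r))
  })
  set_secondary_structure(structure, sec)
}

# signed dihedral angle in degrees for points p1-p2-p3-p4
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}
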