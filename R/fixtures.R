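# Synthetic template structures with ground-truth labels, so the whole
# pipeline (search, alignment, analysis, aggregation, classification) can
# run and be validated without any downloaded data.

.FIXTURE_AA <- setdiff(unname(.AA3[1:20]), c("G", "P"))

random_fixture_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(.FIXTURE_AA, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic fixture structure with ground-truth labels
#'
#' Builds idealised structures whose burial/interaction status is known by
#' construction: \code{helix} (isolated alpha-helix, phi = -57, psi = -47),
#' \code{strand} (extended beta geometry), \code{dimer} (two helices facing
#' each other across a designed gap), \code{ligand_complex} (helix plus a
#' heteroresidue placed at a fixed distance from one sidechain) and
#' \code{nucleic_complex} (helix plus a short DNA strand).
#'
#' @param kind one of \code{"helix"}, \code{"strand"}, \code{"dimer"},
#'   \code{"ligand_complex"}, \code{"nucleic_complex"}.
#' @param n residues per protein chain (default 20; dimer default 15 each).
#' @param seed integer seed controlling the sequence draw (deterministic).
#' @param gap designed minimal heavy-atom separation in Angstrom between
#'   the two partners (dimer and complexes; default 4.5).
#' @param contact_residue index of the residue designed to touch the ligand
#'   (ligand complex; default 8).
#' @param resolution resolution written into the model (default 2.0).
#' @return list with \code{model} (a \code{StructureModel}) and
#'   \code{truth}, a data frame of per-residue ground-truth labels
#'   (chain, resnum, interface/ligand/nucleic contact flags, label).
#' @export
generate_fixture <- function(kind = c("helix", "strand", "dimer",
                                      "ligand_complex", "nucleic_complex"),
                             n = NULL, seed = 1, gap = 4.5,
                             contact_residue = 8, resolution = 2.0) {
  kind <- match.arg(kind)
  if (is.null(n)) n <- if (kind == "dimer") 15L else 20L
  if (n < 5) stop("fixture chains need at least 5 residues")
  if (gap <= 0) stop("gap must be positive")
  seq1 <- random_fixture_sequence(n, seed)

  if (kind == "strand") {
    atoms <- build_peptide_atoms(seq1, phi = -120, psi = 130)
  } else {
    atoms <- build_peptide_atoms(seq1, phi = -57, psi = -47)
  }

  if (kind == "dimer") {
    seq2 <- random_fixture_sequence(n, seed + 1)
    b <- build_peptide_atoms(seq2, phi = -57, psi = -47, chain_id = "B")
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    # translate chain B perpendicular to the helix axis until the closest
    # heavy-atom pair sits exactly at the designed gap
    axis <- prcomp(xyz[atoms$name == "CA", ])$rotation[, 1]
    perp <- pracma_cross(axis, c(0, 0, 1))
    if (sqrt(sum(perp^2)) < 1e-6) perp <- pracma_cross(axis, c(0, 1, 0))
    perp <- perp / sqrt(sum(perp^2))
    bxyz <- as.matrix(b[, c("x", "y", "z")])
    shift_for <- function(t) min(cross_dist(xyz, sweep(bxyz, 2, -t * perp)))
    lo <- 0; hi <- 60
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (shift_for(mid) < gap) lo <- mid else hi <- mid
    }
    t_final <- hi
    b[, c("x", "y", "z")] <- sweep(bxyz, 2, -t_final * perp)
    atoms <- rbind(atoms, b)
  }

  if (kind == "ligand_complex") {
    if (contact_residue > n) stop("contact_residue beyond chain length")
    cb <- atoms[atoms$resnum == contact_residue & atoms$name == "CB", ]
    ca <- atoms[atoms$resnum == contact_residue & atoms$name == "CA", ]
    if (nrow(cb) == 0) stop("contact residue lacks a sidechain")
    dir <- unlist(cb[, c("x", "y", "z")]) - unlist(ca[, c("x", "y", "z")])
    dir <- dir / sqrt(sum(dir^2))
    pos <- unlist(cb[, c("x", "y", "z")]) + (gap - 1) * dir
    # pull the ligand out along the sidechain direction until its closest
    # approach to the whole protein equals the designed gap (to CB)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    for (it in 1:200) {
      dmin <- min(cross_dist(xyz, matrix(pos, 1)))
      if (abs(dmin - gap) < 1e-6) break
      pos <- pos + (gap - dmin) * dir
    }
    lig <- data.frame(serial = max(atoms$serial) + 1:2,
                      name = c("C1", "O1"), altloc = " ", resname = "LIG",
                      chain = "L", resnum = 1L, icode = " ",
                      x = c(pos[1], pos[1] + 1.2 * dir[1]),
                      y = c(pos[2], pos[2] + 1.2 * dir[2]),
                      z = c(pos[3], pos[3] + 1.2 * dir[3]),
                      occupancy = 1, bfactor = 20,
                      element = c("C", "O"), is_hetatm = TRUE,
                      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, lig)
  }

  if (kind == "nucleic_complex") {
    mid <- floor(n / 2)
    cb <- atoms[atoms$resnum == mid & atoms$name == "CB", ]
    ca <- atoms[atoms$resnum == mid & atoms$name == "CA", ]
    dir <- unlist(cb[, c("x", "y", "z")]) - unlist(ca[, c("x", "y", "z")])
    dir <- dir / sqrt(sum(dir^2))
    base <- unlist(cb[, c("x", "y", "z")]) + gap * dir
    axis <- c(0, 0, 1)
    nts <- c("DA", "DT", "DG")
    rows <- list()
    for (i in seq_along(nts)) {
      orig <- base + (i - 2) * 6.0 * axis
      for (j in seq_along(c("P", "C1'", "N1"))) {
        nm <- c("P", "C1'", "N1")[j]
        off <- switch(nm, "P" = c(0, 0, 0), "C1'" = 1.6 * dir,
                      "N1" = 3.0 * dir)
        rows[[length(rows) + 1]] <- data.frame(
          serial = 0L, name = nm, altloc = " ", resname = nts[i],
          chain = "D", resnum = i, icode = " ",
          x = orig[1] + off[1], y = orig[2] + off[2], z = orig[3] + off[3],
          occupancy = 1, bfactor = 20,
          element = substr(nm, 1, 1), is_hetatm = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    nuc <- do.call(rbind, rows)
    nuc$serial <- max(atoms$serial) + seq_len(nrow(nuc))
    atoms <- rbind(atoms, nuc)
  }

  rownames(atoms) <- NULL
  atoms$entity <- entity_type_of(atoms$resname)
  entry_id <- sprintf("FX%s%04d", toupper(substr(kind, 1, 2)), seed %% 10000)
  model <- new_structure_model(entry_id, atoms, resolution, is_model = FALSE)
  list(model = model, truth = fixture_truth(model))
}

# Ground truth from the generated coordinates: a protein residue is an
# interface/ligand/nucleic contact iff any heavy-atom pair to the partner
# lies within 5 A (the same geometric criterion the analysis uses).
fixture_truth <- function(model, cutoff = 5.0) {
  a <- model$atoms
  prot <- a[a$entity == "protein", , drop = FALSE]
  keys <- unique(prot[, c("chain", "resnum", "icode")])
  xyz <- as.matrix(a[, c("x", "y", "z")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    idx <- which(a$chain == keys$chain[i] & a$resnum == keys$resnum[i] &
                 a$icode == keys$icode[i] & a$entity == "protein")
    d <- cross_dist(xyz[idx, , drop = FALSE], xyz)
    other_prot <- a$entity == "protein" & a$chain != keys$chain[i]
    lig <- a$entity %in% c("ligand", "metal", "ion")
    nuc <- a$entity %in% c("dna", "rna")
    data.frame(
      chain = keys$chain[i], resnum = keys$resnum[i], icode = keys$icode[i],
      interface = any(d[, other_prot] <= cutoff),
      ligand_contact = any(d[, lig] <= cutoff),
      nucleic_contact = any(d[, nuc] <= cutoff),
      stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, out)
  tr$label <- ifelse(tr$nucleic_contact, "dna",
              ifelse(tr$ligand_contact, "ligand",
              ifelse(tr$interface, "protein", "surface")))
  tr
}

#' Write a standard set of fixture templates into a directory
#'
#' Emits one PDB file per fixture kind plus the ground-truth label table,
#' forming a ready-to-use template library for tests and examples.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return data frame describing the written files, invisibly.
#' @export
write_fixture_library <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- c("helix", "strand", "dimer", "ligand_complex", "nucleic_complex")
  info <- lapply(seq_along(kinds), function(i) {
    fx <- generate_fixture(kinds[i], seed = seed + (i - 1) * 10)
    path <- file.path(dir, paste0(fx$model$entry_id, ".pdb"))
    write_structure_pdb(fx$model, path)
    truth <- fx$truth
    truth$entry_id <- fx$model$entry_id
    truth$kind <- kinds[i]
    utils::write.table(
      truth, file.path(dir, paste0(fx$model$entry_id, "_truth.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    data.frame(kind = kinds[i], entry_id = fx$model$entry_id, path = path,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, info))
}
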