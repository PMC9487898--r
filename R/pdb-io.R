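# Fixed-column PDB reader/writer. Only the ATOM/HETATM/TER/MODEL/ENDMDL/
# REMARK 2 records are interpreted; everything else is ignored.

.MAINCHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")
.TWO_LETTER_ELEMENTS <- c("ZN", "MG", "FE", "CA", "MN", "CU", "NI", "CO",
                          "CD", "HG", "MO", "PT", "AU", "AG", "NA", "CL",
                          "BR", "SE")

# Element inference from the atom-name columns when the element field is
# blank. PDB right-justifies one-letter elements in columns 13-16, so a
# name starting in column 13 (e.g. "ZN", "FE1") signals a two-letter element.
infer_element <- function(name_raw, resname) {
  name <- trimws(name_raw)
  two <- toupper(substr(name, 1, 2))
  el <- character(length(name))
  starts_col13 <- substr(name_raw, 1, 1) != " "
  is2 <- starts_col13 & two %in% .TWO_LETTER_ELEMENTS &
    entity_type_of(resname) %in% c("metal", "ion", "ligand")
  el[is2] <- two[is2]
  first_alpha <- sub("^[0-9']*", "", name)
  el[!is2] <- toupper(substr(first_alpha[!is2], 1, 1))
  el
}

#' Parse a PDB-format coordinate file into a structure model
#'
#' Reads the fixed-column PDB dialect. Only the first model of an NMR-style
#' multi-model file is kept; for duplicated alternate locations the highest
#' occupancy wins (ties: altloc 'A', then lexicographic); hydrogens are
#' discarded. Resolution is read from REMARK 2 when present.
#'
#' @param path path to a PDB-format file.
#' @param entry_id identifier for the structure; defaults to the file stem.
#' @param is_model flag marking predicted/model coordinates. Auto-detected
#'   from an EXPDTA THEORETICAL MODEL record when not given.
#' @return an object of class \code{StructureModel}: a list with
#'   \code{entry_id}, \code{resolution} (Angstrom or \code{NA}),
#'   \code{is_model}, \code{atoms} (one data frame of all heavy atoms) and
#'   \code{chains} (per-chain residue tables with an entity type).
#' @export
parse_structure <- function(path, entry_id = NULL,
                            is_model = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  if (is.null(entry_id)) {
    entry_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  }
  lines <- readLines(path, warn = FALSE)

  # first model only
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 0) {
    mend <- grep("^ENDMDL", lines)
    end <- if (length(mend) > 0) mend[1] else length(lines)
    pre <- lines[seq_len(mstart[1] - 1)]
    lines <- c(pre, lines[seq(mstart[1], end)])
  }

  resolution <- NA_real_
  rem2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rem2) > 0) {
    tail_part <- sub("^.*RESOLUTION\\.", "", rem2[1])
    m <- regmatches(tail_part, regexpr("[0-9]+\\.[0-9]+", tail_part))
    if (length(m) == 1) resolution <- as.numeric(m)
  }
  if (is.null(is_model)) {
    is_model <- any(grepl("^EXPDTA.*THEORETICAL MODEL", lines))
  }

  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  rec <- formatC(rec, width = 80, flag = "-")

  atoms <- data.frame(
    serial = as.integer(substr(rec, 7, 11)),
    name = trimws(substr(rec, 13, 16)),
    name_raw = substr(rec, 13, 16),
    altloc = substr(rec, 17, 17),
    resname = trimws(substr(rec, 18, 20)),
    chain = substr(rec, 22, 22),
    resnum = as.integer(substr(rec, 23, 26)),
    icode = substr(rec, 27, 27),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(rec, 55, 60))),
    bfactor = suppressWarnings(as.numeric(substr(rec, 61, 66))),
    element = trimws(substr(rec, 77, 78)),
    is_hetatm = substr(rec, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
  atoms$bfactor[is.na(atoms$bfactor)] <- 0.0
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", path)
  }
  blank <- atoms$element == ""
  atoms$element[blank] <- infer_element(atoms$name_raw[blank],
                                        atoms$resname[blank])
  atoms$name_raw <- NULL
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0) stop("no heavy atoms parsed from ", path)

  # altloc resolution: within (chain, resnum, icode, name) keep highest
  # occupancy; ties prefer altloc 'A', then lexicographic
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name, sep = "\r")
  pref <- ifelse(atoms$altloc == "A", 0L, 1L)
  ord <- order(key, -atoms$occupancy, pref, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resnum, atoms$icode, atoms$serial), ,
                 drop = FALSE]
  rownames(atoms) <- NULL

  atoms$entity <- entity_type_of(atoms$resname)
  new_structure_model(entry_id, atoms, resolution, is_model)
}

new_structure_model <- function(entry_id, atoms, resolution, is_model) {
  chains <- lapply(split(seq_len(nrow(atoms)), atoms$chain), function(idx) {
    sub <- atoms[idx, , drop = FALSE]
    rkey <- paste(sub$resnum, sub$icode, sep = "\r")
    first <- !duplicated(rkey)
    res <- data.frame(resnum = sub$resnum[first], icode = sub$icode[first],
                      resname = sub$resname[first], stringsAsFactors = FALSE)
    res <- res[order(res$resnum, res$icode), , drop = FALSE]
    rownames(res) <- NULL
    list(chain_id = sub$chain[1],
         entity_type = classify_entity(res$resname),
         residues = res)
  })
  structure(list(entry_id = entry_id, atoms = atoms, chains = chains,
                 resolution = resolution, is_model = is_model),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", x$entry_id, "-", nrow(x$atoms), "atoms,",
      length(x$chains), "chain(s)")
  if (!is.na(x$resolution)) cat(", resolution", x$resolution, "A")
  cat("\n")
  for (ch in x$chains) {
    cat("  chain", ch$chain_id, sprintf("[%s]", ch$entity_type),
        nrow(ch$residues), "residues\n")
  }
  invisible(x)
}

#' Extract the one-letter sequence of a chain from its ATOM records
#'
#' Residues need at least one backbone atom (N, CA or C) to count as
#' resolved; nonstandard amino acids map to 'X' (MSE to 'M', SEC to 'U').
#'
#' @param model a \code{StructureModel}.
#' @param chain_id one-character chain identifier.
#' @return list with \code{sequence} (string), \code{resnum} and
#'   \code{icode} vectors positionally parallel to the sequence.
#' @export
extract_atom_sequence <- function(model, chain_id) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) stop("no chain '", chain_id, "' in ", model$entry_id)
  if (ch$entity_type != "protein") {
    stop("chain '", chain_id, "' is not protein (", ch$entity_type, ")")
  }
  a <- model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
  bb <- a[a$name %in% c("N", "CA", "C"), , drop = FALSE]
  res <- ch$residues
  has_bb <- paste(res$resnum, res$icode) %in% paste(bb$resnum, bb$icode)
  keep <- res[has_bb & entity_type_of(res$resname) == "protein", ,
              drop = FALSE]
  list(sequence = paste(aa_one_letter(keep$resname), collapse = ""),
       resnum = keep$resnum, icode = keep$icode)
}

fmt_coord <- function(v) formatC(v, format = "f", digits = 3, width = 8)

#' Write a structure model as a PDB-format file
#'
#' Emits REMARK 2 (when resolution is defined), ATOM/HETATM records and TER
#' separators per chain, suitable for round-tripping via
#' \code{\link{parse_structure}}.
#'
#' @param model a \code{StructureModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  out <- character(0)
  if (!is.na(model$resolution)) {
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          model$resolution))
  }
  serial <- 0L
  for (cid in names(model$chains)) {
    sub <- a[a$chain == cid, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      nm <- sub$name[i]
      # standard justification: 1-letter elements start in column 14
      nm4 <- if (nchar(nm) < 4 && !(toupper(nm) %in% .TWO_LETTER_ELEMENTS &&
                                    sub$entity[i] != "protein")) {
        formatC(paste0(" ", nm), width = 4, flag = "-")
      } else formatC(nm, width = 4, flag = "-")
      out <- c(out, sprintf(
        "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8s%8s%8s%6.2f%6.2f          %2s",
        if (sub$is_hetatm[i]) "HETATM" else "ATOM", serial %% 100000L, nm4,
        " ", sub$resname[i], cid, sub$resnum[i], sub$icode[i],
        fmt_coord(sub$x[i]), fmt_coord(sub$y[i]), fmt_coord(sub$z[i]),
        sub$occupancy[i], sub$bfactor[i], sub$element[i]))
    }
    out <- c(out, "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
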