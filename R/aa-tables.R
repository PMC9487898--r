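# Chemical-component typing: every residue name resolves to exactly one
# molecular entity type. Unlisted heteroresidues fall through to "ligand".

.AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  MSE = "M",  # selenomethionine
  SEC = "U"   # selenocysteine
)

.STANDARD_AA3 <- names(.AA3)[1:20]

.DNA_RES <- c("DA", "DC", "DG", "DT", "DI")
.RNA_RES <- c("A", "C", "G", "U", "I")
.METAL_RES <- c("ZN", "MG", "FE", "CA", "MN", "CU", "NI", "CO", "CD",
                "HG", "MO", "W", "V", "PT", "AU", "AG")
.ION_RES <- c("NA", "K", "CL", "BR", "IOD", "F")
.WATER_RES <- c("HOH", "DOD", "WAT")

#' Classify a residue name into a molecular entity type
#'
#' Maps a PDB chemical-component name to one of \code{protein}, \code{dna},
#' \code{rna}, \code{metal}, \code{ion}, \code{water} or \code{ligand}.
#' The map is total: any heteroresidue not recognised is a \code{ligand}.
#'
#' @param resname character vector of 3-letter (or shorter) residue names.
#' @return character vector of entity types, same length as \code{resname}.
#' @export
entity_type_of <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- rep("ligand", length(resname))
  out[resname %in% names(.AA3)] <- "protein"
  out[resname %in% .DNA_RES] <- "dna"
  out[resname %in% .RNA_RES] <- "rna"
  out[resname %in% .METAL_RES] <- "metal"
  out[resname %in% .ION_RES] <- "ion"
  out[resname %in% .WATER_RES] <- "water"
  out
}

#' Classify a chain by majority vote over its residue names
#'
#' @param resnames character vector of residue names observed in one chain.
#' @return single entity type string. Water is never returned for a chain
#'   that contains any non-water residue.
#' @export
classify_entity <- function(resnames) {
  stopifnot(length(resnames) > 0)
  types <- entity_type_of(resnames)
  if (any(types != "water")) types <- types[types != "water"]
  tab <- sort(table(types), decreasing = TRUE)
  # deterministic tie-break: alphabetical among equally frequent types
  top <- names(tab)[tab == tab[1]]
  sort(top)[1]
}

# one-letter code for a residue name; nonstandard amino acids map to X
aa_one_letter <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- unname(.AA3[resname])
  out[is.na(out)] <- "X"
  out
}
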