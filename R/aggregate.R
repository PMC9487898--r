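# Quality-weighted aggregation across all accepted structure annotations of
# a query position, structural classification, and structure selection.
#
# Each annotation i carries a quality score q_i = identity x coverage x
# r(resolution) with r(res) = clamp((6.5 - res)/5, 0.1, 1) and undefined
# resolution treated as 3.5 A. A numeric feature d is aggregated as
# W(D) = sum(q_i d_i) / sum(q_i) over the annotations where d is defined;
# solvent-accessibility features additionally multiply q_i by squared
# alignment coverage, biasing partially resolved structures toward buried
# calls.

.ACC_FEATURES <- c("sasa_all", "sasa_mainchain", "sasa_sidechain",
                   "rsa_all", "rsa_mainchain", "rsa_sidechain")
.INTERFACE_TYPES <- c("metal", "ion", "dna", "rna", "ligand", "protein")
.TYPE_WORDS <- c(metal = "metal", ion = "ion", dna = "DNA", rna = "RNA",
                 ligand = "ligand", protein = "protein")

#' Per-annotation quality score
#'
#' @param identity core sequence identity in [0, 1].
#' @param coverage alignment coverage in [0, 1].
#' @param resolution structure resolution in Angstrom; \code{NA} (models,
#'   unspecified) is treated as 3.5.
#' @return quality in (0, 1].
#' @export
quality_score <- function(identity, coverage, resolution = NA_real_) {
  resolution[is.na(resolution)] <- 3.5
  rfac <- pmin(1.0, pmax(0.1, (6.5 - resolution) / 5.0))
  identity * coverage * rfac
}

#' Quality-weighted mean with sparsity handling
#'
#' Undefined (NA) values are excluded together with their weights; an
#' all-undefined input aggregates to NA.
#'
#' @param values numeric vector (NAs allowed).
#' @param qualities non-negative weights, parallel to \code{values}.
#' @return weighted mean, or NA.
#' @export
weighted_aggregate <- function(values, qualities) {
  stopifnot(length(values) == length(qualities))
  if (any(qualities < 0, na.rm = TRUE)) stop("negative quality weight")
  ok <- !is.na(values) & !is.na(qualities)
  if (!any(ok) || sum(qualities[ok]) == 0) return(NA_real_)
  sum(qualities[ok] * values[ok]) / sum(qualities[ok])
}

#' Coverage-biased aggregation for solvent accessibility
#'
#' Weighted aggregate with weights \eqn{q_i \cdot cov_i^2}.
#'
#' @param values,qualities as in \code{\link{weighted_aggregate}}.
#' @param coverages per-annotation alignment coverage.
#' @return weighted mean, or NA.
#' @export
aggregate_rsa <- function(values, qualities, coverages) {
  stopifnot(length(values) == length(coverages))
  weighted_aggregate(values, qualities * coverages^2)
}

#' Aggregate per-structure feature rows for one query position
#'
#' @param rows data frame of per-annotation feature rows (the 100 registry
#'   columns; one row per annotation that maps the position).
#' @param qualities,coverages per-row quality and coverage.
#' @return named numeric vector of 100 aggregated features.
#' @export
aggregate_position_features <- function(rows, qualities, coverages) {
  reg <- feature_registry()
  out <- stats::setNames(rep(NA_real_, length(reg)), reg)
  if (is.null(rows) || nrow(rows) == 0) return(out)
  for (f in reg) {
    v <- rows[[f]]
    out[f] <- if (f %in% .ACC_FEATURES) {
      aggregate_rsa(v, qualities, coverages)
    } else {
      weighted_aggregate(v, qualities)
    }
  }
  out
}

loc_of <- function(rsa, threshold) {
  if (is.na(rsa)) NA_character_
  else if (rsa > threshold) "Surface" else "Core"
}

#' Classify the structural role of an aggregated position
#'
#' Decision tree: the position is an interaction-interface residue if any
#' aggregated partner degree (mainchain or sidechain) reaches
#' \code{degree_eps}; the class is then named after the highest-priority
#' partner type (metal > ion > DNA > RNA > ligand > protein), with a
#' "Multiple interactions: ..." RIN class when more than one (part, type)
#' combination interacts. Otherwise Surface/Core by aggregated RSA against
#' the threshold (strictly greater means Surface). Positions with no
#' accepted annotation are "No structure".
#'
#' @param agg named 100-entry aggregated feature vector.
#' @param n_annotations number of annotations mapping the position.
#' @param rsa_threshold RSA core/surface threshold (default 0.16).
#' @param degree_eps minimal aggregated degree counting as an interaction
#'   (default 0.1).
#' @return list with \code{location}, \code{mainchain_location},
#'   \code{sidechain_location}, \code{structural_class},
#'   \code{simple_class}, \code{rin_class}, \code{rin_simple_class},
#'   \code{interaction_profile}.
#' @export
classify_position <- function(agg, n_annotations = 1L, rsa_threshold = 0.16,
                              degree_eps = 0.1) {
  if (n_annotations == 0) {
    return(list(location = NA_character_,
                mainchain_location = NA_character_,
                sidechain_location = NA_character_,
                structural_class = "No structure",
                simple_class = "No structure",
                rin_class = "No structure",
                rin_simple_class = "No structure",
                interaction_profile = NA_character_))
  }
  location <- loc_of(agg[["rsa_all"]], rsa_threshold)
  mc_loc <- loc_of(agg[["rsa_mainchain"]], rsa_threshold)
  sc_loc <- loc_of(agg[["rsa_sidechain"]], rsa_threshold)

  comps <- list()   # interacting (type, part) combinations, priority order
  profile <- character(0)
  for (tp in .INTERFACE_TYPES) {
    for (p in c("mainchain", "sidechain")) {
      dg <- agg[[paste0(p, "_", tp, "_degree")]]
      if (!is.na(dg) && dg >= degree_eps) {
        comps[[length(comps) + 1]] <- c(part = p, type = tp)
      }
    }
    dtot <- sum(agg[[paste0("mainchain_", tp, "_degree")]],
                agg[[paste0("sidechain_", tp, "_degree")]], na.rm = TRUE)
    if (dtot >= degree_eps) {
      profile <- c(profile, sprintf("%s:%.2f", .TYPE_WORDS[[tp]], dtot))
    }
  }

  if (length(comps) == 0) {
    cls <- if (is.na(location)) "No structure" else location
    return(list(location = location, mainchain_location = mc_loc,
                sidechain_location = sc_loc,
                structural_class = cls, simple_class = cls,
                rin_class = cls, rin_simple_class = cls,
                interaction_profile = "-"))
  }
  types <- unique(vapply(comps, function(x) x[["type"]], character(1)))
  top <- types[1]  # comps iterated in priority order
  structural_class <- paste0(toupper(substr(.TYPE_WORDS[[top]], 1, 1)),
                             substr(.TYPE_WORDS[[top]], 2, 100),
                             " interaction")
  phrase <- vapply(comps, function(x)
    sprintf("%s contact with a %s", x[["part"]], .TYPE_WORDS[[x[["type"]]]]),
    character(1))
  if (length(comps) > 1) {
    rin_class <- paste0("Multiple interactions: ",
                        paste(phrase, collapse = " and "))
    rin_simple <- "Multiple interactions"
  } else {
    rin_class <- phrase[1]
    rin_simple <- structural_class
  }
  list(location = location, mainchain_location = mc_loc,
       sidechain_location = sc_loc, structural_class = structural_class,
       simple_class = "Interaction", rin_class = rin_class,
       rin_simple_class = rin_simple,
       interaction_profile = paste(profile, collapse = ";"))
}

render_structure_ref <- function(entry_id, chain_id) {
  paste0(entry_id, ":", chain_id)
}

render_residue_ref <- function(resnum, icode, resname) {
  num <- paste0(resnum, ifelse(is.na(icode) | icode == " ", "", icode))
  paste0(num, ":", aa_one_letter(resname))
}

#' Select the max-identity and recommended structures for a position
#'
#' The max-identity reference maximises sequence identity (ties broken by
#' higher coverage, better resolution, then lexicographic entry id). The
#' recommended reference maximises quality times (1 + number of distinct
#' interaction-partner types observed at the position in that structure).
#'
#' @param ann_info data frame with one row per annotation mapping the
#'   position: \code{entry_id}, \code{chain_id}, \code{identity},
#'   \code{coverage}, \code{resolution}, \code{quality},
#'   \code{n_interaction_types}, \code{resnum}, \code{icode},
#'   \code{resname}.
#' @return list with \code{max_identity} and \code{recommended}, each a
#'   one-row data frame, or NULL entries when no annotations exist.
#' @export
select_recommended <- function(ann_info) {
  if (is.null(ann_info) || nrow(ann_info) == 0) {
    return(list(max_identity = NULL, recommended = NULL))
  }
  res_for_order <- ifelse(is.na(ann_info$resolution), 3.5,
                          ann_info$resolution)
  ord <- order(-ann_info$identity, -ann_info$coverage, res_for_order,
               ann_info$entry_id, ann_info$chain_id)
  max_id <- ann_info[ord[1], , drop = FALSE]
  score <- ann_info$quality * (1 + ann_info$n_interaction_types)
  ord2 <- order(-score, res_for_order, ann_info$entry_id, ann_info$chain_id)
  rec <- ann_info[ord2[1], , drop = FALSE]
  list(max_identity = max_id, recommended = rec)
}

#' Names and order of the 23 evidence meta features
#' @return character vector of length 23.
#' @export
evidence_registry <- function() {
  c("n_structures", "n_distinct_entries", "max_identity",
    "wmean_identity", "max_coverage", "mean_coverage", "best_resolution",
    "mean_resolution", "mean_quality", "max_quality", "resolved_count",
    "defined_sidechain_fraction", "n_protein_annotations",
    "n_ligand_annotations", "n_nucleic_annotations",
    "n_metal_ion_annotations", "distinct_ligands",
    "distinct_partner_chains", "helix_majority", "sheet_majority",
    "location_code", "mainchain_location_code", "sidechain_location_code")
}

loc_code <- function(loc) {
  if (is.na(loc)) NA_real_ else if (loc == "Surface") 1 else 0
}

#' Evidence meta features for one query position
#'
#' @param ann_info per-annotation info as in \code{\link{select_recommended}}.
#' @param rows per-annotation feature rows (registry columns plus the
#'   \code{ligand_partners} / \code{chain_partners} metadata columns).
#' @param classes classification list from \code{\link{classify_position}}.
#' @return named numeric vector of 23 evidence features.
#' @export
evidence_features <- function(ann_info, rows, classes) {
  reg <- evidence_registry()
  out <- stats::setNames(rep(NA_real_, length(reg)), reg)
  n <- if (is.null(ann_info)) 0L else nrow(ann_info)
  out["n_structures"] <- n
  if (n == 0) {
    out[c("resolved_count", "n_protein_annotations", "n_ligand_annotations",
          "n_nucleic_annotations", "n_metal_ion_annotations",
          "distinct_ligands", "distinct_partner_chains",
          "n_distinct_entries")] <- 0
    return(out)
  }
  out["n_distinct_entries"] <- length(unique(ann_info$entry_id))
  out["max_identity"] <- max(ann_info$identity)
  out["wmean_identity"] <- weighted_aggregate(ann_info$identity,
                                              ann_info$quality)
  out["max_coverage"] <- max(ann_info$coverage)
  out["mean_coverage"] <- mean(ann_info$coverage)
  res <- ann_info$resolution[!is.na(ann_info$resolution)]
  out["best_resolution"] <- if (length(res) > 0) min(res) else NA_real_
  out["mean_resolution"] <- if (length(res) > 0) mean(res) else NA_real_
  out["mean_quality"] <- mean(ann_info$quality)
  out["max_quality"] <- max(ann_info$quality)
  out["resolved_count"] <- sum(!is.na(rows$rsa_all))
  out["defined_sidechain_fraction"] <- mean(!is.na(rows$rsa_sidechain))
  deg_any <- function(tp) {
    d <- rowSums(cbind(rows[[paste0("mainchain_", tp, "_degree")]],
                       rows[[paste0("sidechain_", tp, "_degree")]]),
                 na.rm = TRUE)
    d > 0
  }
  out["n_protein_annotations"] <- sum(deg_any("protein"))
  out["n_ligand_annotations"] <- sum(deg_any("ligand"))
  out["n_nucleic_annotations"] <- sum(deg_any("dna") | deg_any("rna"))
  out["n_metal_ion_annotations"] <- sum(deg_any("metal") | deg_any("ion"))
  split_set <- function(v) {
    v <- v[!is.na(v) & v != "-" & v != ""]
    unique(unlist(strsplit(v, ",")))
  }
  out["distinct_ligands"] <- length(split_set(rows$ligand_partners))
  out["distinct_partner_chains"] <- length(split_set(rows$chain_partners))
  out["helix_majority"] <- as.numeric(mean(rows$ss_helix, na.rm = TRUE) > 0.5)
  out["sheet_majority"] <- as.numeric(mean(rows$ss_sheet, na.rm = TRUE) > 0.5)
  out["location_code"] <- loc_code(classes$location)
  out["mainchain_location_code"] <- loc_code(classes$mainchain_location)
  out["sidechain_location_code"] <- loc_code(classes$sidechain_location)
  out
}
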