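# Variant notation, mutant sequence construction, and indel region
# decomposition/aggregation.
#
# Grammar: SAV "D833A"; deletion "del10" / "del10-13"; insertion "ins7GS"
# (insert after position 7); delins "delins10-12GS" (replace 10..12 by GS).
# For an indel of length L = max(|wt|, |alt|), the wild-type and mutant
# sequences each decompose into left flank, indel region and right flank,
# with flank length max(1, ceil(L/2)); an insertion has an empty wild-type
# indel region, a deletion an empty mutant indel region. The six regions,
# aggregated feature-wise, concatenate into the 600-entry indel vector.

#' Parse a variant string
#'
#' @param text variant string (see grammar above).
#' @param sequence optional query sequence used to validate stated
#'   wild-type residues and position bounds.
#' @return a \code{Variant}: list with \code{kind} (one of sav, deletion,
#'   insertion, delins), \code{left}, \code{right} (1-based anchors),
#'   \code{wt_residues}, \code{alt_residues} and \code{text}.
#' @export
parse_variant <- function(text, sequence = NULL) {
  text <- trimws(text)
  if (nchar(text) == 0) stop("empty variant string")
  v <- NULL
  if (grepl("^delins([0-9]+)(-([0-9]+))?([A-Z]+)$", text)) {
    m <- regmatches(text,
                    regexec("^delins([0-9]+)(-([0-9]+))?([A-Z]+)$", text))[[1]]
    left <- as.integer(m[2])
    right <- if (m[4] != "") as.integer(m[4]) else left
    v <- list(kind = "delins", left = left, right = right,
              wt_residues = NA_character_, alt_residues = m[5])
  } else if (grepl("^del([0-9]+)(-([0-9]+))?$", text)) {
    m <- regmatches(text, regexec("^del([0-9]+)(-([0-9]+))?$", text))[[1]]
    left <- as.integer(m[2])
    right <- if (m[4] != "") as.integer(m[4]) else left
    v <- list(kind = "deletion", left = left, right = right,
              wt_residues = NA_character_, alt_residues = "")
  } else if (grepl("^ins([0-9]+)([A-Z]+)$", text)) {
    m <- regmatches(text, regexec("^ins([0-9]+)([A-Z]+)$", text))[[1]]
    pos <- as.integer(m[2])
    v <- list(kind = "insertion", left = pos, right = pos + 1L,
              wt_residues = "", alt_residues = m[3])
  } else if (grepl("^[A-Z][0-9]+[A-Z]$", text)) {
    m <- regmatches(text, regexec("^([A-Z])([0-9]+)([A-Z])$", text))[[1]]
    pos <- as.integer(m[3])
    v <- list(kind = "sav", left = pos, right = pos,
              wt_residues = m[2], alt_residues = m[4])
  } else {
    stop("cannot parse variant string: '", text, "'")
  }
  v$text <- text
  if (v$kind %in% c("deletion", "delins") && v$right < v$left) {
    stop("variant '", text, "': end before start")
  }
  if (!is.null(sequence)) {
    n <- nchar(sequence)
    maxpos <- if (v$kind == "insertion") v$left else v$right
    if (v$left < 1 || maxpos > n) {
      stop("variant '", text, "' out of range for sequence of length ", n)
    }
    if (v$kind == "sav") {
      wt <- substr(sequence, v$left, v$left)
      if (wt != v$wt_residues) {
        stop("wild-type mismatch for '", text, "': sequence has ", wt,
             " at position ", v$left)
      }
    }
    if (v$kind %in% c("deletion", "delins")) {
      v$wt_residues <- substr(sequence, v$left, v$right)
    }
  }
  class(v) <- "Variant"
  v
}

is_indel <- function(v) v$kind %in% c("deletion", "insertion", "delins")

#' Apply a variant to a sequence
#'
#' @param seq wild-type sequence.
#' @param v a \code{Variant}.
#' @return the mutant sequence.
#' @export
apply_variant <- function(seq, v) {
  n <- nchar(seq)
  if (v$kind == "insertion") {
    if (v$left < 0 || v$left > n) stop("insertion anchor out of range")
    return(paste0(substr(seq, 1, v$left), v$alt_residues,
                  substr(seq, v$left + 1, n)))
  }
  if (v$left < 1 || v$right > n) stop("variant out of range")
  paste0(substr(seq, 1, v$left - 1), v$alt_residues,
         substr(seq, v$right + 1, n))
}

#' Decompose an indel into flank and indel regions
#'
#' @param seq_wt wild-type sequence.
#' @param seq_mut mutant sequence.
#' @param v an indel \code{Variant}.
#' @return an \code{IndelDecomposition}: list with \code{flank_length} and,
#'   for each of WT and MUT, integer position vectors \code{left_flank},
#'   \code{indel_region}, \code{right_flank} (empty regions are
#'   zero-length, clipped at the sequence bounds).
#' @export
decompose_indel <- function(seq_wt, seq_mut, v) {
  if (!is_indel(v)) stop("decompose_indel needs an indel variant")
  wt_len <- if (is.na(v$wt_residues)) v$right - v$left + 1L
            else nchar(v$wt_residues)
  if (v$kind == "insertion") wt_len <- 0L
  alt_len <- nchar(v$alt_residues)
  L <- max(wt_len, alt_len)
  flank <- max(1L, as.integer(ceiling(L / 2)))

  clip <- function(lo, hi, n) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (hi < lo) return(integer(0))
    seq.int(lo, hi)
  }
  n_wt <- nchar(seq_wt); n_mut <- nchar(seq_mut)
  if (v$kind == "insertion") {
    wt_indel <- integer(0)
    wt_left <- clip(v$left - flank + 1L, v$left, n_wt)
    wt_right <- clip(v$left + 1L, v$left + flank, n_wt)
    mut_indel <- clip(v$left + 1L, v$left + alt_len, n_mut)
    mut_left <- clip(v$left - flank + 1L, v$left, n_mut)
    mut_right <- clip(v$left + alt_len + 1L, v$left + alt_len + flank, n_mut)
  } else {
    wt_indel <- clip(v$left, v$right, n_wt)
    wt_left <- clip(v$left - flank, v$left - 1L, n_wt)
    wt_right <- clip(v$right + 1L, v$right + flank, n_wt)
    mut_indel <- clip(v$left, v$left + alt_len - 1L, n_mut)
    mut_left <- clip(v$left - flank, v$left - 1L, n_mut)
    mut_right <- clip(v$left + alt_len, v$left + alt_len + flank - 1L, n_mut)
  }
  structure(list(flank_length = flank,
                 wt = list(left_flank = wt_left, indel_region = wt_indel,
                           right_flank = wt_right),
                 mut = list(left_flank = mut_left, indel_region = mut_indel,
                            right_flank = mut_right)),
            class = "IndelDecomposition")
}

.INDEL_REGIONS <- c("wt_left", "wt_indel", "wt_right",
                    "mut_left", "mut_indel", "mut_right")

#' Names and order of the 600 indel feature entries
#' @return character vector of length 600.
#' @export
indel_feature_registry <- function() {
  as.vector(vapply(.INDEL_REGIONS,
                   function(r) paste0(r, "_", feature_registry()),
                   character(100)))
}

#' Aggregate aggregated-position features over the six indel regions
#'
#' Each region aggregates each of the 100 registry features across its
#' positions with the quality-weighted mean, using the position's mean
#' annotation quality as its weight; empty regions contribute 100 NAs.
#'
#' @param wt_agg,mut_agg data frames of aggregated per-position features
#'   for the wild-type and mutant protein: columns \code{position},
#'   \code{mean_quality}, plus the 100 registry features.
#' @param dec an \code{IndelDecomposition}.
#' @return named numeric vector of exactly 600 entries.
#' @export
aggregate_indel_features <- function(wt_agg, mut_agg, dec) {
  reg <- feature_registry()
  block <- function(agg, positions) {
    if (length(positions) == 0 || is.null(agg) || nrow(agg) == 0) {
      return(stats::setNames(rep(NA_real_, length(reg)), reg))
    }
    sub <- agg[agg$position %in% positions, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(stats::setNames(rep(NA_real_, length(reg)), reg))
    }
    w <- sub$mean_quality
    w[is.na(w)] <- 0
    vapply(reg, function(f) weighted_aggregate(sub[[f]], w), numeric(1))
  }
  out <- c(block(wt_agg, dec$wt$left_flank),
           block(wt_agg, dec$wt$indel_region),
           block(wt_agg, dec$wt$right_flank),
           block(mut_agg, dec$mut$left_flank),
           block(mut_agg, dec$mut$indel_region),
           block(mut_agg, dec$mut$right_flank))
  stats::setNames(out, indel_feature_registry())
}

#' Assemble the 123-entry SAV feature vector
#'
#' Concatenates the 100 aggregated registry features and the 23 evidence
#' features, in their fixed documented order.
#'
#' @param agg_features named 100-entry aggregated feature vector.
#' @param evidence named 23-entry evidence vector.
#' @return named numeric vector of exactly 123 entries.
#' @export
sav_feature_vector <- function(agg_features, evidence) {
  out <- c(agg_features[feature_registry()],
           evidence[evidence_registry()])
  stats::setNames(out, c(feature_registry(), evidence_registry()))
}
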