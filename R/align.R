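# Candidate search and free-end-gap global alignment.
#
# Candidates come from an exact k-mer screen over the template library
# (maximal sensitivity at desk scale); an adapter hook lets an external
# similarity-search tool substitute the same (entry, chain) list. Accepted
# candidates are aligned with an affine-gap Needleman-Wunsch (gap opening
# 10, gap extension 0.5, BLOSUM62) in which terminal gaps are free in both
# sequences, and query positions are mapped onto template residue numbers.

.VALID_AA <- c(unname(.AA3[1:20]), "X", "U")

check_sequence <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), .VALID_AA)
  if (length(bad) > 0) {
    stop("invalid amino acid characters in ", what, ": ",
         paste(bad, collapse = ", "))
  }
  invisible(chars)
}

#' Find candidate template chains sharing a k-mer with the query
#'
#' Exact k-mer screen over an indexed template library: every chain sharing
#' at least one length-k word with the query is a candidate. Queries shorter
#' than k fall back to all chains. A custom search function can be supplied
#' through the \code{search_hook} to plug in an external tool producing the
#' same candidate list.
#'
#' @param query one-letter amino acid query sequence.
#' @param index template index data frame with columns \code{entry_id},
#'   \code{chain_id}, \code{sequence} (see \code{\link{build_template_index}}).
#' @param k k-mer size (default 5).
#' @param search_hook optional function \code{(query, index) ->
#'   data.frame(entry_id, chain_id)} replacing the built-in screen.
#' @return data frame with columns \code{entry_id}, \code{chain_id}.
#' @export
find_candidates <- function(query, index, k = 5, search_hook = NULL) {
  if (!is.null(search_hook)) return(search_hook(query, index))
  if (nrow(index) == 0) {
    return(data.frame(entry_id = character(0), chain_id = character(0),
                      stringsAsFactors = FALSE))
  }
  if (nchar(query) < k) {
    return(index[, c("entry_id", "chain_id"), drop = FALSE])
  }
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  qk <- kmers(query)
  hit <- vapply(index$sequence,
                function(s) any(kmers(s) %in% qk), logical(1))
  out <- index[hit, c("entry_id", "chain_id"), drop = FALSE]
  rownames(out) <- NULL
  out
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global alignment with free end gaps
#'
#' Affine-gap (three-state) global alignment with zero-cost terminal gaps in
#' both sequences, BLOSUM62 scoring, gap opening 10 and gap extension 0.5
#' (a length-L gap run costs \eqn{10 + 0.5 L}). Selenocysteine (U) is scored
#' as cysteine.
#'
#' @param query,template_seq one-letter amino acid sequences.
#' @param gap_open,gap_extend positive gap penalties.
#' @return an \code{AlignmentResult}: list with \code{aligned_query} and
#'   \code{aligned_template} (equal-length gapped strings spanning both full
#'   sequences), \code{score}, \code{core_start}/\code{core_end} (column
#'   range not part of any end gap), and \code{identity} computed inside
#'   the core only.
#' @export
align_global_free_end <- function(query, template_seq,
                                  gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(query) > 0, nchar(template_seq) > 0)
  check_sequence(query, "query")
  check_sequence(template_seq, "template")
  sub_q <- chartr("U", "C", query)
  sub_t <- chartr("U", "C", template_seq)
  pa <- Biostrings::pairwiseAlignment(
    sub_q, sub_t, type = "overlap",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend)

  qs <- Biostrings::start(Biostrings::pattern(pa))
  qe <- Biostrings::end(Biostrings::pattern(pa))
  ts <- Biostrings::start(Biostrings::subject(pa))
  te <- Biostrings::end(Biostrings::subject(pa))
  core_q <- as.character(Biostrings::alignedPattern(pa))
  core_t <- as.character(Biostrings::alignedSubject(pa))
  # restore original letters (U was substituted for scoring only)
  core_q <- restore_letters(core_q, substr(query, qs, qe))
  core_t <- restore_letters(core_t, substr(template_seq, ts, te))

  nq <- nchar(query); nt <- nchar(template_seq)
  lead_q <- if (qs > 1) substr(query, 1, qs - 1) else ""
  lead_t <- if (ts > 1) substr(template_seq, 1, ts - 1) else ""
  tail_q <- if (qe < nq) substr(query, qe + 1, nq) else ""
  tail_t <- if (te < nt) substr(template_seq, te + 1, nt) else ""
  gaps <- function(n) strrep("-", n)
  aligned_query <- paste0(lead_q, gaps(nchar(lead_t)), core_q,
                          tail_q, gaps(nchar(tail_t)))
  aligned_template <- paste0(gaps(nchar(lead_q)), lead_t, core_t,
                             gaps(nchar(tail_q)), tail_t)
  core_start <- nchar(lead_q) + nchar(lead_t) + 1L
  core_end <- core_start + nchar(core_q) - 1L

  aln <- list(aligned_query = aligned_query,
              aligned_template = aligned_template,
              score = Biostrings::score(pa),
              core_start = core_start, core_end = core_end)
  aln$identity <- sequence_identity_core(aln)
  class(aln) <- "AlignmentResult"
  aln
}

restore_letters <- function(gapped, original) {
  g <- strsplit(gapped, "")[[1]]
  o <- strsplit(original, "")[[1]]
  g[g != "-"] <- o
  paste(g, collapse = "")
}

#' Core sequence identity of an alignment
#'
#' Identical residue pairs divided by the number of core columns: terminal
#' (end-gap) columns are excluded, internal gap columns count in the
#' denominator. An empty core yields identity 0.
#'
#' @param aln an \code{AlignmentResult}.
#' @return fraction in [0, 1].
#' @export
sequence_identity_core <- function(aln) {
  if (aln$core_end < aln$core_start) return(0)
  q <- strsplit(substr(aln$aligned_query, aln$core_start, aln$core_end),
                "")[[1]]
  t <- strsplit(substr(aln$aligned_template, aln$core_start, aln$core_end),
                "")[[1]]
  ncore <- length(q)
  if (ncore == 0) return(0)
  sum(q == t & q != "-") / ncore
}

#' Alignment coverage over resolved template residues
#'
#' Fraction of query positions aligned to a template residue whose
#' coordinates are resolved in the structure.
#'
#' @param aln an \code{AlignmentResult}.
#' @param resolved logical vector, one entry per template residue (in
#'   sequence order); defaults to all resolved.
#' @return fraction in [0, 1].
#' @export
alignment_coverage <- function(aln, resolved = NULL) {
  q <- strsplit(aln$aligned_query, "")[[1]]
  t <- strsplit(aln$aligned_template, "")[[1]]
  nt <- sum(t != "-")
  if (is.null(resolved)) resolved <- rep(TRUE, nt)
  stopifnot(length(resolved) == nt)
  tpos <- cumsum(t != "-")
  covered <- q != "-" & t != "-" & resolved[pmax(tpos, 1)]
  nq <- sum(q != "-")
  if (nq == 0) return(0)
  sum(covered) / nq
}

#' Accept or reject a sequence-to-structure annotation
#'
#' @param identity core sequence identity in [0, 1].
#' @param threshold acceptance threshold (default 0.35, inclusive).
#' @return logical flag.
#' @export
accept_annotation <- function(identity, threshold = 0.35) {
  stopifnot(identity >= 0, identity <= 1)
  identity >= threshold
}

#' Map query positions onto template residues
#'
#' @param aln an \code{AlignmentResult}.
#' @param template_resnum,template_icode parallel vectors giving the residue
#'   numbering of the template sequence (from \code{extract_atom_sequence}).
#' @param resolved optional logical vector marking resolved template
#'   residues; unresolved ones are left unmapped.
#' @return data frame with columns \code{qpos}, \code{resnum}, \code{icode},
#'   one row per mapped query position.
#' @export
map_positions <- function(aln, template_resnum, template_icode = NULL,
                          resolved = NULL) {
  q <- strsplit(aln$aligned_query, "")[[1]]
  t <- strsplit(aln$aligned_template, "")[[1]]
  if (is.null(template_icode)) template_icode <- rep(" ",
                                                     length(template_resnum))
  if (is.null(resolved)) resolved <- rep(TRUE, length(template_resnum))
  qpos <- cumsum(q != "-")
  tpos <- cumsum(t != "-")
  both <- q != "-" & t != "-"
  both <- both & resolved[pmax(tpos, 1)]
  data.frame(qpos = qpos[both],
             resnum = template_resnum[tpos[both]],
             icode = template_icode[tpos[both]],
             stringsAsFactors = FALSE)
}
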