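# Heavy-atom contacts and the residue interaction network (RIN).
#
# A contact is a heavy-atom pair within the distance cutoff (default 5 A),
# excluding intra-residue pairs, water, and the covalent backbone C-N pair
# of chain-adjacent residues. The RIN connects residues by covalent edges
# (chain-adjacent polymer residues, weight 1) and noncovalent edges whose
# weight sums (1 - d/cutoff) over the contributing atom pairs.

.CONTACT_CUTOFF <- 5.0

# residue-level index of a model: one row per non-water residue
residue_index <- function(model) {
  a <- model$atoms
  keep <- a$entity != "water"
  key <- paste(a$chain, a$resnum, a$icode, sep = ":")
  first <- keep & !duplicated(key)
  idx <- data.frame(chain = a$chain[first], resnum = a$resnum[first],
                    icode = a$icode[first], resname = a$resname[first],
                    entity = entity_type_of(a$resname[first]),
                    key = key[first], stringsAsFactors = FALSE)
  # order within chain by (resnum, icode); chain-order position for
  # sequence-separation computations
  idx <- idx[order(idx$chain, idx$resnum, idx$icode), , drop = FALSE]
  idx$res_id <- seq_len(nrow(idx))
  idx$chain_pos <- stats::ave(seq_len(nrow(idx)), idx$chain,
                              FUN = seq_along)
  rownames(idx) <- NULL
  idx
}

#' Find heavy-atom contacts in a structure
#'
#' All inter-residue heavy-atom pairs within the cutoff, water excluded,
#' with the covalent backbone C(i)-N(i+1) pair of chain-adjacent residues
#' removed. Each pair carries the residue ids, the mainchain/sidechain part
#' of each protein atom, and the partner typing used by the interaction
#' scores (inter-chain protein vs short/long-range intra-chain, ligand,
#' metal, ion, dna, rna).
#'
#' @param model a \code{StructureModel}.
#' @param dist_cutoff contact cutoff in Angstrom (default 5.0).
#' @return list with \code{residues} (the residue index) and \code{pairs},
#'   a data frame of unordered atom pairs (each stored once).
#' @export
find_contacts <- function(model, dist_cutoff = .CONTACT_CUTOFF) {
  a <- model$atoms
  ridx <- residue_index(model)
  keep <- which(a$entity != "water")
  sub <- a[keep, , drop = FALSE]
  key <- paste(sub$chain, sub$resnum, sub$icode, sep = ":")
  res_of <- ridx$res_id[match(key, ridx$key)]
  xyz <- as.matrix(sub[, c("x", "y", "z")])
  n <- nrow(xyz)
  dmat <- cross_dist(xyz, xyz)
  hit <- which(upper.tri(dmat) & dmat <= dist_cutoff, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    same_res <- res_of[hit[, 1]] == res_of[hit[, 2]]
    hit <- hit[!same_res, , drop = FALSE]
  }
  i <- hit[, 1]; j <- hit[, 2]
  # covalent backbone pair of adjacent residues: C of k with N of k+1
  adj <- abs(ridx$chain_pos[res_of[i]] - ridx$chain_pos[res_of[j]]) == 1 &
    ridx$chain[res_of[i]] == ridx$chain[res_of[j]]
  cn <- (sub$name[i] == "C" & sub$name[j] == "N" & res_of[j] > res_of[i]) |
        (sub$name[j] == "C" & sub$name[i] == "N" & res_of[i] > res_of[j])
  drop <- adj & cn & ridx$entity[res_of[i]] == "protein" &
    ridx$entity[res_of[j]] == "protein"
  i <- i[!drop]; j <- j[!drop]

  part <- function(k) {
    ifelse(ridx$entity[res_of[k]] != "protein", NA_character_,
           ifelse(sub$name[k] %in% .MAINCHAIN_ATOMS, "mainchain",
                  "sidechain"))
  }
  pairs <- data.frame(
    ai = keep[i], aj = keep[j], d = dmat[cbind(i, j)],
    res_a = res_of[i], res_b = res_of[j],
    part_a = part(i), part_b = part(j),
    stringsAsFactors = FALSE)
  list(residues = ridx, pairs = pairs, dist_cutoff = dist_cutoff)
}

# partner typing of residue b as seen from protein residue a
partner_type <- function(ridx, res_a, res_b, sep_threshold = 6) {
  ent <- ridx$entity[res_b]
  same_chain <- ridx$chain[res_a] == ridx$chain[res_b]
  sep <- abs(ridx$chain_pos[res_a] - ridx$chain_pos[res_b])
  ifelse(ent != "protein", ent,
         ifelse(!same_chain, "protein",
                ifelse(sep <= sep_threshold, "intra_short", "intra_long")))
}

#' Build the residue interaction network
#'
#' Nodes are all non-water residues; covalent edges (weight 1, mainchain)
#' join chain-adjacent polymer residues, noncovalent edges join residue
#' pairs with at least one atom contact, weighted by the sum of
#' \eqn{1 - d / cutoff} over contributing atom pairs. An edge's part is
#' mainchain/sidechain when every contributing protein atom is of that
#' part, and mixed otherwise. Adjacent polymer residues keep only their
#' covalent edge.
#'
#' @param model a \code{StructureModel}.
#' @param contacts result of \code{\link{find_contacts}}.
#' @return an igraph graph with vertex attributes \code{name} (residue
#'   key), \code{chain}, \code{entity} and edge attributes \code{kind},
#'   \code{part}, \code{weight}.
#' @export
build_rin <- function(model, contacts = NULL) {
  if (is.null(contacts)) contacts <- find_contacts(model)
  ridx <- contacts$residues
  pr <- contacts$pairs
  cutoff <- contacts$dist_cutoff

  # covalent backbone: consecutive polymer residues within a chain
  cov <- NULL
  for (cid in unique(ridx$chain)) {
    rows <- which(ridx$chain == cid & ridx$entity %in%
                    c("protein", "dna", "rna"))
    if (length(rows) > 1) {
      cov <- rbind(cov, cbind(rows[-length(rows)], rows[-1]))
    }
  }
  adjacent <- character(0)
  if (!is.null(cov)) {
    adjacent <- paste(pmin(cov[, 1], cov[, 2]), pmax(cov[, 1], cov[, 2]))
  }

  ekey <- paste(pmin(pr$res_a, pr$res_b), pmax(pr$res_a, pr$res_b))
  noncov <- pr[!(ekey %in% adjacent), , drop = FALSE]
  nkey <- ekey[!(ekey %in% adjacent)]
  edges <- NULL
  if (nrow(noncov) > 0) {
    w <- tapply(1 - noncov$d / cutoff, nkey, sum)
    parts <- tapply(seq_len(nrow(noncov)), nkey, function(rows) {
      p <- c(noncov$part_a[rows], noncov$part_b[rows])
      p <- p[!is.na(p)]
      if (length(p) == 0) return("mixed")
      if (all(p == "mainchain")) "mainchain"
      else if (all(p == "sidechain")) "sidechain"
      else "mixed"
    })
    ab <- do.call(rbind, strsplit(names(w), " "))
    edges <- data.frame(from = as.integer(ab[, 1]), to = as.integer(ab[, 2]),
                        weight = as.numeric(w), kind = "noncovalent",
                        part = unname(parts), stringsAsFactors = FALSE)
  }
  if (!is.null(cov)) {
    edges <- rbind(edges, data.frame(
      from = cov[, 1], to = cov[, 2], weight = 1, kind = "covalent",
      part = "mainchain", stringsAsFactors = FALSE))
  }
  g <- igraph::make_empty_graph(n = nrow(ridx), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ridx$key)
  g <- igraph::set_vertex_attr(g, "chain", value = ridx$chain)
  g <- igraph::set_vertex_attr(g, "entity", value = ridx$entity)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to),
                           weight = edges$weight, kind = edges$kind,
                           part = edges$part)
  }
  g
}

# heavy-atom counts per residue part, for score normalisation
residue_part_atoms <- function(model, ridx) {
  a <- model$atoms
  key <- paste(a$chain, a$resnum, a$icode, sep = ":")
  ri <- match(key, ridx$key)
  ok <- !is.na(ri)
  mc <- a$name %in% .MAINCHAIN_ATOMS
  n_mc <- tabulate(ri[ok & mc], nbins = nrow(ridx))
  n_all <- tabulate(ri[ok], nbins = nrow(ridx))
  cbind(mainchain = n_mc, sidechain = n_all - n_mc)
}

.INTERACTION_TYPES <- c("protein", "ligand", "metal", "ion", "dna", "rna",
                        "intra_short", "intra_long")

#' Typed interaction scores and degrees for one residue
#'
#' For each part (mainchain/sidechain) and partner type, the score is the
#' sum of contact weights \eqn{1 - d/cutoff} of that part to partners of
#' that type, divided by ten times the part's heavy-atom count; the degree
#' is the number of distinct partner residues of that type. Parts with zero
#' atoms (glycine sidechain) are undefined.
#'
#' @param model a \code{StructureModel}.
#' @param contacts result of \code{\link{find_contacts}}.
#' @param res_id residue id (row of \code{contacts$residues}).
#' @param sep_threshold sequence-separation cutoff splitting short- from
#'   long-range intra-chain contacts (default 6).
#' @return named numeric vector of 32 entries:
#'   \code{<part>_<type>_score} and \code{<part>_<type>_degree}.
#' @export
interaction_scores <- function(model, contacts, res_id, sep_threshold = 6) {
  ridx <- contacts$residues
  pr <- contacts$pairs
  cutoff <- contacts$dist_cutoff
  n_atoms <- residue_part_atoms(model, ridx)[res_id, ]

  inv_a <- pr$res_a == res_id
  inv_b <- pr$res_b == res_id
  part <- c(pr$part_a[inv_a], pr$part_b[inv_b])
  other <- c(pr$res_b[inv_a], pr$res_a[inv_b])
  d <- c(pr$d[inv_a], pr$d[inv_b])
  type <- partner_type(ridx, res_id, other, sep_threshold)

  out <- numeric(0)
  for (p in c("mainchain", "sidechain")) {
    for (tp in .INTERACTION_TYPES) {
      sel <- !is.na(part) & part == p & type == tp
      if (n_atoms[[p]] == 0) {
        sc <- NA_real_; dg <- NA_real_
      } else {
        sc <- sum(1 - d[sel] / cutoff) / (10 * n_atoms[[p]])
        dg <- length(unique(other[sel]))
      }
      out[paste0(p, "_", tp, "_score")] <- sc
      out[paste0(p, "_", tp, "_degree")] <- dg
    }
  }
  out
}
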