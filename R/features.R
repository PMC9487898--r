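# The per-residue feature registry and the full structural analysis.
#
# Every protein residue of an analysed structure yields exactly 100 numeric
# "aggregatable" features (value or NA, never silently zero):
#   6  solvent accessibility (SASA/RSA, all/mainchain/sidechain)
#   8  10-A neighbourhood profile
#   6  contact counts
#   32 interaction score/degree grid (2 parts x 8 partner types x 2)
#   3  secondary-structure one-hot
#   5  backbone geometry (phi, psi, omega, CA-pentad bend, packing density)
#   4  B-factor statistics
#   36 RIN centralities (2 scopes x 3 edge sets x 6 measures)

.SS_STATES <- c("H", "E", "C")
.CENT_MEASURES <- c("wdegree", "degree", "closeness", "betweenness",
                    "clustering", "mean_edge_weight")

#' Names and order of the 100 aggregatable residue features
#' @return character vector of length 100.
#' @export
feature_registry <- function() {
  acc <- c("sasa_all", "sasa_mainchain", "sasa_sidechain",
           "rsa_all", "rsa_mainchain", "rsa_sidechain")
  nbh <- c("nbh_same_chain_count", "nbh_same_chain_rsa_median",
           "nbh_same_chain_rsa_min", "nbh_same_chain_rsa_max",
           "nbh_other_chain_count", "nbh_other_chain_rsa_median",
           "nbh_other_chain_rsa_min", "nbh_other_chain_rsa_max")
  cnt <- c("n_contacts_total", "n_contacts_mainchain", "n_contacts_sidechain",
           "n_contacts_interchain", "n_contacts_intra_short",
           "n_contacts_intra_long")
  grid <- as.vector(vapply(c("mainchain", "sidechain"), function(p)
    as.vector(t(outer(.INTERACTION_TYPES, c("score", "degree"),
                      function(t, s) paste0(p, "_", t, "_", s)))),
    character(16)))
  ss <- c("ss_helix", "ss_sheet", "ss_coil")
  geo <- c("phi", "psi", "omega", "ca_bend_angle", "packing_density")
  bf <- c("b_mean_all", "b_mean_mainchain", "b_mean_sidechain",
          "b_chain_zscore")
  cent <- as.vector(vapply(c("complex", "chain"), function(sc)
    as.vector(vapply(c("all", "sidechain", "mainchain"), function(es)
      paste0("cent_", sc, "_", es, "_", .CENT_MEASURES), character(6))),
    character(18)))
  c(acc, nbh, cnt, grid, ss, geo, bf, cent)
}

#' Assign three-state secondary structure from backbone dihedrals
#'
#' H when phi in [-100, -30] and psi in [-80, -5]; E when phi in
#' [-170, -70] and psi in [90, 180]; otherwise C. Residues with undefined
#' dihedrals (chain termini) are C. No smoothing.
#'
#' @param phi,psi backbone dihedrals in degrees (NA at termini).
#' @return character vector of states in \code{c("H", "E", "C")}.
#' @export
assign_secondary_structure <- function(phi, psi) {
  out <- rep("C", length(phi))
  ok <- !is.na(phi) & !is.na(psi)
  out[ok & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5] <- "H"
  out[ok & phi >= -170 & phi <= -70 & psi >= 90 & psi <= 180] <- "E"
  out
}

# backbone dihedrals for the protein residues of one chain (ordered rows of
# the residue index); returns a matrix with columns phi, psi, omega
chain_dihedrals <- function(model, ridx_chain) {
  a <- model$atoms
  n <- nrow(ridx_chain)
  get_xyz <- function(i, name) {
    sel <- a$chain == ridx_chain$chain[i] & a$resnum == ridx_chain$resnum[i] &
      a$icode == ridx_chain$icode[i] & a$name == name
    if (!any(sel)) return(NULL)
    unlist(a[which(sel)[1], c("x", "y", "z")], use.names = FALSE)
  }
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("phi", "psi",
                                                        "omega")))
  for (i in seq_len(n)) {
    N <- get_xyz(i, "N"); CA <- get_xyz(i, "CA"); C <- get_xyz(i, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1) {
      Cp <- get_xyz(i - 1, "C")
      if (!is.null(Cp)) out[i, "phi"] <- dihedral_angle(Cp, N, CA, C)
    }
    if (i < n) {
      Nn <- get_xyz(i + 1, "N"); CAn <- get_xyz(i + 1, "CA")
      if (!is.null(Nn)) {
        out[i, "psi"] <- dihedral_angle(N, CA, C, Nn)
        if (!is.null(CAn)) out[i, "omega"] <- dihedral_angle(CA, C, Nn, CAn)
      }
    }
  }
  out
}

#' Ten-Angstrom neighbourhood profile of a residue
#'
#' Counts and RSA statistics of protein residues whose CA lies within the
#' radius of this residue's CA, split into same-chain and other-chain sets.
#' Undefined (NA) when a set is empty.
#'
#' @param ca_xyz matrix of CA coordinates for all protein residues.
#' @param chain chain id per CA row.
#' @param rsa_all per-residue rsa_all parallel to \code{ca_xyz}.
#' @param i focal row.
#' @param radius neighbourhood radius in Angstrom (default 10).
#' @return named numeric vector of the 8 neighbourhood features.
#' @export
neighborhood_profile <- function(ca_xyz, chain, rsa_all, i, radius = 10.0) {
  d <- cross_dist(ca_xyz[i, , drop = FALSE], ca_xyz)[1, ]
  near <- d <= radius & seq_along(d) != i
  same <- which(near & chain == chain[i])
  other <- which(near & chain != chain[i])
  stat <- function(idx) {
    v <- rsa_all[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0) c(NA_real_, NA_real_, NA_real_)
    else c(stats::median(v), min(v), max(v))
  }
  s <- stat(same); o <- stat(other)
  c(nbh_same_chain_count = length(same),
    nbh_same_chain_rsa_median = s[1], nbh_same_chain_rsa_min = s[2],
    nbh_same_chain_rsa_max = s[3],
    nbh_other_chain_count = length(other),
    nbh_other_chain_rsa_median = o[1], nbh_other_chain_rsa_min = o[2],
    nbh_other_chain_rsa_max = o[3])
}

# centrality block for one filtered graph; returns a matrix rows=vertices
graph_centralities <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(NULL)
  w <- igraph::E(g)$weight
  dist_w <- if (length(w) > 0) 1 / pmax(w, 1e-6) else numeric(0)
  deg <- igraph::degree(g)
  strength <- igraph::strength(g, weights = w)
  clo <- suppressWarnings(
    igraph::closeness(g, weights = dist_w, normalized = FALSE))
  btw <- igraph::betweenness(g, weights = dist_w)
  clu <- igraph::transitivity(g, type = "local", isolates = "NaN")
  mew <- ifelse(deg > 0, strength / deg, NA_real_)
  out <- cbind(wdegree = strength, degree = deg,
               closeness = ifelse(is.nan(clo) | deg == 0, NA_real_, clo),
               betweenness = btw,
               clustering = ifelse(is.nan(clu), NA_real_, clu),
               mean_edge_weight = mew)
  rownames(out) <- igraph::V(g)$name
  out
}

filter_edges_by_part <- function(g, parts) {
  keep <- igraph::E(g)$part %in% parts
  igraph::subgraph_from_edges(g, igraph::E(g)[keep], delete.vertices = FALSE)
}

# all 36 centrality features for every residue key
rin_centrality_features <- function(rin) {
  keys <- igraph::V(rin)$name
  chains <- igraph::V(rin)$chain
  blocks <- list()
  edge_sets <- list(all = c("mainchain", "sidechain", "mixed"),
                    sidechain = c("sidechain", "mixed"),
                    mainchain = c("mainchain", "mixed"))
  for (es in names(edge_sets)) {
    gf <- filter_edges_by_part(rin, edge_sets[[es]])
    cm <- graph_centralities(gf)
    blocks[[paste0("complex_", es)]] <- cm[keys, , drop = FALSE]
    chm <- matrix(NA_real_, length(keys), 6,
                  dimnames = list(keys, .CENT_MEASURES))
    for (cid in unique(chains)) {
      vs <- which(chains == cid)
      sub <- igraph::induced_subgraph(gf, vs)
      sm <- graph_centralities(sub)
      if (!is.null(sm)) chm[rownames(sm), ] <- sm
    }
    blocks[[paste0("chain_", es)]] <- chm
  }
  out <- NULL
  for (sc in c("complex", "chain")) {
    for (es in c("all", "sidechain", "mainchain")) {
      b <- blocks[[paste0(sc, "_", es)]]
      colnames(b) <- paste0("cent_", sc, "_", es, "_", .CENT_MEASURES)
      out <- cbind(out, b)
    }
  }
  out
}

#' Full structural analysis of a model
#'
#' Computes the complete 100-entry feature registry for every protein
#' residue of every chain. Deterministic: repeated runs are identical.
#'
#' @param model a \code{StructureModel}.
#' @param n_points SASA quadrature size (default 960).
#' @param probe probe radius (default 1.4).
#' @param dist_cutoff contact cutoff (default 5.0).
#' @param radius neighbourhood radius (default 10.0).
#' @param sep_threshold short/long-range sequence-separation split
#'   (default 6).
#' @param residues optional data frame (chain, resnum, icode) restricting
#'   the returned rows (lite-mode request set); the analysis itself always
#'   covers the whole structure so features are independent of the request.
#' @return data frame: key columns \code{entry_id}, \code{chain},
#'   \code{resnum}, \code{icode}, \code{resname}, then the 100 registry
#'   features.
#' @export
analyze_structure <- function(model, n_points = 960, probe = 1.4,
                              dist_cutoff = .CONTACT_CUTOFF, radius = 10.0,
                              sep_threshold = 6, residues = NULL) {
  atom_sasa <- compute_sasa(model, n_points = n_points, probe = probe)
  contacts <- find_contacts(model, dist_cutoff = dist_cutoff)
  ridx <- contacts$residues
  prot <- which(ridx$entity == "protein")
  if (length(prot) == 0) stop("no protein residues in ", model$entry_id)

  # accessibility
  acc <- t(vapply(prot, function(r)
    residue_rsa(model, atom_sasa, ridx$chain[r], ridx$resnum[r],
                ridx$icode[r]), numeric(6)))

  # CA table for neighbourhood/packing/bend
  a <- model$atoms
  akey <- paste(a$chain, a$resnum, a$icode, sep = ":")
  ca_rows <- vapply(prot, function(r) {
    w <- which(akey == ridx$key[r] & a$name == "CA")
    if (length(w) == 0) NA_integer_ else w[1]
  }, integer(1))
  ca_xyz <- as.matrix(a[ca_rows, c("x", "y", "z")])
  ca_chain <- ridx$chain[prot]

  nbh <- t(vapply(seq_along(prot), function(k) {
    if (is.na(ca_rows[k])) return(rep(NA_real_, 8))
    neighborhood_profile(ca_xyz, ca_chain, acc[, "rsa_all"], k, radius)
  }, numeric(8)))
  colnames(nbh) <- c("nbh_same_chain_count", "nbh_same_chain_rsa_median",
                     "nbh_same_chain_rsa_min", "nbh_same_chain_rsa_max",
                     "nbh_other_chain_count", "nbh_other_chain_rsa_median",
                     "nbh_other_chain_rsa_min", "nbh_other_chain_rsa_max")

  # contact counts + interaction grid
  pr <- contacts$pairs
  cnt <- matrix(0, length(prot), 6,
                dimnames = list(NULL, c(
                  "n_contacts_total", "n_contacts_mainchain",
                  "n_contacts_sidechain", "n_contacts_interchain",
                  "n_contacts_intra_short", "n_contacts_intra_long")))
  grid <- matrix(NA_real_, length(prot), 32)
  ligand_partners <- character(length(prot))
  chain_partners <- character(length(prot))
  for (k in seq_along(prot)) {
    r <- prot[k]
    inv_a <- pr$res_a == r; inv_b <- pr$res_b == r
    part <- c(pr$part_a[inv_a], pr$part_b[inv_b])
    other <- c(pr$res_b[inv_a], pr$res_a[inv_b])
    type <- partner_type(ridx, r, other, sep_threshold)
    het <- unique(ridx$resname[other[type %in% c("ligand", "metal", "ion")]])
    pch <- unique(ridx$chain[other[type == "protein"]])
    ligand_partners[k] <- if (length(het)) paste(sort(het), collapse = ",")
                          else "-"
    chain_partners[k] <- if (length(pch)) paste(sort(pch), collapse = ",")
                         else "-"
    cnt[k, ] <- c(length(other),
                  sum(part == "mainchain", na.rm = TRUE),
                  sum(part == "sidechain", na.rm = TRUE),
                  sum(type == "protein"),
                  sum(type == "intra_short"),
                  sum(type == "intra_long"))
    grid[k, ] <- interaction_scores(model, contacts, r, sep_threshold)
    if (k == 1) colnames(grid) <- names(
      interaction_scores(model, contacts, r, sep_threshold))
  }

  # dihedrals, secondary structure, bend, packing
  geo <- matrix(NA_real_, length(prot), 5,
                dimnames = list(NULL, c("phi", "psi", "omega",
                                        "ca_bend_angle", "packing_density")))
  ss <- character(length(prot))
  for (cid in unique(ridx$chain[prot])) {
    rows <- which(ridx$chain[prot] == cid)
    dih <- chain_dihedrals(model, ridx[prot[rows], , drop = FALSE])
    geo[rows, 1:3] <- dih
    ss[rows] <- assign_secondary_structure(dih[, "phi"], dih[, "psi"])
    for (m in seq_along(rows)) {
      if (m > 2 && m <= length(rows) - 2) {
        k <- rows[m]
        if (!any(is.na(ca_rows[c(rows[m - 2], k, rows[m + 2])]))) {
          geo[k, "ca_bend_angle"] <- vec_angle_deg(
            ca_xyz[rows[m - 2], ] - ca_xyz[k, ],
            ca_xyz[rows[m + 2], ] - ca_xyz[k, ])
        }
      }
    }
  }
  dmat_ca <- cross_dist(ca_xyz, ca_xyz)
  geo[, "packing_density"] <- rowSums(dmat_ca <= radius, na.rm = TRUE) - 1
  ssmat <- cbind(ss_helix = as.numeric(ss == "H"),
                 ss_sheet = as.numeric(ss == "E"),
                 ss_coil = as.numeric(ss == "C"))

  # B-factor statistics
  bf <- matrix(NA_real_, length(prot), 4,
               dimnames = list(NULL, c("b_mean_all", "b_mean_mainchain",
                                       "b_mean_sidechain",
                                       "b_chain_zscore")))
  for (k in seq_along(prot)) {
    sel <- akey == ridx$key[prot[k]]
    mc <- sel & a$name %in% .MAINCHAIN_ATOMS
    sc <- sel & !(a$name %in% .MAINCHAIN_ATOMS)
    bf[k, 1] <- mean(a$bfactor[sel])
    bf[k, 2] <- if (any(mc)) mean(a$bfactor[mc]) else NA_real_
    bf[k, 3] <- if (any(sc)) mean(a$bfactor[sc]) else NA_real_
  }
  for (cid in unique(ca_chain)) {
    rows <- which(ca_chain == cid)
    mu <- mean(bf[rows, 1]); sdv <- stats::sd(bf[rows, 1])
    bf[rows, 4] <- if (is.na(sdv) || sdv == 0) 0 else (bf[rows, 1] - mu) / sdv
  }

  # RIN centralities
  rin <- build_rin(model, contacts)
  centm <- rin_centrality_features(rin)
  cent <- centm[ridx$key[prot], , drop = FALSE]

  out <- data.frame(entry_id = model$entry_id, chain = ridx$chain[prot],
                    resnum = ridx$resnum[prot], icode = ridx$icode[prot],
                    resname = ridx$resname[prot], stringsAsFactors = FALSE)
  out <- cbind(out, acc, nbh, cnt, grid, ssmat, geo, bf, cent)
  stopifnot(identical(setdiff(names(out),
                              c("entry_id", "chain", "resnum", "icode",
                                "resname")), feature_registry()))
  out$ligand_partners <- ligand_partners
  out$chain_partners <- chain_partners
  rownames(out) <- NULL
  if (!is.null(residues)) {
    want <- paste(residues$chain, residues$resnum,
                  if (!is.null(residues$icode)) residues$icode else " ",
                  sep = ":")
    out <- out[paste(out$chain, out$resnum, out$icode, sep = ":") %in% want, ,
               drop = FALSE]
  }
  out
}
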