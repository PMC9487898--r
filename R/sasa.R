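# Solvent accessible surface area, Shrake-Rupley style: a deterministic
# Fibonacci lattice of test points on each atom's solvent-expanded sphere;
# a point is accessible if it lies outside every neighbouring sphere.

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.VDW_DEFAULT <- 1.70

vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# evenly distributed unit sphere points, deterministic
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (seq_len(n) - 1)
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Per-atom solvent accessible surface area
#'
#' Computes SASA for every non-water heavy atom of a structure model by
#' even sphere sampling. Waters are excluded both as targets and as
#' occluders. Deterministic for a given quadrature size.
#'
#' @param model a \code{StructureModel}.
#' @param n_points number of test points per atom (default 960).
#' @param probe probe radius in Angstrom (default 1.4).
#' @return numeric vector of per-atom SASA in square Angstrom, parallel to
#'   the rows of \code{model$atoms}; water atoms get \code{NA}.
#' @export
compute_sasa <- function(model, n_points = 960, probe = 1.4) {
  atoms <- model$atoms
  keep <- atoms$entity != "water"
  xyz <- as.matrix(atoms[keep, c("x", "y", "z")])
  rad <- vdw_radius(atoms$element[keep]) + probe
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  out_keep <- numeric(n)

  # spatial binning: cell width = max expanded diameter so neighbour
  # candidates are confined to the 27 surrounding cells
  cell <- 2 * max(rad)
  bin <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  binkey <- paste(bin[, 1], bin[, 2], bin[, 3])
  bins <- split(seq_len(n), binkey)
  bin_of <- match(binkey, names(bins))

  neighbor_cells <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (i in seq_len(n)) {
    b <- bin[i, ]
    cand <- integer(0)
    for (j in seq_len(27)) {
      key <- paste(b[1] + neighbor_cells$dx[j], b[2] + neighbor_cells$dy[j],
                   b[3] + neighbor_cells$dz[j])
      hit <- bins[[key]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    cand <- cand[cand != i]
    if (length(cand) > 0) {
      dd <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
      cand <- cand[dd < rad[i] + rad[cand]]
    }
    if (length(cand) == 0) {
      out_keep[i] <- 4 * pi * rad[i]^2
      next
    }
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    occluded <- rep(FALSE, n_points)
    for (j in cand) {
      d2 <- colSums((t(sp) - xyz[j, ])^2)
      occluded <- occluded | d2 < rad[j]^2
      if (all(occluded)) break
    }
    out_keep[i] <- 4 * pi * rad[i]^2 * sum(!occluded) / n_points
  }
  out <- rep(NA_real_, nrow(atoms))
  out[keep] <- out_keep
  out
}

# Theoretical maximum accessible surface per residue type (Tien et al.
# 2013, theoretical column), used to normalise SASA into RSA.
.RSA_MAX <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)
.RSA_MAX_X <- mean(.RSA_MAX)      # unknown residue type
.RSA_MAX_MAINCHAIN <- .RSA_MAX[["GLY"]]  # backbone-only reference
.RSA_CAP <- 1.3

rsa_max_of <- function(resname) {
  m <- .RSA_MAX[toupper(resname)]
  m[is.na(m)] <- .RSA_MAX_X
  unname(m)
}

#' Residue-level SASA and relative solvent accessibility
#'
#' Sums per-atom SASA over the residue, split into mainchain (N, CA, C, O,
#' OXT) and sidechain parts, and normalises by per-residue-type theoretical
#' maxima. The sidechain maximum is the residue maximum minus the
#' backbone-only (glycine) reference; glycine therefore has an undefined
#' sidechain RSA. RSA values are capped at 1.3.
#'
#' @param model a \code{StructureModel}.
#' @param atom_sasa per-atom SASA vector from \code{\link{compute_sasa}}.
#' @param chain_id,resnum,icode residue key.
#' @return named numeric vector: \code{sasa_all}, \code{sasa_mainchain},
#'   \code{sasa_sidechain}, \code{rsa_all}, \code{rsa_mainchain},
#'   \code{rsa_sidechain} (\code{NA} where undefined).
#' @export
residue_rsa <- function(model, atom_sasa, chain_id, resnum, icode = " ") {
  a <- model$atoms
  sel <- a$chain == chain_id & a$resnum == resnum & a$icode == icode
  if (!any(sel)) stop("no such residue ", chain_id, ":", resnum)
  if (entity_type_of(a$resname[sel][1]) != "protein") {
    stop("residue_rsa requires a protein residue")
  }
  mc <- sel & a$name %in% .MAINCHAIN_ATOMS
  sc <- sel & !(a$name %in% .MAINCHAIN_ATOMS)
  s_all <- sum(atom_sasa[sel])
  s_mc <- sum(atom_sasa[mc])
  s_sc <- if (any(sc)) sum(atom_sasa[sc]) else NA_real_
  resname <- a$resname[sel][1]
  max_all <- rsa_max_of(resname)
  max_sc <- max_all - .RSA_MAX_MAINCHAIN
  cap <- function(x) pmin(x, .RSA_CAP)
  c(sasa_all = s_all, sasa_mainchain = s_mc, sasa_sidechain = s_sc,
    rsa_all = cap(s_all / max_all),
    rsa_mainchain = cap(s_mc / .RSA_MAX_MAINCHAIN),
    rsa_sidechain = if (is.na(s_sc) || max_sc <= 0) NA_real_ else
      cap(s_sc / max_sc))
}
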