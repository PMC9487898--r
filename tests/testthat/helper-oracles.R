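# Independent oracles used by the property tests. These re-derive the same
# quantities as the package through different algorithms and must never
# call the code paths they check.

.oracle_blosum62 <- local({
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

# plain three-state Gotoh DP with free end gaps; gap run of length L costs
# open + L * ext. Validated below against exhaustive alignment enumeration.
gotoh_oracle <- function(q, t, open = 10, ext = 0.5) {
  B <- .oracle_blosum62()
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  X[1, 2:(m + 1)] <- 0   # free leading gap in query
  Y[2:(n + 1), 1] <- 0   # free leading gap in template
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- B[qc[i - 1], tc[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - open - ext,
                     X[i, j - 1] - ext)
      Y[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - open - ext,
                     Y[i - 1, j] - ext)
    }
  }
  H <- pmax(M, X, Y)
  max(H[n + 1, ], H[, m + 1], 0)
}

# exhaustive enumeration over every gapped alignment (terminal gap runs
# free); only usable at tiny lengths
enum_align_oracle <- function(q, t, open = 10, ext = 0.5) {
  B <- .oracle_blosum62()
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  best <- -Inf
  rec <- function(i, j, moves) {
    if (i == n && j == m) {
      s <- 0; runs <- rle(moves); qi <- 0; ti <- 0
      for (k in seq_along(runs$values)) {
        v <- runs$values[k]; L <- runs$lengths[k]
        if (v == "M") {
          for (z in 1:L) {
            qi <- qi + 1; ti <- ti + 1
            s <- s + B[qc[qi], tc[ti]]
          }
        } else {
          if (k != 1 && k != length(runs$values)) s <- s - open - ext * L
          if (v == "X") ti <- ti + L else qi <- qi + L
        }
      }
      best <<- max(best, s)
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(moves, "M"))
    if (j < m) rec(i, j + 1, c(moves, "X"))
    if (i < n) rec(i + 1, j, c(moves, "Y"))
  }
  rec(0, 0, character(0))
  max(best, 0)
}

# independent SASA quadrature: latitude-longitude banding instead of a
# Fibonacci lattice
sasa_latlong_oracle <- function(xyz, elements, probe = 1.4, n_lat = 40) {
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  radii <- unname(vdw[elements]); radii[is.na(radii)] <- 1.70
  R <- radii + probe
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    area <- 0
    for (k in seq_len(n_lat)) {
      th_lo <- -pi / 2 + (k - 1) * pi / n_lat
      th_hi <- th_lo + pi / n_lat
      th <- (th_lo + th_hi) / 2
      band <- 2 * pi * R[i]^2 * (sin(th_hi) - sin(th_lo))
      n_lon <- max(1L, round(2 * n_lat * cos(th)))
      lam <- 2 * pi * (seq_len(n_lon) - 0.5) / n_lon
      px <- xyz[i, 1] + R[i] * cos(th) * cos(lam)
      py <- xyz[i, 2] + R[i] * cos(th) * sin(lam)
      pz <- xyz[i, 3] + R[i] * sin(th)
      acc <- rep(TRUE, n_lon)
      for (j in seq_len(n)[-i]) {
        d2 <- (px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 + (pz - xyz[j, 3])^2
        acc <- acc & d2 >= R[j]^2
      }
      area <- area + band * sum(acc) / n_lon
    }
    out[i] <- area
  }
  out
}

# graph oracles over a symmetric affinity matrix W (0 = no edge), with
# path distances 1 / max(w, 1e-6) to mirror the package convention
graph_dist_oracle <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[W > 0] <- 1 / pmax(W[W > 0], 1e-6)
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

closeness_oracle <- function(W) {
  D <- graph_dist_oracle(W)
  n <- nrow(W)
  vapply(1:n, function(v) {
    d <- D[v, -v]; d <- d[is.finite(d)]
    if (length(d) == 0) NA_real_ else 1 / sum(d)
  }, numeric(1))
}

betweenness_oracle <- function(W) {
  n <- nrow(W)
  D <- graph_dist_oracle(W)
  edge_w <- matrix(Inf, n, n)
  edge_w[W > 0] <- 1 / pmax(W[W > 0], 1e-6)
  # sigma[s, v]: number of shortest s->v paths, by increasing distance
  sigma <- matrix(0, n, n)
  for (s in 1:n) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      pred <- which(is.finite(edge_w[, v]) &
                    abs(D[s, ] + edge_w[, v] - D[s, v]) < 1e-9)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  bet <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
    for (v in 1:n) {
      if (v == s || v == t) next
      if (abs(D[s, v] + D[v, t] - D[s, t]) < 1e-9) {
        bet[v] <- bet[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  bet
}

clustering_oracle <- function(W) {
  A <- (W > 0) * 1
  n <- nrow(A)
  vapply(1:n, function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(NA_real_)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}
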