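# Internal-coordinate backbone builder. Places atoms with the natural
# extension reference frame (NeRF): given three placed atoms a-b-c, the next
# atom d is defined by bond length |cd|, angle b-c-d and torsion a-b-c-d.

place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- -torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# dihedral angle in degrees for four points (rows of a matrix or vectors)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Build an all-backbone peptide (N, CA, C, O + CB except GLY) from a
# one-letter sequence and per-residue phi/psi. Idealised bond geometry.
build_peptide_atoms <- function(sequence, phi, psi, omega = 180,
                                chain_id = "A", resnum_start = 1L,
                                bfactor = 20) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  stopifnot(length(phi) %in% c(1, n), length(psi) %in% c(1, n))
  phi <- rep(phi, length.out = n)
  psi <- rep(psi, length.out = n)
  omega <- rep(omega, length.out = n)
  three <- .STANDARD_AA3[match(aa, unname(.AA3[1:20]))]
  if (anyNA(three)) stop("fixture sequences must use the 20 standard amino acids")

  rows <- list()
  add <- function(name, el, resi, xyz) {
    rows[[length(rows) + 1]] <<- list(name = name, element = el,
                                      resi = resi, x = xyz[1], y = xyz[2],
                                      z = xyz[3])
  }
  # first residue seeded explicitly
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- CA + 1.525 * c(cos((180 - 111) * pi / 180),
                      sin((180 - 111) * pi / 180), 0)
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(n)) {
    if (i > 1) {
      N <- place_atom(prevN, prevCA, prevC, 1.329, 116.6, psi[i - 1])
      CA <- place_atom(prevCA, prevC, N, 1.458, 121.7, omega[i - 1])
      C <- place_atom(prevC, N, CA, 1.525, 111.0, phi[i])
    }
    add("N", "N", i, N)
    add("CA", "C", i, CA)
    add("C", "C", i, C)
    # carbonyl O anti to the following N along psi
    O <- place_atom(N, CA, C, 1.231, 120.5, psi[i] + 180)
    add("O", "O", i, O)
    if (aa[i] != "G") {
      CB <- place_atom(C, N, CA, 1.530, 110.6, -122.0)
      add("CB", "C", i, CB)
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  data.frame(
    serial = seq_len(nrow(df)),
    name = df$name, altloc = " ",
    resname = three[df$resi],
    chain = chain_id,
    resnum = resnum_start + df$resi - 1L,
    icode = " ",
    x = df$x, y = df$y, z = df$z,
    occupancy = 1.0, bfactor = bfactor,
    element = df$element, is_hetatm = FALSE,
    stringsAsFactors = FALSE
  )
}
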