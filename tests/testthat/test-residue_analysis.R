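test_that("SASA matches closed forms and is additive for distant atoms", {
  # isolated carbon: 4*pi*(1.7+1.4)^2
  lines <- pdb_line("HETATM", 1, "C1", resname = "LIG", chain = "L",
                    resnum = 1, x = 0, y = 0, z = 0, element = "C")
  m1 <- parse_structure(write_mini_pdb(lines), "ONE")
  expect_equal(compute_sasa(m1), 4 * pi * 3.1^2, tolerance = 0.01)

  # two atoms 50 A apart: sum of isolated spheres
  lines2 <- c(lines,
              pdb_line("HETATM", 2, "O1", resname = "LIG", chain = "L",
                       resnum = 2, x = 50, y = 0, z = 0, element = "O"))
  m2 <- parse_structure(write_mini_pdb(lines2), "TWO")
  s2 <- compute_sasa(m2)
  expect_equal(s2[1], 4 * pi * 3.1^2, tolerance = 0.01)
  expect_equal(s2[2], 4 * pi * (1.52 + 1.4)^2, tolerance = 0.01)
})

test_that("SASA agrees with an independent lat-long quadrature oracle", {
  fx <- generate_fixture("helix", n = 8, seed = 21)
  s <- compute_sasa(fx$model)
  o <- sasa_latlong_oracle(as.matrix(fx$model$atoms[, c("x", "y", "z")]),
                           fx$model$atoms$element)
  expect_equal(s, o, tolerance = 0.02)
})

test_that("an enclosed atom has near-zero SASA and burial is monotone", {
  m <- caged_residue_model(spacing = 2.5)
  s <- compute_sasa(m)
  ca3 <- which(m$atoms$chain == "A" & m$atoms$resnum == 3 &
               m$atoms$name == "CA")
  expect_lt(s[ca3], 1.0)
  # adding occluders can only decrease per-atom SASA (nested fixtures)
  helix <- generate_fixture("helix", n = 5, seed = 9)$model
  s_free <- compute_sasa(helix)
  free_ca3 <- which(helix$atoms$resnum == 3 & helix$atoms$name == "CA")
  in_helix <- m$atoms$chain == "A"
  expect_true(all(s[in_helix] <= s_free + 1e-6))
})

test_that("residue RSA normalisation and glycine sidechain handling", {
  m <- caged_residue_model()
  s <- compute_sasa(m)
  rsa_caged <- residue_rsa(m, s, "A", 3)
  expect_lt(rsa_caged[["rsa_all"]], 0.16)     # designed buried residue

  helix <- generate_fixture("helix", n = 5, seed = 9)$model
  sh <- compute_sasa(helix)
  rsa_free <- residue_rsa(helix, sh, "A", 3)
  expect_gt(rsa_free[["rsa_all"]], rsa_caged[["rsa_all"]])
  expect_true(all(rsa_free[c("rsa_all", "rsa_mainchain",
                             "rsa_sidechain")] <= 1.3))

  # glycine: no sidechain atoms, undefined sidechain RSA
  gly <- c(pdb_line("ATOM", 1, "N", resname = "GLY", chain = "A",
                    resnum = 1, x = 0, y = 0, z = 0, element = "N"),
           pdb_line("ATOM", 2, "CA", resname = "GLY", chain = "A",
                    resnum = 1, x = 1.46, y = 0, z = 0, element = "C"),
           pdb_line("ATOM", 3, "C", resname = "GLY", chain = "A",
                    resnum = 1, x = 2.2, y = 1.2, z = 0, element = "C"))
  mg <- parse_structure(write_mini_pdb(gly), "GLY")
  rg <- residue_rsa(mg, compute_sasa(mg), "A", 1)
  expect_true(is.na(rg[["rsa_sidechain"]]))
  expect_false(is.na(rg[["rsa_mainchain"]]))
  expect_error(residue_rsa(mg, compute_sasa(mg), "A", 99), "no such")
})

test_that("contacts: interface by construction, covalent exclusion, symmetry", {
  fx <- generate_fixture("dimer", seed = 2)
  ct <- find_contacts(fx$model)
  ridx <- ct$residues
  inter <- ridx$chain[ct$pairs$res_a] != ridx$chain[ct$pairs$res_b]
  expect_true(any(inter))             # designed 4.5 A interface

  # the covalent backbone C(i)-N(i+1) pair is excluded
  a <- fx$model$atoms
  pn <- ct$pairs
  cn_pairs <- (a$name[pn$ai] == "C" & a$name[pn$aj] == "N" &
               pn$res_b == pn$res_a + 1 &
               ridx$chain[pn$res_a] == ridx$chain[pn$res_b])
  expect_false(any(cn_pairs))

  # degree counts a partner once regardless of atom-pair multiplicity
  feats <- analyze_structure(fx$model, n_points = 120)
  multi <- feats$n_contacts_interchain >
    (feats$mainchain_protein_degree + feats$sidechain_protein_degree)
  expect_true(any(multi, na.rm = TRUE))
})

test_that("short/long-range split respects the 6-residue separation rule", {
  # fold a chain back on itself: residues i and i+7 near 4 A
  mk <- function(resnum, x, y) {
    c(pdb_line("ATOM", resnum * 2 - 1, "CA", resname = "ALA",
               chain = "A", resnum = resnum, x = x, y = y, z = 0,
               element = "C"),
      pdb_line("ATOM", resnum * 2, "CB", resname = "ALA", chain = "A",
               resnum = resnum, x = x, y = y + 1.5, z = 0, element = "C"))
  }
  lines <- c(mk(1, 0, 0), mk(2, 3.8, 0), mk(3, 7.6, 0), mk(4, 11.4, 0),
             mk(5, 15.2, 0), mk(6, 13, 4), mk(7, 9, 5), mk(8, 0, 4))
  m <- parse_structure(write_mini_pdb(lines), "FOLD")
  feats <- analyze_structure(m, n_points = 120)
  # residue 1 vs residue 8: separation 7 (> 6) at 4 A -> long-range
  expect_gt(feats$n_contacts_intra_long[1], 0)
  expect_gt(feats$mainchain_intra_long_degree[1] +
            feats$sidechain_intra_long_degree[1], 0)
  # residue 1 vs 2 (separation 1, <= 6) contributes short-range
  expect_gt(feats$n_contacts_intra_short[1], 0)
})

test_that("RIN: covalent edges, boundary weights and a brute-force weight", {
  # 3-residue strand, residues only adjacent: exactly 2 covalent edges
  mk <- function(resnum, x) {
    pdb_line("ATOM", resnum, "CA", resname = "ALA", chain = "A",
             resnum = resnum, x = x, y = 0, z = 0, element = "C")
  }
  m <- parse_structure(write_mini_pdb(c(mk(1, 0), mk(2, 3.8),
                                        mk(3, 7.6))), "TRI")
  g <- build_rin(m)
  expect_equal(igraph::ecount(g), 2)
  expect_true(all(igraph::E(g)$kind == "covalent"))
  expect_true(all(igraph::E(g)$weight == 1))

  # atom pair exactly at the 5.0 A cutoff: edge weight 0
  two <- c(pdb_line("ATOM", 1, "CA", resname = "ALA", chain = "A",
                    resnum = 1, x = 0, y = 0, z = 0, element = "C"),
           pdb_line("ATOM", 2, "CA", resname = "ALA", chain = "B",
                    resnum = 1, x = 5.0, y = 0, z = 0, element = "C"))
  m2 <- parse_structure(write_mini_pdb(two), "B5")
  g2 <- build_rin(m2)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$weight, 0)

  # noncovalent weight equals independent pairwise recomputation
  fx <- generate_fixture("ligand_complex", n = 5, seed = 13,
                         contact_residue = 3)
  ct <- find_contacts(fx$model)
  g3 <- build_rin(fx$model, ct)
  ridx <- ct$residues
  xyz <- as.matrix(fx$model$atoms[, c("x", "y", "z")])
  akey <- paste(fx$model$atoms$chain, fx$model$atoms$resnum,
                fx$model$atoms$icode, sep = ":")
  for (e in seq_len(igraph::ecount(g3))) {
    if (igraph::E(g3)$kind[e] == "covalent") next
    ends <- igraph::ends(g3, e)
    ai <- which(akey == ends[1]); aj <- which(akey == ends[2])
    d <- sqrt(outer(rowSums(xyz[ai, , drop = FALSE]^2),
                    rowSums(xyz[aj, , drop = FALSE]^2), "+") -
              2 * xyz[ai, , drop = FALSE] %*% t(xyz[aj, , drop = FALSE]))
    expect_equal(igraph::E(g3)$weight[e], sum(1 - d[d <= 5] / 5),
                 tolerance = 1e-9)
  }
})

test_that("interaction scores: designed ligand contact and hand arithmetic", {
  fx <- generate_fixture("ligand_complex", seed = 3, gap = 3.5)
  feats <- analyze_structure(fx$model, n_points = 120)
  r8 <- feats[feats$resnum == 8, ]
  expect_equal(r8$sidechain_ligand_degree, 1)
  expect_equal(r8$mainchain_ligand_degree, 0)
  # residue with no neighbours: all scores 0 (far-apart strand toy)
  iso <- c(pdb_line("ATOM", 1, "CA", resname = "ALA", chain = "A",
                    resnum = 1, x = 0, y = 0, z = 0, element = "C"))
  m <- parse_structure(write_mini_pdb(iso), "ISO")
  f1 <- analyze_structure(m, n_points = 120)
  grid_cols <- grep("mainchain_.*_(score|degree)", names(f1), value = TRUE)
  expect_true(all(f1[1, grid_cols] == 0))

  # hand computation: ALA (CA + CB) + ligand C at 4.0 A from CB, > 5 from CA
  toy <- c(pdb_line("ATOM", 1, "CA", resname = "ALA", chain = "A",
                    resnum = 1, x = 0, y = 0, z = 0, element = "C"),
           pdb_line("ATOM", 2, "CB", resname = "ALA", chain = "A",
                    resnum = 1, x = 1.5, y = 0, z = 0, element = "C"),
           pdb_line("HETATM", 3, "C1", resname = "LIG", chain = "L",
                    resnum = 1, x = 5.5, y = 0, z = 0, element = "C"))
  mt <- parse_structure(write_mini_pdb(toy), "TOY")
  ct <- find_contacts(mt)
  res_id <- which(ct$residues$chain == "A")
  sc <- interaction_scores(mt, ct, res_id)
  expect_equal(sc[["sidechain_ligand_score"]], (1 - 4.0 / 5) / (10 * 1))
  expect_equal(sc[["sidechain_ligand_degree"]], 1)
  expect_equal(sc[["mainchain_ligand_score"]], 0)
})

test_that("secondary structure assignment follows the dihedral windows", {
  expect_equal(assign_secondary_structure(-57, -47), "H")
  expect_equal(assign_secondary_structure(-120, 130), "E")
  expect_equal(assign_secondary_structure(NA, -47), "C")
  expect_equal(assign_secondary_structure(60, 60), "C")
  helix <- analyze_structure(generate_fixture("helix", seed = 1)$model,
                             n_points = 120)
  expect_true(all(helix$ss_helix[2:19] == 1))
  expect_equal(helix$ss_coil[c(1, 20)], c(1, 1))   # termini
  strand <- analyze_structure(generate_fixture("strand", seed = 1)$model,
                              n_points = 120)
  expect_true(all(strand$ss_sheet[2:19] == 1))
})

test_that("neighborhood profile matches direct recomputation", {
  ca <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0), c(9, 0, 0), c(30, 0, 0),
              c(4, 4, 0))
  chain <- c("A", "A", "A", "A", "A", "B")
  rsa <- c(0.5, 0.2, 0.8, 0.4, 0.9, 0.6)
  p <- neighborhood_profile(ca, chain, rsa, i = 1, radius = 10)
  expect_equal(p[["nbh_same_chain_count"]], 3)   # residues 2,3,4
  expect_equal(p[["nbh_same_chain_rsa_median"]], median(c(0.2, 0.8, 0.4)))
  expect_equal(p[["nbh_same_chain_rsa_min"]], 0.2)
  expect_equal(p[["nbh_same_chain_rsa_max"]], 0.8)
  expect_equal(p[["nbh_other_chain_count"]], 1)
  expect_equal(p[["nbh_other_chain_rsa_median"]], 0.6)
  # isolated helix: other-chain features undefined
  helix <- analyze_structure(generate_fixture("helix", seed = 1)$model,
                             n_points = 120)
  expect_true(all(is.na(helix$nbh_other_chain_rsa_median)))
  expect_true(all(helix$nbh_other_chain_count == 0))
  # dimer interface residue sees the other chain
  fd <- generate_fixture("dimer", seed = 2)
  fdf <- analyze_structure(fd$model, n_points = 120)
  expect_true(all(fdf$nbh_other_chain_count[fd$truth$interface] >= 1))
})

test_that("full analysis fills the 100-slot registry deterministically", {
  fx <- generate_fixture("ligand_complex", seed = 3)
  f1 <- analyze_structure(fx$model, n_points = 120)
  expect_true(all(feature_registry() %in% names(f1)))
  expect_equal(length(feature_registry()), 100)
  f2 <- analyze_structure(fx$model, n_points = 120)
  expect_identical(f1, f2)            # byte-identical reruns
  # lite request set restricts rows, not values
  f3 <- analyze_structure(fx$model, n_points = 120,
                          residues = data.frame(chain = "A", resnum = 8))
  expect_equal(nrow(f3), 1)
  expect_equal(f3[1, feature_registry()],
               f1[f1$resnum == 8, feature_registry()],
               ignore_attr = TRUE)
})

test_that("RIN centralities match brute-force graph oracles", {
  fx <- generate_fixture("ligand_complex", n = 8, seed = 17,
                         contact_residue = 4)
  g <- build_rin(fx$model)
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = FALSE))
  feats <- analyze_structure(fx$model, n_points = 120)
  keys <- paste(feats$chain, feats$resnum, feats$icode, sep = ":")
  vorder <- match(keys, igraph::V(g)$name)

  clo <- closeness_oracle(W)[vorder]
  bet <- betweenness_oracle(W)[vorder]
  clu <- clustering_oracle(W)[vorder]
  wdeg <- unname(rowSums(W)[vorder])
  expect_equal(feats$cent_complex_all_closeness, clo, tolerance = 1e-9)
  expect_equal(feats$cent_complex_all_betweenness, bet, tolerance = 1e-9)
  expect_equal(feats$cent_complex_all_clustering, clu, tolerance = 1e-9)
  expect_equal(feats$cent_complex_all_wdegree, wdeg, tolerance = 1e-9)
})
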