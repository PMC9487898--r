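test_that("quality score combines identity, coverage and resolution", {
  expect_equal(quality_score(1, 1, 1.5), 1.0)
  expect_equal(quality_score(1, 1, 6.5), 0.1)      # clamp floor
  expect_equal(quality_score(0.5, 0.8, 4.0), 0.5 * 0.8 * 0.5)
  expect_equal(quality_score(1, 1, NA), (6.5 - 3.5) / 5)  # undefined -> 3.5
})

test_that("weighted aggregation follows the weighted-mean rule", {
  expect_equal(weighted_aggregate(c(0.2, 0.4), c(1, 1)), 0.3)
  expect_equal(weighted_aggregate(c(0.0, 0.4), c(3, 1)), 0.1)
  # sparsity: undefined values are not included
  expect_equal(weighted_aggregate(c(0.7, NA), c(2, 5)), 0.7)
  expect_true(is.na(weighted_aggregate(c(NA, NA), c(1, 1))))
  expect_error(weighted_aggregate(c(1, 2), c(1, -1)), "negative")
})

test_that("aggregation invariants: mean equivalence, scaling, bounds", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(1:8, 1)
    d <- runif(n)
    d[sample(n, sample(0:(n - 1), 1))] <- NA
    q <- runif(n, 0.05, 1)
    w <- weighted_aggregate(d, q)
    if (all(is.na(d))) {
      expect_true(is.na(w))
      next
    }
    # equal weights give the arithmetic mean
    expect_equal(weighted_aggregate(d, rep(0.4, n)), mean(d, na.rm = TRUE))
    # invariance under scaling all weights
    expect_equal(weighted_aggregate(d, q * 7.3), w)
    # bounded by defined inputs
    expect_gte(w, min(d, na.rm = TRUE) - 1e-12)
    expect_lte(w, max(d, na.rm = TRUE) + 1e-12)
    # single-input identity
    expect_equal(weighted_aggregate(d[1], q[1]),
                 if (is.na(d[1])) NA_real_ else d[1])
  }
})

test_that("RSA aggregation multiplies quality by squared coverage", {
  expect_equal(aggregate_rsa(c(0.1, 0.9), c(1, 1), c(1.0, 0.5)),
               (0.1 * 1 + 0.9 * 0.25) / 1.25)   # = 0.26
  expect_equal(aggregate_rsa(0.42, 0.7, 0.9), 0.42)  # single annotation
  # equal coverages reduce to the plain weighted mean
  d <- c(0.2, 0.5, 0.8); q <- c(0.3, 0.6, 0.9)
  expect_equal(aggregate_rsa(d, q, rep(0.7, 3)), weighted_aggregate(d, q))
})

make_agg <- function(rsa = NA, degrees = list()) {
  reg <- feature_registry()
  agg <- stats::setNames(rep(NA_real_, length(reg)), reg)
  agg["rsa_all"] <- rsa
  agg["rsa_mainchain"] <- rsa
  agg["rsa_sidechain"] <- rsa
  for (nm in names(degrees)) agg[nm] <- degrees[[nm]]
  agg
}

test_that("classification truth table over RSA x interaction presence", {
  types <- c("metal", "ion", "dna", "rna", "ligand", "protein")
  for (rsa in c(0.10, 0.16, 0.50)) {
    # no interactions: surface/core by threshold (strict > is Surface)
    cl <- classify_position(make_agg(rsa = rsa), n_annotations = 2)
    expected_loc <- if (rsa > 0.16) "Surface" else "Core"
    expect_equal(cl$structural_class, expected_loc)
    expect_equal(cl$simple_class, expected_loc)
    for (tp in types) {
      for (part in c("mainchain", "sidechain")) {
        dg <- stats::setNames(list(1.0), paste0(part, "_", tp, "_degree"))
        cl <- classify_position(make_agg(rsa = rsa, degrees = dg),
                                n_annotations = 2)
        expect_equal(cl$simple_class, "Interaction")
        expect_match(cl$structural_class, "interaction")
        expect_equal(cl$rin_class,
                     sprintf("%s contact with a %s", part,
                             c(metal = "metal", ion = "ion", dna = "DNA",
                               rna = "RNA", ligand = "ligand",
                               protein = "protein")[[tp]]))
        # location labels still reflect RSA irrespective of interactions
        expect_equal(cl$location, expected_loc)
      }
      # below the degree threshold: not an interaction
      dg <- stats::setNames(list(0.05), paste0("sidechain_", tp, "_degree"))
      cl <- classify_position(make_agg(rsa = rsa, degrees = dg),
                              n_annotations = 2)
      expect_equal(cl$simple_class, expected_loc)
    }
  }
})

test_that("multiple interactions produce the combined RIN class string", {
  agg <- make_agg(rsa = 0.3, degrees = list(
    sidechain_ligand_degree = 1.0, sidechain_protein_degree = 1.0))
  cl <- classify_position(agg, n_annotations = 3)
  expect_equal(cl$rin_class,
               paste("Multiple interactions: sidechain contact with a",
                     "ligand and sidechain contact with a protein"))
  expect_equal(cl$structural_class, "Ligand interaction")  # priority
  expect_equal(cl$rin_simple_class, "Multiple interactions")
  # priority: metal beats ligand
  agg2 <- make_agg(rsa = 0.3, degrees = list(
    sidechain_ligand_degree = 2.0, mainchain_metal_degree = 1.0))
  expect_equal(classify_position(agg2, 1)$structural_class,
               "Metal interaction")
})

test_that("zero annotations classify as No structure", {
  cl <- classify_position(make_agg(), n_annotations = 0)
  expect_equal(cl$structural_class, "No structure")
  expect_equal(cl$simple_class, "No structure")
  expect_true(is.na(cl$location))
})

ann_info_fixture <- function() {
  data.frame(
    entry_id = c("E2", "E1", "E3"), chain_id = c("A", "A", "B"),
    identity = c(0.9, 0.9, 0.5), coverage = c(0.8, 0.9, 1.0),
    resolution = c(2.0, 2.0, NA), quality = c(0.6, 0.7, 0.3),
    n_interaction_types = c(0, 0, 2),
    resnum = c(10, 11, 12), icode = " ",
    resname = c("ASP", "ASP", "GLY"), stringsAsFactors = FALSE)
}

test_that("structure selection: identity ties and interaction bonus", {
  info <- ann_info_fixture()
  sel <- select_recommended(info)
  # identity tie between E1/E2 broken by higher coverage -> E1
  expect_equal(sel$max_identity$entry_id, "E1")
  # recommended maximises q * (1 + types): E1 0.7 vs E3 0.3*3 = 0.9
  expect_equal(sel$recommended$entry_id, "E3")
  # single annotation: both references identical
  one <- select_recommended(info[1, ])
  expect_equal(one$max_identity$entry_id, one$recommended$entry_id)
  # deterministic under permutation
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(3, 1, 2))) {
    sel2 <- select_recommended(info[perm, ])
    expect_equal(sel2$max_identity$entry_id, sel$max_identity$entry_id)
    expect_equal(sel2$recommended$entry_id, sel$recommended$entry_id)
  }
  expect_null(select_recommended(info[0, ])$recommended)
})

test_that("evidence features count and summarise the annotation set", {
  info <- ann_info_fixture()
  rows <- data.frame(
    rsa_all = c(0.2, 0.3, NA), rsa_sidechain = c(0.1, NA, NA),
    mainchain_protein_degree = c(0, 1, 0),
    sidechain_protein_degree = c(0, 0, 0),
    mainchain_ligand_degree = c(0, 0, 0),
    sidechain_ligand_degree = c(0, 0, 2),
    mainchain_dna_degree = 0, sidechain_dna_degree = 0,
    mainchain_rna_degree = 0, sidechain_rna_degree = 0,
    mainchain_metal_degree = 0, sidechain_metal_degree = 0,
    mainchain_ion_degree = 0, sidechain_ion_degree = 0,
    ss_helix = c(1, 1, 0), ss_sheet = c(0, 0, 0),
    ligand_partners = c("-", "-", "ATP,ZN"),
    chain_partners = c("-", "B", "-"))
  cl <- classify_position(make_agg(rsa = 0.4), 3)
  ev <- evidence_features(info, rows, cl)
  expect_equal(length(ev), 23)
  expect_equal(unname(ev["n_structures"]), 3)
  expect_equal(unname(ev["n_distinct_entries"]), 3)
  expect_equal(unname(ev["max_identity"]), 0.9)
  expect_equal(unname(ev["best_resolution"]), 2.0)
  expect_equal(unname(ev["n_protein_annotations"]), 1)
  expect_equal(unname(ev["n_ligand_annotations"]), 1)
  expect_equal(unname(ev["distinct_ligands"]), 2)
  expect_equal(unname(ev["distinct_partner_chains"]), 1)
  expect_equal(unname(ev["helix_majority"]), 1)
  expect_equal(unname(ev["sheet_majority"]), 0)
  expect_equal(unname(ev["defined_sidechain_fraction"]), 1 / 3)
  # zero annotations: counts zero, the rest undefined
  ev0 <- evidence_features(NULL, NULL, classify_position(make_agg(), 0))
  expect_equal(unname(ev0["n_structures"]), 0)
  expect_true(is.na(ev0["max_identity"]))
})

test_that("aggregated features stay within the range of their inputs", {
  set.seed(31)
  reg <- feature_registry()
  rows <- as.data.frame(matrix(runif(3 * 100), 3, 100,
                               dimnames = list(NULL, reg)))
  rows$rsa_all[2] <- NA
  agg <- aggregate_position_features(rows, qualities = c(0.9, 0.5, 0.2),
                                     coverages = c(1, 0.8, 0.6))
  for (f in reg) {
    v <- rows[[f]]
    expect_gte(agg[[f]], min(v, na.rm = TRUE) - 1e-12)
    expect_lte(agg[[f]], max(v, na.rm = TRUE) + 1e-12)
  }
})
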