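test_that("variant grammar parses SAVs, deletions, insertions, delins", {
  v <- parse_variant("D833A")
  expect_equal(v$kind, "sav")
  expect_equal(v$left, 833)
  expect_equal(v$wt_residues, "D")
  expect_equal(v$alt_residues, "A")

  d <- parse_variant("del10-13")
  expect_equal(d$kind, "deletion")
  expect_equal(c(d$left, d$right), c(10, 13))
  expect_equal(parse_variant("del7")$right, 7)

  i <- parse_variant("ins7GS")
  expect_equal(i$kind, "insertion")
  expect_equal(i$left, 7)
  expect_equal(i$alt_residues, "GS")

  di <- parse_variant("delins10-12GSW")
  expect_equal(di$kind, "delins")
  expect_equal(di$alt_residues, "GSW")

  expect_error(parse_variant("garbage!"), "cannot parse.*garbage")
  expect_error(parse_variant("del13-10"), "end before start")
  # wild-type validation against the sequence
  expect_error(parse_variant("D5A", "AAAAAAA"), "wild-type mismatch")
  expect_no_error(parse_variant("A5G", "AAAAAAA"))
  expect_error(parse_variant("A99G", "AAAAAAA"), "out of range")
})

test_that("apply_variant edits sequences with correct bookkeeping", {
  expect_equal(apply_variant("ABCDEFG", parse_variant("del3-4")), "ABEFG")
  expect_equal(apply_variant("ABCDEFG", parse_variant("ins2XY")),
               "ABXYCDEFG")
  expect_equal(apply_variant("ABCDEFG", parse_variant("delins3-4QQ")),
               "ABQQEFG")
  expect_equal(apply_variant("ACDEFGH", parse_variant("C2W")), "AWDEFGH")
  # random battery against an independent string-edit oracle
  set.seed(77)
  for (rep in 1:100) {
    seq <- random_aa_seq(sample(10:40, 1))
    n <- nchar(seq)
    chars <- strsplit(seq, "")[[1]]
    kind <- sample(c("deletion", "insertion", "delins"), 1)
    if (kind == "insertion") {
      pos <- sample(1:(n - 1), 1)
      ins <- random_aa_seq(sample(1:5, 1))
      v <- parse_variant(paste0("ins", pos, ins), seq)
      oracle <- paste(c(chars[1:pos], strsplit(ins, "")[[1]],
                        chars[(pos + 1):n]), collapse = "")
    } else {
      lo <- sample(1:(n - 2), 1)
      hi <- min(n, lo + sample(0:4, 1))
      alt <- if (kind == "delins") random_aa_seq(sample(1:5, 1)) else ""
      v <- parse_variant(paste0(sub("deletion", "del", sub("delins",
                          "delins", kind)), lo, "-", hi, alt), seq)
      keep_l <- if (lo > 1) chars[1:(lo - 1)] else character(0)
      keep_r <- if (hi < n) chars[(hi + 1):n] else character(0)
      oracle <- paste(c(keep_l, strsplit(alt, "")[[1]], keep_r),
                      collapse = "")
    }
    mut <- apply_variant(seq, v)
    expect_equal(mut, oracle)
    expect_equal(nchar(mut),
                 n - nchar(if (is.na(v$wt_residues)) "" else
                           v$wt_residues) + nchar(v$alt_residues))
  }
})

test_that("indel decomposition spans follow the flank arithmetic", {
  wt <- strrep("A", 100)
  # 4-residue deletion: flanks of 2, empty MUT indel region
  v <- parse_variant("del10-13", wt)
  dec <- decompose_indel(wt, apply_variant(wt, v), v)
  expect_equal(dec$flank_length, 2)
  expect_equal(dec$wt$left_flank, 8:9)
  expect_equal(dec$wt$indel_region, 10:13)
  expect_equal(dec$wt$right_flank, 14:15)
  expect_length(dec$mut$indel_region, 0)
  expect_equal(dec$mut$left_flank, 8:9)
  expect_equal(dec$mut$right_flank, 10:11)

  # insertion of 2 after 7: flank 1, empty WT indel region
  vi <- parse_variant("ins7GS", wt)
  di <- decompose_indel(wt, apply_variant(wt, vi), vi)
  expect_equal(di$flank_length, 1)
  expect_length(di$wt$indel_region, 0)
  expect_equal(di$mut$indel_region, 8:9)

  # deletion at position 1: left flank clipped to empty
  vd <- parse_variant("del1-2", wt)
  dd <- decompose_indel(wt, apply_variant(wt, vd), vd)
  expect_length(dd$wt$left_flank, 0)
  expect_equal(dd$wt$indel_region, 1:2)
})

test_that("decomposition spans never overlap and stay in bounds", {
  set.seed(42)
  for (rep in 1:80) {
    wt <- random_aa_seq(sample(8:60, 1))
    n <- nchar(wt)
    kind <- sample(c("del", "ins", "delins"), 1)
    txt <- if (kind == "ins") {
      paste0("ins", sample(1:(n - 1), 1), random_aa_seq(sample(1:6, 1)))
    } else {
      lo <- sample(1:(n - 1), 1); hi <- min(n, lo + sample(0:5, 1))
      paste0(kind, lo, "-", hi,
             if (kind == "delins") random_aa_seq(sample(1:6, 1)) else "")
    }
    v <- parse_variant(txt, wt)
    mut <- apply_variant(wt, v)
    dec <- decompose_indel(wt, mut, v)
    for (side in c("wt", "mut")) {
      spans <- dec[[side]]
      all_pos <- c(spans$left_flank, spans$indel_region, spans$right_flank)
      expect_false(any(duplicated(all_pos)), info = txt)
      lim <- if (side == "wt") nchar(wt) else nchar(mut)
      expect_true(all(all_pos >= 1 & all_pos <= lim), info = txt)
      # ordered left -> indel -> right
      expect_true(all(diff(all_pos) > 0), info = txt)
    }
  }
})

test_that("the 600- and 123-entry vectors hold structurally", {
  expect_length(indel_feature_registry(), 600)
  expect_length(feature_registry(), 100)
  expect_length(evidence_registry(), 23)

  reg <- feature_registry()
  mk_agg <- function(n) {
    df <- as.data.frame(matrix(runif(n * 100), n, 100,
                               dimnames = list(NULL, reg)))
    df$position <- seq_len(n)
    df$mean_quality <- runif(n, 0.2, 1)
    df
  }
  set.seed(9)
  wt_agg <- mk_agg(30); mut_agg <- mk_agg(32)
  v <- parse_variant("ins7GS")
  dec <- decompose_indel(strrep("A", 30), strrep("A", 32), v)
  vec <- aggregate_indel_features(wt_agg, mut_agg, dec)
  expect_length(vec, 600)
  # insertion: WT indel block (entries 101-200) all undefined
  expect_true(all(is.na(vec[101:200])))
  expect_false(all(is.na(vec[1:100])))

  # single-position region equals that position's features (Eq. 1 identity)
  v2 <- parse_variant("del10")
  dec2 <- decompose_indel(strrep("A", 30), strrep("A", 29), v2)
  expect_equal(dec2$flank_length, 1)
  vec2 <- aggregate_indel_features(wt_agg, mk_agg(29), dec2)
  expect_equal(unname(vec2[101:200]),
               unname(as.numeric(wt_agg[10, reg])))

  # SAV vector: 100 + 23 in fixed order
  agg <- stats::setNames(runif(100), reg)
  ev <- stats::setNames(runif(23), evidence_registry())
  sv <- sav_feature_vector(agg, ev)
  expect_length(sv, 123)
  expect_equal(names(sv), c(reg, evidence_registry()))
  expect_equal(unname(sv[1]), unname(agg[1]))   # ordering contract
})
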