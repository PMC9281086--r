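fake_hits <- function(identity_counts, labels = NULL, antigen = "TAA1") {
  n <- length(identity_counts)
  if (is.null(labels)) {
    labels <- vapply(identity_counts, function(k) {
      paste(c(rep("I", k), rep("N", 9 - k)), collapse = "")
    }, character(1))
  }
  tibble::tibble(
    antigen_name = antigen, epitope = "KVAELVHFL",
    hla_allele = "HLA-A*02:01", hit_sequence = "KVAELVHFL",
    protein_id = paste0("P", seq_len(n)), start = 1L,
    phylum = "Firmicutes", identity_count = as.integer(identity_counts),
    labels = labels
  )
}

test_that("identity distribution and the 6-or-7 share match hand counts", {
  hits <- fake_hits(c(6, 7, 7, 9))
  d <- identity_distribution(hits)
  expect_equal(sum(d$pct), 100)
  expect_equal(d$n[d$identity_count == 7], 2)
  s <- identity_summary(hits)
  expect_equal(s$pct_6_or_7, 75)

  all9 <- identity_distribution(fake_hits(rep(9, 5)))
  expect_equal(all9$pct, 100)
  one5 <- identity_summary(fake_hits(5))
  expect_equal(one5$pct_6_or_7, 0)
  expect_equal(glance(identity_summary(hits))$avg_pct_6_or_7, 75)
})

test_that("per-position percentages sum to 100 and recover planted mixes", {
  hits <- fake_hits(c(9, 0), labels = c(strrep("I", 9), strrep("C", 9)))
  ps <- per_position_stats(hits)
  df <- tidy(ps)
  for (j in 1:9) {
    expect_equal(sum(df$pct[df$position == j]), 100)
    expect_equal(df$pct[df$position == j & df$category == "identical"], 50)
    expect_equal(df$pct[df$position == j & df$category == "conservative"], 50)
  }
  g <- glance(ps)
  expect_equal(g$avg_pct_identical, 50)
  expect_equal(g$avg_pct_non_conservative, 0)

  # deterministic planting: exactly 20% non-conservative at position 7
  labs <- c(rep("IIIIIIIII", 8), rep("IIIIIINII", 2))
  ps2 <- per_position_stats(fake_hits(c(rep(9, 8), rep(8, 2)), labels = labs))
  df2 <- tidy(ps2)
  expect_equal(df2$pct[df2$position == 7 & df2$category == "non_conservative"], 20)

  single <- tidy(per_position_stats(fake_hits(9)))
  expect_true(all(single$pct %in% c(0, 100)))
})

test_that("PFM frequencies, information content and consensus behave", {
  p1 <- build_pfm("AAAAAAAAA")
  expect_equal(colSums(p1$freq), rep(1, 9))
  expect_equal(p1$ic, rep(log2(20), 9))
  expect_equal(p1$consensus, "AAAAAAAAA")

  p2 <- build_pfm(c("AAAAAAAAA", "AAAAAAAAC"))
  expect_equal(unname(p2$freq["A", 9]), 0.5)
  expect_equal(unname(p2$freq["C", 9]), 0.5)
  expect_equal(p2$ic[9], log2(20) - 1)
  expect_false(any(p2$ties[1:8]))
  expect_true(p2$ties[9])        # tie at position 9, broken alphabetically
  expect_equal(substr(p2$consensus, 9, 9), "A")

  # duplicating every sequence leaves the PFM unchanged
  set.seed(5)
  seqs <- random_nonamer(12)
  expect_equal(build_pfm(seqs)$freq, build_pfm(c(seqs, seqs))$freq)

  # large uniform random sample: information content near zero
  set.seed(6)
  big <- build_pfm(random_nonamer(4000))
  expect_true(all(big$ic >= 0))
  expect_true(all(big$ic < 0.05))

  expect_error(build_pfm(character()), "zero")
})

test_that("information content stays within [0, log2 20] on random cohorts", {
  set.seed(8)
  for (i in 1:20) {
    p <- build_pfm(random_nonamer(sample(1:50, 1)))
    expect_true(all(p$ic >= -1e-12 & p$ic <= log2(20) + 1e-12))
    expect_equal(colSums(p$freq), rep(1, 9), tolerance = 1e-9)
  }
})

test_that("KL information content is used under a non-uniform background", {
  bg <- aa_background("swissprot")
  p <- build_pfm("AAAAAAAAA", background = bg)
  expect_equal(p$ic, rep(log2(1 / bg[["A"]]), 9))
})

test_that("consensus comparison flags matching and mismatching positions", {
  hits_seqs <- c("KVAELVHFL", "KVAELVHFL", "KIAELVHFL")
  cm <- consensus_match(build_pfm(hits_seqs), "KVAELVHFL")
  expect_true(all(cm$match))
  expect_true(attr(cm, "overall_match"))

  cm2 <- consensus_match(build_pfm(c("KIAELVHFL", "KIAELVHFL")), "KVAELVHFL")
  expect_equal(sum(!cm2$match), 1)
  expect_false(attr(cm2, "overall_match"))
})

test_that("stretch-match probability reproduces the printed endpoints", {
  expect_equal(stretch_match_probability(6), 1.5625e-8)
  expect_equal(stretch_match_probability(9), 1.953125e-12)
  expect_equal(stretch_match_probability(1), 0.05)
  # strictly decreasing and multiplicative
  p <- stretch_match_probability(1:9)
  expect_true(all(diff(p) < 0))
  for (k1 in 1:4) {
    for (k2 in 1:4) {
      expect_equal(stretch_match_probability(k1 + k2),
                   stretch_match_probability(k1) * stretch_match_probability(k2))
    }
  }
  # any-window variant multiplies by the number of windows in a nonamer
  expect_equal(stretch_match_probability(6, any_window = TRUE), 4 * 0.05^6)
  expect_error(stretch_match_probability(0), "1..9")
  expect_error(stretch_match_probability(10), "1..9")
})
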