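test_that("hand-enumerated example: one hit at offset 3 of the 14-mer", {
  eps <- make_epitopes("KVAELVHFL")
  prot <- make_proteins("MAAKIAELVHFLGG")
  hits <- scan_proteome(eps, prot, min_identity = 6)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 4L)           # 1-based; 0-based offset 3
  expect_equal(hits$hit_sequence, "KIAELVHFL")
  expect_equal(hits$identity_count, 8L)
  expect_equal(hits$labels, "ICIIIIIII")
})

test_that("identity self-hit and too-short proteins behave as specified", {
  eps <- make_epitopes("KVAELVHFL")
  self <- scan_proteome(eps, make_proteins("KVAELVHFL"), min_identity = 9)
  expect_equal(nrow(self), 1)
  expect_equal(self$identity_count, 9L)

  expect_message(
    none <- scan_proteome(eps, make_proteins("KVAELVHF"), min_identity = 0),
    "shorter than 9"
  )
  expect_equal(nrow(none), 0)
  expect_error(scan_proteome(eps[0, ], make_proteins("KVAELVHFL")), "at least one")
})

test_that("ambiguity codes are skipped when requested", {
  eps <- make_epitopes("KVAELVHFL")
  prot <- make_proteins("KVAELVHXLKVAELVHFL")
  hits <- scan_proteome(eps, prot, min_identity = 5)
  # windows overlapping the X are dropped; the clean tail window remains
  expect_false(any(grepl("X", hits$hit_sequence)))
  expect_true(any(hits$start == 10 & hits$identity_count == 9))
})

test_that("scanner equals the brute-force oracle on random small instances", {
  set.seed(101)
  for (i in 1:60) {
    n_prot <- sample(1:8, 1)
    lens <- sample(9:60, n_prot, replace = TRUE)
    prot <- make_proteins(vapply(lens, function(n) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], n,
                   replace = TRUE, prob = c(rep(1, 20), 0.5)),
            collapse = "")
    }, character(1)))
    eps <- make_epitopes(random_nonamer(sample(1:2, 1)))
    m <- sample(2:6, 1)
    got <- scan_proteome(eps, prot, min_identity = m)
    want <- brute_force_scan(eps, prot, m)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(
        got[, c("antigen_name", "hit_sequence", "protein_id", "start",
                "identity_count")],
        want,
        ignore_attr = TRUE
      )
    }
  }
})

test_that("raising min_identity never adds hits (monotone filtering)", {
  set.seed(7)
  prot <- make_proteins(replicate(5, paste(sample(strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]], 80, replace = TRUE), collapse = "")))
  eps <- make_epitopes(random_nonamer(1))
  prev <- scan_proteome(eps, prot, min_identity = 0)
  for (m in 1:9) {
    cur <- scan_proteome(eps, prot, min_identity = m)
    key <- function(h) paste(h$protein_id, h$start)
    expect_true(all(key(cur) %in% key(prev)))
    prev <- cur
  }
})

test_that("hit counting splits totals by the 10 nM high-affinity threshold", {
  eps <- make_epitopes("KVAELVHFL")
  prot <- make_proteins(c("KVAELVHFLAAKVAELVHML", "KVAELVHFI"))
  hits <- scan_proteome(eps, prot, min_identity = 8)
  expect_equal(nrow(hits), 3)
  preds <- tibble::tibble(
    peptide = unique(hits$hit_sequence),
    hla_allele = "HLA-A*02:01",
    affinity_nm = c(5, 8, 12)[seq_along(peptide)],
    stability_h = NA_real_,
    binder_class = classify_binder(c(5, 8, 12)[seq_along(peptide)])
  )
  # force a deterministic mapping peptide -> affinity
  preds$affinity_nm <- c(5, 8, 12)[match(preds$peptide, unique(hits$hit_sequence))]
  counts <- count_hits(hits, preds)
  expect_equal(sum(counts$n_total), 3)
  expect_equal(sum(counts$n_high_affinity), 2)
  expect_true(all(counts$n_high_affinity <= counts$n_total))

  expect_equal(nrow(count_hits(hits[0, ])), 0)
  expect_error(count_hits(hits, preds[1, ]), "No binding prediction")
})

test_that("unique-peptide view collapses repeated windows", {
  eps <- make_epitopes("KVAELVHFL")
  prot <- make_proteins("KVAELVHFLAAKVAELVHFL")
  hits <- scan_proteome(eps, prot, min_identity = 9)
  expect_equal(nrow(hits), 2)
  uq <- unique_peptides(hits)
  expect_equal(nrow(uq), 1)
  expect_equal(uq$n_occurrences, 2L)
})

test_that("max_hits_per_epitope caps after ordering by identity", {
  eps <- make_epitopes("KVAELVHFL")
  prot <- make_proteins("KVAELVHFLAAKIAELVHFL")
  hits <- scan_proteome(eps, prot, min_identity = 5, max_hits_per_epitope = 1)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity_count, 9L)  # the best window is kept
})
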