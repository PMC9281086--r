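test_that("proteome generation is a pure function of its arguments and seed", {
  a <- generate_proteome(5, c(30, 60), seed = 42)
  b <- generate_proteome(5, c(30, 60), seed = 42)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$protein_id, b$protein_id)
  c <- generate_proteome(5, c(30, 60), seed = 43)
  expect_false(identical(a$sequence, c$sequence))
  expect_error(generate_proteome(0, c(30, 60)), ">= 1")
  expect_error(generate_proteome(2, c(5, 8)), ">= 9")

  # FASTA writing round-trips byte-identically for a fixed seed
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_proteins_fasta(generate_proteome(5, c(30, 60), seed = 42), f1)
  write_proteins_fasta(generate_proteome(5, c(30, 60), seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated residue frequencies follow the background", {
  prot <- generate_proteome(500, c(200, 200), seed = 9)
  chars <- unlist(strsplit(prot$sequence, ""))
  n <- length(chars)
  expect_gte(n, 1e5)
  counts <- table(factor(chars, levels = c("A","C","D","E","F","G","H","I","K","L",
                                           "M","N","P","Q","R","S","T","V","W","Y")))
  p0 <- 1 / 20
  se <- sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(counts / n - p0) < 4 * se))
})

test_that("planting writes exactly the requested substitutions", {
  prot <- generate_proteome(10, c(50, 80), seed = 1)

  p0 <- plant_homolog(prot, "KVAELVHFL", 0, seed = 2)
  led0 <- plant_ledger(p0)
  expect_equal(led0$planted_sequence, "KVAELVHFL")
  window <- substr(p0$sequence[p0$protein_id == led0$protein_id],
                   led0$start, led0$start + 8)
  expect_equal(window, "KVAELVHFL")

  p1 <- plant_homolog(prot, "KVAELVHFL", 1, class_policy = "conservative_only",
                      seed = 3)
  led1 <- plant_ledger(p1)
  cls <- classify_pair("KVAELVHFL", led1$planted_sequence)
  expect_equal(cls$identity_count, 8)
  expect_equal(sum(cls$position_labels == "conservative"), 1)
  expect_equal(cls$mismatch_positions, led1$substitution_positions[[1]])

  pn <- plant_homolog(prot, "KVAELVHFL", 2, class_policy = "non_conservative_only",
                      seed = 4)
  cln <- classify_pair("KVAELVHFL", plant_ledger(pn)$planted_sequence)
  expect_equal(sum(cln$position_labels == "non_conservative"), 2)

  # reproducible for a fixed seed
  pa <- plant_homolog(prot, "KVAELVHFL", 3, class_policy = "mixed", seed = 5)
  pb <- plant_homolog(prot, "KVAELVHFL", 3, class_policy = "mixed", seed = 5)
  expect_identical(plant_ledger(pa), plant_ledger(pb))
  expect_identical(pa$sequence, pb$sequence)
})

test_that("planted windows never overlap and explicit overlaps error", {
  prot <- generate_proteome(1, c(60, 60), seed = 11)
  p <- prot
  for (s in 1:4) p <- plant_homolog(p, "KVAELVHFL", 1, seed = 100 + s)
  led <- plant_ledger(p)
  starts <- sort(led$start)
  expect_true(all(diff(starts) >= 9))
  expect_error(
    plant_homolog(p, "KVAELVHFL", 0, protein_id = led$protein_id[1],
                  start = led$start[1] + 1, seed = 6),
    "overlap"
  )
})

test_that("scanner recovers planted homologs at the ledger location", {
  eps <- make_epitopes("KVAELVHFL")
  for (k in 0:4) {
    prot <- generate_proteome(8, c(60, 100), phylum = "Bacteroidetes",
                              seed = 20 + k)
    prot <- plant_homolog(prot, "KVAELVHFL", k, class_policy = "mixed",
                          seed = 30 + k)
    led <- plant_ledger(prot)
    hits <- scan_proteome(eps, prot, min_identity = 9 - k)
    planted_found <- any(hits$protein_id == led$protein_id &
                           hits$start == led$start)
    expect_true(planted_found)
    # the planted window carries exactly 9 - k identities
    row <- hits[hits$protein_id == led$protein_id & hits$start == led$start, ]
    expect_equal(row$identity_count, 9L - k)
    # any extra hits are verifiable chance windows per the brute-force oracle
    want <- brute_force_scan(eps, prot, 9 - k)
    expect_equal(nrow(hits), nrow(want))
  }
})

test_that("ideal peptides reproduce requested torsions to 1e-3 degrees", {
  cases <- list(extended = extended_torsions(), helix = helical_torsions(),
                groove = hla_groove_torsions())
  for (nm in names(cases)) {
    tor <- cases[[nm]]
    s <- generate_ideal_peptide("KVAELVHFL", tor)
    for (i in 2:9) {
      phi <- measure_angle(s, angle_descriptor("dihedral",
                                               c(i - 1, i, i, i),
                                               c("C", "N", "CA", "C")))
      expect_equal(circ_diff_deg(phi, tor[i, 1]), 0, tolerance = 1e-3)
    }
    for (i in 1:8) {
      psi <- measure_angle(s, angle_descriptor("dihedral",
                                               c(i, i, i, i + 1),
                                               c("N", "CA", "C", "N")))
      expect_equal(circ_diff_deg(psi, tor[i, 2]), 0, tolerance = 1e-3)
    }
  }
  # identical arguments give identical coordinates
  s1 <- generate_ideal_peptide("GLYDGMEHL", helical_torsions())
  s2 <- generate_ideal_peptide("GLYDGMEHL", helical_torsions())
  expect_identical(s1$atoms, s2$atoms)
  # glycine gets no CB stub
  expect_false(any(s1$atoms$atom == "CB" & s1$atoms$resno == 1))
  expect_error(generate_ideal_peptide("KVAELVHFL", matrix(NA, 9, 2)), "finite")
})
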