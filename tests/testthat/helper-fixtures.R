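# Shared fixture builders. Everything is generated in code under a fixed
# seed; no binary fixtures.

random_nonamer <- function(n = 1) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y"),
                 9, replace = TRUE), collapse = "")
  }, character(1))
}

make_epitopes <- function(seqs, allele = "HLA-A*02:01") {
  tibble::tibble(
    antigen_name = paste0("TAA", seq_along(seqs)),
    sequence = seqs,
    hla_allele = allele
  )
}

make_proteins <- function(seqs, phylum = "Firmicutes") {
  tibble::tibble(
    protein_id = paste0("P", seq_along(seqs)),
    description = "",
    phylum = phylum,
    sequence = seqs
  )
}

# Independent brute-force oracle for the scanner: plain nested loops over
# every window, identity counted by direct character comparison.
brute_force_scan <- function(epitopes, proteins, min_identity,
                             skip_ambiguous = TRUE) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- list()
  for (e in seq_len(nrow(epitopes))) {
    eseq <- strsplit(epitopes$sequence[e], "")[[1]]
    for (p in seq_len(nrow(proteins))) {
      pseq <- proteins$sequence[p]
      if (nchar(pseq) < 9) next
      for (st in 1:(nchar(pseq) - 8)) {
        win <- strsplit(substr(pseq, st, st + 8), "")[[1]]
        if (skip_ambiguous && !all(win %in% std)) next
        ident <- sum(win == eseq)
        if (ident >= min_identity) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            antigen_name = epitopes$antigen_name[e],
            hit_sequence = paste(win, collapse = ""),
            protein_id = proteins$protein_id[p],
            start = st,
            identity_count = ident
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  dplyr::arrange(out, antigen_name, dplyr::desc(identity_count),
                 protein_id, start)
}

# Random proper rigid-body transform (rotation with det +1, translation).
random_rigid_transform <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 10)
  function(p) as.vector(q %*% p + shift)
}

# Minimal hand-built complex: a 9-residue CA-trace peptide along x, one HLA
# atom near residue 3, one TCR-alpha atom near residue 5, one TCR-beta atom
# near residue 8; every planted distance is known by construction.
make_contact_fixture <- function(hla_d = 3.5, tcra_d = 3.0, tcrb_d = 3.8,
                                 with_tcr = TRUE) {
  pep <- tibble::tibble(
    chain = "C", role = "peptide", resno = 1:9, resid = "ALA",
    atom = "CA", element = "C",
    x = 3.8 * (0:8), y = 0, z = 0
  )
  others <- tibble::tibble(
    chain = c("A", "D", "E"),
    role = c("hla", "tcr_alpha", "tcr_beta"),
    resno = 1L, resid = "GLY", atom = "CA", element = "C",
    x = 3.8 * c(2, 4, 7), y = c(-hla_d, tcra_d, tcrb_d), z = 0
  )
  if (!with_tcr) others <- others[others$role == "hla", ]
  roles <- c(C = "peptide", A = "hla", D = "tcr_alpha", E = "tcr_beta")
  if (!with_tcr) roles <- roles[c("C", "A")]
  peptide_structure("fixture", dplyr::bind_rows(pep, others), roles)
}

extended_torsions <- function() {
  matrix(rep(c(180, 180), 9), ncol = 2, byrow = TRUE)
}

helical_torsions <- function() {
  matrix(rep(c(-57, -47), 9), ncol = 2, byrow = TRUE)
}

circ_diff_deg <- function(a, b) abs(((a - b + 180) %% 360) - 180)
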