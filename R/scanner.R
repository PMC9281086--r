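#' Exhaustive ungapped nonamer scan of a protein collection
#'
#' Slides every epitope across every protein one residue at a time and keeps
#' each 9-residue window whose identity with the epitope reaches
#' `min_identity`. Every alignment is gapless, so results are exactly
#' reproducible and independent of any external search heuristic. Windows
#' containing ambiguity codes (X/B/Z/U/O) are skipped by default; proteins
#' shorter than 9 residues yield no windows.
#'
#' @param epitopes Epitope tibble (see [read_epitopes()]); must be non-empty.
#' @param proteins Protein tibble (see [read_proteins()]); must be non-empty.
#' @param scheme A [substitution_scheme()] used to label substitutions.
#' @param min_identity Minimum identical positions (0-9) for a window to be
#'   reported. The default 5 admits homologs down to 5/9 (about 51%)
#'   identity.
#' @param skip_ambiguous Skip windows containing non-standard residues
#'   (default `TRUE`).
#' @param max_hits_per_epitope Optional cap on reported hits per epitope,
#'   applied after the deterministic ordering.
#' @return A tibble of mimicry hits with columns `antigen_name`, `epitope`,
#'   `hla_allele`, `hit_sequence`, `protein_id`, `start` (1-based window
#'   start within the protein), `phylum`, `identity_count` and `labels`
#'   (9-character string, I = identical, C = conservative,
#'   N = non-conservative). Rows are ordered by antigen name, then
#'   decreasing identity, then protein id and start.
#' @examples
#' eps <- tibble::tibble(antigen_name = "MAGE-A3", sequence = "KVAELVHFL",
#'                       hla_allele = "HLA-A*02:01")
#' prot <- tibble::tibble(protein_id = "P1", description = "",
#'                        phylum = "Firmicutes", sequence = "MAAKIAELVHFLGG")
#' scan_proteome(eps, prot, min_identity = 6)
#' @export
scan_proteome <- function(epitopes, proteins, scheme = substitution_scheme(),
                          min_identity = 5, skip_ambiguous = TRUE,
                          max_hits_per_epitope = NULL) {
  epitopes <- validate_epitopes(epitopes)
  if (nrow(epitopes) == 0) abort("`epitopes` must contain at least one epitope.")
  proteins <- validate_proteins(proteins)
  if (nrow(proteins) == 0) abort("`proteins` must contain at least one protein.")
  if (min_identity < 0 || min_identity > 9) abort("`min_identity` must be in 0..9.")

  short <- proteins$sequence[nchar(proteins$sequence) < 9]
  if (length(short) > 0) {
    inform(sprintf("%d protein(s) shorter than 9 residues yield no windows.",
                   length(short)))
  }

  hits <- vector("list", nrow(epitopes))
  for (e in seq_len(nrow(epitopes))) {
    per_prot <- vector("list", nrow(proteins))
    eseq <- strsplit(epitopes$sequence[e], "")[[1]]
    for (p in seq_len(nrow(proteins))) {
      w <- scan_windows(eseq, proteins$sequence[p], scheme,
                        min_identity, skip_ambiguous)
      if (!is.null(w)) w$.prot_row <- p
      per_prot[[p]] <- w
    }
    found <- bind_rows(per_prot[lengths(per_prot) > 0])
    if (nrow(found) == 0) next
    found$protein_id <- proteins$protein_id[found$.prot_row]
    found$phylum <- proteins$phylum[found$.prot_row]
    found <- found |>
      mutate(
        antigen_name = epitopes$antigen_name[e],
        epitope = epitopes$sequence[e],
        hla_allele = epitopes$hla_allele[e]
      ) |>
      select("antigen_name", "epitope", "hla_allele", "hit_sequence",
             "protein_id", "start", "phylum", "identity_count", "labels") |>
      arrange(desc(.data$identity_count), .data$protein_id, .data$start)
    if (!is.null(max_hits_per_epitope)) {
      found <- head(found, max_hits_per_epitope)
    }
    hits[[e]] <- found
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble(
      antigen_name = character(), epitope = character(),
      hla_allele = character(), hit_sequence = character(),
      protein_id = character(), start = integer(), phylum = character(),
      identity_count = integer(), labels = character()
    ))
  }
  arrange(out, .data$antigen_name, desc(.data$identity_count),
          .data$protein_id, .data$start)
}

# All qualifying windows of one protein against one epitope (split to chars).
# Returns a tibble with .prot_row filled in by the caller.
scan_windows <- function(eseq, prot_seq, scheme, min_identity, skip_ambiguous) {
  len <- nchar(prot_seq)
  if (len < 9) return(NULL)
  chars <- strsplit(prot_seq, "")[[1]]
  n_win <- len - 8L
  # identity matrix: 9 x n_win, position j of window w is chars[w + j - 1]
  ident <- matrix(FALSE, nrow = 9, ncol = n_win)
  std <- matrix(TRUE, nrow = 9, ncol = n_win)
  is_std <- chars %in% AA_STANDARD
  for (j in 1:9) {
    idx <- j:(j + n_win - 1L)
    ident[j, ] <- chars[idx] == eseq[j]
    std[j, ] <- is_std[idx]
  }
  counts <- colSums(ident)
  ok <- counts >= min_identity
  if (skip_ambiguous) ok <- ok & (colSums(std) == 9L)
  starts <- which(ok)
  if (length(starts) == 0) return(NULL)
  seqs <- substring(prot_seq, starts, starts + 8L)
  if (!skip_ambiguous) {
    # labels need standard residues; non-standard windows cannot be classified
    keep <- map_lgl(seqs, ~ all(strsplit(.x, "")[[1]] %in% AA_STANDARD))
    if (!all(keep)) {
      warn("Windows with non-standard residues cannot be classified; skipped.")
      starts <- starts[keep]
      seqs <- seqs[keep]
      if (length(starts) == 0) return(NULL)
    }
  }
  lab <- map_chr(seqs, function(s) {
    labels_to_string(classify_substitution(eseq, strsplit(s, "")[[1]], scheme))
  })
  tibble(
    .prot_row = NA_integer_,
    hit_sequence = seqs,
    start = as.integer(starts),
    identity_count = as.integer(counts[starts]),
    labels = lab
  )
}

#' Count hits per antigen and phylum, optionally split by high affinity
#'
#' Tallies mimicry hits into a per-(antigen, phylum) table of total hits and,
#' when binding predictions are supplied, of high-affinity hits (predicted
#' affinity below `high_nm`, 10 nM by default).
#'
#' @param hits Hit tibble from [scan_proteome()].
#' @param predictions Optional prediction tibble (see [import_predictions()]
#'   or [pwm_predict()]); when given, every (hit peptide, allele) pair must
#'   be covered.
#' @param high_nm High-affinity threshold in nM (default 10).
#' @return A tibble with columns `antigen_name`, `phylum`, `n_total` and
#'   `n_high_affinity` (NA when no predictions are supplied).
#' @export
count_hits <- function(hits, predictions = NULL, high_nm = 10) {
  if (nrow(hits) == 0) {
    return(tibble(antigen_name = character(), phylum = character(),
                  n_total = integer(), n_high_affinity = integer()))
  }
  if (is.null(predictions)) {
    return(hits |>
      count(.data$antigen_name, .data$phylum, name = "n_total") |>
      mutate(n_high_affinity = NA_integer_))
  }
  joined <- join_predictions(hits, predictions)
  joined |>
    group_by(.data$antigen_name, .data$phylum) |>
    summarise(
      n_total = n(),
      n_high_affinity = sum(.data$affinity_nm < high_nm),
      .groups = "drop"
    )
}

# Left-join hit peptides to predictions on (peptide, allele); error listing
# uncovered peptides.
join_predictions <- function(hits, predictions) {
  joined <- left_join(
    hits,
    select(predictions, "peptide", "hla_allele", "affinity_nm", "stability_h",
           "binder_class"),
    by = c(hit_sequence = "peptide", "hla_allele")
  )
  uncovered <- joined |> filter(is.na(.data$affinity_nm))
  if (nrow(uncovered) > 0) {
    miss <- unique(paste0(uncovered$hit_sequence, "/", uncovered$hla_allele))
    abort(paste0("No binding prediction for peptide-allele pair(s): ",
                 paste(head(miss, 10), collapse = ", "),
                 if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10) else ""))
  }
  joined
}

#' Unique-peptide view of a hit table
#'
#' The scanner reports every window, so the same bacterial peptide can occur
#' at several (protein, start) locations. This view collapses a hit table to
#' distinct (antigen, peptide, phylum) combinations, keeping the first
#' occurrence in scan order.
#'
#' @param hits Hit tibble from [scan_proteome()].
#' @return A tibble with one row per distinct (antigen_name, hit_sequence,
#'   phylum), plus `n_occurrences`.
#' @export
unique_peptides <- function(hits) {
  if (nrow(hits) == 0) return(mutate(hits, n_occurrences = integer()))
  hits |>
    group_by(.data$antigen_name, .data$hit_sequence, .data$phylum) |>
    mutate(n_occurrences = n()) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$antigen_name, desc(.data$identity_count),
            .data$protein_id, .data$start)
}
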