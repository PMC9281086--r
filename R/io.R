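#' Read a tumor-epitope table
#'
#' Reads a tab-separated table of TAA nonamer epitopes with columns
#' `antigen_name`, `sequence`, `hla_allele` and optionally `source_note`.
#' Sequences are upper-cased and validated as standard nonamers.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per epitope.
#' @examples
#' path <- system.file("extdata", "epitopes_printed.tsv", package = "mimicryscan")
#' read_epitopes(path)
#' @export
read_epitopes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  validate_epitopes(df)
}

#' Validate (and normalise) an epitope table
#'
#' Checks the invariants of an epitope table: required columns present,
#' every sequence a 9-letter standard-residue peptide, antigen names
#' non-empty. Lower-case input sequences are accepted and upper-cased.
#'
#' @param epitopes A data frame with columns `antigen_name`, `sequence`,
#'   `hla_allele` (and optionally `source_note`).
#' @return The validated tibble (sequences upper-cased).
#' @export
validate_epitopes <- function(epitopes) {
  required <- c("antigen_name", "sequence", "hla_allele")
  missing <- setdiff(required, names(epitopes))
  if (length(missing) > 0) {
    abort(paste0("Epitope table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  epitopes <- as_tibble(epitopes) |>
    mutate(sequence = str_to_upper(.data$sequence))
  if (any(is.na(epitopes$antigen_name)) || any(epitopes$antigen_name == "")) {
    abort("Every epitope needs a non-empty `antigen_name`.")
  }
  if (any(nchar(epitopes$sequence) != 9)) {
    bad <- epitopes$sequence[nchar(epitopes$sequence) != 9]
    abort(paste0("Epitope sequences must be nonamers; offending: ",
                 paste(bad, collapse = ", ")))
  }
  check_standard_residues(
    unlist(strsplit(epitopes$sequence, "")), "epitope residue"
  )
  epitopes
}

#' Read bacterial protein sequences from FASTA
#'
#' Standard multi-FASTA reader (via Biostrings). The description line is
#' split into an accession-like `protein_id` (first whitespace-delimited
#' token) and the remaining free-text `description`. A phylum label is
#' attached to every record; sequences are upper-cased.
#'
#' @param path Path to a (multi-)FASTA file of protein sequences.
#' @param phylum Phylum label for every record in this file, e.g.
#'   `"Firmicutes"`, `"Bacteroidetes"` or `"other"`.
#' @return A tibble with columns `protein_id`, `description`, `phylum`,
#'   `sequence`.
#' @export
read_proteins <- function(path, phylum = "other") {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(paste0("No sequences found in ", path))
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  out <- tibble(
    protein_id = ids,
    description = desc,
    phylum = phylum,
    sequence = str_to_upper(as.character(aa))
  )
  validate_proteins(out)
}

#' Validate a protein table
#'
#' @param proteins A data frame with columns `protein_id`, `phylum`,
#'   `sequence` (and optionally `description`).
#' @return The validated tibble.
#' @export
validate_proteins <- function(proteins) {
  required <- c("protein_id", "phylum", "sequence")
  missing <- setdiff(required, names(proteins))
  if (length(missing) > 0) {
    abort(paste0("Protein table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  proteins <- as_tibble(proteins)
  if (!"description" %in% names(proteins)) proteins$description <- ""
  if (anyDuplicated(proteins$protein_id)) {
    dup <- unique(proteins$protein_id[duplicated(proteins$protein_id)])
    abort(paste0("Duplicated protein_id within the collection: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  if (any(is.na(proteins$sequence)) || any(proteins$sequence == "")) {
    abort("Protein sequences must be non-empty.")
  }
  proteins |>
    mutate(sequence = str_to_upper(.data$sequence)) |>
    select("protein_id", "description", "phylum", "sequence")
}

#' Write a protein table to FASTA
#'
#' @param proteins A protein tibble (see [read_proteins()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteins_fasta <- function(proteins, path) {
  proteins <- validate_proteins(proteins)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(
    proteins$description == "",
    proteins$protein_id,
    paste(proteins$protein_id, proteins$description)
  )
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Import binding predictions from a tab-separated table
#'
#' Reads affinity (and optional stability) predictions for peptide-allele
#' pairs, e.g. exported from NetMHCpan/NetMHCstabpan runs, and assigns each
#' row a binder class via [classify_binder()]. The reader matches columns by
#' name, so whitespace-aligned exports re-saved as TSV are tolerated; the
#' allele column may be named `allele` or `hla_allele`.
#'
#' @param path Path to a TSV file with header columns `peptide`, `allele`
#'   (or `hla_allele`), `affinity_nm`, optional `stability_h`.
#' @return A tibble with columns `peptide`, `hla_allele`, `affinity_nm`,
#'   `stability_h` (NA when absent) and `binder_class`.
#' @export
import_predictions <- function(path) {
  raw <- readr::read_delim(path, show_col_types = FALSE, comment = "#",
                           trim_ws = TRUE)
  nms <- tolower(names(raw))
  names(raw) <- nms
  if ("hla_allele" %in% nms && !"allele" %in% nms) {
    raw <- rename(raw, allele = "hla_allele")
  }
  required <- c("peptide", "allele", "affinity_nm")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Prediction table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"stability_h" %in% names(raw)) raw$stability_h <- NA_real_
  raw <- as_tibble(raw) |>
    mutate(peptide = str_to_upper(.data$peptide))

  bad_len <- which(nchar(raw$peptide) != 9)
  if (length(bad_len) > 0) {
    abort(sprintf("Malformed peptide (not a nonamer) at data row(s): %s",
                  paste(head(bad_len, 5), collapse = ", ")))
  }
  bad_aff <- which(!is.finite(raw$affinity_nm) | raw$affinity_nm <= 0)
  if (length(bad_aff) > 0) {
    abort(sprintf("Non-positive or missing affinity_nm at data row(s): %s",
                  paste(head(bad_aff, 5), collapse = ", ")))
  }
  check_standard_residues(unlist(strsplit(raw$peptide, "")), "peptide residue")

  raw |>
    mutate(binder_class = classify_binder(.data$affinity_nm, .data$stability_h)) |>
    select("peptide", hla_allele = "allele", "affinity_nm", "stability_h",
           "binder_class")
}
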