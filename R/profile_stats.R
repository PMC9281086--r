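check_background <- function(background) {
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-9 ||
      any(background < 0)) {
    abort("`background` must be 20 non-negative frequencies summing to 1.")
  }
  if (!is.null(names(background))) {
    if (!setequal(names(background), AA_STANDARD)) {
      abort("`background` names must be the 20 standard residues.")
    }
    background <- background[AA_STANDARD]
  } else {
    names(background) <- AA_STANDARD
  }
  background
}

#' Amino-acid background frequencies
#'
#' `"uniform"` gives 1/20 per residue (the assumption behind the
#' stretch-match probability model); `"swissprot"` gives a fixed
#' Swiss-Prot-like natural protein composition for use as a non-uniform
#' scanning or logo background.
#'
#' @param which `"uniform"` or `"swissprot"`.
#' @return Named numeric vector of 20 frequencies summing to 1.
#' @export
aa_background <- function(which = c("uniform", "swissprot")) {
  which <- match.arg(which)
  if (which == "uniform") {
    return(setNames(rep(1 / 20, 20), AA_STANDARD))
  }
  # UniProtKB/Swiss-Prot release-statistics style composition (percent).
  f <- c(
    A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07, H = 2.27,
    I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06, P = 4.74, Q = 3.93,
    R = 5.53, S = 6.64, T = 5.35, V = 6.86, W = 1.10, Y = 2.92
  )
  f / sum(f)
}

#' Identity-count distribution of mimicry hits
#'
#' For each antigen, the number and percentage of hits at every identity
#' count 0-9 (only observed counts are listed; percentages per antigen sum
#' to 100).
#'
#' @param hits Hit tibble from [scan_proteome()].
#' @return A tibble with columns `antigen_name`, `identity_count`, `n`,
#'   `pct`.
#' @seealso [identity_summary()] for the per-antigen share of hits with 6 or
#'   7 identical residues.
#' @export
identity_distribution <- function(hits) {
  if (nrow(hits) == 0) {
    inform("Empty hit table; nothing to distribute.")
    return(tibble(antigen_name = character(), identity_count = integer(),
                  n = integer(), pct = numeric()))
  }
  hits |>
    count(.data$antigen_name, .data$identity_count) |>
    group_by(.data$antigen_name) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$antigen_name, .data$identity_count)
}

#' Per-antigen share of 6-or-7-identical hits
#'
#' Summarises, for each antigen, the percentage of its hits carrying exactly
#' 6 or 7 identical residues (of 9) and the mean identity count; the
#' cross-antigen average of the 6-or-7 share is returned as attribute
#' `"avg_pct_6_or_7"` and by [glance()] on the result.
#'
#' @param hits Hit tibble from [scan_proteome()].
#' @return A tibble with columns `antigen_name`, `n_hits`, `pct_6_or_7`,
#'   `mean_identity`, of class `identity_summary`.
#' @export
identity_summary <- function(hits) {
  if (nrow(hits) == 0) {
    inform("Empty hit table; nothing to summarise.")
    out <- tibble(antigen_name = character(), n_hits = integer(),
                  pct_6_or_7 = numeric(), mean_identity = numeric())
    attr(out, "avg_pct_6_or_7") <- NA_real_
    return(out)
  }
  out <- hits |>
    group_by(.data$antigen_name) |>
    summarise(
      n_hits = n(),
      pct_6_or_7 = 100 * mean(.data$identity_count %in% c(6L, 7L)),
      mean_identity = mean(.data$identity_count),
      .groups = "drop"
    )
  attr(out, "avg_pct_6_or_7") <- mean(out$pct_6_or_7)
  class(out) <- c("identity_summary", class(out))
  out
}

#' @exportS3Method generics::glance
glance.identity_summary <- function(x, ...) {
  tibble(
    n_antigens = nrow(x),
    avg_pct_6_or_7 = attr(x, "avg_pct_6_or_7"),
    avg_mean_identity = mean(x$mean_identity)
  )
}

#' Per-position substitution statistics
#'
#' Tallies, at each of the 9 peptide positions, how many hits carry an
#' identical, conservative or non-conservative residue relative to their
#' paired TAA, as counts and as percentages of the number of hits. The
#' three percentages sum to 100 at every position.
#'
#' @param hits Hit tibble from [scan_proteome()] (the `labels` column is
#'   used; the scheme that produced it decides conservativeness).
#' @return An object of class `position_stats`: a long tibble with columns
#'   `position` (1-9), `category`, `n`, `pct`. [tidy()] returns it as a
#'   plain tibble; [glance()] returns the per-category averages across
#'   positions and the number of hits.
#' @export
per_position_stats <- function(hits) {
  if (nrow(hits) == 0) abort("Cannot compute position statistics on an empty hit table.")
  lab_mat <- do.call(rbind, strsplit(hits$labels, ""))  # n x 9 of I/C/N
  key <- c(I = "identical", C = "conservative", N = "non_conservative")
  long <- purrr::map_dfr(1:9, function(j) {
    tab <- table(factor(key[lab_mat[, j]], levels = SUBSTITUTION_LABELS))
    tibble(position = j, category = SUBSTITUTION_LABELS,
           n = as.integer(tab), pct = 100 * as.integer(tab) / nrow(hits))
  })
  structure(long, class = c("position_stats", class(long)),
            n_hits = nrow(hits))
}

#' @exportS3Method generics::tidy
tidy.position_stats <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' @exportS3Method generics::glance
glance.position_stats <- function(x, ...) {
  avg <- x |>
    group_by(.data$category) |>
    summarise(avg_pct = mean(.data$pct), .groups = "drop")
  tibble(
    n_hits = attr(x, "n_hits"),
    avg_pct_identical = avg$avg_pct[avg$category == "identical"],
    avg_pct_conservative = avg$avg_pct[avg$category == "conservative"],
    avg_pct_non_conservative = avg$avg_pct[avg$category == "non_conservative"]
  )
}

unclass_keep <- function(x) {
  class(x) <- setdiff(class(x), c("position_stats", "identity_summary"))
  x
}

#' Build a position frequency matrix from hit nonamers
#'
#' Column-normalised residue frequencies at each of the 9 positions, the
#' per-position information content in bits, and the consensus sequence.
#' With the default uniform background the information content is the
#' Shannon form `log2(20) - H(position)`; with a non-uniform background it
#' is the Kullback-Leibler divergence from that background. Consensus ties
#' are broken alphabetically and flagged.
#'
#' @param sequences Character vector of standard nonamers (e.g. the
#'   `hit_sequence` column of one antigen's hits); must be non-empty.
#' @param background Length-20 background frequencies summing to 1 (default
#'   uniform; see [aa_background()]).
#' @return An object of class `pfm`: list with `freq` (20 x 9 matrix, each
#'   column sums to 1), `ic` (length-9 bits), `consensus` (9-character
#'   string), `ties` (logical 9), `n_sequences`, `background`.
#' @examples
#' pfm <- build_pfm(c("KVAELVHFL", "KIAELVHFL", "KIAELVHFL"))
#' pfm$consensus
#' @export
build_pfm <- function(sequences, background = aa_background("uniform")) {
  if (length(sequences) == 0) abort("Cannot build a PFM from zero sequences.")
  background <- check_background(background)
  sequences <- str_to_upper(sequences)
  if (any(nchar(sequences) != 9)) abort("All sequences must be nonamers.")
  mat <- do.call(rbind, strsplit(sequences, ""))
  check_standard_residues(as.vector(mat), "residue")
  counts <- vapply(1:9, function(j) {
    as.integer(table(factor(mat[, j], levels = AA_STANDARD)))
  }, integer(20))
  rownames(counts) <- AA_STANDARD
  freq <- counts / length(sequences)          # 20 x 9, columns sum to 1
  uniform <- max(abs(background - 1 / 20)) < 1e-12
  ic <- vapply(1:9, function(j) {
    f <- freq[, j]
    nz <- f > 0
    if (uniform) {
      log2(20) + sum(f[nz] * log2(f[nz]))
    } else {
      sum(f[nz] * log2(f[nz] / background[nz]))
    }
  }, numeric(1))
  top <- apply(freq, 2, max)
  consensus <- vapply(1:9, function(j) AA_STANDARD[which.max(freq[, j])],
                      character(1))
  ties <- vapply(1:9, function(j) sum(freq[, j] == top[j]) > 1, logical(1))
  structure(
    list(freq = freq, ic = ic, consensus = paste(consensus, collapse = ""),
         ties = ties, n_sequences = length(sequences),
         background = background),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat("<pfm> built from", x$n_sequences, "nonamer(s)\n")
  cat("  consensus:", x$consensus,
      if (any(x$ties)) paste0("(ties at ", paste(which(x$ties), collapse = ","), ")") else "",
      "\n")
  cat("  information content (bits):",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pfm <- function(x, ...) {
  tibble(
    position = rep(1:9, each = 20),
    residue = rep(AA_STANDARD, times = 9),
    freq = as.vector(x$freq),
    ic = rep(x$ic, each = 20)
  )
}

#' @exportS3Method generics::glance
glance.pfm <- function(x, ...) {
  tibble(
    n_sequences = x$n_sequences,
    mean_ic = mean(x$ic),
    consensus = x$consensus,
    any_ties = any(x$ties)
  )
}

#' Does the hit consensus match the paired TAA?
#'
#' Compares the consensus residue of a PFM (built from one antigen's hit
#' peptides) to the TAA epitope, position by position.
#'
#' @param pfm A [build_pfm()] object built from that epitope's hits.
#' @param epitope The TAA nonamer.
#' @return A tibble with columns `position`, `consensus`, `epitope_residue`,
#'   `match` (and `tie`, whether the consensus at that position was tied).
#'   The overall flag (`all(match)`) is attached as attribute
#'   `"overall_match"`.
#' @export
consensus_match <- function(pfm, epitope) {
  stopifnot(inherits(pfm, "pfm"))
  epitope <- str_to_upper(epitope)
  if (nchar(epitope) != 9) abort("`epitope` must be a nonamer.")
  cons <- strsplit(pfm$consensus, "")[[1]]
  epi <- strsplit(epitope, "")[[1]]
  out <- tibble(
    position = 1:9,
    consensus = cons,
    epitope_residue = epi,
    match = cons == epi,
    tie = pfm$ties
  )
  attr(out, "overall_match") <- all(out$match)
  out
}

#' Probability of a random identical stretch
#'
#' The probability that `k` specified positions are identical between two
#' independent peptides drawn uniformly over an `alphabet_size`-letter
#' alphabet: `(1/alphabet_size)^k`. For the 20 amino acids this gives
#' 1.5625e-8 at k = 6 and 1.953125e-12 at k = 9, quantifying how unlikely
#' the observed 6-9-residue identical stretches are as chance events. The
#' `any_window` variant multiplies by the number of length-`k` windows in a
#' nonamer (10 - k), an upper bound on the probability that some window
#' matches.
#'
#' @param k Integer vector, stretch length(s) in 1-9.
#' @param alphabet_size Alphabet size (default 20).
#' @param any_window Apply the windows multiplier (default `FALSE`, the
#'   per-stretch form).
#' @return Numeric vector of probabilities.
#' @examples
#' stretch_match_probability(c(6, 9))
#' @export
stretch_match_probability <- function(k, alphabet_size = 20,
                                      any_window = FALSE) {
  if (any(k != as.integer(k)) || any(k < 1) || any(k > 9)) {
    abort("`k` must be integer(s) in 1..9.")
  }
  p <- (1 / alphabet_size)^k
  if (any_window) p <- p * (10 - k)
  p
}
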