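#' Classify predicted binding strength
#'
#' Threshold logic for MHC class I binding calls: `"high"` for predicted
#' affinity below 10 nM; `"strong"` for affinity below 100 nM that also
#' passes the stability criterion (half-life above 1 h) whenever a stability
#' value is available; `"non"` otherwise. When `stability_h` is `NA` the
#' stability criterion is skipped and the call is affinity-only.
#'
#' @param affinity_nm Positive numeric vector, predicted affinity in nM.
#' @param stability_h Optional numeric vector, predicted complex half-life
#'   in hours (NA = not predicted).
#' @param strong_nm,high_nm,min_stability_h Thresholds: strong-binder
#'   affinity (100 nM), high-affinity (10 nM), minimum stability (1 h).
#' @return Character vector with values in `c("high", "strong", "non")`.
#' @examples
#' classify_binder(c(8, 99.9, 150), stability_h = c(2, 1.5, 3))
#' @export
classify_binder <- function(affinity_nm, stability_h = NA_real_,
                            strong_nm = 100, high_nm = 10,
                            min_stability_h = 1) {
  if (any(!is.finite(affinity_nm) | affinity_nm <= 0)) {
    abort("`affinity_nm` must be positive and finite.")
  }
  n <- max(length(affinity_nm), length(stability_h))
  affinity_nm <- rep_len(affinity_nm, n)
  stability_h <- rep_len(stability_h, n)
  stable <- is.na(stability_h) | stability_h > min_stability_h
  out <- rep("non", n)
  out[affinity_nm < strong_nm & stable] <- "strong"
  out[affinity_nm < high_nm] <- "high"
  out
}

#' Build a position-weight-matrix predictor
#'
#' A transparent stand-in for neural-network affinity predictors so the
#' pipeline runs end to end on synthetic data: a 9 x 20 log-odds matrix is
#' summed over peptide positions, the raw score is mapped linearly (and
#' clamped) onto \[0, 1\] using the matrix's attainable score range, and the
#' normalised score `s` is converted to nanomolar affinity as
#' `50000^(1 - s)` -- the conventional transform that places `s = 1` at 1 nM
#' and `s = 0` at 50000 nM.
#'
#' @param allele Allele label the matrix applies to.
#' @param log_odds Numeric 9 x 20 matrix; columns named by the 20 standard
#'   one-letter residue codes, rows = peptide positions 1-9.
#' @return An object of class `pwm_predictor`.
#' @seealso [pwm_from_peptides()] to estimate one from a peptide set,
#'   [pwm_predict()] to score peptides.
#' @export
pwm_predictor <- function(allele, log_odds) {
  if (!is.matrix(log_odds) || nrow(log_odds) != 9) {
    abort("`log_odds` must be a 9 x 20 matrix (positions x residues).")
  }
  if (!setequal(colnames(log_odds), AA_STANDARD)) {
    abort("`log_odds` columns must be named by the 20 standard residues.")
  }
  log_odds <- log_odds[, AA_STANDARD]
  structure(
    list(
      allele = allele,
      log_odds = log_odds,
      score_min = sum(apply(log_odds, 1, min)),
      score_max = sum(apply(log_odds, 1, max))
    ),
    class = "pwm_predictor"
  )
}

#' @export
print.pwm_predictor <- function(x, ...) {
  cat("<pwm_predictor>", x$allele,
      sprintf(" raw score range [%.3g, %.3g]\n", x$score_min, x$score_max))
  invisible(x)
}

#' Estimate a PWM predictor from a set of binding peptides
#'
#' Position-specific log2 odds of observed residue frequencies (with a
#' pseudocount) against a background distribution.
#'
#' @param peptides Character vector of standard nonamers known or assumed to
#'   bind `allele`.
#' @param allele Allele label.
#' @param pseudocount Added to every positional residue count (default 1).
#' @param background Length-20 background frequency vector summing to 1
#'   (default uniform), named or in alphabetical residue order.
#' @return A [pwm_predictor()].
#' @export
pwm_from_peptides <- function(peptides, allele, pseudocount = 1,
                              background = rep(1 / 20, 20)) {
  stopifnot(length(peptides) >= 1)
  background <- check_background(background)
  mat <- do.call(rbind, strsplit(str_to_upper(peptides), ""))
  if (ncol(mat) != 9) abort("All peptides must be nonamers.")
  check_standard_residues(as.vector(mat), "peptide residue")
  counts <- sapply(1:9, function(j) {
    table(factor(mat[, j], levels = AA_STANDARD))
  })  # 20 x 9
  freq <- t(counts + pseudocount)
  freq <- freq / rowSums(freq)          # 9 x 20
  colnames(freq) <- AA_STANDARD
  pwm_predictor(allele, log2(sweep(freq, 2, background, "/")))
}

#' Predict binding affinity with a PWM predictor
#'
#' @param peptides Character vector of standard nonamers.
#' @param predictor A [pwm_predictor()].
#' @param stability_h Optional stability values to attach (recycled; NA by
#'   default, i.e. no stability prediction).
#' @return A prediction tibble with columns `peptide`, `hla_allele`,
#'   `affinity_nm`, `stability_h`, `binder_class` and the normalised
#'   `score`.
#' @export
pwm_predict <- function(peptides, predictor, stability_h = NA_real_) {
  stopifnot(inherits(predictor, "pwm_predictor"))
  peptides <- str_to_upper(peptides)
  if (any(nchar(peptides) != 9)) abort("All peptides must be nonamers.")
  mat <- do.call(rbind, strsplit(peptides, ""))
  check_standard_residues(as.vector(mat), "peptide residue")
  raw <- vapply(seq_along(peptides), function(i) {
    sum(predictor$log_odds[cbind(1:9, match(mat[i, ], AA_STANDARD))])
  }, numeric(1))
  rng <- predictor$score_max - predictor$score_min
  s <- if (rng > 0) (raw - predictor$score_min) / rng else rep(0.5, length(raw))
  s <- pmin(pmax(s, 0), 1)
  affinity <- 50000^(1 - s)
  tibble(
    peptide = peptides,
    hla_allele = predictor$allele,
    affinity_nm = affinity,
    stability_h = rep_len(stability_h, length(peptides)),
    binder_class = classify_binder(affinity, rep_len(stability_h, length(peptides))),
    score = s
  )
}

#' Summarise predicted affinity of mimicry hits
#'
#' Per-(antigen, phylum) affinity summary of the bacterial peptides found
#' for each TAA: mean predicted affinity, the fraction of peptides with
#' affinity strictly below that mean, and the fraction strictly below the
#' paired TAA's own predicted affinity. By default each distinct (antigen,
#' peptide) is counted once; set `distinct_peptides = FALSE` to weight by
#' hit occurrences.
#'
#' @param hits Hit tibble from [scan_proteome()].
#' @param predictions Prediction tibble covering every hit peptide-allele
#'   pair AND every TAA epitope-allele pair.
#' @param distinct_peptides Collapse repeated (antigen, peptide, phylum)
#'   occurrences before averaging (default `TRUE`).
#' @return A tibble with columns `antigen_name`, `phylum`, `n_peptides`,
#'   `mean_affinity_nm`, `taa_affinity_nm`, `frac_below_mean`,
#'   `frac_below_taa`. Antigens with no hits are omitted (with a message).
#' @export
summarize_affinity <- function(hits, predictions, distinct_peptides = TRUE) {
  if (nrow(hits) == 0) {
    inform("No hits to summarise.")
    return(tibble(antigen_name = character(), phylum = character(),
                  n_peptides = integer(), mean_affinity_nm = numeric(),
                  taa_affinity_nm = numeric(), frac_below_mean = numeric(),
                  frac_below_taa = numeric()))
  }
  taa <- hits |>
    distinct(.data$antigen_name, .data$epitope, .data$hla_allele) |>
    left_join(select(predictions, "peptide", "hla_allele",
                     taa_affinity_nm = "affinity_nm"),
              by = c(epitope = "peptide", "hla_allele"))
  if (any(is.na(taa$taa_affinity_nm))) {
    miss <- taa$antigen_name[is.na(taa$taa_affinity_nm)]
    abort(paste0("Missing TAA prediction for: ", paste(miss, collapse = ", ")))
  }
  use <- if (distinct_peptides) unique_peptides(hits) else hits
  joined <- join_predictions(use, predictions) |>
    left_join(select(taa, "antigen_name", "taa_affinity_nm"),
              by = "antigen_name")
  joined |>
    group_by(.data$antigen_name, .data$phylum) |>
    summarise(
      n_peptides = n(),
      mean_affinity_nm = mean(.data$affinity_nm),
      taa_affinity_nm = .data$taa_affinity_nm[1],
      frac_below_mean = mean(.data$affinity_nm < mean(.data$affinity_nm)),
      frac_below_taa = mean(.data$affinity_nm < .data$taa_affinity_nm[1]),
      .groups = "drop"
    )
}
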