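#' Physicochemical amino-acid classes
#'
#' The default partition of the 20 standard residues used to call a
#' substitution "conservative": two different residues are conservative
#' replacements of one another when they fall in the same class.
#'
#' @return A named list of character vectors partitioning the 20 standard
#'   one-letter codes into six classes: aliphatic, aromatic, polar uncharged,
#'   positively charged, negatively charged and special (glycine/proline).
#' @examples
#' default_aa_classes()
#' @export
default_aa_classes <- function() {
  list(
    aliphatic       = c("A", "V", "L", "I", "M"),
    aromatic        = c("F", "W", "Y"),
    polar_uncharged = c("S", "T", "N", "Q", "C"),
    positive        = c("K", "R", "H"),
    negative        = c("D", "E"),
    special         = c("G", "P")
  )
}

#' Define a substitution-classification scheme
#'
#' A scheme decides, for a pair of aligned residues, whether a mismatch is a
#' conservative or a non-conservative substitution. Two modes are supported:
#' `"class_partition"` (same physicochemical class = conservative; the
#' default, using [default_aa_classes()]) and `"matrix_nonnegative"`
#' (substitution-matrix score >= 0 = conservative; BLOSUM62 by default).
#'
#' @param mode `"class_partition"` or `"matrix_nonnegative"`.
#' @param classes Named list of character vectors partitioning the 20
#'   standard residues (class_partition mode only).
#' @param matrix A symmetric substitution matrix with the 20 standard
#'   one-letter codes among its dimnames (matrix_nonnegative mode only);
#'   defaults to BLOSUM62 shipped with Biostrings.
#' @return An object of class `substitution_scheme`.
#' @examples
#' substitution_scheme()
#' substitution_scheme("matrix_nonnegative")
#' @export
substitution_scheme <- function(mode = c("class_partition", "matrix_nonnegative"),
                                classes = default_aa_classes(),
                                matrix = NULL) {
  mode <- match.arg(mode)
  if (mode == "class_partition") {
    members <- unlist(classes, use.names = FALSE)
    if (!setequal(members, AA_STANDARD) || anyDuplicated(members)) {
      abort("`classes` must partition the 20 standard residues: each appears in exactly one class.")
    }
    class_of <- setNames(
      rep(names(classes), lengths(classes)),
      unlist(classes, use.names = FALSE)
    )
    scheme <- list(mode = mode, classes = classes, class_of = class_of)
  } else {
    if (is.null(matrix)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      matrix <- e$BLOSUM62
    }
    if (!all(AA_STANDARD %in% rownames(matrix)) || !all(AA_STANDARD %in% colnames(matrix))) {
      abort("`matrix` must cover all 20 standard residues in its dimnames.")
    }
    scheme <- list(mode = mode, matrix = matrix[AA_STANDARD, AA_STANDARD])
  }
  structure(scheme, class = "substitution_scheme")
}

#' @export
print.substitution_scheme <- function(x, ...) {
  cat("<substitution_scheme> mode:", x$mode, "\n")
  if (x$mode == "class_partition") {
    for (nm in names(x$classes)) {
      cat("  ", nm, ": ", paste(x$classes[[nm]], collapse = " "), "\n", sep = "")
    }
  } else {
    cat("  conservative iff matrix score >= 0\n")
  }
  invisible(x)
}

check_standard_residues <- function(x, arg = "residue") {
  bad <- setdiff(unique(x), AA_STANDARD)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-standard %s code(s): %s. Allowed: the 20 standard one-letter amino-acid codes.",
      arg, paste(sQuote(bad), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Classify a residue substitution
#'
#' Compares two aligned residues under a [substitution_scheme()]:
#' `"identical"` when they are the same residue, `"conservative"` when they
#' differ but the scheme judges the replacement chemically equivalent,
#' `"non_conservative"` otherwise. Vectorised over `a` and `b`.
#'
#' @param a,b Character vectors of standard one-letter residue codes
#'   (recycled to a common length).
#' @param scheme A [substitution_scheme()].
#' @return Character vector of labels in
#'   `c("identical", "conservative", "non_conservative")`.
#' @examples
#' classify_substitution("I", "V")  # aliphatic pair -> conservative
#' classify_substitution("D", "F")  # acidic vs aromatic -> non_conservative
#' @export
classify_substitution <- function(a, b, scheme = substitution_scheme()) {
  stopifnot(inherits(scheme, "substitution_scheme"))
  a <- str_to_upper(a)
  b <- str_to_upper(b)
  check_standard_residues(c(a, b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  out <- rep("non_conservative", n)
  if (scheme$mode == "class_partition") {
    cons <- scheme$class_of[a] == scheme$class_of[b]
  } else {
    cons <- scheme$matrix[cbind(a, b)] >= 0
  }
  out[cons] <- "conservative"
  out[a == b] <- "identical"
  out
}

#' Classify an epitope/hit nonamer pair position by position
#'
#' Position-wise substitution labels and identity count for a gapless
#' alignment of two nonamers. Positions are 1-based in all outputs.
#'
#' @param epitope_seq,hit_seq 9-letter peptides over the standard residues.
#' @inheritParams classify_substitution
#' @return A list with `position_labels` (character, length 9),
#'   `identity_count` (integer 0-9) and `mismatch_positions` (1-based
#'   integer vector of non-identical positions).
#' @examples
#' classify_pair("KVAELVHFL", "KIAELVHFL")$mismatch_positions  # position 2
#' @export
classify_pair <- function(epitope_seq, hit_seq, scheme = substitution_scheme()) {
  epitope_seq <- str_to_upper(epitope_seq)
  hit_seq <- str_to_upper(hit_seq)
  if (length(epitope_seq) != 1 || length(hit_seq) != 1 ||
      nchar(epitope_seq) != 9 || nchar(hit_seq) != 9) {
    abort("Both sequences must be single strings of exactly 9 residues.")
  }
  a <- strsplit(epitope_seq, "")[[1]]
  b <- strsplit(hit_seq, "")[[1]]
  labels <- classify_substitution(a, b, scheme)
  list(
    position_labels = labels,
    identity_count = sum(labels == "identical"),
    mismatch_positions = which(labels != "identical")
  )
}

# Compact 9-character encoding of position labels used in hit tables:
# I = identical, C = conservative, N = non_conservative.
labels_to_string <- function(labels) {
  paste(c(identical = "I", conservative = "C", non_conservative = "N")[labels],
        collapse = "")
}

labels_from_string <- function(s) {
  key <- c(I = "identical", C = "conservative", N = "non_conservative")
  unname(key[strsplit(s, "")[[1]]])
}
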