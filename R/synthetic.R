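#' Generate a synthetic protein collection
#'
#' Draws `n_proteins` random protein sequences with residues sampled
#' independently from a background distribution; lengths are uniform over
#' `length_range`. Deterministic for a fixed seed.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer range of protein lengths (default 100-400
#'   residues, a typical bacterial protein size range).
#' @param background Length-20 residue frequencies summing to 1 (default
#'   uniform; see [aa_background()]).
#' @param phylum Phylum label attached to every record (default
#'   `"Firmicutes"`).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param id_prefix Prefix for generated protein ids.
#' @return A protein tibble (see [read_proteins()]) with an empty plant
#'   ledger attached (see [plant_ledger()]).
#' @export
generate_proteome <- function(n_proteins, length_range = c(100, 400),
                              background = aa_background("uniform"),
                              phylum = "Firmicutes", seed = 1,
                              id_prefix = "SYN") {
  if (n_proteins < 1) abort("`n_proteins` must be >= 1.")
  if (any(length_range < 9)) abort("Protein lengths must be >= 9.")
  background <- check_background(background)
  out <- withr::with_seed(seed, {
    len_pool <- seq.int(length_range[1], length_range[2])
    lens <- len_pool[sample.int(length(len_pool), n_proteins, replace = TRUE)]
    tibble(
      protein_id = sprintf("%s_%s_%04d", id_prefix, substr(phylum, 1, 3),
                           seq_len(n_proteins)),
      description = "synthetic protein",
      phylum = phylum,
      sequence = map_chr(lens, function(n) {
        paste(sample(AA_STANDARD, n, replace = TRUE, prob = background),
              collapse = "")
      })
    )
  })
  attr(out, "plant_ledger") <- empty_ledger()
  out
}

empty_ledger <- function() {
  tibble(
    antigen_name = character(), epitope = character(),
    protein_id = character(), start = integer(),
    planted_sequence = character(), n_substitutions = integer(),
    substitution_positions = list(), substitution_classes = list(),
    seed = integer()
  )
}

#' Plant ledger of a synthetic proteome
#'
#' Every [plant_homolog()] call records what it wrote and where; the ledger
#' is sufficient to predict the scanner's output on the planted windows
#' exactly.
#'
#' @param proteome A proteome tibble from [generate_proteome()] /
#'   [plant_homolog()].
#' @return The ledger tibble.
#' @export
plant_ledger <- function(proteome) {
  attr(proteome, "plant_ledger") %||% empty_ledger()
}

# Residues that `class_policy` allows as a replacement for residue `a`.
policy_candidates <- function(a, class_policy, scheme) {
  others <- setdiff(AA_STANDARD, a)
  lab <- classify_substitution(rep(a, length(others)), others, scheme)
  switch(class_policy,
    conservative_only = others[lab == "conservative"],
    non_conservative_only = others[lab == "non_conservative"],
    mixed = others,
    abort("`class_policy` must be conservative_only, non_conservative_only or mixed.")
  )
}

#' Plant a homolog of an epitope into a synthetic proteome
#'
#' Overwrites a 9-residue window of one protein with a sequence differing
#' from `epitope` at exactly `n_substitutions` positions, each substitution
#' drawn according to `class_policy` under `scheme`. Overwriting (rather
#' than inserting) keeps protein lengths and downstream window offsets
#' stable. Planted windows never overlap a previously planted window; the
#' plant is recorded in the proteome's ledger.
#'
#' @param proteome Proteome tibble (ledger-carrying, from
#'   [generate_proteome()] or a previous plant).
#' @param epitope The TAA nonamer to mimic.
#' @param n_substitutions Number of substituted positions, 0-9.
#' @param class_policy `"conservative_only"`, `"non_conservative_only"` or
#'   `"mixed"` (any residue change).
#' @param positions Optional 1-based epitope positions to substitute
#'   (length `n_substitutions`); sampled when `NULL`.
#' @param protein_id,start Optional explicit location (1-based window
#'   start); sampled when `NULL`.
#' @param scheme [substitution_scheme()] used to draw and label
#'   substitutions.
#' @param antigen_name Label recorded in the ledger.
#' @param seed Integer seed.
#' @param max_retries Bounded retries when a sampled location overlaps an
#'   earlier plant (default 100).
#' @return The modified proteome tibble with its ledger extended.
#' @export
plant_homolog <- function(proteome, epitope, n_substitutions,
                          class_policy = "mixed", positions = NULL,
                          protein_id = NULL, start = NULL,
                          scheme = substitution_scheme(),
                          antigen_name = "", seed = 1,
                          max_retries = 100) {
  epitope <- str_to_upper(epitope)
  if (nchar(epitope) != 9) abort("`epitope` must be a nonamer.")
  check_standard_residues(strsplit(epitope, "")[[1]], "epitope residue")
  if (n_substitutions < 0 || n_substitutions > 9) {
    abort("`n_substitutions` must be in 0..9.")
  }
  if (!is.null(positions) && length(positions) != n_substitutions) {
    abort("`positions` must have length `n_substitutions`.")
  }
  ledger <- plant_ledger(proteome)
  eligible <- which(nchar(proteome$sequence) >= 9)
  if (length(eligible) == 0) abort("No protein long enough to host a window.")

  result <- withr::with_seed(seed, {
    # choose substituted positions and replacement residues
    subs_pos <- positions %||%
      (if (n_substitutions > 0) sort(sample(1:9, n_substitutions)) else integer())
    echars <- strsplit(epitope, "")[[1]]
    planted <- echars
    sub_classes <- character(length(subs_pos))
    for (j in seq_along(subs_pos)) {
      cand <- policy_candidates(echars[subs_pos[j]], class_policy, scheme)
      if (length(cand) == 0) {
        abort(sprintf(
          "class_policy '%s' unsatisfiable for residue %s at position %d.",
          class_policy, echars[subs_pos[j]], subs_pos[j]
        ))
      }
      planted[subs_pos[j]] <- sample(cand, 1)
      sub_classes[j] <- classify_substitution(echars[subs_pos[j]],
                                              planted[subs_pos[j]], scheme)
    }
    planted_seq <- paste(planted, collapse = "")

    # choose a non-overlapping location
    loc <- NULL
    for (try in seq_len(max_retries)) {
      pid <- protein_id %||% proteome$protein_id[sample(eligible, 1)]
      row <- match(pid, proteome$protein_id)
      if (is.na(row)) abort(sprintf("Unknown protein_id '%s'.", pid))
      len <- nchar(proteome$sequence[row])
      if (len < 9) abort(sprintf("Protein '%s' is shorter than 9 residues.", pid))
      st <- start %||% sample(seq_len(len - 8L), 1)
      if (st < 1 || st > len - 8L) abort("`start` leaves no room for a 9-mer window.")
      prior <- ledger[ledger$protein_id == pid, ]
      overlap <- any(abs(prior$start - st) < 9)
      if (!overlap) {
        loc <- list(row = row, pid = pid, st = as.integer(st))
        break
      }
      if (!is.null(protein_id) && !is.null(start)) {
        abort("Requested window overlaps a previously planted window.")
      }
    }
    if (is.null(loc)) abort("Could not find a non-overlapping window after bounded retries.")
    list(planted_seq = planted_seq, subs_pos = as.integer(subs_pos),
         sub_classes = sub_classes, loc = loc)
  })

  row <- result$loc$row
  st <- result$loc$st
  seqs <- proteome$sequence
  substr(seqs[row], st, st + 8L) <- result$planted_seq
  proteome$sequence <- seqs
  entry <- tibble(
    antigen_name = antigen_name, epitope = epitope,
    protein_id = result$loc$pid, start = st,
    planted_sequence = result$planted_seq,
    n_substitutions = as.integer(n_substitutions),
    substitution_positions = list(result$subs_pos),
    substitution_classes = list(result$sub_classes),
    seed = as.integer(seed)
  )
  attr(proteome, "plant_ledger") <- bind_rows(ledger, entry)
  proteome
}

# --- idealized peptide backbones -------------------------------------------

# Standard backbone geometry (Angstrom / degrees).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_CA_CB <- 1.521
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.8
ANGLE_N_CA_CB <- 110.5

# Natural-extension-reference-frame placement: position D such that
# |C-D| = bond, angle(B,C,D) = angle_deg and dihedral(A,B,C,D) = torsion_deg.
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  theta <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  bc <- C - B
  bc <- bc / vec_norm(bc)
  n <- vec_cross(B - A, bc)
  n <- n / vec_norm(n)
  m <- vec_cross(n, bc)
  d <- c(-bond * cos(theta), bond * sin(theta) * cos(chi),
         bond * sin(theta) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Generate an idealized nonamer backbone with specified torsions
#'
#' Builds a peptide-only structure (backbone N/CA/C/O plus CB stubs for
#' non-glycine residues) with standard bond lengths and angles, trans
#' peptide bonds (omega = 180 degrees) and the requested phi/psi backbone
#' torsions. The construction is exact: torsions measured back from the
#' emitted coordinates equal the requested values to numerical precision.
#' phi of the first residue has no meaning (no preceding carbonyl) and is
#' ignored; psi of the last residue only orients its carbonyl oxygen.
#'
#' @param sequence A standard nonamer (decides residue names and CB stubs).
#' @param phi_psi A 9 x 2 matrix (or list of 9 `c(phi, psi)` pairs) of
#'   torsions in degrees.
#' @param structure_id Identifier for the structure (default
#'   `"ideal_<sequence>"`).
#' @param chain Chain id (default `"P"`).
#' @return A [peptide_structure()] with a single peptide chain.
#' @examples
#' helix <- generate_ideal_peptide("KVAELVHFL",
#'                                 matrix(rep(c(-57, -47), 9), ncol = 2, byrow = TRUE))
#' @export
generate_ideal_peptide <- function(sequence, phi_psi,
                                   structure_id = NULL, chain = "P") {
  sequence <- str_to_upper(sequence)
  if (nchar(sequence) != 9) abort("`sequence` must be a nonamer.")
  chars <- strsplit(sequence, "")[[1]]
  check_standard_residues(chars, "residue")
  if (is.list(phi_psi)) phi_psi <- do.call(rbind, phi_psi)
  if (!is.matrix(phi_psi) || nrow(phi_psi) != 9 || ncol(phi_psi) != 2 ||
      any(!is.finite(phi_psi))) {
    abort("`phi_psi` must be 9 finite (phi, psi) pairs in degrees.")
  }
  phi <- phi_psi[, 1]
  psi <- phi_psi[, 2]

  N <- CA <- C <- vector("list", 9)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(BOND_N_CA, 0, 0)
  th <- ANGLE_N_CA_C * pi / 180
  C[[1]] <- CA[[1]] + BOND_CA_C * c(-cos(th), sin(th), 0)
  for (i in 1:8) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                             BOND_C_N, ANGLE_CA_C_N, psi[i])
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]],
                              BOND_N_CA, ANGLE_C_N_CA, 180)
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]],
                             BOND_CA_C, ANGLE_N_CA_C, phi[i + 1])
  }
  rows <- list()
  for (i in 1:9) {
    resid <- AA_ONE_TO_THREE[chars[i]]
    O <- place_atom(N[[i]], CA[[i]], C[[i]], BOND_C_O, ANGLE_CA_C_O,
                    psi[i] + 180)
    add <- function(atom, element, p) {
      tibble(chain = chain, role = "peptide", resno = i, resid = resid,
             atom = atom, element = element, x = p[1], y = p[2], z = p[3])
    }
    res_rows <- list(add("N", "N", N[[i]]), add("CA", "C", CA[[i]]),
                     add("C", "C", C[[i]]), add("O", "O", O))
    if (chars[i] != "G") {
      CB <- place_atom(C[[i]], N[[i]], CA[[i]], BOND_CA_CB, ANGLE_N_CA_CB,
                       -122.6)
      res_rows <- c(res_rows, list(add("CB", "C", CB)))
    }
    rows[[i]] <- bind_rows(res_rows)
  }
  peptide_structure(
    structure_id = structure_id %||% paste0("ideal_", sequence),
    atoms = bind_rows(rows),
    chain_roles = setNames("peptide", chain)
  )
}
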