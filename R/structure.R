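#' Construct a peptide-HLA(-TCR) structure object
#'
#' Container for the atoms of a peptide-MHC(-TCR) complex with a role
#' assigned to every chain. Usually created by [read_peptide_structure()]
#' or [generate_ideal_peptide()].
#'
#' @param structure_id Text identifier (e.g. a PDB id).
#' @param atoms Tibble with columns `chain`, `role`, `resno`, `resid`,
#'   `atom`, `element`, `x`, `y`, `z` (coordinates in Angstrom).
#' @param chain_roles Named character vector mapping chain id to role in
#'   `c("peptide", "hla", "b2m", "tcr_alpha", "tcr_beta")`.
#' @return An object of class `peptide_structure`.
#' @export
peptide_structure <- function(structure_id, atoms, chain_roles) {
  atoms <- as_tibble(atoms)
  required <- c("chain", "role", "resno", "resid", "atom", "element",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("`atoms` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("All atom coordinates must be finite.")
  }
  roles <- c("peptide", "hla", "b2m", "tcr_alpha", "tcr_beta")
  bad <- setdiff(unique(atoms$role), roles)
  if (length(bad) > 0) {
    abort(paste0("Unknown chain role(s): ", paste(bad, collapse = ", ")))
  }
  pep <- filter(atoms, .data$role == "peptide")
  if (nrow(pep) == 0) abort("Structure has no peptide chain.")
  n_res <- length(unique(pep$resno))
  if (n_res < 8 || n_res > 11) {
    abort(sprintf("Peptide chain must have 8-11 residues, found %d.", n_res))
  }
  # residue numbering strictly increasing along the stored atom order
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(r)) {
      abort(sprintf("Residue numbering is not increasing within chain %s.", ch))
    }
  }
  structure(
    list(structure_id = structure_id, atoms = atoms, chain_roles = chain_roles),
    class = "peptide_structure"
  )
}

#' @export
print.peptide_structure <- function(x, ...) {
  cat("<peptide_structure>", x$structure_id, "\n")
  tab <- x$atoms |> count(.data$chain, .data$role)
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  chain %s (%s): %d atoms\n",
                tab$chain[i], tab$role[i], tab$n[i]))
  }
  cat("  peptide:", peptide_sequence(x), "\n")
  invisible(x)
}

AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)
AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

#' Peptide one-letter sequence of a structure
#'
#' @param structure A [peptide_structure()].
#' @return One-letter peptide sequence (unknown residues as `X`).
#' @export
peptide_sequence <- function(structure) {
  pep <- peptide_residues(structure)
  one <- AA_THREE_TO_ONE[pep$resid]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

# Ordered peptide residues: tibble(position, resno, resid).
peptide_residues <- function(structure) {
  structure$atoms |>
    filter(.data$role == "peptide") |>
    distinct(.data$resno, .data$resid) |>
    arrange(.data$resno) |>
    mutate(position = row_number()) |>
    select("position", "resno", "resid")
}

#' Read a peptide-HLA(-TCR) complex from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d), keeps blank or 'A'
#' alternate locations, drops waters, and assigns a role to each declared
#' chain. Chains not listed in `chain_roles` are ignored. The peptide chain
#' must contain 8-11 residues.
#'
#' @param path Path to a PDB-format file.
#' @param chain_roles Named character vector mapping chain id to role, e.g.
#'   `c(C = "peptide", A = "hla", B = "b2m", D = "tcr_alpha", E = "tcr_beta")`
#'   (the layout of the 1AO7 entry).
#' @return A [peptide_structure()].
#' @export
read_peptide_structure <- function(path, chain_roles) {
  if (is.null(names(chain_roles)) || any(names(chain_roles) == "")) {
    abort("`chain_roles` must be a named vector: names are chain ids.")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) abort(paste0("Cannot parse PDB file ", path, ": ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    abort(paste0("No ATOM records found in ", path))
  }
  at <- at[at$type %in% c("ATOM", "HETATM") & at$resid != "HOH", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  missing <- setdiff(names(chain_roles), unique(at$chain))
  if (length(missing) > 0) {
    abort(paste0("Declared chain(s) absent from ", path, ": ",
                 paste(missing, collapse = ", ")))
  }
  at <- at[at$chain %in% names(chain_roles), , drop = FALSE]
  element <- at$elesy
  guess <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  element <- ifelse(is.na(element) | element == "", guess, element)
  atoms <- tibble(
    chain = at$chain,
    role = unname(chain_roles[at$chain]),
    resno = at$resno,
    resid = at$resid,
    atom = at$elety,
    element = toupper(element),
    x = at$x, y = at$y, z = at$z
  )
  peptide_structure(
    structure_id = tools::file_path_sans_ext(basename(path)),
    atoms = atoms,
    chain_roles = chain_roles
  )
}

#' Write a structure to a PDB file
#'
#' Minimal fixed-column ATOM-record emitter used for synthetic fixtures.
#'
#' @param structure A [peptide_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    a$resid, a$chain, a$resno, a$x, a$y, a$z, a$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

vec_norm <- function(v) sqrt(sum(v^2))
vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Planar (three-atom) angle
#'
#' Angle at vertex `p2` between the vectors to `p1` and `p3`, in degrees.
#'
#' @param p1,p2,p3 Numeric xyz coordinates (Angstrom).
#' @return Angle in degrees, in \[0, 180\].
#' @examples
#' planar_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # 90
#' @export
planar_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  if (vec_norm(u) < 1e-9 || vec_norm(v) < 1e-9) {
    abort("Coincident points: planar angle undefined.")
  }
  atan2(vec_norm(vec_cross(u, v)), sum(u * v)) * 180 / pi
}

#' Dihedral (torsion) angle
#'
#' Signed torsion of `p4` about the `p2`-`p3` axis relative to `p1`, using
#' the IUPAC sign convention (positive = clockwise rotation of the far bond
#' when sighting from `p2` to `p3`).
#'
#' @param p1,p2,p3,p4 Numeric xyz coordinates (Angstrom).
#' @return Angle in degrees, in (-180, 180\].
#' @examples
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))  # 0 (cis)
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  nb1 <- vec_norm(b1)
  if (nb1 < 1e-9) abort("Coincident axis points: dihedral undefined.")
  b1 <- b1 / nb1
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  if (vec_norm(v) < 1e-9 || vec_norm(w) < 1e-9) {
    abort("Degenerate geometry (collinear points): dihedral undefined.")
  }
  x <- sum(v * w)
  y <- sum(vec_cross(b1, v) * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Define angle descriptors
#'
#' An angle descriptor names 3 (planar) or 4 (dihedral) atoms by peptide
#' position and atom name; applied to a structure it yields one angle.
#'
#' @param kind `"planar"` or `"dihedral"`.
#' @param positions Integer vector (length 3 or 4) of 1-based peptide
#'   positions.
#' @param atoms Character vector of atom names, same length.
#' @param label Optional descriptor label.
#' @return A one-row descriptor tibble with a list-column `refs`.
#' @export
angle_descriptor <- function(kind = c("planar", "dihedral"), positions, atoms,
                             label = NULL) {
  kind <- match.arg(kind)
  need <- if (kind == "planar") 3L else 4L
  if (length(positions) != need || length(atoms) != need) {
    abort(sprintf("A %s descriptor needs exactly %d atom references.", kind, need))
  }
  label <- label %||% paste0(kind, ":", paste0(atoms, positions, collapse = "-"))
  tibble(kind = kind, label = label,
         refs = list(tibble(pos = as.integer(positions), atom = atoms)))
}

#' Backbone angle descriptors for selected peptide positions
#'
#' For each position `i`: the C-alpha planar angle
#' (CA at i-1, i, i+1; requires 2 <= i <= n-1), the phi torsion
#' (C(i-1), N(i), CA(i), C(i); requires i >= 2) and the psi torsion
#' (N(i), CA(i), C(i), N(i+1); requires i <= n-1).
#'
#' @param positions 1-based peptide positions (default 4:8, the
#'   TCR-facing central stretch).
#' @param n_residues Peptide length (default 9).
#' @param planar,phi,psi Which descriptor families to include.
#' @return A descriptor tibble (rows = descriptors).
#' @export
backbone_descriptors <- function(positions = 4:8, n_residues = 9,
                                 planar = TRUE, phi = TRUE, psi = TRUE) {
  out <- list()
  for (i in positions) {
    if (planar && i >= 2 && i <= n_residues - 1) {
      out[[length(out) + 1]] <- angle_descriptor(
        "planar", c(i - 1, i, i + 1), c("CA", "CA", "CA"),
        label = sprintf("planar:CA%d-CA%d-CA%d", i - 1, i, i + 1)
      )
    }
    if (phi && i >= 2) {
      out[[length(out) + 1]] <- angle_descriptor(
        "dihedral", c(i - 1, i, i, i), c("C", "N", "CA", "C"),
        label = sprintf("dihedral:phi%d", i)
      )
    }
    if (psi && i <= n_residues - 1) {
      out[[length(out) + 1]] <- angle_descriptor(
        "dihedral", c(i, i, i, i + 1), c("N", "CA", "C", "N"),
        label = sprintf("dihedral:psi%d", i)
      )
    }
  }
  bind_rows(out)
}

# Heavy side-chain atom farthest from CA, used as the terminal reference of
# the side-chain orientation dihedral. NULL when the residue has no side
# chain beyond CB (Gly, or CB-stub models).
sidechain_terminal_atom <- function(structure, pos) {
  res <- peptide_residues(structure)
  resno <- res$resno[res$position == pos]
  at <- structure$atoms |>
    filter(.data$role == "peptide", .data$resno == !!resno,
           !.data$atom %in% c("N", "CA", "C", "O", "OXT"),
           .data$element != "H")
  if (nrow(at) < 2) return(NULL)   # need CB plus at least one more atom
  ca <- structure$atoms |>
    filter(.data$role == "peptide", .data$resno == !!resno, .data$atom == "CA")
  d <- sqrt((at$x - ca$x[1])^2 + (at$y - ca$y[1])^2 + (at$z - ca$z[1])^2)
  at$atom[which.max(d)]
}

#' Default mimicry descriptor set
#'
#' The default angle selection for the structural comparison: for every
#' TCR-facing position, the C-alpha planar angle through the flanking
#' residues, and (where the residue has a side chain beyond C-beta in the
#' reference structure) the side-chain orientation dihedral
#' N-CA-CB-terminal atom.
#'
#' @param structure Reference [peptide_structure()] used to resolve
#'   side-chain terminal atoms.
#' @param positions 1-based peptide positions (default the TCR-facing set
#'   of `structure`, falling back to 4:8).
#' @return A descriptor tibble.
#' @export
default_descriptors <- function(structure, positions = NULL) {
  n_res <- nrow(peptide_residues(structure))
  if (is.null(positions)) {
    positions <- tryCatch(
      tcr_facing_positions(contact_map(structure)),
      error = function(e) 4:8
    )
    if (length(positions) == 0) positions <- 4:8
  }
  out <- list()
  for (i in positions) {
    if (i >= 2 && i <= n_res - 1) {
      out[[length(out) + 1]] <- angle_descriptor(
        "planar", c(i - 1, i, i + 1), c("CA", "CA", "CA"),
        label = sprintf("planar:CA%d-CA%d-CA%d", i - 1, i, i + 1)
      )
    }
    term <- sidechain_terminal_atom(structure, i)
    if (!is.null(term)) {
      out[[length(out) + 1]] <- angle_descriptor(
        "dihedral", c(i, i, i, i), c("N", "CA", "CB", term),
        label = sprintf("dihedral:sidechain%d", i)
      )
    }
  }
  if (length(out) == 0) abort("No resolvable descriptors at the requested positions.")
  bind_rows(out)
}

# Resolve one (pos, atom) reference to coordinates within the peptide chain.
resolve_atom <- function(structure, pos, atom) {
  res <- peptide_residues(structure)
  if (!pos %in% res$position) {
    abort(sprintf("Cannot resolve peptide position %d in structure %s.",
                  pos, structure$structure_id))
  }
  resno <- res$resno[res$position == pos]
  hit <- structure$atoms |>
    filter(.data$role == "peptide", .data$resno == !!resno, .data$atom == !!atom)
  if (nrow(hit) == 0) {
    abort(sprintf("Cannot resolve atom %s of peptide position %d in structure %s.",
                  atom, pos, structure$structure_id))
  }
  c(hit$x[1], hit$y[1], hit$z[1])
}

#' Measure one descriptor on a structure
#'
#' @param structure A [peptide_structure()].
#' @param descriptor A one-row descriptor tibble (see [angle_descriptor()]).
#' @return Angle in degrees.
#' @export
measure_angle <- function(structure, descriptor) {
  refs <- descriptor$refs[[1]]
  pts <- lapply(seq_len(nrow(refs)), function(i) {
    resolve_atom(structure, refs$pos[i], refs$atom[i])
  })
  if (descriptor$kind == "planar") {
    planar_angle(pts[[1]], pts[[2]], pts[[3]])
  } else {
    dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }
}

#' Compare angles between two peptide structures
#'
#' Measures every descriptor on a reference (TAA) and an alternative
#' (microbial) structure and flags each pair "identical" under a relative
#' criterion: the circular absolute difference must not exceed
#' `tolerance` x |reference angle|, with an absolute floor of `floor_deg`
#' applied when the reference angle magnitude is below 50 degrees (so
#' near-zero reference angles remain comparable).
#'
#' @param ref_structure,alt_structure [peptide_structure()] objects; the
#'   descriptors must resolve in both.
#' @param descriptors Descriptor tibble (default:
#'   [default_descriptors()] of the reference).
#' @param tolerance Relative tolerance (default 0.10, i.e. +/-10%).
#' @param floor_deg Absolute floor in degrees for small reference angles
#'   (default 5).
#' @param magnitudes Compare absolute values instead of signed angles
#'   (default `FALSE`: circular difference of signed values).
#' @return A tibble of class `angle_comparison` with columns `label`,
#'   `kind`, `value_ref`, `value_alt`, `difference` (circular, degrees),
#'   `relative_difference` and `identical`. [glance()] gives
#'   `percent_identical` pooled and per kind.
#' @export
compare_angles <- function(ref_structure, alt_structure, descriptors = NULL,
                           tolerance = 0.10, floor_deg = 5,
                           magnitudes = FALSE) {
  if (is.null(descriptors)) descriptors <- default_descriptors(ref_structure)
  rows <- purrr::map_dfr(seq_len(nrow(descriptors)), function(i) {
    d <- descriptors[i, ]
    a <- measure_angle(ref_structure, d)
    b <- measure_angle(alt_structure, d)
    if (magnitudes) {
      a <- abs(a)
      b <- abs(b)
    }
    diff <- circular_difference(a, b)
    crit <- tolerance * abs(a)
    if (abs(a) < 50) crit <- max(crit, floor_deg)
    tibble(
      label = d$label, kind = d$kind,
      value_ref = a, value_alt = b,
      difference = diff,
      relative_difference = if (abs(a) > 0) diff / abs(a) else Inf,
      identical = diff <= crit
    )
  })
  structure(rows, class = c("angle_comparison", class(rows)),
            tolerance = tolerance, floor_deg = floor_deg)
}

circular_difference <- function(a, b) {
  abs(((a - b + 180) %% 360) - 180)
}

#' @exportS3Method generics::glance
glance.angle_comparison <- function(x, ...) {
  per_kind <- x |>
    group_by(.data$kind) |>
    summarise(pct = 100 * mean(.data$identical), .groups = "drop")
  tibble(
    n_angles = nrow(x),
    percent_identical = 100 * mean(x$identical),
    percent_identical_planar =
      if ("planar" %in% per_kind$kind) per_kind$pct[per_kind$kind == "planar"] else NA_real_,
    percent_identical_dihedral =
      if ("dihedral" %in% per_kind$kind) per_kind$pct[per_kind$kind == "dihedral"] else NA_real_
  )
}

#' Per-residue contact map of a peptide against HLA and TCR chains
#'
#' A peptide residue contacts a chain role when any of its heavy atoms lies
#' within `cutoff_A` of any heavy atom of a chain carrying that role. The
#' beta-2-microglobulin chain is never a contact category.
#'
#' @param structure A [peptide_structure()] with a peptide chain.
#' @param cutoff_A Distance cutoff in Angstrom (default 4.0).
#' @return A tibble of class `contact_map` with columns `position`, `resid`
#'   and logicals `hla`, `tcr_alpha`, `tcr_beta`; attribute `cutoff_A`.
#' @export
contact_map <- function(structure, cutoff_A = 4.0) {
  stopifnot(inherits(structure, "peptide_structure"))
  heavy <- filter(structure$atoms, .data$element != "H")
  pep <- filter(heavy, .data$role == "peptide")
  if (nrow(pep) == 0) abort("Structure has no peptide chain.")
  res <- peptide_residues(structure)
  categories <- c("hla", "tcr_alpha", "tcr_beta")
  out <- res |> mutate(hla = FALSE, tcr_alpha = FALSE, tcr_beta = FALSE)
  for (cat in categories) {
    other <- filter(heavy, .data$role == cat)
    if (nrow(other) == 0 || cutoff_A <= 0) next
    om <- as.matrix(other[, c("x", "y", "z")])
    for (i in seq_len(nrow(res))) {
      pm <- as.matrix(pep[pep$resno == res$resno[i], c("x", "y", "z")])
      if (nrow(pm) == 0) next
      d2 <- outer(rowSums(pm^2), rowSums(om^2), "+") - 2 * pm %*% t(om)
      if (min(d2) <= cutoff_A^2 + 1e-12) out[[cat]][i] <- TRUE
    }
  }
  out <- select(out, "position", "resid", "hla", "tcr_alpha", "tcr_beta")
  structure(out, class = c("contact_map", class(out)), cutoff_A = cutoff_A,
            roles_present = unique(structure$atoms$role))
}

#' TCR-facing peptide positions
#'
#' From a [contact_map()]: the 1-based peptide positions contacting the TCR
#' alpha or beta chain; when the structure contained no TCR chains the
#' static central-residue fallback `{4,5,6,7,8}` is returned with a message
#' (HLA class I nonamers anchor at positions 2 and 9, leaving the central
#' stretch exposed to the TCR). From an allele label: the static fallback.
#'
#' @param x A `contact_map` or an allele label (character).
#' @param ... Unused.
#' @return Integer vector of 1-based positions.
#' @export
tcr_facing_positions <- function(x, ...) UseMethod("tcr_facing_positions")

#' @export
tcr_facing_positions.contact_map <- function(x, ...) {
  roles <- attr(x, "roles_present")
  if (!any(c("tcr_alpha", "tcr_beta") %in% roles)) {
    inform("No TCR chains in structure; using static central positions 4-8.")
    return(4:8)
  }
  sort(x$position[x$tcr_alpha | x$tcr_beta])
}

#' @export
tcr_facing_positions.character <- function(x, ...) {
  4:8
}
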