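#' Annotate hits with stretch-match probabilities
#'
#' Adds, per hit, the length of its longest run of consecutive identical
#' positions and the random-match probabilities for that run and for its
#' total identity count: the probability that so many specified positions
#' agree between two independent uniform random peptides
#' (see [stretch_match_probability()]). A hit with no identical position
#' gets probability 1 (empty product) and is flagged.
#'
#' @param hits Hit tibble from [scan_proteome()].
#' @return `hits` with columns `longest_run`, `p_longest_run`,
#'   `p_identity_count` and `no_identity` appended.
#' @export
annotate_stretch_probability <- function(hits) {
  runs <- map_int(hits$labels, function(s) {
    r <- rle(strsplit(s, "")[[1]] == "I")
    runs <- r$lengths[r$values]
    if (length(runs) == 0) 0L else as.integer(max(runs))
  })
  p_of <- function(k) ifelse(k == 0, 1, stretch_match_probability(pmax(k, 1)))
  hits |>
    mutate(
      longest_run = runs,
      p_longest_run = p_of(runs),
      p_identity_count = p_of(.data$identity_count),
      no_identity = runs == 0
    )
}

#' Demo pipeline configuration
#'
#' A self-contained configuration for [run_pipeline()]: the packaged
#' epitope table plus a seeded synthetic proteome pair (one per phylum)
#' with homologs of each epitope planted at 1-3 substitutions, PWM-based
#' affinity prediction, and a structural comparison of the two worked
#' example pairs on idealized HLA-groove-like backbones.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer master seed.
#' @return A config list understood by [run_pipeline()].
#' @export
demo_config <- function(out_dir, seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    epitopes = system.file("extdata", "epitopes_printed.tsv",
                           package = "mimicryscan"),
    synthetic = list(
      n_proteins = 40,
      length_range = c(80, 200),
      phyla = c("Firmicutes", "Bacteroidetes"),
      plants_per_epitope = 6,
      max_substitutions = 3,
      class_policy = "conservative_only"
    ),
    scan = list(min_identity = 5, skip_ambiguous = TRUE),
    binding = list(source = "pwm", stability_h = 2),
    thresholds = list(strong_nm = 100, high_nm = 10, min_stability_h = 1),
    stats = list(background = "uniform"),
    geometry = list(
      enabled = TRUE,
      tolerance = 0.10,
      pairs = list(
        list(ref = "KVAELVHFL", alt = "KIAELVHFL", antigen = "MAGE-A3"),
        list(ref = "GLYDGMEHL", alt = "GMYDGLEHV", antigen = "MAGE-A10")
      )
    )
  )
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) abort("Config must set `seed`.", class = "mimicry_validation")
  if (is.null(config$out_dir)) abort("Config must set `out_dir`.", class = "mimicry_validation")
  if (is.null(config$epitopes)) abort("Config must set `epitopes`.", class = "mimicry_validation")
  if (!file.exists(config$epitopes)) {
    abort(paste0("Epitope table not found: ", config$epitopes),
          class = "mimicry_validation")
  }
  if (is.null(config$synthetic)) {
    if (is.null(config$fasta)) {
      abort("Config needs either a `synthetic` section or `fasta` inputs.",
            class = "mimicry_validation")
    }
    for (f in config$fasta) {
      if (is.null(f$path) || !file.exists(f$path)) {
        abort(paste0("FASTA input not found: ", f$path %||% "<missing path>"),
              class = "mimicry_validation")
      }
      if (is.null(f$phylum)) {
        abort("Every FASTA input needs a `phylum` label.",
              class = "mimicry_validation")
      }
    }
  }
  if (!is.null(config$predictions) && !file.exists(config$predictions)) {
    abort(paste0("Prediction table not found: ", config$predictions),
          class = "mimicry_validation")
  }
  config
}

# TSV writer stamping provenance (tool version, config hash, seed) as
# comment lines so outputs are self-describing and runs are comparable.
write_report_tsv <- function(df, path, meta) {
  con <- file(path, open = "wb")  # binary mode: byte-identical across OSes
  on.exit(close(con))
  writeLines(c(
    sprintf("# mimicryscan %s", meta$version),
    sprintf("# config_hash %s", meta$config_hash),
    sprintf("# seed %d", meta$seed)
  ), con)
  # flatten list-columns for on-disk representation
  df <- mutate(df, across(dplyr::where(is.list),
                          ~ map_chr(.x, paste, collapse = ",")))
  readr::write_tsv(df, con, append = TRUE, col_names = TRUE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
          class = "mimicry_stage_failure", parent = e)
  })
}

#' Run the full mimicry-discovery pipeline
#'
#' Orchestrates every stage on one configuration: load (or synthesise) the
#' inputs, scan for homologous nonamers, predict or import binding
#' affinities, tally hit counts and identity distributions, compute
#' per-position substitution statistics and position frequency matrices
#' with consensus checks, summarise affinities, annotate stretch-match
#' probabilities, and (optionally) compare backbone angles of selected
#' pairs on idealized structures. All outputs are written to
#' `config$out_dir` as TSV files stamped with the package version, a config
#' hash and the seed; identical config + seed gives byte-identical outputs.
#'
#' @param config A config list (see [demo_config()]) or the path to a YAML
#'   file holding one.
#' @return (Invisibly) the report bundle: a named list with `hits`,
#'   `counts`, `identity_distribution`, `identity_summary`,
#'   `position_stats`, `pfms`, `consensus`, `affinity`, `predictions` and
#'   (when enabled) `angles`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  seed <- as.integer(config$seed)
  # hash the analysis-relevant config: where outputs land must not change them
  hashed <- config
  hashed$out_dir <- NULL
  meta <- list(
    version = as.character(packageVersion("mimicryscan")),
    config_hash = rlang::hash(hashed),
    seed = seed
  )
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  epitopes <- stage("epitopes", read_epitopes(config$epitopes))
  scheme <- substitution_scheme(config$scheme %||% "class_partition")

  proteins <- stage("proteome", {
    if (!is.null(config$synthetic)) {
      synth <- config$synthetic
      parts <- imap(synth$phyla %||% "Firmicutes", function(ph, k) {
        prot <- generate_proteome(
          n_proteins = synth$n_proteins %||% 40,
          length_range = unlist(synth$length_range %||% c(80, 200)),
          phylum = ph,
          seed = seed + 1000L * k
        )
        for (e in seq_len(nrow(epitopes))) {
          for (j in seq_len(synth$plants_per_epitope %||% 6)) {
            nsub <- (j - 1L) %% ((synth$max_substitutions %||% 3) + 1L)
            prot <- plant_homolog(
              prot, epitopes$sequence[e], n_substitutions = nsub,
              class_policy = synth$class_policy %||% "conservative_only",
              scheme = scheme, antigen_name = epitopes$antigen_name[e],
              seed = seed + 1000L * k + 37L * e + j
            )
          }
        }
        prot
      })
      out <- bind_rows(parts)
      attr(out, "plant_ledger") <- bind_rows(map(parts, plant_ledger))
      out
    } else {
      bind_rows(map(config$fasta, ~ read_proteins(.x$path, .x$phylum)))
    }
  })

  hits <- stage("scan", scan_proteome(
    epitopes, proteins, scheme = scheme,
    min_identity = config$scan$min_identity %||% 5,
    skip_ambiguous = config$scan$skip_ambiguous %||% TRUE,
    max_hits_per_epitope = config$scan$max_hits_per_epitope
  ))

  predictions <- stage("binding", {
    if (!is.null(config$predictions)) {
      import_predictions(config$predictions)
    } else {
      # PWM stand-in: one predictor per allele, anchored on that allele's
      # own epitope set, scoring all hit peptides and the TAAs themselves.
      stab <- config$binding$stability_h %||% NA_real_
      bind_rows(map(unique(epitopes$hla_allele), function(al) {
        pep <- unique(c(epitopes$sequence[epitopes$hla_allele == al],
                        hits$hit_sequence[hits$hla_allele == al]))
        predictor <- pwm_from_peptides(
          epitopes$sequence[epitopes$hla_allele == al], al
        )
        pwm_predict(pep, predictor, stability_h = stab)
      }))
    }
  })

  counts <- stage("counts", count_hits(
    hits, predictions, high_nm = config$thresholds$high_nm %||% 10
  ))
  idist <- stage("identity_distribution", identity_distribution(hits))
  isum <- stage("identity_summary", identity_summary(hits))
  pstats <- stage("position_stats", per_position_stats(hits))

  background <- aa_background(config$stats$background %||% "uniform")
  pfms <- stage("pfm", {
    split(hits, hits$antigen_name) |>
      map(~ build_pfm(.x$hit_sequence, background = background))
  })
  consensus <- stage("consensus", {
    bind_rows(imap(pfms, function(p, antigen) {
      epi <- epitopes$sequence[match(antigen, epitopes$antigen_name)]
      cm <- consensus_match(p, epi)
      tibble(antigen_name = antigen,
             consensus = p$consensus, epitope = epi,
             n_matching_positions = sum(cm$match),
             overall_match = attr(cm, "overall_match"))
    }))
  })

  affinity <- stage("affinity", summarize_affinity(hits, predictions))
  hits <- stage("probability", annotate_stretch_probability(hits))

  angles <- NULL
  if (isTRUE(config$geometry$enabled)) {
    angles <- stage("geometry", {
      torsions <- hla_groove_torsions()
      bind_rows(map(config$geometry$pairs, function(pr) {
        ref <- generate_ideal_peptide(pr$ref, torsions)
        alt <- generate_ideal_peptide(pr$alt, torsions)
        cmp <- compare_angles(
          ref, alt,
          descriptors = backbone_descriptors(4:8),
          tolerance = config$geometry$tolerance %||% 0.10
        )
        mutate(cmp, antigen_name = pr$antigen %||% pr$ref,
               ref_peptide = pr$ref, alt_peptide = pr$alt)
      }))
    })
  }

  # ---- write the bundle -----------------------------------------------
  write_report_tsv(hits, file.path(config$out_dir, "hits.tsv"), meta)
  write_report_tsv(counts, file.path(config$out_dir, "counts.tsv"), meta)
  write_report_tsv(idist, file.path(config$out_dir, "identity_distribution.tsv"), meta)
  write_report_tsv(as_tibble(unclass_keep(isum)),
                   file.path(config$out_dir, "identity_summary.tsv"), meta)
  write_report_tsv(tidy(pstats), file.path(config$out_dir, "position_stats.tsv"), meta)
  write_report_tsv(bind_rows(imap(pfms, ~ mutate(tidy(.x), antigen_name = .y))),
                   file.path(config$out_dir, "pfm.tsv"), meta)
  write_report_tsv(consensus, file.path(config$out_dir, "consensus.tsv"), meta)
  write_report_tsv(affinity, file.path(config$out_dir, "affinity_summary.tsv"), meta)
  if (!is.null(angles)) {
    write_report_tsv(angles, file.path(config$out_dir, "angle_comparisons.tsv"), meta)
  }

  invisible(list(
    hits = hits, counts = counts, identity_distribution = idist,
    identity_summary = isum, position_stats = pstats, pfms = pfms,
    consensus = consensus, affinity = affinity, predictions = predictions,
    angles = angles, ledger = plant_ledger(proteins), meta = meta
  ))
}

#' Idealized HLA class I groove torsions
#'
#' A fixed set of 9 (phi, psi) pairs approximating the extended,
#' slightly-bulged conformation a nonamer adopts in the HLA class I
#' groove: extended polyproline-II-like ends and a central bulge. Used to
#' build comparable idealized backbones for paired peptides.
#'
#' @return A 9 x 2 matrix of torsions in degrees.
#' @export
hla_groove_torsions <- function() {
  matrix(c(
    -120, 140,   # 1 extended N-terminal anchor region
    -130, 150,   # 2 anchor
    -140, 155,   # 3
    -85,  120,   # 4 start of central bulge
    -70,  -30,   # 5 bulge
    -75,  -20,   # 6 bulge
    -90,  110,   # 7
    -130, 150,   # 8
    -120, 140    # 9 C-terminal anchor
  ), ncol = 2, byrow = TRUE)
}
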