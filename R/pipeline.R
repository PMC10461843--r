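#' Default end-to-end run configuration
#'
#' Nested parameter list for [run_all()]: karyotype geometry, read
#' simulation, k-mer discovery thresholds and profile rendering. All values
#' have the package defaults; override individual entries before passing the
#' config on.
#'
#' @param seed integer master seed; every stage derives its own stream from
#'   it, so one seed fixes the whole run.
#' @return a `run_config` list.
#' @export
#' @examples
#' cfg <- default_run_config(seed = 7)
#' cfg$discovery$k
default_run_config <- function(seed = 1) {
  structure(
    list(
      seed = as.integer(seed),
      karyotype = list(
        germline_2n = 52L, somatic_2n = 36L,
        e_length = 50000L, retained_length = 100000L
      ),
      dispersed_spacing = 10000,
      reads = list(coverage = 20, read_length = 100L, error_rate = 0.001),
      discovery = list(k = 21L, ratio_threshold = 100,
                       min_germline_count = 10, pseudocount = 1),
      profiles = list(bin_bp = 500L, background_level = 0, noise_sd = 0)
    ),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' Checks structural and numeric sanity; called by [run_all()] and after
#' [load_run_config()].
#'
#' @param config a `run_config` list.
#' @return the config, invisibly; aborts with an informative message on the
#'   first violated constraint.
#' @export
validate_run_config <- function(config) {
  need <- c("seed", "karyotype", "dispersed_spacing", "reads", "discovery",
            "profiles")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    abort(paste("invalid-config: missing entries:",
                paste(missing, collapse = ", ")))
  }
  ky <- config$karyotype
  if (ky$germline_2n %% 2 != 0 || ky$somatic_2n %% 2 != 0) {
    abort("invalid-config: diploid counts must be even")
  }
  if (ky$germline_2n <= ky$somatic_2n) {
    abort("invalid-config: germline_2n must exceed somatic_2n")
  }
  if (ky$e_length < 42000) {
    abort("invalid-config: e_length must be >= 42000 for the pattern layout")
  }
  d <- config$discovery
  if (d$k %% 2 == 0 || d$k < 11 || d$k > 31) {
    abort("invalid-config: k must be odd and in [11, 31]")
  }
  if (d$ratio_threshold < 1) abort("invalid-config: ratio_threshold must be >= 1")
  if (d$min_germline_count < 0) {
    abort("invalid-config: min_germline_count must be >= 0")
  }
  if (d$pseudocount <= 0) abort("invalid-config: pseudocount must be > 0")
  r <- config$reads
  if (r$coverage <= 0) abort("invalid-config: coverage must be > 0")
  if (r$error_rate < 0 || r$error_rate >= 0.5) {
    abort("invalid-config: error_rate must be in [0, 0.5)")
  }
  if (config$profiles$bin_bp < 1) abort("invalid-config: bin_bp must be >= 1")
  if (config$dispersed_spacing < 0) {
    abort("invalid-config: dispersed_spacing must be >= 0")
  }
  invisible(config)
}

#' Save / load a run configuration as YAML
#'
#' The YAML round-trip preserves every parameter value; loading validates
#' the result.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `save_run_config` returns `path` invisibly; `load_run_config`
#'   returns the validated `run_config`.
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  class(config) <- "run_config"
  validate_run_config(config)
  config
}

#' Discover germline-restricted repeat monomers from read sets
#'
#' Chains the discovery stages: canonical k-mer counting of both read sets,
#' germline-enrichment filtering, greedy unitig assembly of the enriched set
#' and monomer inference per contig, with an optional k-mer-depth copy-number
#' estimate.
#'
#' @param germ_reads,soma_reads `read_set`s (or character vectors of reads).
#' @param k odd k-mer size.
#' @param ratio_threshold,min_germline_count,pseudocount see
#'   [enrichment_filter()].
#' @param per_base_coverage germline fold coverage; when given, circular
#'   monomer calls receive an `est_copies` column (see
#'   [estimate_copy_number()]).
#' @param read_length read length for the copy-number edge correction
#'   (optional).
#' @return a `repeat_discovery` list: `enriched` (tibble), `contigs`
#'   (tibble), `monomers` (tibble: `contig`, `circular`, `unit_length`,
#'   `canonical_monomer`, `no_call`, `est_copies`), `k`, plus germline and
#'   somatic table summaries.
#' @export
discover_repeats <- function(germ_reads, soma_reads, k = 21,
                             ratio_threshold = 100, min_germline_count = 10,
                             pseudocount = 1, per_base_coverage = NULL,
                             read_length = NULL) {
  germ_tab <- count_kmers(germ_reads, k)
  soma_tab <- count_kmers(soma_reads, k)
  enriched <- enrichment_filter(germ_tab, soma_tab,
                                ratio_threshold = ratio_threshold,
                                min_germline_count = min_germline_count,
                                pseudocount = pseudocount)
  tab_summary <- function(tab) {
    list(distinct_kmers = nrow(tab), total_kmers = attr(tab, "total_kmers"))
  }
  germ_summary <- tab_summary(germ_tab)
  soma_summary <- tab_summary(soma_tab)
  rm(germ_tab, soma_tab)

  contigs <- assemble_enriched(enriched)
  monomers <- purrr::map(seq_len(nrow(contigs)), function(i) {
    m <- infer_monomer(contigs[i, ])
    m$contig <- contigs$contig[i]
    m$circular <- contigs$circular[i]
    m
  }) |> list_rbind()
  if (nrow(contigs) == 0) {
    monomers <- tibble(unit_length = integer(0),
                       canonical_monomer = character(0),
                       no_call = logical(0), contig = character(0),
                       circular = logical(0))
  }
  monomers <- monomers[, c("contig", "circular", "unit_length",
                           "canonical_monomer", "no_call")]
  if (!is.null(per_base_coverage)) {
    monomers$est_copies <- purrr::map2_dbl(
      monomers$canonical_monomer, monomers$no_call,
      function(m, nc) {
        if (nc) return(NA_real_)
        estimate_copy_number(m, enriched, per_base_coverage, read_length)
      })
  }
  structure(
    list(enriched = enriched, contigs = contigs, monomers = monomers,
         k = as.integer(k), germ_summary = germ_summary,
         soma_summary = soma_summary),
    class = "repeat_discovery"
  )
}

#' @export
print.repeat_discovery <- function(x, ...) {
  called <- x$monomers[!x$monomers$no_call, , drop = FALSE]
  cat(sprintf(
    "repeat_discovery: %d enriched %d-mers, %d contigs, %d monomer call(s)\n",
    nrow(x$enriched), x$k, nrow(x$contigs), nrow(called)))
  if (nrow(called) > 0) {
    cat("unit lengths:", paste(sort(unique(called$unit_length)),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname discover_repeats
#' @param x a `repeat_discovery`.
#' @param ... unused.
#' @export
tidy.repeat_discovery <- function(x, ...) x$monomers

#' @rdname discover_repeats
#' @export
glance.repeat_discovery <- function(x, ...) {
  tibble(
    k = x$k,
    n_enriched_kmers = nrow(x$enriched),
    n_contigs = nrow(x$contigs),
    n_monomer_calls = sum(!x$monomers$no_call),
    n_circular = sum(x$monomers$circular)
  )
}

# the four families modelled on cloned repeats, with their primer-pair names
cloned_family_map <- function() {
  tibble(
    family = c("EEEb7", "EEEb8", "EEEb9", "EEEb10"),
    primer_pair = c("family0", "family38", "family10", "family5")
  )
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates a germline/somatic genome pair with planted repeat arrays, then
#' runs every analysis stage on the simulated data: read simulation and
#' k-mer-based repeat discovery, clone characterization (consensus, GC,
#' divergence, direct repeats, ORFs, germline-vs-somatic substitutions),
#' in-silico PCR ladders, profile rendering plus karyogram classification,
#' and a fiber interspersion test. Every stage draws from a seed stream
#' derived from `config$seed`, so equal configs give identical runs.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param outdir optional directory; when given, FASTA/TSV/JSON artifacts of
#'   each stage are written there.
#' @return an `elimrep_run` list: `config`, `families`, `germline`,
#'   `somatic` (genomes), `discovery`, `clone_reports` (tibble),
#'   `substitutions` (tibble), `ladders` (tibble), `profiles`, `karyogram`,
#'   `fiber`.
#' @export
run_all <- function(config = default_run_config(), outdir = NULL) {
  validate_run_config(config)
  seed <- config$seed
  ky <- config$karyotype

  families <- default_families(seed)
  kc <- karyotype_config(ky$germline_2n, ky$somatic_2n, ky$e_length,
                         ky$retained_length)
  placement <- default_placement(kc, families, seed)
  germ <- build_germline_genome(kc, families, placement, seed,
                                dispersed_spacing = config$dispersed_spacing)
  soma <- derive_somatic_genome(germ)

  r <- config$reads
  germ_reads <- simulate_reads(germ, r$coverage, r$read_length, r$error_rate,
                               seed = child_seed(seed, "germ_reads"))
  soma_reads <- simulate_reads(soma, r$coverage, r$read_length, r$error_rate,
                               seed = child_seed(seed, "soma_reads"))

  d <- config$discovery
  discovery <- discover_repeats(germ_reads, soma_reads, k = d$k,
                                ratio_threshold = d$ratio_threshold,
                                min_germline_count = d$min_germline_count,
                                pseudocount = d$pseudocount,
                                per_base_coverage = r$coverage,
                                read_length = r$read_length)
  rm(germ_reads, soma_reads)

  cloned <- cloned_family_map()
  clone_reports <- purrr::pmap(cloned, function(family, primer_pair) {
    fam <- families[families$name == family, , drop = FALSE]
    purrr::map(c("germline", "somatic"), function(src) {
      n <- if (src == "germline") fam$clone_n_germ else fam$clone_n_soma
      rate <- if (src == "germline") fam$clone_rate_germ else fam$clone_rate_soma
      clones <- sample_clones(fam, src, n, rate,
                              seed = child_seed(seed,
                                                paste("clones", family, src)))
      tidy(characterize_clones(clones))
    }) |> list_rbind()
  }) |> list_rbind()

  substitutions <- purrr::map(cloned$family, function(family) {
    g <- clone_reports$consensus[clone_reports$family == family &
                                   clone_reports$source == "germline"]
    s <- clone_reports$consensus[clone_reports$family == family &
                                   clone_reports$source == "somatic"]
    tibble(family = family, substitutions = as.integer(
      count_substitutions(g, s)))
  }) |> list_rbind()

  primers <- default_primer_pairs()
  ladders <- purrr::pmap(cloned, function(family, primer_pair) {
    fam <- families[families$name == family, , drop = FALSE]
    pair <- primers[primers$name == primer_pair, , drop = FALSE]
    template <- strrep(fam$monomer, 3)
    ladder <- predict_amplicons(template, pair)
    rep <- ladder_report(ladder, fam$unit_length)
    rep$family <- family
    rep$primer_pair <- primer_pair
    rep
  }) |> list_rbind()

  p <- config$profiles
  profiles <- render_fish_profiles(germ, bin_bp = p$bin_bp,
                                   background_level = p$background_level,
                                   noise_sd = p$noise_sd,
                                   seed = child_seed(seed, "profiles"))
  karyogram <- build_karyogram(profiles)

  fiber_chrom <- germ$chromosomes$id[germ$chromosomes$is_eliminated][1]
  fiber_segs <- fiber_segments(germ, fiber_chrom, from = 0, to = 14000)
  fiber <- fiber_interspersion(fiber_segs,
                               seed = child_seed(seed, "fiber"))
  fiber$chromosome <- fiber_chrom

  run <- structure(
    list(config = config, families = families, germline = germ,
         somatic = soma, discovery = discovery,
         clone_reports = clone_reports, substitutions = substitutions,
         ladders = ladders, profiles = profiles, karyogram = karyogram,
         fiber = fiber),
    class = "elimrep_run"
  )
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

#' @export
print.elimrep_run <- function(x, ...) {
  cat("elimrep_run\n")
  print(x$germline)
  print(x$discovery)
  cat(sprintf("karyogram: %d patterns; fiber index %.2f (p = %.3g)\n",
              x$karyogram$n_patterns, x$fiber$index, x$fiber$p_value))
  invisible(x)
}

#' @rdname run_all
#' @param x an `elimrep_run`.
#' @param ... unused.
#' @export
glance.elimrep_run <- function(x, ...) {
  tibble(
    seed = x$config$seed,
    n_chromosomes = nrow(x$germline$chromosomes),
    n_eliminated = sum(x$germline$chromosomes$is_eliminated),
    genome_bp = genome_size(x$germline),
    n_enriched_kmers = nrow(x$discovery$enriched),
    n_contigs = nrow(x$discovery$contigs),
    n_monomer_calls = sum(!x$discovery$monomers$no_call),
    n_patterns = x$karyogram$n_patterns,
    fiber_index = x$fiber$index,
    fiber_p = x$fiber$p_value
  )
}

#' Write the artifacts of a run to a directory
#'
#' Genome FASTA, placement map, enriched k-mers, contigs, monomer calls,
#' profiles, karyogram calls, ladders, run summary JSON and the ground-truth
#' manifest. Read FASTQ is not written (it is large and fully reproducible
#' from the seed).
#'
#' @param run an `elimrep_run`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(outdir, x)
  write_genome_fasta(run$germline, fp("germline.fasta"))
  write_genome_fasta(run$somatic, fp("somatic.fasta"))
  write_placement_bed(run$germline$placement, fp("placement.bed"))
  write_enriched_tsv(run$discovery$enriched, fp("enriched_kmers.tsv"))
  if (nrow(run$discovery$contigs) > 0) {
    write_contigs_fasta(run$discovery$contigs, fp("contigs.fasta"))
  }
  readr::write_tsv(run$discovery$monomers, fp("monomers.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$clone_reports, fp("clone_reports.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$ladders, fp("ladders.tsv"), progress = FALSE)
  write_profiles_tsv(run$profiles, fp("profiles.tsv"))
  readr::write_tsv(tidy(run$karyogram), fp("karyogram.tsv"),
                   progress = FALSE)
  jsonlite::write_json(glance(run), fp("run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_truth_manifest(run$germline, fp("truth.json"))
  invisible(outdir)
}

#' Write the ground-truth manifest of a simulated genome
#'
#' JSON record of everything the simulator planted: karyotype numbers,
#' family panel (monomers, unit lengths, GC, substitution counts), per-family
#' placement totals and the pattern assignment of each E-chromosome pair.
#'
#' @param genome a germline `genome`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(genome, path) {
  placement <- genome$placement
  per_family <- placement |>
    group_by(.data$family) |>
    summarise(
      total_copies = sum(.data$copies),
      n_arrays = sum(.data$kind == "array"),
      n_dispersed = sum(.data$kind == "dispersed"),
      on_retained = any(!startsWith(.data$chromosome_id, "E")),
      .groups = "drop"
    )
  patterns <- placement |>
    filter(.data$kind == "array") |>
    distinct(.data$pair_id, .data$pattern)
  manifest <- list(
    karyotype = list(
      germline_2n = genome$config$germline_2n,
      somatic_2n = genome$config$somatic_2n,
      e_chromosome_count = genome$config$e_chromosome_count,
      e_length = genome$config$e_length,
      retained_length = genome$config$retained_length,
      eliminated_fraction = genome$config$eliminated_fraction_realized
    ),
    families = genome$families[, c("name", "monomer", "somatic_monomer",
                                   "unit_length", "target_gc", "gc",
                                   "dispersed", "planted_substitutions")],
    placement_summary = per_family,
    pattern_assignment = patterns,
    seed = genome$seed
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Rand index between two flat partitions given as label vectors: the
# fraction of element pairs on which the partitions agree (together in both
# or separate in both).
rand_index <- function(x, y) {
  if (length(x) != length(y)) abort("partitions must have equal length")
  if (length(x) < 2) return(1)
  same_x <- outer(x, x, "==")
  same_y <- outer(y, y, "==")
  idx <- upper.tri(same_x)
  mean(same_x[idx] == same_y[idx])
}

#' Score a run against its own ground truth
#'
#' Compares the discovery and karyogram results of an [run_all()] run with
#' what the simulator planted. Planted targets for discovery are the
#' germline-restricted families: those whose placements lie exclusively on
#' eliminated chromosomes (a family also dispersed over retained chromosomes
#' is, correctly, not germline-restricted). A family counts as recovered
#' when some called monomer equals its canonical monomer exactly.
#'
#' @param run an `elimrep_run`.
#' @return one-row tibble: `n_planted`, `n_called`, `recall`, `precision`,
#'   `unit_lengths_exact` (all recovered calls have the planted unit
#'   length), `pattern_rand_index` (karyogram partition of the E-pairs
#'   vs the planted pattern assignment; 1 = identical partition).
#' @export
compare_to_truth <- function(run) {
  stopifnot(inherits(run, "elimrep_run"))
  placement <- run$germline$placement
  on_retained <- placement |>
    group_by(.data$family) |>
    summarise(ret = any(!.data$chromosome_id %in%
                          run$germline$chromosomes$id[
                            run$germline$chromosomes$is_eliminated]),
              .groups = "drop")
  planted <- run$families |>
    filter(.data$name %in% on_retained$family[!on_retained$ret]) |>
    mutate(canonical = vapply(.data$monomer, canonical_monomer,
                              character(1)))

  calls <- run$discovery$monomers |>
    filter(!.data$no_call) |>
    distinct(.data$canonical_monomer, .data$unit_length)
  matched <- planted$canonical %in% calls$canonical_monomer
  recall <- if (nrow(planted) == 0) NA_real_ else mean(matched)
  precision <- if (nrow(calls) == 0) {
    NA_real_
  } else {
    mean(calls$canonical_monomer %in% planted$canonical)
  }
  unit_ok <- all(
    calls$unit_length[match(planted$canonical[matched],
                            calls$canonical_monomer)] ==
      planted$unit_length[matched]
  )

  truth_patterns <- placement |>
    filter(.data$kind == "array") |>
    distinct(.data$pair_id, .data$pattern) |>
    arrange(.data$pair_id)
  kg <- run$karyogram$patterns |> arrange(.data$pair)
  if (!identical(truth_patterns$pair_id, kg$pair)) {
    abort("karyogram pairs do not match the placement pairs")
  }
  rand <- rand_index(truth_patterns$pattern, kg$pattern)

  tibble(
    n_planted = nrow(planted),
    n_called = nrow(calls),
    recall = recall,
    precision = precision,
    unit_lengths_exact = unit_ok,
    pattern_rand_index = rand
  )
}
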