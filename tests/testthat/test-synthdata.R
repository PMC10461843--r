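test_that("karyotype_config does the chromosome bookkeeping and validates", {
  cfg <- karyotype_config(52, 36)
  expect_equal(cfg$e_chromosome_count, 16L)
  expect_gt(cfg$eliminated_fraction_realized, 0)
  expect_error(karyotype_config(51, 36), "even")
  expect_error(karyotype_config(36, 52), "exceed")
})

test_that("make_repeat_family hits length, GC and primitivity, deterministically", {
  f1 <- make_repeat_family("x", 180, 0.35, seed = 11)
  f2 <- make_repeat_family("x", 180, 0.35, seed = 11)
  expect_identical(f1$monomer, f2$monomer)
  expect_equal(nchar(f1$monomer), 180L)
  expect_equal(f1$gc, round(0.35 * 180) / 180)
  # primitive: not an exact tandem of a shorter word
  expect_false(any(vapply(
    setdiff(seq_len(179)[180 %% seq_len(179) == 0], integer(0)),
    function(d) strrep(substr(f1$monomer, 1, d), 180 / d) == f1$monomer,
    logical(1))))
  f3 <- make_repeat_family("y", 180, 0.35, seed = 12)
  expect_false(identical(f1$monomer, f3$monomer))
})

test_that("make_repeat_family embeds fixed segments verbatim", {
  emb <- list(`1` = "ACGTACGTAC", `51` = "GGGGGGGGGG")
  f <- make_repeat_family("x", 60, 0.4, seed = 5, embed = emb)
  expect_identical(substr(f$monomer, 1, 10), "ACGTACGTAC")
  expect_identical(substr(f$monomer, 51, 60), "GGGGGGGGGG")
  expect_error(
    make_repeat_family("x", 20, 0.4, embed = list(`15` = "ACGTACGTAC")),
    "bounds")
})

test_that("mutate_monomer changes exactly n sites and honors protection", {
  set.seed(3)
  m <- rand_seq(100)
  mut <- mutate_monomer(m, 5)
  d <- mapply(`!=`, strsplit(m, NULL)[[1]], strsplit(mut, NULL)[[1]])
  expect_equal(sum(d), 5)
  mut2 <- mutate_monomer(m, 10, protect = 1:50)
  d2 <- which(strsplit(m, NULL)[[1]] != strsplit(mut2, NULL)[[1]])
  expect_true(all(d2 > 50))
})

test_that("default family panel carries the documented unit lengths and flags", {
  fams <- default_families(1)
  expect_equal(fams$name, paste0("EEEb", 1:10))
  expect_equal(fams$unit_length[7:10], c(360L, 47L, 84L, 120L))
  expect_true(fams$dispersed[10])
  expect_false(any(fams$dispersed[1:9]))
  expect_true(fams$is_reference[1])
  # the four cloned analogues embed their primer pairs at the unit boundaries
  primers <- default_primer_pairs()
  map <- c(EEEb7 = "family0", EEEb8 = "family38",
           EEEb9 = "family10", EEEb10 = "family5")
  for (fam in names(map)) {
    p <- primers[primers$name == map[[fam]], ]
    m <- fams$monomer[fams$name == fam]
    expect_true(startsWith(m, p$forward))
    expect_true(endsWith(m, revcomp(p$reverse)))
  }
  # panel is reproducible from the seed
  expect_identical(fams$monomer, default_families(1)$monomer)
})

test_that("default placement is valid, mirror-patterned and pattern-assigned", {
  fams <- default_families(1)
  cfg <- karyotype_config()
  pl <- default_placement(cfg, fams, seed = 1)
  # non-overlap within each chromosome
  by_chrom <- split(pl, pl$chromosome_id)
  for (df in by_chrom) {
    df <- df[order(df$start), ]
    expect_true(all(utils::head(df$end, -1) <= utils::tail(df$start, -1)))
    expect_true(all(df$end <= cfg$e_length))
  }
  expect_setequal(unique(pl$pair_id), paste0("E", 1:8))
  # patterns 1 and 2 each cover two pairs, 3-6 one pair each
  pp <- unique(pl[, c("pair_id", "pattern")])
  expect_equal(sort(as.integer(table(pp$pattern))), c(1L, 1L, 1L, 1L, 2L, 2L))
  # block widths equal copies x unit length
  fam_len <- setNames(fams$unit_length, fams$name)
  expect_true(all(pl$end - pl$start == fam_len[pl$family] * pl$copies))
})

test_that("germline genome splices arrays at the recorded coordinates", {
  fams <- default_families(1)
  cfg <- karyotype_config()
  g <- build_germline_genome(cfg, fams, default_placement(cfg, fams, 1),
                             seed = 1)
  expect_equal(nrow(g$chromosomes), 52L)
  expect_equal(sum(g$chromosomes$is_eliminated), 16L)
  expect_true(all(nchar(g$chromosomes$sequence) == g$chromosomes$length))
  monomers <- setNames(fams$monomer, fams$name)
  rows <- g$placement[g$placement$chromosome_id == "E1a", ]
  seqs <- g$chromosomes$sequence[g$chromosomes$id == "E1a"]
  for (i in sample(nrow(rows), 10)) {
    r <- rows[i, ]
    expected <- strrep(monomers[[r$family]], r$copies)
    if (r$orientation == "-") expected <- revcomp(expected)
    expect_identical(substr(seqs, r$start + 1, r$end), expected)
  }
})

test_that("dispersed family reaches retained chromosomes; others do not", {
  fams <- default_families(1)
  cfg <- karyotype_config()
  g <- build_germline_genome(cfg, fams, default_placement(cfg, fams, 1),
                             seed = 1)
  on_ret <- g$placement[startsWith(g$placement$chromosome_id, "S"), ]
  expect_true(nrow(on_ret) > 0)
  expect_setequal(unique(on_ret$family), "EEEb10")
  expect_true(all(on_ret$kind == "dispersed"))
})

test_that("somatic derivation drops E-chromosomes, keeps others byte-identical, idempotent", {
  fams <- default_families(1)
  cfg <- karyotype_config()
  g <- build_germline_genome(cfg, fams, default_placement(cfg, fams, 1),
                             seed = 1)
  s <- derive_somatic_genome(g)
  expect_equal(nrow(s$chromosomes), 36L)
  expect_false(any(s$chromosomes$is_eliminated))
  keep <- !g$chromosomes$is_eliminated
  expect_identical(s$chromosomes$sequence, g$chromosomes$sequence[keep])
  s2 <- derive_somatic_genome(s)
  expect_identical(s2$chromosomes, s$chromosomes)
})

test_that("simulated error-free reads are genuine genome substrings", {
  fams <- default_families(1)
  cfg <- karyotype_config(44, 40, e_length = 50000, retained_length = 50000)
  pl <- default_placement(cfg, fams, 1)
  pl <- pl[pl$pair_id %in% paste0("E", 1:2), ]
  # a tiny two-pair genome for speed
  expect_error(elimrep:::validate_placement(pl), NA)
  g <- build_germline_genome(karyotype_config(40, 36, 50000, 50000), fams,
                             pl, seed = 2)
  rs <- simulate_reads(g, coverage = 0.5, read_length = 80, error_rate = 0,
                       seed = 4)
  expect_equal(nchar(rs$reads$sequence[1]), 80L)
  expect_equal(nrow(rs$reads),
               round(0.5 * genome_size(g) / 80))
  idx <- sample(nrow(rs$reads), 20)
  hay <- c(g$chromosomes$sequence, revcomp(g$chromosomes$sequence))
  for (r in rs$reads$sequence[idx]) {
    expect_true(any(vapply(hay, function(h) grepl(r, h, fixed = TRUE),
                           logical(1))))
  }
})

test_that("FASTQ round-trips a read set", {
  set.seed(1)
  rs <- list(reads = tibble::tibble(
    id = sprintf("r%02d", 1:5),
    sequence = vapply(1:5, function(i) rand_seq(50), character(1)),
    quality = strrep("I", 50)
  ), read_length = 50L, coverage = 1, error_rate = 0, seed = 1L)
  class(rs) <- "read_set"
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rs, path)
  back <- read_fastq(path)
  expect_identical(back$reads$sequence, rs$reads$sequence)
  expect_identical(back$reads$id, rs$reads$id)
})

test_that("truth manifest records the planted panel", {
  fams <- default_families(1)
  cfg <- karyotype_config()
  g <- build_germline_genome(cfg, fams, default_placement(cfg, fams, 1),
                             seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(g, path)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(manifest$karyotype$e_chromosome_count, 16)
  expect_equal(nrow(manifest$families), 10)
  expect_equal(sort(manifest$pattern_assignment$pattern),
               c(1, 1, 2, 2, 3, 4, 5, 6))
  expect_true(manifest$placement_summary$on_retained[
    manifest$placement_summary$family == "EEEb10"])
})
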