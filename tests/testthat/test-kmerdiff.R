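test_that("count_kmers matches a hand-computed table and validates k", {
  # read ACGTACGTACGT (12 bp), k = 11 -> windows ACGTACGTACG, CGTACGTACGT;
  # canonical forms: ACGTACGTACG vs revcomp CGTACGTACGT -> ACGTACGTACG;
  # CGTACGTACGT vs revcomp ACGTACGTACG -> ACGTACGTACG: one k-mer, count 2
  tab <- count_kmers("ACGTACGTACGT", k = 11)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$kmer, "ACGTACGTACG")
  expect_equal(tab$count, 2)
  expect_equal(attr(tab, "total_kmers"), 2)
  expect_error(count_kmers("ACGT", k = 12), "odd")
  expect_error(count_kmers("ACGT", k = 9), "11")
})

test_that("count_kmers is strand-canonical and skips non-ACGT", {
  set.seed(7)
  reads <- vapply(1:30, function(i) rand_seq(60), character(1))
  a <- count_kmers(reads, k = 13)
  b <- count_kmers(revcomp(reads), k = 13)
  expect_identical(a$kmer, b$kmer)
  expect_identical(a$count, b$count)
  # N breaks a read into two windowsless fragments here
  withN <- count_kmers("ACGTACGTACGTNACGTACGTACGT", k = 21)
  expect_equal(nrow(withN), 0L)
  # every reported k-mer is its own canonical form
  expect_identical(a$kmer, pmin(a$kmer, revcomp(a$kmer)))
})

test_that("enrichment filter implements the scaled ratio with floor", {
  set.seed(21)
  shared <- rand_seq(400)
  germ_only <- rand_seq(400)
  germ <- count_kmers(c(rep(shared, 10), rep(germ_only, 12)), k = 15)
  soma <- count_kmers(rep(shared, 10), k = 15)
  enr <- enrichment_filter(germ, soma, ratio_threshold = 5,
                           min_germline_count = 10, pseudocount = 1)
  # only germ-only k-mers survive; each occurs 12 times >= floor
  expect_true(all(enr$soma_count == 0))
  expect_true(all(enr$germ_count >= 10))
  scale <- attr(germ, "total_kmers") / attr(soma, "total_kmers")
  joined <- merge(as.data.frame(germ), as.data.frame(soma), by = "kmer",
                  all.x = TRUE)
  joined$count.y[is.na(joined$count.y)] <- 0
  expected <- joined$kmer[
    joined$count.x / (joined$count.y * scale + 1) >= 5 & joined$count.x >= 10]
  expect_setequal(enr$kmer, expected)
  # shared k-mers have ratio near 1 and are excluded
  expect_false(any(count_kmers(shared, 15)$kmer %in% enr$kmer))
})

test_that("assembly turns a pure tandem array into one circular contig", {
  set.seed(5)
  fam <- make_repeat_family("u", 90, 0.45, seed = 31)
  reads <- reads_from_template(strrep(fam$monomer, 150), coverage = 30)
  soma <- vapply(1:100, function(i) rand_seq(100), character(1))
  enr <- enrichment_filter(count_kmers(reads, 21), count_kmers(soma, 21),
                           ratio_threshold = 50, min_germline_count = 5)
  contigs <- assemble_enriched(enr)
  expect_equal(nrow(contigs), 1L)
  expect_true(contigs$circular[1])
  expect_equal(contigs$length[1], 90L)
  call <- infer_monomer(contigs[1, ])
  expect_equal(call$unit_length, 90L)
  expect_identical(call$canonical_monomer, canonical_monomer(fam$monomer))
})

test_that("monomer calls are rotation- and strand-invariant", {
  set.seed(6)
  fam <- make_repeat_family("u", 84, 0.4, seed = 32)
  rot <- paste0(substr(fam$monomer, 31, 84), substr(fam$monomer, 1, 30))
  soma <- vapply(1:100, function(i) rand_seq(100), character(1))
  soma_tab <- count_kmers(soma, 21)
  call_of <- function(template) {
    reads <- reads_from_template(template, coverage = 30)
    enr <- enrichment_filter(count_kmers(reads, 21), soma_tab,
                             ratio_threshold = 50, min_germline_count = 5)
    contigs <- assemble_enriched(enr)
    infer_monomer(contigs[1, ])
  }
  a <- call_of(strrep(fam$monomer, 120))
  b <- call_of(strrep(rot, 120))
  c <- call_of(revcomp(strrep(fam$monomer, 120)))
  expect_identical(a$canonical_monomer, b$canonical_monomer)
  expect_identical(a$canonical_monomer, c$canonical_monomer)
  expect_equal(a$unit_length, 84L)
})

test_that("linear contigs without two full units are no-calls", {
  call <- infer_monomer(list(sequence = "ACGTGGTCAATCGGATTACAGGTT",
                             circular = FALSE))
  expect_true(call$no_call)
  expect_true(is.na(call$unit_length))
  # two full units are enough
  unit <- "ACGTGGTCAATCGGATTACAGGTT"
  call2 <- infer_monomer(list(sequence = strrep(unit, 2), circular = FALSE))
  expect_false(call2$no_call)
  expect_equal(call2$unit_length, nchar(unit))
})

test_that("copy number estimate recovers the planted copy count", {
  set.seed(8)
  fam <- make_repeat_family("u", 120, 0.4, seed = 33)
  copies <- 200
  reads <- reads_from_template(strrep(fam$monomer, copies), coverage = 40)
  soma <- vapply(1:100, function(i) rand_seq(100), character(1))
  enr <- enrichment_filter(count_kmers(reads, 21), count_kmers(soma, 21),
                           ratio_threshold = 50, min_germline_count = 5)
  est <- estimate_copy_number(fam$monomer, enr, per_base_coverage = 40,
                              read_length = 100)
  expect_lt(abs(est - copies) / copies, 0.1)
  # without the edge correction the estimate is biased low by (R-k+1)/R
  raw <- estimate_copy_number(fam$monomer, enr, per_base_coverage = 40)
  expect_equal(raw, est * (100 - 21 + 1) / 100)
})

test_that("string period helpers behave on knowns", {
  expect_equal(smallest_period("ACGACGACG"), 3L)
  expect_equal(smallest_period("ACGTT"), 5L)
  expect_equal(minimal_rotation("GTAC"), "ACGT")
  expect_identical(canonical_monomer("GTAC"),
                   canonical_monomer(revcomp("GTAC")))
})
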