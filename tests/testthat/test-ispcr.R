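test_that("primer sites require an exact 3' anchor and tolerate mismatches elsewhere", {
  set.seed(61)
  primer <- "ACGTACGGTTCAGATCAGGT"
  template <- paste0(rand_seq(40), primer, rand_seq(40))
  hits <- find_primer_sites(template, primer, max_mismatch = 0)
  expect_equal(hits$position, 41L)
  expect_equal(hits$strand, "+")
  # two mismatches outside the anchor are tolerated
  mm <- primer
  substr(mm, 2, 2) <- "T"; substr(mm, 5, 5) <- "C"
  expect_equal(find_primer_sites(template, mm, max_mismatch = 2)$position,
               41L)
  expect_equal(nrow(find_primer_sites(template, mm, max_mismatch = 1)), 0L)
  # a single mismatch inside the 5-base 3' anchor kills the site
  anchor_mm <- primer
  substr(anchor_mm, 19, 19) <- "C"
  expect_equal(nrow(find_primer_sites(template, anchor_mm,
                                      max_mismatch = 2)), 0L)
})

test_that("minus-strand sites are found at the correct plus-strand position", {
  set.seed(62)
  primer <- "TGGATCAGGTACCAGTTCAG"
  template <- paste0(rand_seq(30), revcomp(primer), rand_seq(25))
  hits <- find_primer_sites(template, primer)
  expect_equal(hits$strand, "-")
  expect_equal(hits$position, 31L)
})

test_that("a three-copy tandem template yields the unit ladder", {
  fams <- default_families(1)
  primers <- default_primer_pairs()
  fam0 <- primers[primers$name == "family0", ]
  template <- strrep(fams$monomer[fams$name == "EEEb7"], 3)
  ladder <- predict_amplicons(template, fam0)
  expect_equal(ladder$band_bp[1:2], c(360L, 720L))
  rep <- ladder_report(ladder, 360)
  expect_equal(rep$label[1:3], c("monomer", "dimer", "trimer"))
  expect_equal(rep$n_units[1:3], 1:3)
})

test_that("consecutive ladder bands on pure arrays differ by the unit length", {
  fams <- default_families(1)
  primers <- default_primer_pairs()
  pairs <- list(c("EEEb8", "family38"), c("EEEb9", "family10"),
                c("EEEb10", "family5"))
  for (p in pairs) {
    fam <- fams[fams$name == p[1], ]
    pr <- primers[primers$name == p[2], ]
    ladder <- predict_amplicons(strrep(fam$monomer, 5), pr)
    expect_gt(nrow(ladder), 2)
    expect_true(all(diff(ladder$band_bp) == fam$unit_length))
    expect_equal(ladder$band_bp[1], fam$unit_length)
  }
})

test_that("off-ladder products are labelled variant", {
  rep <- ladder_report(
    tibble::tibble(band_bp = c(120L, 190L, 240L), fwd_site = 1L,
                   rev_site = 1L), unit_length = 120)
  expect_equal(rep$label, c("monomer", "variant", "dimer"))
  expect_true(is.na(rep$n_units[2]))
})

test_that("degenerate inputs give empty ladders and clear errors", {
  set.seed(63)
  template <- rand_seq(500)
  pair <- list(forward = "ACGGATTACAGGACCAGTTA",
               reverse = "TTGACCAGGATTTACAGGCA")
  ladder <- predict_amplicons(template, pair)
  expect_s3_class(ladder, "amplicon_ladder")
  expect_equal(nrow(ladder), 0L)
  expect_equal(nrow(ladder_report(ladder, 100)), 0L)
  expect_error(predict_amplicons(template,
                                 list(forward = "ACGT", reverse = pair$reverse)),
               "15-30")
  expect_error(ladder_report(ladder, 0), "unit_length")
})
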