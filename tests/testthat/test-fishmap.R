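test_that("segment_signal thresholds, zero rule and min-run filtering", {
  x <- c(rep(0, 20), rep(5, 4), rep(0, 20))
  seg <- segment_signal(x)
  expect_equal(seg$threshold, 0)
  expect_equal(which(seg$mask), 21:24)
  expect_equal(seg$runs$start_bin, 21L)
  expect_equal(seg$runs$end_bin, 24L)
  # an isolated single-bin spike is removed
  y <- c(rep(0, 10), 5, rep(0, 10))
  expect_false(any(segment_signal(y)$mask))
  # with background, the threshold is median + 3 MAD of the low bins;
  # the fixed background stays strictly below median + 3 MAD
  bg <- rep(c(0.9, 1, 1.1, 1), 20)
  z <- c(bg[1:40], rep(10, 6), bg[41:80])
  seg2 <- segment_signal(z)
  low <- z[z <= quantile(z, 0.75)]
  expect_equal(seg2$threshold, median(low) + 3 * mad(low))
  expect_equal(which(seg2$mask), 41:46)
  expect_error(segment_signal(1:5), ">= 10")
})

test_that("overlap_fraction is the in-mask share of target mass", {
  mask <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(overlap_fraction(c(rep(2, 5), rep(1, 5)), mask), 10 / 15)
  expect_equal(overlap_fraction(rep(0, 10), mask), 0)
  expect_error(overlap_fraction(1:3, mask), "grids")
})

test_that("classification boundary table is exact at the cut-offs", {
  # clean zero-background profiles (threshold exactly 0): fraction f of the
  # target mass lies inside the reference mask (bins 1-10)
  reference <- c(rep(1, 10), rep(0, 190))
  # integer per-bin masses keep the overlap fraction exact in floating point
  make_target <- function(f) {
    inside <- round(100 * f)
    c(rep(inside, 10), rep(100 - inside, 10), rep(0, 180))
  }
  cases <- tibble::tribble(
    ~f, ~call,
    0.34, "peripheral",
    0.35, "half_overlapping",
    0.59, "half_overlapping",
    0.60, "largely_overlapping",
    0.89, "largely_overlapping",
    0.90, "coincident"
  )
  for (i in seq_len(nrow(cases))) {
    got <- classify_localization(make_target(cases$f[i]), reference)
    expect_equal(as.character(got$call), cases$call[i],
                 label = paste("fraction", cases$f[i]))
    expect_equal(got$overlap, cases$f[i], tolerance = 1e-12)
  }
})

test_that("absent and dispersed calls trigger on their rules", {
  reference <- c(rep(1, 20), rep(0, 80))
  # total below the detection floor -> absent
  weak <- rep(0.0001, 100)
  expect_equal(as.character(
    classify_localization(weak * 0, reference)$call), "absent")
  # flat genome-wide haze (as rendered for sub-resolution dispersed copies)
  # -> dispersed: threshold > 0, most bins positive, no bin reaching twice
  # the threshold
  haze <- rep(2, 100)
  got <- classify_localization(haze, reference)
  expect_equal(as.character(got$call), "dispersed")
})

test_that("symmetry score separates mirrored from one-sided profiles", {
  two_sided <- c(rep(1, 10), rep(0, 30), rep(1, 10))
  expect_equal(symmetry_score(two_sided), 1)
  one_sided <- c(rep(1, 10), rep(0, 40))
  expect_lt(symmetry_score(one_sided), 0)
  expect_equal(symmetry_score(rep(3, 20)), 0)
})

test_that("noise-free karyogram recovers the planted partition exactly", {
  fams <- default_families(1)
  cfg <- karyotype_config()
  g <- build_germline_genome(cfg, fams, default_placement(cfg, fams, 1),
                             seed = 1)
  profiles <- render_fish_profiles(g)
  kg <- build_karyogram(profiles)
  expect_equal(kg$n_patterns, 6L)
  truth <- unique(g$placement[g$placement$kind == "array",
                              c("pair_id", "pattern")])
  truth <- truth[order(truth$pair_id), ]
  got <- kg$patterns[order(kg$patterns$pair), ]
  # same partition (pattern ids may be relabelled)
  expect_equal(elimrep:::rand_index(truth$pattern, got$pattern), 1)
  # reference probe is coincident with itself everywhere
  ref_calls <- tidy(kg)
  ref_calls <- ref_calls[ref_calls$probe == "EEEb1", ]
  expect_true(all(ref_calls$call == "coincident"))
  # pattern 6 pairs (one-sided layout) are flagged asymmetric on the reference
  asym <- tidy(kg)
  asym <- asym[asym$probe == "EEEb1", ]
  expect_equal(sum(!asym$symmetric), 1L)
})

test_that("profile rendering conserves probe mass on clean settings", {
  fams <- default_families(1)
  cfg <- karyotype_config()
  g <- build_germline_genome(cfg, fams, default_placement(cfg, fams, 1),
                             seed = 1)
  profiles <- render_fish_profiles(g, probes = "EEEb2")
  bin_bp <- attr(profiles, "bin_bp")
  placed <- sum((g$placement$end - g$placement$start)[
    g$placement$family == "EEEb2"])
  expect_equal(sum(profiles$intensity) * bin_bp, placed, tolerance = 1e-8)
})

test_that("fiber interspersion separates alternating from blocked layouts", {
  # ten alternating segments: maximal index, significant
  alt <- tibble::tibble(probe = rep(c("A", "B"), 5),
                        start = seq(0, 90, by = 10),
                        end = seq(10, 100, by = 10))
  res <- fiber_interspersion(alt, n_permutations = 2000, seed = 1)
  expect_equal(res$index, 1)
  expect_lte(res$p_value, 0.05)
  # fully blocked: minimal index, not significant
  blk <- tibble::tibble(probe = rep(c("A", "B"), each = 5),
                        start = seq(0, 90, by = 10),
                        end = seq(10, 100, by = 10))
  res2 <- fiber_interspersion(blk, n_permutations = 2000, seed = 1)
  expect_equal(res2$index, 1 / 9)
  expect_gt(res2$p_value, 0.5)
  # fewer than two probes with >= 2 segments: no-call
  res3 <- fiber_interspersion(
    tibble::tibble(probe = c("A", "A", "B"), start = c(0, 20, 10),
                   end = c(5, 25, 15)))
  expect_true(is.na(res3$index))
})
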