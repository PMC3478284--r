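test_that("synthetic_spec enforces its invariants", {
  expect_error(synthetic_spec(c(1, 0.5), class_weights = c(.5, .5)),
               "increasing")
  expect_error(synthetic_spec(c(-1, 0.5), class_weights = c(.5, .5)),
               "positive")
  expect_error(synthetic_spec(c(0.5, 1), class_weights = c(.6, .6)),
               "sum to 1")
  expect_error(synthetic_spec(0.5, class_weights = 1, cv = 1.2), "cv")
  expect_error(synthetic_spec(0.5, class_weights = 1, n = 0), "n must be")
  expect_error(preset_cytotype("no_such_row"), "unknown preset")
})

test_that("degenerate dispersion collapses all areas onto the centre", {
  spec <- synthetic_spec(0.5, class_weights = 1, cv = 1e-6, n = 5, seed = 1)
  rec <- sample_nuclei(spec)
  expect_equal(nrow(rec), 5L)
  expect_equal(rec$area, rep(0.5, 5), tolerance = 1e-4)
})

test_that("sampling is reproducible from the seed and seeds differ", {
  spec <- preset_cytotype("taxifolia_frond", seed = 7)
  expect_identical(sample_nuclei(spec), sample_nuclei(spec))
  spec2 <- preset_cytotype("taxifolia_frond", seed = 8)
  expect_false(identical(sample_nuclei(spec)$area, sample_nuclei(spec2)$area))
})

test_that("class membership follows the mixture weights", {
  spec <- synthetic_spec(c(0.5, 1.0), class_weights = c(0.9, 0.1),
                         cv = 0.1, n = 10000, seed = 42)
  rec <- sample_nuclei(spec)
  expect_equal(nrow(rec), 10000L)
  frac <- mean(rec$class_index == 1L)
  # analytic 99% binomial interval around 0.9 at n = 10^4
  half <- qnorm(0.995) * sqrt(0.9 * 0.1 / 10000)
  expect_gt(frac, 0.9 - half)
  expect_lt(frac, 0.9 + half)
})

test_that("published presets carry the printed class structure", {
  tx <- preset_cytotype("taxifolia_frond")
  expect_equal(tx$class_centers, c(0.55, 1.12))
  expect_equal(tx$class_counts, c(123L, 29L))
  expect_equal(tx$n, 152L)
  gm <- preset_cytotype("prolifera_gametes")
  expect_equal(gm$class_centers, c(0.49, 0.88))
  expect_equal(gm$class_counts, c(18L, 8L))
  sf <- preset_cytotype("prolifera_sterile_frond")
  expect_equal(sf$class_centers, c(1.07, 2.29, 3.67, 7.54))
  expect_equal(sf$n, 452L)
  expect_equal(sf$multipliers, c(4L, 8L, 16L, 32L))
  # every preset constructs a valid spec and cvs are sd/mean
  for (nm in cytotype_presets()) {
    sp <- preset_cytotype(nm)
    expect_s3_class(sp, "synthetic_spec")
    expect_true(all(sp$cv > 0 & sp$cv < 1))
  }
})

test_that("empirical class means converge to the spec centres", {
  spec <- synthetic_spec(c(1.07, 2.29), class_weights = c(0.9, 0.1),
                         cv = c(0.35, 0.10), n = 10000, seed = 11)
  rec <- sample_nuclei(spec)
  for (k in 1:2) {
    v <- rec$area[rec$class_index == k]
    se <- sd(v) / sqrt(length(v))
    # truncation at zero shifts the widest class by well under 1 SE here
    expect_lt(abs(mean(v) - spec$class_centers[k]), 3 * se + 0.01)
  }
})

test_that("preset regeneration at printed n reproduces Table-style rows", {
  rec <- sample_nuclei(preset_cytotype("prolifera_sterile_frond", seed = 5))
  expect_equal(nrow(rec), 452L)
  for (k in seq_along(c(1.07, 2.29, 3.67, 7.54))) {
    v <- rec$area[rec$class_index == k]
    if (length(v) >= 5) {
      ctr <- c(1.07, 2.29, 3.67, 7.54)[k]
      se <- sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - ctr), 3 * se + 0.01)
    }
  }
})
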