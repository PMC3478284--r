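test_that("class boundaries sit at geometric means with geometric outer bounds", {
  b <- class_boundaries(c(0.5, 1.0))
  expect_equal(b[2], sqrt(0.5), tolerance = 1e-9)  # 0.7071
  b3 <- class_boundaries(c(1, 2, 4))
  expect_equal(b3[2:3], c(sqrt(2), sqrt(8)), tolerance = 1e-9)
  expect_equal(class_boundaries(0.8), c(0, Inf))
  expect_error(class_boundaries(c(1, 1)), "increasing")
  expect_error(class_boundaries(numeric()), "at least one")
})

test_that("the Cx unit is anchored at half the gamete G1 peak", {
  expect_equal(estimate_unit(rep(0.5, 30)), 0.25, tolerance = 1e-9)
  rec <- sample_nuclei(synthetic_spec(0.5, class_weights = 1, cv = 0.16,
                                      n = 1000, seed = 13))
  expect_lt(abs(estimate_unit(rec$area) - 0.25), 0.01)
  # G2 nuclei sharpen the estimate instead of corrupting it
  rec2 <- sample_nuclei(synthetic_spec(c(0.5, 1.0), class_weights = c(.7, .3),
                                       cv = 0.16, n = 1000, seed = 13))
  expect_lt(abs(estimate_unit(rec2$area) - 0.25), 0.01)
  expect_error(estimate_unit(numeric()), "gamete")
})

test_that("doubling-family choice separates triploid from diploid series", {
  f3 <- choose_doubling_family(c(0.70, 1.33), unit = 0.25)
  expect_equal(f3$base, 3)
  f2 <- choose_doubling_family(c(0.55, 1.12), unit = 0.25)
  expect_equal(f2$base, 2)
  # a lone rhizoid G1 at 0.57 reads as diploid in isolation but as
  # triploid in the context of its sibling portions
  alone <- choose_doubling_family(0.57, unit = 0.245)
  expect_equal(alone$base, 2)
  pooled <- choose_doubling_family(list(c(0.70, 1.33), c(0.76, 1.47), 0.57),
                                   unit = 0.245)
  expect_equal(pooled$base, 3)
})

test_that("assign_classes applies half-open geometric boundaries", {
  pop <- toy_population(c(0.5, 0.72, 1.0), c(2L, 4L), c(0.5, 1.0))
  expect_equal(pop$records$cx, c(2L, 4L, 4L))
  # all areas at one centre occupy a single class
  one <- toy_population(rep(0.5, 7), c(2L, 4L), c(0.5, 1.0))
  expect_equal(sum(one$classes$n > 0), 1L)
  expect_equal(one$classes$n[one$classes$cx == 2L], 7L)
})

test_that("class counts are conserved and every record is classified once", {
  for (seed in 1:20) {
    set.seed(seed)
    areas <- rlnorm(150, log(1), 0.6)
    model <- ploidy_series_model(0.25, c(2L, 4L, 8L),
                                 centers = c(0.5, 1.0, 2.0))
    pop <- assign_classes(tibble::tibble(area = areas), model)
    expect_equal(sum(pop$classes$n), 150L)
    expect_false(anyNA(pop$records$cx))
  }
})

test_that("assignment equals brute-force nearest centre in log space", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(10:200, 1)
    centers <- c(0.5, 1.0, 2.0, 4.0)
    areas <- exp(runif(n, log(0.4), log(5)))
    model <- ploidy_series_model(0.25, c(2L, 4L, 8L, 16L),
                                 centers = centers)
    pop <- assign_classes(tibble::tibble(area = areas), model)
    oracle <- c(2L, 4L, 8L, 16L)[
      apply(abs(outer(log(areas), log(centers), `-`)), 1, which.min)]
    expect_identical(pop$records$cx, oracle)
  }
})

test_that("assignments are equivariant under a common rescaling", {
  set.seed(5)
  areas <- rlnorm(100, log(0.9), 0.5)
  base <- assign_classes(tibble::tibble(area = areas),
                         ploidy_series_model(0.25, c(2L, 4L, 8L),
                                             centers = c(0.5, 1, 2)))
  for (k in c(0.5, 3)) {
    scaled <- assign_classes(
      tibble::tibble(area = k * areas),
      ploidy_series_model(k * 0.25, c(2L, 4L, 8L),
                          centers = k * c(0.5, 1, 2)))
    expect_identical(scaled$records$cx, base$records$cx)
  }
})

test_that("rare large nuclei found extension classes only near the grid", {
  model <- ploidy_series_model(0.25, c(2L, 4L), centers = c(0.5, 1.0))
  pop <- assign_classes(tibble::tibble(area = c(0.5, 1.0, 2.05)), model)
  expect_equal(sort(pop$classes$cx[pop$classes$n > 0]), c(2L, 4L, 8L))
  expect_equal(pop$classes$origin[pop$classes$cx == 8L], "extension")
  # far off any predicted level: flagged, kept in the nearest class
  pop2 <- assign_classes(tibble::tibble(area = c(0.5, 1.0, 2.9)), model)
  expect_equal(sort(pop2$classes$cx[pop2$classes$n > 0]), c(2L, 4L))
  expect_equal(pop2$records$flag[3], "out_of_series")
  # well below the G1 class: stays in it, flagged
  pop3 <- assign_classes(tibble::tibble(area = c(0.5, 1.0, 0.2)), model)
  expect_equal(pop3$records$cx[3], 2L)
  expect_equal(pop3$records$flag[3], "below_series")
})

test_that("overlap splitting sends each half to one class", {
  # boundary at sqrt(0.5) ~ 0.707; records straddle it inside +/-10%
  areas <- c(rep(0.5, 10), rep(1.0, 10), 0.66, 0.68, 0.72, 0.74)
  pop <- toy_population(areas, c(2L, 4L), c(0.5, 1.0))
  split <- split_overlap(pop, 2L, 4L, overlap = 0.1)
  in_zone <- which(areas >= sqrt(0.5) / 1.1 & areas <= sqrt(0.5) * 1.1)
  got <- split$records$cx[in_zone]
  expect_equal(got[order(areas[in_zone])], c(2L, 2L, 4L, 4L))
  expect_equal(sum(split$classes$n), length(areas))
  # five records: floor(5/2) = 2 go low, 3 go high
  areas5 <- c(rep(0.5, 10), rep(1.0, 10), 0.65, 0.68, 0.70, 0.73, 0.76)
  pop5 <- toy_population(areas5, c(2L, 4L), c(0.5, 1.0))
  split5 <- split_overlap(pop5, 2L, 4L, overlap = 0.1)
  zone5 <- 21:25
  expect_equal(split5$records$cx[zone5][order(areas5[zone5])],
               c(2L, 2L, 4L, 4L, 4L))
  expect_error(split_overlap(pop, 2L, 8L), "adjacent")
})

test_that("cytotypes are inferred from the lowest occupied class", {
  # triploid: G1 at 0.70 with unit 0.25
  tri <- toy_population(c(rep(0.70, 30), rep(1.4, 8)), c(3L, 6L),
                        c(0.70, 1.40))
  prof <- infer_cytotype(tri)
  expect_equal(prof$base_multiplier, 3L)
  expect_equal(prof$ploidy, "triploid")
  expect_equal(prof$dominant_phase, "haplophasic")
  expect_false(prof$endopolyploid)

  # two classes only: no endopolyploidy (the diploid invader pattern)
  dip <- toy_population(c(rep(0.55, 20), rep(1.12, 6)), c(2L, 4L),
                        c(0.55, 1.12))
  expect_false(infer_cytotype(dip)$endopolyploid)

  # four somatic classes: endopolyploid, diplophasic tetraploid
  tet <- toy_population(c(rep(1.07, 30), rep(2.29, 8), rep(3.67, 4),
                          rep(7.54, 2)),
                        c(4L, 8L, 16L, 32L), c(1.07, 2.29, 3.67, 7.54))
  ptet <- infer_cytotype(tet)
  expect_equal(ptet$base_multiplier, 4L)
  expect_true(ptet$endopolyploid)
  expect_equal(ptet$dominant_phase, "diplophasic")
})

test_that("an unplaceable lowest class raises an unresolved-cytotype error", {
  # with only doubling multipliers allowed, a G1 at 0.7 units x 2.8 cannot
  # be reconciled with any level
  model <- ploidy_series_model(0.25, c(2L), centers = 0.70,
                               allowed = c(2, 4, 8), scale = 1)
  pop <- assign_classes(tibble::tibble(area = rep(0.70, 10)), model)
  expect_error(infer_cytotype(pop), "unresolved cytotype")
})

test_that("phase attribution pairs each G2 with a G1 at half its level", {
  pop <- toy_population(c(rep(0.5, 12), rep(1.0, 5)), c(2L, 4L),
                        c(0.5, 1.0))
  cls <- pop$classes
  expect_equal(cls$phase[cls$cx == 2L], "G1")
  expect_equal(cls$phase[cls$cx == 4L], "G2")
  for (i in which(cls$phase == "G2")) {
    expect_true((cls$cx[i] / 2) %in% cls$cx[cls$n > 0])
  }
})

test_that("species-level analysis recovers structure from pooled portions", {
  recs <- generate_presets(1)
  an <- suppressWarnings(analyze_cytotypes(recs))
  expect_equal(nrow(an$group_profiles), 4L)
  bases <- an$group_profiles$base_multiplier[
    order(an$group_profiles$group)]
  expect_equal(bases, c(2L, 4L, 3L, 2L))
  expect_equal(sum(vapply(an$populations, function(p) nrow(p$records), 0L)),
               nrow(recs))
})
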