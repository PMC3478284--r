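test_that("group summaries report n, mean and n-1 sd", {
  rec <- tibble::tibble(area = c(0.4, 0.6, 1.0),
                        species = c("a", "a", "b"))
  sm <- summarize_groups(rec, species)
  expect_equal(sm$mean[sm$species == "a"], 0.5)
  expect_equal(sm$sd[sm$species == "a"], sqrt(0.02), tolerance = 1e-9)
  expect_equal(sm$n, c(2L, 1L))
})

test_that("one-way ANOVA matches the direct-formula oracle", {
  brute <- function(groups) {
    all <- unlist(groups)
    gm <- mean(all)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
    dfb <- length(groups) - 1
    dfw <- length(all) - length(groups)
    f <- (ssb / dfb) / (ssw / dfw)
    list(ssb = ssb, ssw = ssw, f = f)
  }
  # SS_between = 3(2-3.5)^2 + 3(5-3.5)^2 = 13.5, MS_within = 1
  hand <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(hand$f, 13.5, tolerance = 1e-12)
  expect_equal(hand$table$sum_sq[1], 13.5, tolerance = 1e-12)
  for (seed in 1:20) {
    set.seed(seed)
    groups <- lapply(1:3, function(i) rnorm(sample(5:30, 1), i * 0.2, 1))
    a <- one_way_anova(groups)
    o <- brute(groups)
    expect_equal(a$f, o$f, tolerance = 1e-9)
    tb <- a$table
    # decomposition identity
    expect_equal(tb$sum_sq[3], tb$sum_sq[1] + tb$sum_sq[2],
                 tolerance = 1e-9)
    expect_equal(tb$df[3], sum(lengths(groups)) - 1)
  }
  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(1:3, 5)), "two observations")
})

test_that("identical groups give F equal to zero", {
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$f, 0,
               tolerance = 1e-12)
})

test_that("published ANOVA tables rebuild their own arithmetic", {
  t2 <- anova_from_summary(93.7443, 3, 131.887, 2546)
  expect_equal(t2$table$mean_sq[1], 31.2481, tolerance = 1e-6)
  expect_equal(round(t2$f, 2), 603.23)
  t3 <- anova_from_summary(126.513, 3, 775.6, 3152)
  expect_equal(round(t3$f, 2), 171.38)
  expect_lt(t3$p, 1e-4)
})

test_that("pooled t tests match the direct formula and its df rule", {
  brute_t <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }
  for (seed in 1:10) {
    set.seed(seed)
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), 0.3)
    tt <- two_sample_t(a, b)
    expect_equal(tt$t, brute_t(a, b), tolerance = 1e-12)
    expect_equal(tt$df, length(a) + length(b) - 2)
  }
  same <- c(1, 2, 3, 4)
  tt <- two_sample_t(same, same)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  # both constant with equal means: defined as t = 0, not an error
  zz <- two_sample_t(rep(2, 5), rep(2, 7))
  expect_equal(zz$t, 0)
  # Welch uses fewer (fractional) degrees of freedom
  set.seed(1)
  a <- rnorm(20, sd = 3); b <- rnorm(8, sd = 0.5)
  expect_lt(two_sample_t(a, b, pooled = FALSE)$df, 26)
})

test_that("F equals t squared for two groups", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- rnorm(15); b <- rnorm(22, 0.4)
    f <- one_way_anova(list(a, b))$f
    t <- two_sample_t(a, b)$t
    expect_equal(f, t^2, tolerance = 1e-9)
  }
})

test_that("minimum-genome and first-level extraction follow class structure", {
  pop <- toy_population(c(rep(0.5, 6), rep(1.0, 3), rep(2.0, 2)),
                        c(2L, 4L, 8L), c(0.5, 1.0, 2.0))
  expect_equal(nrow(extract_min_genome(pop)), 6L)
  expect_equal(nrow(extract_first_level(pop)), 9L)
  single <- toy_population(rep(0.5, 5), c(2L, 4L), c(0.5, 1.0))
  expect_equal(nrow(extract_min_genome(single)), 5L)
  expect_equal(nrow(extract_min_genome(list(pop, single))), 11L)
})

test_that("published per-class counts reconstruct the sample-size arithmetic", {
  # G1-only sterile thallus subset
  g1 <- sum(vapply(c("prolifera_sterile_frond", "prolifera_sterile_stolon",
                     "prolifera_sterile_rhizoid"),
                   function(nm) unname(preset_class_counts(nm)[1]), 0L))
  expect_equal(g1, 791L)
  expect_equal(preset_first_level_count("taxifolia_frond"), 152L)
  expect_equal(preset_first_level_count("prolifera_repro_frond"), 810L)
  expect_equal(preset_first_level_count("prolifera_sterile_frond"), 427L)
})
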