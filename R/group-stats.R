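#' Per-group summaries of nuclear areas
#'
#' Mean, standard deviation (denominator n − 1) and count per group, the
#' cells of a genome-size summary table.
#'
#' @param records Data frame with an `area` column.
#' @param ... Grouping columns (tidy-select style), e.g. `species, portion`.
#' @return Tibble with the grouping columns plus `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(records, ...) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    warning("no records to summarise")
    return(tibble::tibble(n = integer(), mean = numeric(), sd = numeric()))
  }
  dplyr::summarise(
    dplyr::group_by(records, ...),
    n = dplyr::n(),
    mean = mean(.data$area),
    sd = stats::sd(.data$area),
    .groups = "drop"
  )
}

as_population_list <- function(pops) {
  if (inherits(pops, "classified_population")) pops <- list(pops)
  if (!all(vapply(pops, inherits, NA, "classified_population"))) {
    stop("expected classified_population objects")
  }
  pops
}

#' Extract the minimum-genome-size (G1-only) subset
#'
#' The minimum genome size of a sample is carried by the nuclei at G1 in
#' the first (lowest) occupied ploidy class; this extracts those records
#' from one or more classified populations.
#'
#' @param pops A `classified_population` or a list of them.
#' @return Tibble of the G1 records of the lowest occupied class of each
#'   population.
#' @export
extract_min_genome <- function(pops) {
  pops <- as_population_list(pops)
  dplyr::bind_rows(lapply(pops, function(p) {
    if (is.null(p$records$phase)) stop("population lacks phase attribution")
    occ <- p$classes$cx[p$classes$n > 0]
    p$records[p$records$cx == min(occ), , drop = FALSE]
  }))
}

#' Extract the first ploidy level (G1 plus its replicated G2 class)
#'
#' @inheritParams extract_min_genome
#' @return Tibble of the records in the lowest occupied class and the
#'   class at twice its Cx value.
#' @export
extract_first_level <- function(pops) {
  pops <- as_population_list(pops)
  dplyr::bind_rows(lapply(pops, function(p) {
    if (is.null(p$records$phase)) stop("population lacks phase attribution")
    occ <- p$classes$cx[p$classes$n > 0]
    m1 <- min(occ)
    p$records[p$records$cx %in% c(m1, 2 * m1), , drop = FALSE]
  }))
}

#' One-way fixed-effects analysis of variance
#'
#' Classical decomposition of the total sum of squares into between- and
#' within-group components, with the F statistic referred to the F
#' distribution on (df between, df within).
#'
#' @param groups Named or unnamed list of at least two numeric vectors,
#'   each with at least two observations.
#' @return An object of class `anova_result`: a list with `table` (rows
#'   Between groups / Within groups / Total, columns sum of squares, df,
#'   mean square, F, p), and scalars `f`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("supply at least two groups")
  }
  if (any(vapply(groups, length, 0L) < 2L)) {
    stop("every group needs at least two observations")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 0L)))
  )
  a <- stats::anova(stats::lm(value ~ g, data = df))
  ss_b <- a$`Sum Sq`[1]; ss_w <- a$`Sum Sq`[2]
  df_b <- a$Df[1]; df_w <- a$Df[2]
  structure(
    list(
      table = tibble::tibble(
        source = c("Between groups", "Within groups", "Total"),
        sum_sq = c(ss_b, ss_w, ss_b + ss_w),
        df = c(df_b, df_w, df_b + df_w),
        mean_sq = c(ss_b / df_b, ss_w / df_w, NA),
        f = c(a$`F value`[1], NA, NA),
        p = c(a$`Pr(>F)`[1], NA, NA)
      ),
      f = a$`F value`[1], p = a$`Pr(>F)`[1],
      df_between = df_b, df_within = df_w
    ),
    class = "anova_result"
  )
}

#' Rebuild an ANOVA table from its printed summary cells
#'
#' Reconstructs mean squares, the F ratio and the p value from the sums of
#' squares and degrees of freedom printed in a published one-way ANOVA
#' table, for checking a table's internal arithmetic.
#'
#' @param ss_between,df_between,ss_within,df_within Printed cells.
#' @return An `anova_result`.
#' @export
anova_from_summary <- function(ss_between, df_between, ss_within, df_within) {
  ms_b <- ss_between / df_between
  ms_w <- ss_within / df_within
  f <- ms_b / ms_w
  p <- stats::pf(f, df_between, df_within, lower.tail = FALSE)
  structure(
    list(
      table = tibble::tibble(
        source = c("Between groups", "Within groups", "Total"),
        sum_sq = c(ss_between, ss_within, ss_between + ss_within),
        df = c(df_between, df_within, df_between + df_within),
        mean_sq = c(ms_b, ms_w, NA),
        f = c(f, NA, NA),
        p = c(p, NA, NA)
      ),
      f = f, p = p, df_between = df_between, df_within = df_within
    ),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' Two-sample t test on nuclear areas
#'
#' Student's pooled-variance t test by default (every published df in the
#' genome-size comparisons equals n1 + n2 − 2); Welch's unequal-variance
#' form by flag. Two identical constant samples return t = 0, p = 1
#' rather than an error.
#'
#' @param a,b Numeric vectors, each with at least two observations.
#' @param pooled Use the pooled-variance (Student) form.
#' @return List of class `t_test_result`: `t`, `df`, `p`, `pooled`,
#'   `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b, pooled = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least two observations")
  }
  res <- tryCatch(
    stats::t.test(a, b, var.equal = pooled),
    error = function(e) {
      if (grepl("constant", conditionMessage(e)) &&
          isTRUE(all.equal(mean(a), mean(b)))) {
        list(statistic = c(t = 0),
             parameter = c(df = length(a) + length(b) - 2L),
             p.value = 1)
      } else {
        stop(e)
      }
    }
  )
  structure(
    list(t = unname(res$statistic), df = unname(res$parameter),
         p = res$p.value, pooled = pooled,
         mean_a = mean(a), mean_b = mean(b)),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t test: t = %.4f, df = %s, p = %.4g\n",
              if (x$pooled) "Pooled" else "Welch", x$t,
              format(x$df), max(x$p, .Machine$double.xmin)))
  invisible(x)
}
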