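#' Specification of a synthetic nucleus-area population
#'
#' A `synthetic_spec` describes a mixture of nuclear size classes from which
#' per-nucleus areas are drawn: one truncated-at-zero normal component per
#' class, parameterised by a class centre (mean area, µm²) and a coefficient
#' of variation. The mixture emulates the doubling-series structure of
#' DNA-content histograms, where successive classes correspond to successive
#' ploidy levels and the G1/G2 phases of the cell cycle.
#'
#' @param class_centers Numeric vector of class mean areas (µm²), strictly
#'   positive and strictly increasing.
#' @param class_weights Mixture proportions, same length as
#'   `class_centers`; must sum to 1 (within 1e-9). Alternatively supply
#'   `class_counts` and the weights are derived.
#' @param cv Coefficient of variation per class (recycled if scalar); each
#'   value must lie strictly inside (0, 1).
#' @param n Total number of nuclei to draw (>= 1).
#' @param seed Integer seed making the draw reproducible.
#' @param labels Named list of metadata attached to every record: `species`,
#'   `portion` (one of `"frond"`, `"stolon"`, `"rhizoid"`, `"gamete"`),
#'   `individual`, `location`, `reproductive` (logical).
#' @param class_counts Optional integer vector of per-class counts (as
#'   printed in a summary table); used to derive `class_weights` when those
#'   are missing and kept as metadata for count arithmetic.
#' @param multipliers Optional integer Cx multipliers labelling each class
#'   (generating ground truth for parameter-recovery checks).
#'
#' @return An object of class `synthetic_spec`.
#' @seealso [sample_nuclei()], [preset_cytotype()]
#' @export
synthetic_spec <- function(class_centers,
                           class_weights = NULL,
                           cv = 0.15,
                           n = 100L,
                           seed = 1L,
                           labels = list(),
                           class_counts = NULL,
                           multipliers = NULL) {
  k <- length(class_centers)
  if (k < 1L) stop("at least one class centre is required")
  if (any(!is.finite(class_centers)) || any(class_centers <= 0)) {
    stop("class centres must be strictly positive")
  }
  if (k > 1L && any(diff(class_centers) <= 0)) {
    stop("class centres must be strictly increasing")
  }
  if (is.null(class_weights)) {
    if (is.null(class_counts)) stop("supply class_weights or class_counts")
    class_weights <- class_counts / sum(class_counts)
  }
  if (length(class_weights) != k) {
    stop("class_weights must match class_centers in length")
  }
  if (abs(sum(class_weights) - 1) > 1e-9 || any(class_weights < 0)) {
    stop("class_weights must be non-negative and sum to 1 (within 1e-9)")
  }
  cv <- rep_len(cv, k)
  if (any(cv <= 0) || any(cv >= 1)) stop("cv values must lie in (0, 1)")
  if (!is_number(n) || n < 1 || n != round(n)) stop("n must be an integer >= 1")
  if (!is.null(multipliers) && length(multipliers) != k) {
    stop("multipliers must match class_centers in length")
  }
  defaults <- list(species = NA_character_, portion = NA_character_,
                   individual = NA_character_, location = NA_character_,
                   reproductive = NA)
  labels <- utils::modifyList(defaults, as.list(labels))
  structure(
    list(class_centers = as.numeric(class_centers),
         class_weights = as.numeric(class_weights),
         class_counts = class_counts,
         cv = cv,
         n = as.integer(n),
         seed = as.integer(seed),
         labels = labels,
         multipliers = multipliers),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>", x$n, "nuclei,", length(x$class_centers),
      "classes\n")
  cat("  centers (um^2):", paste(signif(x$class_centers, 4), collapse = ", "),
      "\n")
  cat("  weights       :", paste(signif(x$class_weights, 4), collapse = ", "),
      "\n")
  if (!is.null(x$multipliers)) {
    cat("  Cx levels     :", paste(x$multipliers, collapse = ", "), "\n")
  }
  invisible(x)
}

# Published per-portion summaries of the three Mediterranean Caulerpa
# species (class counts, class mean areas in um^2 and their SDs, Cx levels).
# Where a single-nucleus class has no SD, the cv of the nearest class of the
# same row is imputed at spec construction.
caulerpa_preset_table <- function() {
  row <- function(name, species, portion, reproductive, mult, counts, means, sds) {
    tibble::tibble(preset = name, species = species, portion = portion,
                   reproductive = reproductive,
                   multipliers = list(mult), counts = list(counts),
                   means = list(means), sds = list(sds))
  }
  dplyr::bind_rows(
    row("prolifera_gametes", "C. prolifera", "gamete", TRUE,
        c(2L, 4L), c(18L, 8L), c(0.49, 0.88), c(0.08, 0.08)),
    row("prolifera_repro_frond", "C. prolifera", "frond", TRUE,
        c(2L, 4L, 8L, 16L), c(517L, 293L, 51L, 9L),
        c(0.51, 0.97, 1.96, 3.72), c(0.10, 0.21, 0.37, 0.75)),
    row("prolifera_sterile_frond", "C. prolifera", "frond", FALSE,
        c(4L, 8L, 16L, 32L), c(389L, 38L, 22L, 3L),
        c(1.07, 2.29, 3.67, 7.54), c(0.37, 0.23, 0.30, 1.29)),
    row("prolifera_sterile_stolon", "C. prolifera", "stolon", FALSE,
        c(4L, 8L), c(238L, 7L), c(0.86, 1.71), c(0.23, 0.17)),
    row("prolifera_sterile_rhizoid", "C. prolifera", "rhizoid", FALSE,
        c(4L, 8L), c(164L, 32L), c(1.00, 1.75), c(0.28, 0.31)),
    row("racemosa_frond", "C. racemosa var. cylindracea", "frond", FALSE,
        c(3L, 6L, 12L), c(390L, 43L, 1L), c(0.70, 1.33, 2.94),
        c(0.18, 0.14, NA_real_)),
    row("racemosa_stolon", "C. racemosa var. cylindracea", "stolon", FALSE,
        c(3L, 6L), c(380L, 29L), c(0.76, 1.47), c(0.18, 0.25)),
    row("racemosa_rhizoid", "C. racemosa var. cylindracea", "rhizoid", FALSE,
        c(3L, 6L), c(192L, 13L), c(0.57, 1.34), c(0.16, 0.29)),
    row("taxifolia_frond", "C. taxifolia", "frond", FALSE,
        c(2L, 4L), c(123L, 29L), c(0.55, 1.12), c(0.11, 0.14)),
    row("taxifolia_stolon", "C. taxifolia", "stolon", FALSE,
        c(2L, 4L), c(157L, 10L), c(0.54, 1.14), c(0.15, 0.12))
  )
}

#' Names of the bundled Caulerpa cytotype presets
#'
#' One preset per published species x thallus-portion row (gametes,
#' reproductive and sterile *C. prolifera*, *C. racemosa* var.
#' *cylindracea*, *C. taxifolia*).
#'
#' @return Character vector of preset names accepted by [preset_cytotype()].
#' @export
cytotype_presets <- function() caulerpa_preset_table()$preset

#' Build the synthetic spec for a published cytotype preset
#'
#' Converts one published species/portion summary row (per-class nucleus
#' counts and class mean (SD) areas) into a [synthetic_spec()]: class
#' centres are the printed class means, mixture weights the printed counts,
#' and dispersions the printed SDs converted to coefficients of variation
#' (sd/mean). A single-nucleus class with no printed SD inherits the cv of
#' the nearest class in the same row.
#'
#' @param name Preset name; see [cytotype_presets()].
#' @param seed Seed stored in the returned spec.
#' @param n Total count; defaults to the printed row total.
#' @return A [synthetic_spec()].
#' @export
preset_cytotype <- function(name, seed = 1L, n = NULL) {
  tab <- caulerpa_preset_table()
  i <- match(name, tab$preset)
  if (is.na(i)) {
    stop(sprintf("unknown preset '%s'; see cytotype_presets()", name))
  }
  means <- tab$means[[i]]
  sds <- tab$sds[[i]]
  counts <- tab$counts[[i]]
  cv <- sds / means
  if (any(is.na(cv))) {
    for (j in which(is.na(cv))) {
      ok <- which(!is.na(cv))
      cv[j] <- cv[ok[which.min(abs(ok - j))]]
    }
  }
  synthetic_spec(
    class_centers = means,
    class_counts = counts,
    cv = cv,
    n = n %||% sum(counts),
    seed = seed,
    labels = list(species = tab$species[i], portion = tab$portion[i],
                  individual = tab$preset[i], location = "Mediterranean",
                  reproductive = tab$reproductive[i]),
    multipliers = tab$multipliers[[i]]
  )
}

#' Draw a synthetic nucleus-area population
#'
#' Class membership is multinomial with the spec's mixture weights; each
#' area is then drawn from its class's truncated-at-zero normal
#' distribution (mean = class centre, sd = cv x centre). The draw is fully
#' reproducible from `spec$seed` and does not disturb the caller's RNG.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with one row per nucleus: `area` (µm²), the metadata
#'   columns `species`, `portion`, `individual`, `location`,
#'   `reproductive`, and the generating ground truth `class_index` /
#'   `cx_true` (NA when the spec carries no multipliers).
#' @export
sample_nuclei <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("`spec` must be a synthetic_spec object")
  }
  k <- length(spec$class_centers)
  with_seed(spec$seed, {
    cls <- sample.int(k, spec$n, replace = TRUE, prob = spec$class_weights)
    mu <- spec$class_centers[cls]
    sd <- spec$cv[cls] * mu
    area <- rnorm_pos(spec$n, mu, sd)
    tibble::tibble(
      area = area,
      species = spec$labels$species,
      portion = spec$labels$portion,
      individual = spec$labels$individual,
      location = spec$labels$location,
      reproductive = spec$labels$reproductive,
      class_index = cls,
      cx_true = if (is.null(spec$multipliers)) NA_integer_ else
        spec$multipliers[cls]
    )
  })
}
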