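#' Configuration of a full cytometry-analysis run
#'
#' @param presets Character vector of synthetic preset names (see
#'   [cytotype_presets()]) to generate and analyse.
#' @param images Optional character vector of image paths to quantify
#'   instead of / in addition to presets; requires `pixel_scale`.
#' @param pixel_scale µm/pixel for image quantification.
#' @param unit µm² per Cx. `NULL` anchors the unit in gamete records
#'   (exactly one unit source: explicit value or gamete anchoring).
#' @param bin_width Histogram bin width (µm²).
#' @param multipliers Allowed Cx multipliers.
#' @param overlap Overlap-splitting half-width (0 disables).
#' @param seed Root seed; every stochastic stage derives its stream from
#'   it.
#' @param out_dir Output directory; `NULL` writes nothing.
#' @return A `run_config` object.
#' @export
run_config <- function(presets = cytotype_presets(), images = NULL,
                       pixel_scale = NULL, unit = NULL, bin_width = 0.1,
                       multipliers = c(2, 3, 4, 6, 8, 12, 16, 32),
                       overlap = 0.1, seed = 1L, out_dir = NULL) {
  if (!is.null(images) && is.null(pixel_scale)) {
    stop("image inputs require a pixel_scale")
  }
  if (length(presets) == 0L && is.null(images)) {
    stop("nothing to analyse: supply presets or images")
  }
  unknown <- setdiff(presets, cytotype_presets())
  if (length(unknown)) {
    stop("unknown presets: ", paste(unknown, collapse = ", "))
  }
  structure(
    list(presets = presets, images = images, pixel_scale = pixel_scale,
         unit = unit,
         unit_source = if (is.null(unit)) "gamete" else "explicit",
         bin_width = bin_width, multipliers = multipliers,
         overlap = overlap, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Generates (or quantifies) nucleus records, infers the ploidy series and
#' cytotypes, and produces the published-style statistical comparisons:
#' the species x portion class-summary table, the minimum-genome-size
#' (G1-only) one-way ANOVA across species/phase groups, the full-data
#' ANOVA, and pooled t tests of the reproductive frond's first ploidy
#' level against each sterile species' frond first level. The run is
#' idempotent given the seed.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `config`, `unit`, `records`, `analysis`
#'   (see [analyze_cytotypes()]), `table1`, `anova_min_genome`,
#'   `anova_full`, `t_tests`, `counts` (per-stage record counts).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  counts <- list()
  records <- list()
  for (i in seq_along(config$presets)) {
    nm <- config$presets[i]
    spec <- preset_cytotype(nm, seed = config$seed + i)
    rec <- sample_nuclei(spec)
    rec$sample <- nm
    records[[nm]] <- rec
    log_stage("simulate", nm, nrow(rec))
  }
  for (path in config$images %||% character()) {
    img <- read_field_image(path)
    rec <- measure_population(img, config$pixel_scale,
                              metadata = list(sample = basename(path)))
    records[[basename(path)]] <- rec
    log_stage("quantify", basename(path), nrow(rec))
  }
  records <- dplyr::bind_rows(records)
  counts$input <- nrow(records)

  analysis <- analyze_cytotypes(records, unit = config$unit,
                                multipliers = config$multipliers,
                                bin_width = config$bin_width,
                                overlap = config$overlap)
  counts$classified <- sum(vapply(analysis$populations,
                                  function(p) nrow(p$records), 0L))
  log_stage("classify", "all samples", counts$classified)

  pops <- analysis$populations
  meta <- dplyr::distinct(records[c("sample", "species", "portion",
                                    "reproductive")])
  somatic_samples <- unique(meta$sample[meta$portion != "gamete"])

  g1 <- extract_min_genome(pops)
  g1 <- g1[g1$portion != "gamete", ]
  g1_groups <- split(g1$area, paste(g1$species,
                                    ifelse(g1$reproductive, "reproductive",
                                           "sterile")))
  anova_min <- if (length(g1_groups) >= 2L) one_way_anova(g1_groups) else NULL
  counts$min_genome <- nrow(g1)
  log_stage("stats", "minimum genome size", nrow(g1))

  all_groups <- split(records$area,
                      paste(records$species,
                            ifelse(records$reproductive, "reproductive",
                                   "sterile")))
  anova_full <- if (length(all_groups) >= 2L) one_way_anova(all_groups) else
    NULL

  t_tests <- pipeline_t_tests(pops, meta)
  counts$t_tests <- nrow(t_tests)

  report <- structure(
    list(config = config, unit = analysis$unit, records = records,
         analysis = analysis,
         table1 = write_table1_report(pops),
         anova_min_genome = anova_min, anova_full = anova_full,
         t_tests = t_tests, counts = counts),
    class = "run_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

log_stage <- function(stage, what, n) {
  message(sprintf("[%s] %s: %d records", stage, what, n))
}

# Pooled t tests of the reproductive frond first ploidy level against each
# sterile species' frond first level.
pipeline_t_tests <- function(pops, meta) {
  ref_sample <- meta$sample[meta$portion == "frond" & meta$reproductive]
  if (length(ref_sample) != 1L) {
    return(tibble::tibble(comparison = character(), t = numeric(),
                          df = numeric(), p = numeric(),
                          n_ref = integer(), n = integer()))
  }
  ref <- extract_first_level(pops[[ref_sample]])
  rows <- list()
  sterile_fronds <- meta$sample[meta$portion == "frond" & !meta$reproductive]
  for (s in sterile_fronds) {
    x <- extract_first_level(pops[[s]])
    tt <- two_sample_t(ref$area, x$area, pooled = TRUE)
    rows[[s]] <- tibble::tibble(
      comparison = paste(ref_sample, "vs", s),
      t = tt$t, df = tt$df, p = tt$p,
      n_ref = nrow(ref), n = nrow(x)
    )
  }
  dplyr::bind_rows(rows)
}

#' Render the species x portion class-summary table
#'
#' One row per classified population: total nucleus count with the
#' per-class breakdown in the published `"total (n1:n2:...)"` format,
#' followed by one `"mean (sd)"` column per Cx level, ordered by
#' increasing Cx.
#'
#' @param pops A `classified_population`, a list of them, or the
#'   `populations` element of [analyze_cytotypes()].
#' @param path Optional TSV output path.
#' @return A tibble (invisibly written to `path` when given).
#' @export
write_table1_report <- function(pops, path = NULL) {
  pops <- as_population_list(pops)
  all_cx <- sort(unique(unlist(lapply(pops, function(p) {
    p$classes$cx[p$classes$n > 0]
  }))))
  rows <- lapply(seq_along(pops), function(i) {
    p <- pops[[i]]
    occ <- p$classes[p$classes$n > 0, ]
    get1 <- function(nm) {
      if (nm %in% names(p$records)) p$records[[nm]][1] else NA_character_
    }
    row <- tibble::tibble(
      sample = names(pops)[i] %||% get1("sample") %||% paste0("pop", i),
      species = get1("species"),
      portion = get1("portion"),
      nuclei = sprintf("%d (%s)", sum(occ$n), paste(occ$n, collapse = ":"))
    )
    for (m in all_cx) {
      j <- match(m, occ$cx)
      row[[sprintf("%dCx", m)]] <- if (is.na(j)) "-" else if
      (is.na(occ$sd[j])) sprintf("%.2f", occ$mean[j]) else
        sprintf("%.2f (%.2f)", occ$mean[j], occ$sd[j])
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

# serialisable machine-readable summary (stable across identical runs)
report_json <- function(report) {
  prof <- report$analysis$profiles
  prof$classes <- vapply(prof$classes, paste, "", collapse = ",")
  gprof <- report$analysis$group_profiles
  gprof$classes <- vapply(gprof$classes, paste, "", collapse = ",")
  jsonlite::toJSON(list(
    seed = report$config$seed,
    presets = report$config$presets,
    unit = report$unit,
    n_records = nrow(report$records),
    counts = report$counts,
    profiles = prof,
    group_profiles = gprof,
    anova_min_genome = if (!is.null(report$anova_min_genome))
      report$anova_min_genome$table,
    anova_full = if (!is.null(report$anova_full)) report$anova_full$table,
    t_tests = report$t_tests,
    package_version = as.character(utils::packageVersion("areaPloidy"))
  ), auto_unbox = TRUE, digits = 10, na = "null")
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$records, file.path(out_dir, "nuclei.csv"),
                   row.names = FALSE)
  classified <- dplyr::bind_rows(lapply(report$analysis$populations,
                                        function(p) p$records))
  utils::write.csv(classified, file.path(out_dir, "classified.csv"),
                   row.names = FALSE)
  write_table1_report(report$analysis$populations,
                      file.path(out_dir, "table1.tsv"))
  if (!is.null(report$anova_min_genome)) {
    utils::write.table(format_anova(report$anova_min_genome),
                       file.path(out_dir, "anova_min_genome.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$anova_full)) {
    utils::write.table(format_anova(report$anova_full),
                       file.path(out_dir, "anova_full.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$t_tests, file.path(out_dir, "t_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report_json(report), file.path(out_dir, "report.json"))
  invisible(out_dir)
}

# table shaped like the published ANOVA tables; p floored at machine
# precision rather than printed as an impossible exact zero
format_anova <- function(a) {
  tb <- a$table
  tibble::tibble(
    source = tb$source,
    `Sum of squares` = signif(tb$sum_sq, 6),
    Df = tb$df,
    `Mean square` = signif(tb$mean_sq, 6),
    F = signif(tb$f, 5),
    `P value` = ifelse(is.na(tb$p), NA,
                       sprintf("%.4f", pmax(tb$p, .Machine$double.xmin)))
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$config$seed, "-", nrow(x$records),
      "nuclei,", nrow(x$analysis$group_profiles), "cytotypes\n")
  print(x$analysis$group_profiles)
  invisible(x)
}

# --- published-count arithmetic helpers -----------------------------------

#' Per-class counts of a published preset row
#'
#' @param name Preset name.
#' @return Named integer vector of per-class counts, names = Cx level.
#' @export
preset_class_counts <- function(name) {
  tab <- caulerpa_preset_table()
  i <- match(name, tab$preset)
  if (is.na(i)) stop("unknown preset: ", name)
  stats::setNames(tab$counts[[i]], tab$multipliers[[i]])
}

#' First-ploidy-level count of a published preset row
#'
#' Number of nuclei in the lowest class plus its replicated (2x Cx) class,
#' the denominator of the published first-level t tests.
#'
#' @param name Preset name.
#' @return Integer count.
#' @export
preset_first_level_count <- function(name) {
  cc <- preset_class_counts(name)
  m <- as.integer(names(cc))
  sum(cc[m %in% c(m[1], 2 * m[1])])
}
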