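# Shared fixture builders (everything is generated in code).

# regenerate every preset at printed n with seeds derived from one root
generate_presets <- function(root_seed) {
  dplyr::bind_rows(lapply(seq_along(cytotype_presets()), function(i) {
    nm <- cytotype_presets()[i]
    rec <- sample_nuclei(preset_cytotype(nm, seed = root_seed + i))
    rec$sample <- nm
    rec
  }))
}

# a small classified population with known class membership
toy_population <- function(areas, multipliers, centers, unit = 0.25) {
  model <- ploidy_series_model(unit, multipliers, centers = centers)
  assign_classes(tibble::tibble(area = areas), model)
}

# render one field and score nucleus detection against ground truth
score_field <- function(seed, n_nuclei = 20, n_chloroplasts = 3,
                        n_bacteria = 8) {
  rec <- sample_nuclei(synthetic_spec(c(0.8, 1.6), class_weights = c(.7, .3),
                                      cv = 0.2, n = n_nuclei, seed = seed))
  fs <- field_spec(n_chloroplasts = n_chloroplasts, n_bacteria = n_bacteria,
                   seed = seed)
  fld <- render_field(rec, fs)
  det <- classify_objects(detect_objects(fld$image, fs$pixel_scale))
  gtn <- fld$truth[fld$truth$category == "nucleus", ]
  nuc <- det[det$category == "nucleus", ]
  tp <- 0L
  errs <- numeric()
  for (i in seq_len(nrow(gtn))) {
    d <- sqrt((nuc$x - gtn$x[i])^2 + (nuc$y - gtn$y[i])^2)
    if (length(d) && min(d) < gtn$radius_px[i]) {
      tp <- tp + 1L
      j <- which.min(d)
      errs <- c(errs, abs(nuc$area_um2[j] - gtn$area_um2[i]) /
                  gtn$area_um2[i])
    }
  }
  list(recall = tp / nrow(gtn), precision = tp / max(nrow(nuc), 1L),
       area_err = mean(errs), detections = det, truth = fld$truth)
}
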