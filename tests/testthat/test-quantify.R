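test_that("blank or constant images yield an empty detection table", {
  expect_equal(nrow(detect_objects(matrix(0, 64, 64), 0.1)), 0L)
  expect_equal(nrow(detect_objects(matrix(0.3, 64, 64), 0.1)), 0L)
})

test_that("noise-free fields are detected completely and accurately", {
  rec <- tibble::tibble(area = c(0.7, 1.2, 2.4))
  fs <- field_spec(seed = 3, noise_sd = 0)
  fld <- render_field(rec, fs)
  det <- detect_objects(fld$image, fs$pixel_scale)
  expect_equal(nrow(det), 3L)
  got <- sort(det$area_um2)
  want <- sort(fld$truth$area_um2)
  expect_true(all(abs(got - want) / want < 0.05))
})

test_that("detection holds precision, recall and area accuracy with confounders", {
  sc <- lapply(1:5, score_field)
  expect_true(all(vapply(sc, `[[`, 0, "recall") >= 0.95))
  expect_true(all(vapply(sc, `[[`, 0, "precision") >= 0.95))
  expect_lt(mean(vapply(sc, `[[`, 0, "area_err")), 0.05)
})

test_that("classification follows the morphological rule table", {
  obj <- function(d, h, p) {
    tibble::tibble(equiv_diameter_um = d, homogeneity = h,
                   peripheral_ratio = p)
  }
  expect_equal(classify_object(obj(2, 0.9, 0.8)), "nucleus")
  expect_equal(classify_object(obj(3, 0.4, 3.0)), "chloroplast")
  expect_equal(classify_object(obj(0.2, 0.9, 1.0)), "bacterium")
  expect_equal(classify_object(obj(6, 0.9, 0.9)), "unclassified")
  expect_equal(classify_object(obj(2, 0.2, 0.9)), "unclassified")
  expect_error(classify_objects(tibble::tibble(equiv_diameter_um = 2)),
               "missing")
  expect_error(classify_object(obj(2, NA, 0.9)), "missing values")
})

test_that("each detection gets exactly one category", {
  sc <- score_field(6)
  det <- sc$detections
  tab <- table(det$category)
  expect_equal(sum(tab), nrow(det))
  expect_true(all(det$category %in%
                    c("nucleus", "chloroplast", "bacterium", "unclassified")))
})

test_that("calibrated areas are invariant to the pixel scale", {
  rec <- tibble::tibble(area = c(0.8, 1.5, 2.5))
  areas <- lapply(c(0.1, 0.05), function(ps) {
    fld <- render_field(rec, field_spec(pixel_scale = ps, seed = 3))
    sort(measure_population(fld$image, ps)$area)
  })
  expect_equal(length(areas[[1]]), 3L)
  expect_true(all(abs(areas[[1]] - areas[[2]]) / areas[[2]] < 0.02))
})

test_that("measure_population returns nucleus records with metadata", {
  rec <- sample_nuclei(synthetic_spec(1.0, class_weights = 1, cv = 0.15,
                                      n = 3, seed = 8))
  fs <- field_spec(n_chloroplasts = 2, n_bacteria = 5, seed = 8)
  fld <- render_field(rec, fs)
  pop <- measure_population(fld$image, fs$pixel_scale,
                            metadata = list(species = "C. taxifolia",
                                            portion = "frond"))
  expect_equal(nrow(pop), 3L)
  expect_true(all(pop$species == "C. taxifolia"))
  blank <- measure_population(matrix(0, 64, 64), 0.1)
  expect_equal(nrow(blank), 0L)
})
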