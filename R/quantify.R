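#' Detect DAPI-stained objects in a fluorescence field
#'
#' Segments all connected bright objects above an adaptive threshold and
#' measures, for each, the features used downstream to separate nuclei from
#' plastids and bacteria. Background is estimated by a robust global
#' statistic (median + `k` x MAD); each detected object is then locally
#' refined to the half-maximum of its own intensity plateau, which makes
#' the pixel area of a homogeneous object an almost unbiased estimate of
#' its analytic area. Touching objects are separated by watershedding the
#' distance map of the binary mask. Objects touching the image border are
#' discarded because their areas are censored.
#'
#' @param image Numeric matrix in `[0, 1]` (single channel).
#' @param pixel_scale Calibration in µm/pixel (> 0).
#' @param threshold_k Multiplier on the MAD for the global background
#'   threshold.
#' @param min_pixels Minimum object size in pixels; smaller specks are
#'   dropped as noise.
#' @return A tibble with one row per detected object: `object`, centroid
#'   `x`/`y` (pixels), `pixel_area`, `area_um2`
#'   (= pixel_area x pixel_scale²), `equiv_diameter_um`, `mean_intensity`,
#'   `homogeneity` (1 − interior coefficient of variation, clipped to
#'   `[0, 1]`) and `peripheral_ratio` (mean 2-pixel-rim intensity over mean
#'   eroded-interior intensity). An empty or constant image yields a
#'   zero-row tibble.
#' @export
detect_objects <- function(image, pixel_scale, threshold_k = 5,
                           min_pixels = 3L) {
  stop_if_not_number(pixel_scale, "pixel_scale", positive = TRUE)
  img <- unclass(image)
  if (!is.matrix(img)) stop("`image` must be a single-channel matrix")
  empty <- empty_detections()
  if (length(img) == 0L || diff(range(img)) == 0) return(empty)

  bg <- stats::median(img)
  thr <- bg + threshold_k * max(stats::mad(img), 1e-6)
  mask <- img > thr
  if (!any(mask)) return(empty)

  mask <- EBImage::fillHull(mask * 1)
  labels <- EBImage::bwlabel(mask)
  # declared splitting rule: watershed on the distance map of the mask
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = 1.5)
  labels <- if (max(ws) > max(labels)) ws else labels
  labels <- matrix(as.integer(labels), nrow = nrow(img))

  out <- vector("list", max(labels))
  for (lab in seq_len(max(labels))) {
    idx <- which(labels == lab, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    # local refinement: keep pixels above half of the object's plateau
    plateau <- stats::median(img[idx])
    half <- bg + 0.5 * (plateau - bg)
    keep <- img[idx] >= half
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) < min_pixels) next
    # border-touching objects carry censored areas
    if (any(idx[, 1] %in% c(1L, nrow(img))) ||
        any(idx[, 2] %in% c(1L, ncol(img)))) next

    obj_mask <- matrix(0L, nrow(img), ncol(img))
    obj_mask[idx] <- 1L
    filled <- EBImage::fillHull(obj_mask)
    interior <- EBImage::erode(filled, EBImage::makeBrush(5, "disc"))
    rim_idx <- which(filled == 1 & interior == 0)
    int_idx <- which(interior == 1)
    if (length(int_idx) == 0L) {  # too small to erode: whole object
      int_idx <- which(filled == 1)
      rim_idx <- integer()
    }
    int_mean <- mean(img[int_idx])
    homog <- 1 - stats::sd(img[int_idx]) / max(int_mean, 1e-9)
    if (is.na(homog)) homog <- 1
    px_area <- nrow(idx)
    out[[lab]] <- tibble::tibble(
      x = mean(idx[, 2]), y = mean(idx[, 1]),
      pixel_area = px_area,
      area_um2 = px_area * pixel_scale^2,
      equiv_diameter_um = 2 * sqrt(px_area / pi) * pixel_scale,
      mean_intensity = mean(img[idx]),
      homogeneity = min(max(homog, 0), 1),
      peripheral_ratio = if (length(rim_idx))
        mean(img[rim_idx]) / max(int_mean, 1e-9) else 1
    )
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) return(empty)
  out$object <- seq_len(nrow(out))
  dplyr::relocate(out, "object")
}

empty_detections <- function() {
  tibble::tibble(object = integer(), x = numeric(), y = numeric(),
                 pixel_area = integer(), area_um2 = numeric(),
                 equiv_diameter_um = numeric(), mean_intensity = numeric(),
                 homogeneity = numeric(), peripheral_ratio = numeric())
}

#' Classify detected objects as nucleus, chloroplast or bacterium
#'
#' Applies the morphological identification criteria used for DAPI-stained
#' *Caulerpa* preparations: nuclei are homogeneously stained objects whose
#' equivalent diameter lies in the configured nuclear range; chloroplasts
#' carry their DNA signal in the periphery, so a bright rim over a dim core
#' (high peripheral ratio) identifies them regardless of size; bacteria are
#' much smaller than nuclei and are separated on size alone.
#'
#' @param objects Tibble from [detect_objects()] (all feature columns must
#'   be present and populated).
#' @param diameter_range Admissible nuclear equivalent-diameter range (µm).
#' @param homogeneity_min Minimum interior homogeneity for a nucleus.
#' @param peripheral_max Maximum rim/interior intensity ratio for a
#'   nucleus; objects above it are chloroplasts.
#' @return `objects` with a `category` column added (one of `"nucleus"`,
#'   `"chloroplast"`, `"bacterium"`, `"unclassified"`).
#' @export
classify_objects <- function(objects, diameter_range = c(0.6, 4),
                             homogeneity_min = 0.5, peripheral_max = 1.5) {
  needed <- c("equiv_diameter_um", "homogeneity", "peripheral_ratio")
  if (!all(needed %in% names(objects))) {
    stop("objects are missing required features: ",
         paste(setdiff(needed, names(objects)), collapse = ", "))
  }
  if (nrow(objects) > 0 && anyNA(objects[needed])) {
    stop("object features contain missing values")
  }
  d <- objects$equiv_diameter_um
  category <- rep("unclassified", nrow(objects))
  category[objects$peripheral_ratio > peripheral_max] <- "chloroplast"
  is_bact <- category == "unclassified" & d < diameter_range[1]
  category[is_bact] <- "bacterium"
  is_nuc <- category == "unclassified" &
    d >= diameter_range[1] & d <= diameter_range[2] &
    objects$homogeneity >= homogeneity_min &
    objects$peripheral_ratio <= peripheral_max
  category[is_nuc] <- "nucleus"
  objects$category <- category
  objects
}

#' Classify a single detected object
#'
#' @inheritParams classify_objects
#' @param object A one-row data frame (or list coercible to one) with the
#'   features of [detect_objects()].
#' @return A single category string.
#' @export
classify_object <- function(object, diameter_range = c(0.6, 4),
                            homogeneity_min = 0.5, peripheral_max = 1.5) {
  classify_objects(tibble::as_tibble(as.list(object)), diameter_range,
                   homogeneity_min, peripheral_max)$category
}

#' Measure the nucleus population of a fluorescence field
#'
#' Composes detection and classification and returns one record per object
#' classified as a nucleus, carrying the calibrated area and the supplied
#' sample metadata.
#'
#' @inheritParams detect_objects
#' @inheritParams classify_objects
#' @param metadata Named list of metadata columns attached to every record
#'   (e.g. species, portion, individual, location, reproductive).
#' @return A tibble of nucleus records (`area` in µm² plus metadata and the
#'   detection features).
#' @export
measure_population <- function(image, pixel_scale, metadata = list(),
                               diameter_range = c(0.6, 4),
                               homogeneity_min = 0.5, peripheral_max = 1.5,
                               threshold_k = 5) {
  objs <- detect_objects(image, pixel_scale, threshold_k = threshold_k)
  objs <- classify_objects(objs, diameter_range, homogeneity_min,
                           peripheral_max)
  nuc <- objs[objs$category == "nucleus", , drop = FALSE]
  rec <- tibble::tibble(area = nuc$area_um2)
  for (nm in names(metadata)) rec[[nm]] <- metadata[[nm]]
  dplyr::bind_cols(rec, nuc[c("x", "y", "equiv_diameter_um",
                              "mean_intensity", "homogeneity",
                              "peripheral_ratio")])
}
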