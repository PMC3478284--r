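#' Specification of a synthetic fluorescence field
#'
#' Describes the scene rendered by [render_field()]: image geometry, pixel
#' calibration, how many confounding objects accompany the nuclei, and the
#' intensity/noise model. Nuclei are rendered as compact objects with a
#' homogeneously stained interior; chloroplasts as larger bodies whose
#' DNA-containing signal sits in a bright peripheral rim around a dim core;
#' bacteria as much smaller bright dots.
#'
#' @param width,height Image size in pixels.
#' @param pixel_scale Calibration in µm/pixel (> 0). The default 0.1 makes
#'   the smallest admissible nuclei (0.6 µm diameter) span 6 pixels.
#' @param n_chloroplasts,n_bacteria Number of confounders to render.
#' @param background Background level (fraction of full scale).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param nucleus_intensity Interior amplitude of nuclei above background.
#' @param chloroplast_rim_intensity,chloroplast_interior_intensity Rim and
#'   core amplitudes of chloroplasts above background.
#' @param bacterium_intensity Amplitude of bacteria above background.
#' @param chloroplast_diameter_um Range (min, max) of chloroplast diameters.
#' @param chloroplast_rim_um Thickness of the stained rim (µm).
#' @param bacterium_diameter_um Range (min, max) of bacterium diameters.
#' @param seed Integer seed controlling placement, confounder sizes and
#'   noise.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(width = 512L, height = 512L, pixel_scale = 0.1,
                       n_chloroplasts = 0L, n_bacteria = 0L,
                       background = 0.05, noise_sd = 0.02,
                       nucleus_intensity = 0.5,
                       chloroplast_rim_intensity = 0.6,
                       chloroplast_interior_intensity = 0.12,
                       bacterium_intensity = 0.85,
                       chloroplast_diameter_um = c(3, 6),
                       chloroplast_rim_um = 0.3,
                       bacterium_diameter_um = c(0.2, 0.4),
                       seed = 1L) {
  stop_if_not_number(pixel_scale, "pixel_scale", positive = TRUE)
  if (width < 16 || height < 16) stop("field must be at least 16x16 pixels")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_scale = pixel_scale,
         n_chloroplasts = as.integer(n_chloroplasts),
         n_bacteria = as.integer(n_bacteria),
         background = background, noise_sd = noise_sd,
         nucleus_intensity = nucleus_intensity,
         chloroplast_rim_intensity = chloroplast_rim_intensity,
         chloroplast_interior_intensity = chloroplast_interior_intensity,
         bacterium_intensity = bacterium_intensity,
         chloroplast_diameter_um = chloroplast_diameter_um,
         chloroplast_rim_um = chloroplast_rim_um,
         bacterium_diameter_um = bacterium_diameter_um,
         seed = as.integer(seed)),
    class = "field_spec"
  )
}

# Add an anti-aliased disc to `img`: per-pixel coverage ramps linearly over
# one pixel across the analytic circle boundary, so summed coverage equals
# the analytic disc area to sub-pixel accuracy.
draw_disc <- function(img, cx, cy, r, amplitude) {
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(ncol(img), ceiling(cx + r + 1))
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(nrow(img), ceiling(cy + r + 1))
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  cov <- pmin(pmax(r - d + 0.5, 0), 1)
  img[ys, xs] <- img[ys, xs] + amplitude * cov
  img
}

draw_ring <- function(img, cx, cy, r_outer, r_inner, rim_amp, core_amp) {
  img <- draw_disc(img, cx, cy, r_outer, rim_amp)
  img <- draw_disc(img, cx, cy, r_inner, core_amp - rim_amp)
  img
}

place_objects <- function(radii, width, height, margin_px = 3, gap_px = 2,
                          max_tries = 4000L) {
  n <- length(radii)
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    r <- radii[i]
    lo_x <- r + margin_px; hi_x <- width - r - margin_px
    lo_y <- r + margin_px; hi_y <- height - r - margin_px
    if (lo_x >= hi_x || lo_y >= hi_y) {
      stop("field dimensions too small for requested object sizes")
    }
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      x <- stats::runif(1, lo_x, hi_x)
      y <- stats::runif(1, lo_y, hi_y)
      if (i == 1L ||
          all(sqrt((cx[seq_len(i - 1)] - x)^2 + (cy[seq_len(i - 1)] - y)^2) >
              radii[seq_len(i - 1)] + r + gap_px)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place all objects without overlap; enlarge the field")
    }
  }
  list(cx = cx, cy = cy)
}

#' Render a synthetic DAPI field with ground truth
#'
#' Draws the supplied nuclei (areas in µm²) plus the confounders requested
#' by the field spec into a single-channel image. Object shapes are
#' anti-aliased circular primitives, so the ground-truth area of every
#' object is analytic (pi r²) rather than a rasterised pixel count. Nuclei
#' have homogeneous interiors; chloroplasts carry their signal in a
#' peripheral rim; bacteria are small and bright. Additive Gaussian noise
#' is applied last. Identical spec and records give a bit-identical image.
#'
#' @param records Data frame of nuclei with at least an `area` column
#'   (µm²); typically the output of [sample_nuclei()].
#' @param fspec A [field_spec()].
#' @return A list with `image` (numeric matrix in `[0, 1]`, rows = y) and
#'   `truth`, a tibble with one row per rendered object: `object`,
#'   `category`, `x`, `y` (pixel centroids), `radius_px`, `area_um2` and
#'   `diameter_um`.
#' @export
render_field <- function(records, fspec) {
  if (!inherits(fspec, "field_spec")) stop("`fspec` must be a field_spec")
  areas <- records$area
  if (is.null(areas)) stop("`records` must have an `area` column")
  scale <- fspec$pixel_scale
  if (length(areas) && any(areas / scale^2 < 1)) {
    stop("nucleus area below one pixel at this pixel_scale")
  }
  with_seed(fspec$seed, {
    r_nuc <- sqrt(areas / pi) / scale
    d_chl <- if (fspec$n_chloroplasts > 0)
      stats::runif(fspec$n_chloroplasts, fspec$chloroplast_diameter_um[1],
                   fspec$chloroplast_diameter_um[2]) else numeric()
    d_bac <- if (fspec$n_bacteria > 0)
      stats::runif(fspec$n_bacteria, fspec$bacterium_diameter_um[1],
                   fspec$bacterium_diameter_um[2]) else numeric()
    r_chl <- d_chl / 2 / scale
    r_bac <- pmax(d_bac / 2 / scale, 0.6)  # keep bacteria detectable
    radii <- c(r_nuc, r_chl, r_bac)
    category <- rep(c("nucleus", "chloroplast", "bacterium"),
                    c(length(r_nuc), length(r_chl), length(r_bac)))
    pos <- place_objects(radii, fspec$width, fspec$height)
    img <- matrix(fspec$background, nrow = fspec$height, ncol = fspec$width)
    for (i in seq_along(radii)) {
      img <- switch(category[i],
        nucleus = draw_disc(img, pos$cx[i], pos$cy[i], radii[i],
                            fspec$nucleus_intensity),
        chloroplast = draw_ring(img, pos$cx[i], pos$cy[i], radii[i],
                                max(radii[i] - fspec$chloroplast_rim_um /
                                      scale, 1),
                                fspec$chloroplast_rim_intensity,
                                fspec$chloroplast_interior_intensity),
        bacterium = draw_disc(img, pos$cx[i], pos$cy[i], radii[i],
                              fspec$bacterium_intensity)
      )
    }
    img <- img + stats::rnorm(length(img), 0, fspec$noise_sd)
    img <- pmin(pmax(img, 0), 1)
    attr(img, "pixel_scale") <- scale
    truth <- tibble::tibble(
      object = seq_along(radii),
      category = category,
      x = pos$cx, y = pos$cy,
      radius_px = radii,
      area_um2 = pi * (radii * scale)^2,
      diameter_um = 2 * radii * scale
    )
    list(image = img, truth = truth)
  })
}

#' Write a rendered field to a 16-bit grayscale TIFF
#'
#' @param image Numeric matrix in `[0, 1]` (as returned by
#'   [render_field()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_tiff <- function(image, path) {
  tiff::writeTIFF(unclass(image), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale image for quantification
#'
#' Reads 8/16-bit grayscale TIFF or PNG into a numeric matrix in `[0, 1]`.
#' Multi-channel images are averaged to one channel.
#'
#' @param path Image file path.
#' @return Numeric matrix (rows = y).
#' @export
read_field_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package")
    }
    png::readPNG(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}
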