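#' Build a nuclear-area histogram
#'
#' Counts areas over contiguous half-open bins `[lo, lo + w)` covering the
#' data range. The raw areas are kept inside the object so that peak
#' centres can later be refined from the data rather than from bin
#' midpoints.
#'
#' @param areas Numeric vector of nuclear areas (µm²), nonempty.
#' @param bin_width Bin width in µm² (> 0). The default 0.1 resolves the
#'   0.5 vs 0.7 µm² separation between diploid and triploid G1 classes.
#' @return An object of class `area_histogram` with elements `breaks`,
#'   `mids`, `counts`, `smoothed` (3-bin moving average) and `values`.
#' @export
build_histogram <- function(areas, bin_width = 0.1) {
  if (length(areas) == 0L) stop("`areas` must be nonempty")
  if (anyNA(areas) || any(areas <= 0)) {
    stop("areas must be positive and non-missing")
  }
  stop_if_not_number(bin_width, "bin_width", positive = TRUE)
  lo <- floor(min(areas) / bin_width) * bin_width
  nbin <- floor((max(areas) - lo) / bin_width) + 1L
  breaks <- lo + bin_width * (0:nbin)
  idx <- floor((areas - lo) / bin_width) + 1L
  idx[idx > nbin] <- nbin  # guard against floating-point edge on the max
  counts <- tabulate(idx, nbins = nbin)
  smoothed <- smooth_counts(counts)
  structure(
    list(breaks = breaks, mids = breaks[-length(breaks)] + bin_width / 2,
         counts = counts, smoothed = smoothed, bin_width = bin_width,
         values = as.numeric(areas)),
    class = "area_histogram"
  )
}

# light smoothing pass before peak picking: 3-bin moving average with
# zero-padded edges
smooth_counts <- function(counts) {
  n <- length(counts)
  padded <- c(0, counts, 0)
  (padded[seq_len(n)] + padded[seq_len(n) + 1L] + padded[seq_len(n) + 2L]) / 3
}

#' @export
print.area_histogram <- function(x, ...) {
  cat("<area_histogram>", length(x$values), "areas,", length(x$counts),
      "bins of width", x$bin_width, "\n")
  invisible(x)
}

# Local maxima of the smoothed counts, filtered by a minimum height and a
# valley (prominence) rule: a candidate is kept only if, between it and any
# taller kept peak, the smoothed counts dip below `valley_frac` times the
# candidate's own height. Returns bin indices, tallest first; plateau ties
# resolve toward the smaller area.
find_peak_bins <- function(hist, min_height = 2, valley_frac = 0.5) {
  s <- hist$smoothed
  n <- length(s)
  if (n == 1L) return(if (s[1] >= min_height) 1L else integer())
  ext <- c(-Inf, s, -Inf)
  # strict rise on the left, non-strict on the right: a plateau contributes
  # its first (smaller-area) bin
  cand <- which(s > ext[seq_len(n)] & s >= ext[seq_len(n) + 2L])
  cand <- cand[s[cand] >= min_height]
  if (length(cand) == 0L) return(integer())
  ord <- cand[order(-s[cand], cand)]
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      rng <- if (i < j) i:j else j:i
      if (min(s[rng]) > valley_frac * s[i]) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# Refine a peak centre: mean of the raw areas within the modal bin +/- one
# bin. Robust to binning phase and nearly unbiased for a symmetric mode.
refine_peak_center <- function(hist, bin) {
  lo <- hist$breaks[max(bin - 1L, 1L)]
  hi <- hist$breaks[min(bin + 2L, length(hist$breaks))]
  v <- hist$values[hist$values >= lo & hist$values < hi]
  if (length(v) == 0L) hist$mids[bin] else mean(v)
}

#' Detect the size-class peaks of an area histogram
#'
#' Finds the modes of the smoothed histogram (candidate G1/G2 peaks of the
#' ploidy series) and refines each mode's centre as the mean of the
#' observations in the modal bin and its two neighbours.
#'
#' @param areas Numeric vector of areas, or an [build_histogram()] object.
#' @param bin_width Bin width when `areas` is numeric.
#' @param min_height Minimum smoothed bin count for a mode to count as a
#'   peak.
#' @param valley_frac A mode must be separated from every taller mode by a
#'   dip below this fraction of its own height.
#' @return Tibble with `center` (µm², increasing) and `height` (smoothed
#'   count).
#' @export
detect_area_peaks <- function(areas, bin_width = 0.1, min_height = 2,
                              valley_frac = 0.5) {
  hist <- if (inherits(areas, "area_histogram")) areas else
    build_histogram(areas, bin_width)
  bins <- find_peak_bins(hist, min_height, valley_frac)
  if (length(bins) == 0L) {
    return(tibble::tibble(center = numeric(), height = numeric()))
  }
  out <- tibble::tibble(
    center = vapply(bins, function(b) refine_peak_center(hist, b), 0),
    height = hist$smoothed[bins],
    bin = bins
  )
  dplyr::arrange(out, .data$center)
}

#' Locate the G1 peak of an area histogram
#'
#' The tallest mode of the (smoothed) histogram is attributed to G1
#' (unreplicated nuclei), because most of the cell cycle is spent in G1.
#' Ties between equally tall modes are broken toward the smaller area, with
#' a warning, since G1 precedes G2.
#'
#' @param hist An [build_histogram()] object (or numeric areas).
#' @param bin_width Bin width when raw areas are supplied.
#' @return Peak centre in µm² (refined from the data around the modal
#'   bin).
#' @export
find_g1_peak <- function(hist, bin_width = 0.1) {
  if (!inherits(hist, "area_histogram")) {
    hist <- build_histogram(hist, bin_width)
  }
  if (length(hist$counts) > 1L && length(unique(hist$counts)) == 1L) {
    stop("flat histogram: G1 peak is ambiguous")
  }
  top <- max(hist$smoothed)
  at <- which(hist$smoothed == top)
  if (length(at) > 1L && any(diff(at) > 1L)) {
    warning("multiple equal modes; taking the smaller area as G1")
  }
  refine_peak_center(hist, at[1L])
}
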