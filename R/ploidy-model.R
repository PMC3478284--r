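#' Class boundaries of a doubling series
#'
#' Boundaries between adjacent size classes sit at the geometric means of
#' their centres, the split uniquely consistent with a multiplicative
#' doubling structure (for G1 at 0.5 µm² and G2 at 1.0 µm² it reproduces
#' the 0.70/0.71 split). The outermost bounds extrapolate the ratio to the
#' missing neighbour geometrically; a single class spans all positive
#' areas.
#'
#' @param centers Strictly increasing positive class centres (µm²).
#' @return Numeric vector of `length(centers) + 1` boundaries; class `i`
#'   owns the half-open interval `[b[i], b[i+1])`.
#' @export
class_boundaries <- function(centers) {
  k <- length(centers)
  if (k < 1L) stop("at least one centre is required")
  if (any(centers <= 0) || (k > 1L && any(diff(centers) <= 0))) {
    stop("centres must be positive and strictly increasing")
  }
  if (k == 1L) return(c(0, Inf))
  inner <- sqrt(centers[-k] * centers[-1])
  lower <- centers[1] * sqrt(centers[1] / centers[2])
  upper <- centers[k] * sqrt(centers[k] / centers[k - 1])
  c(lower, inner, upper)
}

#' Estimate the monoploid area unit from gamete nuclei
#'
#' The minimum ploidy level is anchored in gametes: their G1 peak is taken
#' as unreplicated nuclei at the 2Cx level, so one Cx unit (`c`, µm² per
#' monoploid genome) is half the gamete G1 peak. Because G2 nuclei carry
#' exactly twice the G1 content, both gamete classes inform the unit: after
#' a provisional peak-based estimate, every gamete nucleus is snapped to
#' the nearest doubling class and the unit is refined as the count-weighted
#' geometric mean of (class mean / class multiplier), which roughly halves
#' the estimate's sampling error on small gamete samples. If gametes are
#' instead assumed reduced (1Cx), the unit doubles but every class
#' assignment, being ratio-based, is unchanged.
#'
#' @param gamete_areas Areas (µm²) of gamete-flagged nuclei.
#' @param bin_width Histogram bin width for peak finding.
#' @param gamete_cx Ploidy level attributed to gamete G1 nuclei (default 2,
#'   i.e. unreduced gametes).
#' @return The unit in µm² per Cx.
#' @export
estimate_unit <- function(gamete_areas, bin_width = 0.1, gamete_cx = 2) {
  if (length(gamete_areas) == 0L) {
    stop("no gamete records: supply the unit explicitly")
  }
  u0 <- find_g1_peak(gamete_areas, bin_width) / gamete_cx
  # snap every gamete to the nearest doubling of the provisional G1 class
  k <- round(log2(gamete_areas / (u0 * gamete_cx)))
  k <- pmin(pmax(k, 0), 2)
  m <- gamete_cx * 2^k
  cls <- split(gamete_areas / m, m)
  w <- vapply(cls, length, 0L)
  exp(sum(w * log(vapply(cls, mean, 0))) / sum(w))
}

# Multiplier families: maximal doubling chains b, 2b, 4b, ... inside the
# allowed multiplier set, one per base (a base is a multiplier whose half
# is not allowed).
doubling_families <- function(multipliers) {
  multipliers <- sort(unique(as.integer(multipliers)))
  bases <- multipliers[!(multipliers / 2) %in% multipliers]
  lapply(stats::setNames(bases, bases), function(b) {
    fam <- b
    while ((2 * fam[length(fam)]) %in% multipliers) {
      fam <- c(fam, 2L * fam[length(fam)])
    }
    fam
  })
}

map_peaks_to_family <- function(peaks, unit, family) {
  kmax <- log2(family[length(family)] / family[1])
  k <- round(log2(peaks / (unit * family[1])))
  k <- pmin(pmax(k, 0), kmax)
  m <- family[1] * 2^k
  list(multiplier = as.integer(m), residual = log(peaks / (unit * m)))
}

#' Choose the doubling family that best explains a set of peaks
#'
#' Candidate families are the doubling chains of the allowed multiplier
#' set (by default 2,4,8,16,32 and 3,6,12). Each detected peak is snapped
#' to the nearest member of a candidate family in log space and the family
#' with the smallest mean squared log residual wins; ties go to the
#' smaller base. Supplying the peaks of several samples (a list) fits one
#' family across a species, which is how an ambiguous portion (e.g. a G1
#' peak falling between 3x and 4x the unit) is resolved by its siblings.
#'
#' @param peaks Numeric vector of peak centres, or a list of such vectors.
#' @param unit µm² per Cx (see [estimate_unit()]).
#' @param multipliers Allowed Cx multipliers.
#' @return List with `base`, `family`, `scale` (geometric mean ratio of
#'   peaks to their predicted centres) and `cost`.
#' @export
choose_doubling_family <- function(peaks, unit,
                                   multipliers = c(2, 3, 4, 6, 8, 12, 16, 32)) {
  if (!is.list(peaks)) peaks <- list(peaks)
  flat <- unlist(peaks)
  if (length(flat) == 0L) stop("no peaks supplied")
  stop_if_not_number(unit, "unit", positive = TRUE)
  fams <- doubling_families(multipliers)
  fits <- lapply(fams, function(fam) {
    m <- map_peaks_to_family(flat, unit, fam)
    list(family = fam, cost = mean(m$residual^2), residual = m$residual)
  })
  costs <- vapply(fits, `[[`, 0, "cost")
  best <- fits[[which.min(costs)]]
  mapped <- map_peaks_to_family(flat, unit, best$family)
  list(base = best$family[1], family = best$family,
       scale = exp(mean(mapped$residual)), cost = best$cost)
}

#' Gamete-anchored doubling-series model
#'
#' Holds the unit (µm² per Cx), the Cx multipliers of the size classes, the
#' class centres and the geometric-mean class boundaries, plus the
#' extension grid used to place rare nuclei beyond the last detected class
#' (higher endopolyploidy levels seen in a handful of nuclei produce no
#' histogram mode of their own).
#'
#' @param unit µm² per Cx.
#' @param multipliers Strictly increasing Cx multipliers of the classes.
#' @param centers Class centres; default `scale * unit * multipliers`.
#' @param scale Multiplicative calibration between predicted
#'   (`unit * multiplier`) and observed centres; default fitted from
#'   `centers`.
#' @param allowed Full allowed multiplier set (for the extension grid).
#' @param family Doubling family the classes belong to; default the chain
#'   through `multipliers[1]`.
#' @param out_tolerance A nucleus beyond the last class founds a new
#'   extension class only if within this multiplicative factor of the
#'   extension centre (default 1.3, safely inside the sqrt(2) = 1.41
#'   half-spacing of a doubling series).
#' @return An object of class `ploidy_series_model`.
#' @export
ploidy_series_model <- function(unit, multipliers, centers = NULL,
                                scale = NULL,
                                allowed = c(2, 3, 4, 6, 8, 12, 16, 32),
                                family = NULL, out_tolerance = 1.3) {
  stop_if_not_number(unit, "unit", positive = TRUE)
  multipliers <- as.integer(multipliers)
  if (length(multipliers) < 1L || any(diff(multipliers) <= 0)) {
    stop("multipliers must be strictly increasing")
  }
  if (is.null(centers) && is.null(scale)) scale <- 1
  if (is.null(centers)) centers <- scale * unit * multipliers
  if (length(centers) != length(multipliers)) {
    stop("centers must match multipliers in length")
  }
  if (is.null(scale)) {
    scale <- exp(mean(log(centers / (unit * multipliers))))
  }
  allowed <- sort(unique(c(as.integer(allowed), multipliers)))
  if (is.null(family)) {
    fams <- doubling_families(allowed)
    hit <- vapply(fams, function(f) all(multipliers %in% f), NA)
    family <- if (any(hit)) fams[[which(hit)[1]]] else multipliers
  }
  boundaries <- class_boundaries(centers)
  ext <- setdiff(family[family > max(multipliers)], multipliers)
  structure(
    list(unit = unit, multipliers = multipliers, centers = centers,
         boundaries = boundaries, scale = scale, allowed = allowed,
         family = as.integer(family),
         ext_multipliers = as.integer(ext),
         ext_centers = scale * unit * ext,
         out_tolerance = out_tolerance),
    class = "ploidy_series_model"
  )
}

#' @export
print.ploidy_series_model <- function(x, ...) {
  cat("<ploidy_series_model> unit =", signif(x$unit, 4), "um^2/Cx\n")
  cat("  classes:", paste0(x$multipliers, "Cx @ ",
                           signif(x$centers, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Fit a doubling-series model to a population of nuclear areas
#'
#' Detects the modes of the area histogram and snaps them onto the allowed
#' multiplier grid (choosing the doubling family that best explains them,
#' unless one is imposed from a species-level fit). The tallest mode
#' anchors the lowest class — the dominant G1 peak defines the minimum
#' ploidy level — and the model's classes are all family multipliers from
#' there up to the highest mode, including interior levels whose minor
#' peaks ride on the tail of a larger class and therefore may not survive
#' mode detection on the raw mixture. Each class centre is then estimated
#' empirically as the tallest histogram mode falling inside the class's
#' predicted window (grid boundaries at geometric means of predicted
#' centres), falling back to the mean of the window's records for classes
#' represented by a handful of nuclei.
#'
#' @param areas Nuclear areas (µm²).
#' @param unit µm² per Cx.
#' @param multipliers Allowed multiplier set.
#' @param bin_width,min_height,valley_frac Peak-detection controls; see
#'   [detect_area_peaks()].
#' @param family Optional doubling family imposed from a species-level fit.
#' @param scale Optional calibration between predicted and observed
#'   centres (e.g. pooled across the portions of a species); default
#'   fitted from this sample's peaks.
#' @param out_tolerance See [ploidy_series_model()].
#' @return A [ploidy_series_model()].
#' @export
fit_ploidy_series <- function(areas, unit,
                              multipliers = c(2, 3, 4, 6, 8, 12, 16, 32),
                              bin_width = 0.1, min_height = 2,
                              valley_frac = 0.5, family = NULL,
                              scale = NULL, out_tolerance = 1.3) {
  hist <- build_histogram(areas, bin_width)
  # strong (valley-separated) peaks anchor family and scale; the full mode
  # list, shoulder modes included, defines how far the class grid extends
  peaks <- detect_area_peaks(hist, min_height = min_height,
                             valley_frac = valley_frac)
  modes <- detect_area_peaks(hist, min_height = min_height, valley_frac = 1)
  if (nrow(modes) == 0L) stop("no histogram peaks found")
  if (nrow(peaks) == 0L) peaks <- modes
  if (is.null(family) || is.null(scale)) {
    fit <- choose_doubling_family(peaks$center, unit, multipliers)
    if (is.null(family)) family <- fit$family
    if (is.null(scale)) scale <- fit$scale
  }
  mp <- map_peaks_to_family(modes$center, unit, family)
  m_low <- mp$multiplier[which.max(modes$height)]
  m_top <- max(mp$multiplier[mp$multiplier >= m_low], m_low)
  # a class buried in a larger neighbour's tail may show no mode of its
  # own: extend the grid while the next level's predicted window holds a
  # non-trivial number of nuclei (stray outliers instead join through the
  # capped extension rule at assignment time)
  scl <- if (is.null(scale)) 1 else scale
  repeat {
    nxt <- family[family > m_top]
    if (length(nxt) == 0L) break
    w <- scl * unit * nxt[1] * c(1 / sqrt(2), sqrt(2))
    n_in <- sum(areas >= w[1] & areas < w[2])
    if (n_in < max(3, round(0.005 * length(areas)))) break
    m_top <- nxt[1]
  }
  grid_m <- family[family >= m_low & family <= m_top]
  pred <- scale * unit * grid_m
  win <- class_boundaries(pred)
  dominant <- modes$center[which.max(modes$height)]
  # centre-estimation window: grid window clipped to a +/-30% linear band
  # around x, so an unbounded outer window cannot leak a neighbour in
  est_win <- function(i, x) {
    c(max(win[i], 0.7 * x), min(win[i + 1], 1.3 * x))
  }
  # classes are estimated bottom-up so each minor class can subtract the
  # estimated tail of the class below it before taking its centroid
  centers <- numeric(length(grid_m))
  lower_sd <- numeric(length(grid_m))
  lower_n <- numeric(length(grid_m))
  for (i in seq_along(grid_m)) {
    if (dominant >= win[i] && dominant < win[i + 1]) {
      # dominant (G1) class: iterated windowed median, robust to
      # modal-bin noise in broad classes
      x <- dominant
      for (it in 1:10) {
        w <- est_win(i, x)
        v <- hist$values[hist$values >= w[1] & hist$values < w[2]]
        if (length(v) == 0L) break
        x <- stats::median(v)
      }
      centers[i] <- x
    } else {
      # minor class: centroid of the window's bin counts after
      # subtracting the expected tail of the class below, the
      # within-window analogue of background subtraction; a large
      # neighbour's tail otherwise drags the centre toward the shared
      # boundary
      sel <- which(hist$mids >= win[i] & hist$mids < win[i + 1])
      if (length(sel) == 0L) {
        centers[i] <- pred[i]
      } else {
        tail_cnt <- 0
        if (i > 1L && lower_n[i - 1L] > 0) {
          tail_cnt <- lower_n[i - 1L] *
            (stats::pnorm(hist$breaks[sel + 1L], centers[i - 1L],
                          lower_sd[i - 1L]) -
               stats::pnorm(hist$breaks[sel], centers[i - 1L],
                            lower_sd[i - 1L]))
        }
        obs <- hist$counts[sel]
        # keep the bins where the class signal dominates the subtracted
        # tail; residuals stay unclipped so Poisson fluctuations cancel
        # instead of accumulating at the shared boundary
        keep <- obs > 0 & tail_cnt <= 0.7 * obs
        res <- (obs - tail_cnt)[keep]
        centers[i] <- if (sum(res) >= 3) {
          sum(res * hist$mids[sel][keep]) / sum(res)
        } else {
          w <- est_win(i, pred[i])
          v <- hist$values[hist$values >= w[1] & hist$values < w[2]]
          if (length(v)) stats::median(v) else pred[i]
        }
      }
    }
    # robust spread and count of this class, for the next class's
    # tail subtraction
    if (dominant >= win[i] && dominant < win[i + 1]) {
      # the dominant class's left flank is uncontaminated (no class sits
      # below the G1 of the lowest level), so its spread and size follow
      # from the left half alone, assuming a symmetric class
      v_left <- hist$values[hist$values < centers[i]]
      lower_n[i] <- 2 * length(v_left)
      s <- if (length(v_left) >= 5) {
        stats::median(centers[i] - v_left) / 0.6745
      } else {
        0.15 * centers[i]
      }
    } else {
      w <- est_win(i, centers[i])
      v <- hist$values[hist$values >= w[1] & hist$values < w[2]]
      lower_n[i] <- length(v)
      s <- if (length(v) >= 5) stats::mad(v, center = centers[i])
        else 0.15 * centers[i]
    }
    lower_sd[i] <- min(max(s, 0.03 * centers[i]), 0.4 * centers[i])
  }
  # guard against an estimate crossing its neighbour's window
  centers <- pmin(pmax(centers, win[seq_along(grid_m)] + 1e-9),
                  win[seq_along(grid_m) + 1L] - 1e-9)
  centers[is.infinite(centers)] <- pred[is.infinite(centers)]
  ploidy_series_model(unit, grid_m, centers = centers, scale = scale,
                      allowed = multipliers, family = family,
                      out_tolerance = out_tolerance)
}

#' Assign nuclei to size classes on a doubling series
#'
#' Every record is assigned to exactly one class. Within the modelled
#' range, membership is by the half-open geometric-boundary intervals
#' (equivalently: nearest class centre in log space). A record beyond the
#' last class's extrapolated bound founds (or joins) an extension class at
#' the next multipliers of the family, provided it lies within the model's
#' `out_tolerance` of that predicted centre; otherwise it stays in the
#' nearest modelled class flagged `out_of_series`. Records below the first
#' class's bound stay in the lowest class flagged `below_series`: the
#' dominant G1 peak defines the minimum level and smaller areas are its
#' measurement spread.
#'
#' @param records Data frame with an `area` column (µm²) and optional
#'   metadata (`species`, `portion`, ...), e.g. from [sample_nuclei()] or
#'   [measure_population()].
#' @param model A [ploidy_series_model()].
#' @return An object of class `classified_population`: list with `records`
#'   (input plus `cx`, `phase`, `flag`), `classes` (per-class summary:
#'   `cx`, `center`, `lower`, `upper`, `n`, `mean`, `sd`, `origin`),
#'   `model` and `unit`.
#' @export
assign_classes <- function(records, model) {
  if (!inherits(model, "ploidy_series_model")) {
    stop("`model` must be a ploidy_series_model")
  }
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L || is.null(records$area)) {
    stop("`records` must be nonempty and carry an `area` column")
  }
  a <- records$area
  if (any(a <= 0)) stop("areas must be positive")
  k <- length(model$centers)
  b <- model$boundaries
  # nearest detected centre in log space
  la <- log(a)
  det_idx <- apply(abs(outer(la, log(model$centers), `-`)), 1, which.min)
  cx <- model$multipliers[det_idx]
  flag <- rep(NA_character_, length(a))
  flag[a < b[1]] <- "below_series"

  beyond <- which(a >= b[k + 1] | (k == 1L & length(model$ext_centers) > 0 &
                                     a >= model$centers[1] * sqrt(2)))
  if (length(beyond) && length(model$ext_centers)) {
    cand <- c(model$centers, model$ext_centers)
    cand_mult <- c(model$multipliers, model$ext_multipliers)
    is_ext <- c(rep(FALSE, k), rep(TRUE, length(model$ext_centers)))
    for (i in beyond) {
      j <- which.min(abs(la[i] - log(cand)))
      if (is_ext[j] &&
          abs(la[i] - log(cand[j])) <= log(model$out_tolerance)) {
        cx[i] <- cand_mult[j]
      } else {
        flag[i] <- "out_of_series"
      }
    }
  } else if (length(beyond)) {
    flag[beyond] <- "out_of_series"
  }

  records$cx <- cx
  records$flag <- flag
  pop <- structure(list(records = records, model = model,
                        unit = model$unit),
                   class = "classified_population")
  rebuild_classes(pop)
}

# per-class summary table + phase attribution, recomputed after any
# reassignment
rebuild_classes <- function(pop) {
  rec <- pop$records
  model <- pop$model
  occupied_ext <- sort(unique(rec$cx[!rec$cx %in% model$multipliers]))
  all_mult <- sort(unique(c(model$multipliers, occupied_ext)))
  center_of <- function(m) {
    if (m %in% model$multipliers) {
      model$centers[match(m, model$multipliers)]
    } else {
      mean(rec$area[rec$cx == m])  # extension class: centre from members
    }
  }
  centers <- vapply(all_mult, center_of, 0)
  bounds <- class_boundaries(centers)
  cls <- tibble::tibble(
    cx = as.integer(all_mult),
    center = centers,
    lower = bounds[-length(bounds)],
    upper = bounds[-1],
    n = vapply(all_mult, function(m) sum(rec$cx == m), 0L),
    mean = vapply(all_mult, function(m) {
      if (any(rec$cx == m)) mean(rec$area[rec$cx == m]) else NA_real_
    }, 0),
    sd = vapply(all_mult, function(m) {
      if (sum(rec$cx == m) > 1L) stats::sd(rec$area[rec$cx == m]) else
        NA_real_
    }, 0),
    origin = ifelse(all_mult %in% model$multipliers, "peak", "extension")
  )
  occ <- cls$cx[cls$n > 0]
  m1 <- min(occ)
  phase_of <- function(m) {
    if (m == m1) "G1" else if ((m / 2) %in% occ) "G2" else "G1"
  }
  cls$phase <- vapply(cls$cx, phase_of, "")
  pop$classes <- cls
  pop$records$phase <- cls$phase[match(pop$records$cx, cls$cx)]
  pop
}

#' @export
print.classified_population <- function(x, ...) {
  cat("<classified_population>", nrow(x$records), "nuclei in",
      sum(x$classes$n > 0), "occupied classes\n")
  occ <- x$classes[x$classes$n > 0, ]
  cat(sprintf("  %2dCx: n = %4d, mean = %.3g (%s)\n", occ$cx, occ$n,
              occ$mean, occ$phase), sep = "")
  invisible(x)
}

#' Split the overlap between two adjacent size classes
#'
#' Where adjacent somatic ploidy levels overlap, the records inside a
#' declared overlap interval around the shared boundary are sorted by area
#' and each half is assigned to one of the two levels: the lower
#' `floor(n/2)` records to the lower class, the rest to the upper class.
#' Reassigned records are flagged `overlap_split`.
#'
#' @param pop A `classified_population`.
#' @param lower_cx,upper_cx Multipliers of two adjacent classes of `pop`.
#' @param overlap Half-width of the overlap interval as a multiplicative
#'   fraction of the boundary: the interval is
#'   `[b / (1 + overlap), b * (1 + overlap)]`.
#' @return The updated `classified_population`.
#' @export
split_overlap <- function(pop, lower_cx, upper_cx, overlap = 0.1) {
  if (!inherits(pop, "classified_population")) {
    stop("`pop` must be a classified_population")
  }
  cls <- pop$classes
  i <- match(lower_cx, cls$cx); j <- match(upper_cx, cls$cx)
  if (is.na(i) || is.na(j) || j != i + 1L) {
    stop("classes must be adjacent classes of the population")
  }
  b <- sqrt(cls$center[i] * cls$center[j])
  zone <- which(pop$records$cx %in% c(lower_cx, upper_cx) &
                  pop$records$area >= b / (1 + overlap) &
                  pop$records$area <= b * (1 + overlap))
  if (length(zone) == 0L) return(pop)
  zone <- zone[order(pop$records$area[zone])]
  n_low <- floor(length(zone) / 2)
  new_cx <- rep(as.integer(upper_cx), length(zone))
  if (n_low > 0) new_cx[seq_len(n_low)] <- as.integer(lower_cx)
  changed <- pop$records$cx[zone] != new_cx
  pop$records$cx[zone] <- new_cx
  pop$records$flag[zone][changed] <- "overlap_split"
  rebuild_classes(pop)
}

#' Apply overlap splitting to every adjacent pair of occupied classes
#'
#' @inheritParams split_overlap
#' @return The updated `classified_population`.
#' @export
apply_overlap_splits <- function(pop, overlap = 0.1) {
  occ <- pop$classes$cx[pop$classes$n > 0]
  if (length(occ) < 2L) return(pop)
  for (i in seq_len(length(occ) - 1L)) {
    cls <- pop$classes$cx
    a <- occ[i]; b <- occ[i + 1L]
    if (match(b, cls) == match(a, cls) + 1L) {
      pop <- split_overlap(pop, a, b, overlap)
    }
  }
  pop
}

#' Infer the cytotype of a classified population
#'
#' The base multiplier is the smallest occupied Cx level; the sample is
#' endopolyploid when more than two distinct size classes occur in somatic
#' tissue (gametes excluded); the dominant phase is haplophasic for base
#' 2Cx/3Cx (gamete-equivalent genome) and diplophasic for 4Cx and above.
#' Inference fails with an unresolved-cytotype error when the lowest
#' occupied class centre is farther than the model's tolerance (default
#' 25%, multiplicative) from its predicted centre on the multiplier grid.
#'
#' @param pop A `classified_population`.
#' @param model Its model (defaults to `pop$model`).
#' @param tolerance Multiplicative mismatch tolerated between the lowest
#'   class centre and `scale * unit * multiplier`.
#' @return A tibble row: `sample`, `species`, `base_multiplier`, `ploidy`,
#'   `classes` (list of occupied Cx), `n_classes`, `endopolyploid`,
#'   `dominant_phase`.
#' @export
infer_cytotype <- function(pop, model = pop$model, tolerance = 1.25) {
  cls <- pop$classes[pop$classes$n > 0, ]
  if (nrow(cls) == 0L) stop("no occupied classes")
  m1 <- cls$cx[1]
  predicted <- model$scale * model$unit * m1
  if (abs(log(cls$center[1] / predicted)) > log(tolerance)) {
    stop(sprintf(
      "unresolved cytotype: lowest class centre %.3g is over %g%% from %.3g (= %dCx)",
      cls$center[1], (tolerance - 1) * 100, predicted, m1))
  }
  rec <- pop$records
  col_or <- function(nm, default) {
    if (nm %in% names(rec)) rec[[nm]] else default
  }
  somatic <- col_or("portion", rep("frond", nrow(rec)))
  somatic_classes <- unique(rec$cx[is.na(somatic) | somatic != "gamete"])
  ploidy_names <- c("2" = "diploid", "3" = "triploid", "4" = "tetraploid",
                    "6" = "hexaploid", "8" = "octoploid")
  tibble::tibble(
    sample = col_or("individual", NA_character_)[1],
    species = col_or("species", NA_character_)[1],
    base_multiplier = as.integer(m1),
    ploidy = unname(ploidy_names[as.character(m1)] %|NA|% paste0(m1, "x")),
    classes = list(cls$cx),
    n_classes = nrow(cls),
    endopolyploid = length(somatic_classes) > 2L,
    dominant_phase = if (m1 <= 3) "haplophasic" else "diplophasic"
  )
}

`%|NA|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Full cytotype analysis of a nucleus-record table
#'
#' End-to-end inference over one or more samples: estimates the Cx unit
#' from gamete records (unless supplied), detects per-sample histogram
#' peaks, chooses one doubling family and one scale calibration per
#' species/phase group (so an ambiguous portion is resolved by the other
#' portions of its species), fits and assigns classes per sample, splits
#' class overlaps, and infers per-sample and per-group cytotypes.
#'
#' @param records Tibble of nucleus records: `area` plus `species`,
#'   `portion`, `reproductive`; an optional `sample` column names the
#'   analysis unit (default species x portion x phase).
#' @param unit µm² per Cx; estimated from gamete records when `NULL`.
#' @param multipliers Allowed Cx multipliers.
#' @param bin_width,min_height Peak-detection controls.
#' @param overlap Overlap-splitting half-width (0 disables splitting).
#' @param gamete_cx Ploidy level attributed to gamete G1 nuclei.
#' @return List with `unit`, `populations` (named list of
#'   `classified_population`), `profiles` (per-sample cytotypes) and
#'   `group_profiles` (per species/phase: base multiplier, union of
#'   classes, endopolyploidy).
#' @export
analyze_cytotypes <- function(records, unit = NULL,
                              multipliers = c(2, 3, 4, 6, 8, 12, 16, 32),
                              bin_width = 0.1, min_height = 2,
                              overlap = 0.1, gamete_cx = 2) {
  records <- tibble::as_tibble(records)
  if (is.null(records$area)) stop("records must carry an `area` column")
  if (is.null(records$species)) records$species <- "sample"
  if (is.null(records$portion)) records$portion <- "frond"
  if (is.null(records$reproductive)) records$reproductive <- FALSE
  if (is.null(records$sample)) {
    records$sample <- paste(records$species, records$portion,
                            ifelse(records$reproductive, "reproductive",
                                   "sterile"), sep = " / ")
  }
  if (is.null(unit)) {
    gam <- records$area[records$portion == "gamete"]
    unit <- estimate_unit(gam, bin_width, gamete_cx)
  }
  records$group <- paste(records$species,
                         ifelse(records$reproductive, "reproductive",
                                "sterile"), sep = " / ")
  populations <- list()
  profiles <- list()
  group_rows <- list()
  for (g in unique(records$group)) {
    grec <- records[records$group == g, ]
    samples <- unique(grec$sample)
    peak_sets <- lapply(samples, function(s) {
      detect_area_peaks(grec$area[grec$sample == s], bin_width,
                        min_height)$center
    })
    fam <- choose_doubling_family(peak_sets, unit, multipliers)
    for (s in samples) {
      srec <- grec[grec$sample == s, ]
      model <- fit_ploidy_series(srec$area, unit, multipliers, bin_width,
                                 min_height, family = fam$family,
                                 scale = fam$scale)
      pop <- assign_classes(srec, model)
      if (overlap > 0) pop <- apply_overlap_splits(pop, overlap)
      populations[[s]] <- pop
      prof <- tryCatch(infer_cytotype(pop), error = function(e) {
        warning(sprintf("sample '%s': %s", s, conditionMessage(e)),
                call. = FALSE)
        occ <- pop$classes[pop$classes$n > 0, ]
        tibble::tibble(sample = s, species = NA_character_,
                       base_multiplier = NA_integer_,
                       ploidy = NA_character_, classes = list(occ$cx),
                       n_classes = nrow(occ), endopolyploid = NA,
                       dominant_phase = NA_character_)
      })
      prof$sample <- s
      prof$group <- g
      if (is.na(prof$species[1])) {
        prof$species <- grec$species[1]
      }
      profiles[[s]] <- prof
    }
    gprof <- dplyr::bind_rows(profiles[samples])
    somatic <- vapply(samples, function(s) {
      pop <- populations[[s]]
      !all(pop$records$portion == "gamete")
    }, NA)
    base_idx <- which.min(gprof$base_multiplier)
    group_rows[[g]] <- tibble::tibble(
      group = g,
      species = gprof$species[1],
      base_multiplier = if (length(base_idx))
        gprof$base_multiplier[base_idx] else NA_integer_,
      ploidy = if (length(base_idx)) gprof$ploidy[base_idx] else
        NA_character_,
      classes = list(sort(unique(unlist(gprof$classes)))),
      endopolyploid = any(gprof$endopolyploid[somatic], na.rm = TRUE),
      dominant_phase = if (length(base_idx))
        gprof$dominant_phase[base_idx] else NA_character_
    )
  }
  list(unit = unit,
       populations = populations,
       profiles = dplyr::bind_rows(profiles),
       group_profiles = dplyr::bind_rows(group_rows))
}
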