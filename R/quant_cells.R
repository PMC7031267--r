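#' Segment single cells from a high-magnification image
#'
#' Standard single-cell segmentation for the constitutive channel: Gaussian
#' smoothing, global Otsu threshold (within the optional biofilm mask),
#' distance-transform watershed to split touching cells, then area gates.
#' Per-object records carry the centroid, area, depth (sampled from the
#' depth map at the centroid when supplied) and the mean raw intensity of
#' every channel passed in `channels`.
#'
#' @param image Single-channel matrix used for segmentation (constitutive
#'   reporter).
#' @param mask Optional logical matrix restricting the search.
#' @param channels Named list of co-registered intensity matrices to
#'   measure (defaults to `list(rfp = image)`).
#' @param depthmap Optional depth matrix (um) from [depth_map()].
#' @param pixel_size_um Pixel size (um) for centroid coordinates.
#' @param smooth_sigma Smoothing sigma in px.
#' @param min_area_px,max_area_px Area gates in px.
#' @param watershed_tolerance Minimum object-separating depth of the
#'   distance-transform watershed.
#' @return A tibble of cell records: `label`, `row`, `col`, `x_um`, `y_um`,
#'   `depth_um`, `area_px`, `perimeter_px`, `mean_<channel>` columns and
#'   `is_spore = FALSE`. Zero objects yield an empty tibble, not an error.
#' @export
segment_cells <- function(image, mask = NULL,
                          channels = list(rfp = image), depthmap = NULL,
                          pixel_size_um = 0.05, smooth_sigma = 2,
                          min_area_px = 20, max_area_px = Inf,
                          watershed_tolerance = 1) {
  stopifnot(is.matrix(image))
  if (diff(range(image)) < 1e-12) return(empty_cell_records(channels))
  v <- image / max(image, 1e-12)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(v), sigma = smooth_sigma))
  if (!is.null(mask)) {
    if (inherits(mask, "biofilm_mask")) mask <- mask$mask
    sm_in <- sm[mask]
    if (length(sm_in) == 0) return(empty_cell_records(channels))
    thr <- EBImage::otsu(EBImage::Image(matrix(sm_in, ncol = 1)))
    bin <- sm > thr & mask
  } else {
    thr <- EBImage::otsu(EBImage::Image(sm))
    bin <- sm > thr
  }
  if (!any(bin)) return(empty_cell_records(channels))
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  measure_objects(lab, channels, depthmap, pixel_size_um,
                  min_area_px, max_area_px)
}

empty_cell_records <- function(channels) {
  base <- tibble::tibble(
    label = integer(), row = numeric(), col = numeric(),
    x_um = numeric(), y_um = numeric(), depth_um = numeric(),
    area_px = numeric(), perimeter_px = numeric()
  )
  for (ch in names(channels)) base[[paste0("mean_", ch)]] <- numeric()
  base$is_spore <- logical()
  base
}

# Shared feature measurement for labelled objects.
measure_objects <- function(lab, channels, depthmap, pixel_size_um,
                            min_area_px, max_area_px) {
  shape <- EBImage::computeFeatures.shape(lab)
  if (is.null(shape) || nrow(shape) == 0) {
    return(empty_cell_records(channels))
  }
  mom <- EBImage::computeFeatures.moment(lab)
  labels <- seq_len(nrow(shape))
  area <- shape[, "s.area"]
  keep <- area >= min_area_px & area <= max_area_px
  # m.cx is the coordinate along dim 1 (our rows), m.cy along dim 2 (cols)
  rows <- mom[, "m.cx"]
  cols <- mom[, "m.cy"]
  rec <- tibble::tibble(
    label = labels[keep], row = rows[keep], col = cols[keep],
    x_um = cols[keep] * pixel_size_um, y_um = rows[keep] * pixel_size_um,
    depth_um = NA_real_,
    area_px = area[keep], perimeter_px = shape[keep, "s.perimeter"]
  )
  if (!is.null(depthmap) && nrow(rec) > 0) {
    ri <- pmin(pmax(round(rec$row), 1), nrow(depthmap))
    ci <- pmin(pmax(round(rec$col), 1), ncol(depthmap))
    rec$depth_um <- depthmap[cbind(ri, ci)]
  }
  labmat <- as.matrix(EBImage::imageData(lab))
  for (ch in names(channels)) {
    vals <- tapply(as.vector(channels[[ch]]), as.vector(labmat), mean)
    rec[[paste0("mean_", ch)]] <-
      as.numeric(vals[as.character(rec$label)])
  }
  rec$is_spore <- FALSE
  rec
}

#' Segment spores from the spore-reporter channel
#'
#' Labels bright objects in the late-sporulation reporter channel and keeps
#' those passing the spore gates: area within `area_range` times the median
#' cell area (spores are smaller than cells) and circularity
#' (`4 * pi * area / perimeter^2`) above `min_circularity` (spores are
#' round).
#'
#' @param spore_image Spore-reporter channel matrix.
#' @param median_cell_area_px Median segmented cell area; when `NULL` the
#'   area gate is skipped.
#' @param area_range Relative area gate (default 0.25 to 1 times the median
#'   cell area).
#' @param min_circularity Circularity gate.
#' @param ... Passed to [segment_cells()] (mask, depthmap, pixel size,
#'   smoothing).
#' @return Tibble of spore records with `is_spore = TRUE`.
#' @export
segment_spores <- function(spore_image, median_cell_area_px = NULL,
                           area_range = c(0.25, 1),
                           min_circularity = 0.8, ...) {
  rec <- segment_cells(spore_image, channels = list(spore = spore_image),
                       ...)
  if (nrow(rec) == 0) return(rec)
  circ <- 4 * pi * rec$area_px / rec$perimeter_px^2
  keep <- circ >= min_circularity
  if (!is.null(median_cell_area_px)) {
    keep <- keep & rec$area_px >= area_range[1] * median_cell_area_px &
      rec$area_px <= area_range[2] * median_cell_area_px
  }
  rec <- rec[keep, ]
  rec$is_spore <- TRUE
  rec
}

#' Filter out-of-focal-plane cells from a bimodal constitutive signal
#'
#' Live-biofilm snapshots can show a bimodal constitutive (RFP) intensity:
#' a dimmer population of cells lying in a different focal plane. A
#' two-component Gaussian mixture is fitted to the per-cell mean RFP; the
#' exclusion threshold is the mean minus the standard deviation of the
#' brighter component and dimmer cells are removed. When the two components
#' are not separable (Ashman's D < 2) no filtering is applied and a warning
#' flag is returned.
#'
#' @param cell_records Tibble with a `mean_rfp` column (>= 50 cells).
#' @param min_ashman_d Separability requirement on Ashman's
#'   `D = sqrt(2) |mu1 - mu2| / sqrt(s1^2 + s2^2)`.
#' @return List: `cells` (kept records), `threshold` (NA when degenerate),
#'   `means`, `sds`, `ashman_d`, `filtered` (logical flag).
#' @importFrom mclust Mclust mclustBIC
#' @export
bimodal_rfp_filter <- function(cell_records, min_ashman_d = 2) {
  if (nrow(cell_records) < 50) {
    stop("need at least 50 cells to fit the mixture")
  }
  x <- cell_records$mean_rfp
  fit <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  d <- sqrt(2) * abs(diff(mu)) / sqrt(sum(sdv^2))
  bright <- which.max(mu)
  if (d < min_ashman_d) {
    warning("mixture components indistinguishable: no cells filtered")
    return(list(cells = cell_records, threshold = NA_real_, means = mu,
                sds = sdv, ashman_d = d, filtered = FALSE))
  }
  thr <- mu[bright] - sdv[bright]
  list(cells = cell_records[x >= thr, ], threshold = unname(thr),
       means = mu, sds = sdv, ashman_d = unname(d), filtered = TRUE)
}

#' Normalised single-cell histogram in a depth band
#'
#' Emulates the near-surface heterogeneity analysis: cells with depth in
#' `[d_min, d_max]` um are selected and their YFP means are divided by the
#' mean RFP of the band's cells for that image, making the histogram
#' invariant to the instrument gain.
#'
#' @param cell_records Tibble with `depth_um`, `mean_yfp`, `mean_rfp`.
#' @param d_min,d_max Depth band (um), default 5 to 7.
#' @param breaks Passed to [graphics::hist()] (computed, not plotted).
#' @return List: `values` (normalised YFP per cell), `mids`, `density`,
#'   `n_cells`, `skewness`.
#' @importFrom graphics hist
#' @export
band_histogram <- function(cell_records, d_min = 5, d_max = 7,
                           breaks = 30) {
  sel <- !is.na(cell_records$depth_um) &
    cell_records$depth_um >= d_min & cell_records$depth_um <= d_max
  if (!any(sel)) stop("no cells in the requested depth band")
  band <- cell_records[sel, ]
  norm <- band$mean_yfp / mean(band$mean_rfp)
  h <- hist(norm, breaks = breaks, plot = FALSE)
  m <- mean(norm)
  s <- sd(norm)
  list(values = norm, mids = h$mids, density = h$density,
       n_cells = length(norm),
       skewness = mean((norm - m)^3) / s^3)
}

#' Anticorrelation between two reporters across single cells
#'
#' Ordinary-least-squares slope of the (mean-normalised) sporulation
#' reporter on the stress reporter, together with the slope distribution
#' under random permutations of the sporulation column (the shuffle null:
#' an anticorrelated pair gives a negative slope, a merely uncorrelated
#' pair is indistinguishable from its shuffles).
#'
#' @param cell_table Data frame with columns `yfp` and `cfp`,
#'   mean-normalised per image; at least 100 cells.
#' @param n_shuffles Number of random permutations.
#' @param seed Optional seed for the permutations.
#' @return List: `slope`, `intercept`, `shuffle_slopes` (length
#'   `n_shuffles`), `shuffle_mean`, `shuffle_se`.
#' @export
anticorrelation_slope <- function(cell_table, n_shuffles = 100,
                                  seed = NULL) {
  if (nrow(cell_table) < 100) stop("need at least 100 cells")
  if (var(cell_table$yfp) == 0) stop("zero variance in yfp")
  if (!is.null(seed)) set.seed(as.integer(seed))
  fit <- lm(cfp ~ yfp, data = cell_table)
  sl <- unname(coef(fit)[2])
  sh <- vapply(seq_len(n_shuffles), function(i) {
    yp <- cell_table$yfp
    cp <- sample(cell_table$cfp)
    unname(coef(lm(cp ~ yp))[2])
  }, numeric(1))
  list(slope = sl, intercept = unname(coef(fit)[1]), shuffle_slopes = sh,
       shuffle_mean = mean(sh), shuffle_se = sd(sh) / sqrt(n_shuffles))
}

#' Bivariate histogram of reporter co-expression
#'
#' 2D frequency table of mean-normalised stress-reporter versus
#' sporulation-reporter values across cells; the marginals sum to the
#' number of cells.
#'
#' @param cell_table Data frame with columns `yfp` and `cfp`.
#' @param bins Number of bins per axis.
#' @return List: `counts` (matrix `bins x bins`, rows = yfp bins),
#'   `yfp_breaks`, `cfp_breaks`.
#' @export
bivariate_histogram <- function(cell_table, bins = 50) {
  rng <- function(v) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  }
  ybr <- rng(cell_table$yfp)
  cbr <- rng(cell_table$cfp)
  yi <- findInterval(cell_table$yfp, ybr, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ci <- findInterval(cell_table$cfp, cbr, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(yi)) {
    counts[yi[k], ci[k]] <- counts[yi[k], ci[k]] + 1L
  }
  list(counts = counts, yfp_breaks = ybr, cfp_breaks = cbr)
}
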