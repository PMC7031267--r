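#' Ratiometric expression gradient versus depth
#'
#' The per-image sigma-B activity profile: within each depth bin, the mean
#' YFP-channel intensity over foreground pixels divided by the mean
#' RFP-channel intensity over the same pixels. Near the air interface the
#' cell density falls off and the biofilm start is ambiguous, so the top
#' `min_depth_um` (2 um by default) of all gradient data are discarded.
#' Bins whose RFP mean is zero are dropped and logged.
#'
#' @param yfp,rfp Corrected, co-registered channel matrices.
#' @param depthmap Depth matrix from [depth_map()] (um; `NA` outside the
#'   biofilm).
#' @param bin_width_um Depth bin width.
#' @param min_depth_um Depth below which data are discarded.
#' @return A `depth_profile` tibble: `depth` (bin centre, um), `value`
#'   (ratio), `n` (contributing pixels); attribute `dropped_bins` lists any
#'   zero-RFP bins.
#' @export
ratio_gradient <- function(yfp, rfp, depthmap, bin_width_um = 1,
                           min_depth_um = 2) {
  stopifnot(all(dim(yfp) == dim(rfp)), all(dim(yfp) == dim(depthmap)))
  d <- as.vector(depthmap)
  ok <- !is.na(d) & d >= min_depth_um
  if (!any(ok)) stop("no foreground pixels below the excluded top band")
  d <- d[ok]
  y <- as.vector(yfp)[ok]
  r <- as.vector(rfp)[ok]
  bin <- floor((d - min_depth_um) / bin_width_um)
  centres <- min_depth_um + (sort(unique(bin)) + 0.5) * bin_width_um
  ybar <- tapply(y, bin, mean)
  rbar <- tapply(r, bin, mean)
  n <- as.integer(tapply(y, bin, length))
  keep <- rbar > 0
  prof <- tibble::tibble(
    depth = centres[keep],
    value = as.numeric(ybar[keep] / rbar[keep]),
    n = n[keep]
  )
  attr(prof, "dropped_bins") <- centres[!keep]
  attr(prof, "stat") <- "ratio"
  class(prof) <- c("depth_profile", class(prof))
  prof
}

#' Average depth profiles across images
#'
#' Per-bin mean and standard error of the mean across a set of per-image
#' profiles (matched on bin centre), the error model used for gradient
#' plots.
#'
#' @param profiles List of `depth_profile` tibbles.
#' @return Tibble: `depth`, `mean`, `sem`, `n_images`.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  all <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    tibble::tibble(depth = p$depth, value = p$value, image = i)
  }))
  depths <- sort(unique(all$depth))
  out <- lapply(depths, function(d) {
    v <- all$value[all$depth == d]
    tibble::tibble(depth = d, mean = mean(v),
                   sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
                   n_images = length(v))
  })
  do.call(rbind, out)
}

#' Spore density profile versus depth
#'
#' Counts spores and cells in sliding depth windows `d - 1` to `d + 1` um
#' with centres every 0.5 um from 2 um (the excluded top band) to 140 um,
#' and reports either the ratio of spores to all objects
#' (`spores / (cells + spores)`) or the spore count scaled by the number of
#' biofilm pixels in the window. Windows containing no objects have no
#' ratio and are reported as `NA`.
#'
#' @param cells,spores Data frames of segmented objects carrying a
#'   `depth_um` column (e.g. from [segment_cells()] / [segment_spores()]).
#' @param depthmap,mask Depth matrix and biofilm mask; required for
#'   `mode = "per_pixel"`.
#' @param mode `"ratio"` or `"per_pixel"`.
#' @param d_min,d_max,step,halfwidth Window grid (um).
#' @return A `depth_profile` tibble: `depth`, `value`, `n` (objects or
#'   pixels in the window).
#' @export
spore_density_profile <- function(cells, spores, depthmap = NULL,
                                  mask = NULL,
                                  mode = c("ratio", "per_pixel"),
                                  d_min = 2, d_max = 140, step = 0.5,
                                  halfwidth = 1) {
  mode <- match.arg(mode)
  centres <- seq(d_min, d_max, by = step)
  dc <- cells$depth_um
  ds <- spores$depth_um
  nc <- vapply(centres, function(d) {
    sum(dc >= d - halfwidth & dc <= d + halfwidth, na.rm = TRUE)
  }, numeric(1))
  ns <- vapply(centres, function(d) {
    sum(ds >= d - halfwidth & ds <= d + halfwidth, na.rm = TRUE)
  }, numeric(1))
  if (mode == "ratio") {
    tot <- nc + ns
    value <- ifelse(tot > 0, ns / tot, NA_real_)
    n <- as.integer(tot)
  } else {
    if (is.null(depthmap)) {
      stop("per_pixel mode needs the depth map")
    }
    if (inherits(mask, "biofilm_mask")) mask <- mask$mask
    d <- as.vector(depthmap)
    if (!is.null(mask)) d[!as.vector(mask)] <- NA_real_
    npx <- vapply(centres, function(x) {
      sum(d >= x - halfwidth & d <= x + halfwidth, na.rm = TRUE)
    }, numeric(1))
    value <- ifelse(npx > 0, ns / npx, NA_real_)
    n <- as.integer(npx)
  }
  prof <- tibble::tibble(depth = centres, value = value, n = n)
  attr(prof, "stat") <- paste0("spore_", mode)
  class(prof) <- c("depth_profile", class(prof))
  prof
}
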