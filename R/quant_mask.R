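#' Subtract the mean background signal
#'
#' Pixelwise subtraction of the instrument/mounting-medium background,
#' clipped at zero.
#'
#' @param image Numeric matrix.
#' @param background_mean Non-negative scalar.
#' @return Matrix of the same dimension.
#' @export
subtract_background <- function(image, background_mean) {
  if (background_mean < 0) stop("background_mean must be >= 0")
  m <- pmax(image - background_mean, 0)
  dim(m) <- dim(image)
  m
}

#' Correct and estimate channel bleed-through
#'
#' `correct_bleedthrough` removes the fraction of the constitutive (RFP)
#' signal that leaks into the YFP channel: `yfp - fraction * rfp`, clipped
#' at zero. `estimate_bleedthrough` quantifies that fraction from
#' single-reporter controls: the mean excess YFP-channel signal of an
#' RFP-only strain (after subtracting the autofluorescence a reporterless
#' strain shows in the yellow channel) divided by its mean RFP signal, over
#' the biofilm foreground.
#'
#' @param yfp,rfp Co-registered, background-subtracted channel matrices.
#' @param fraction Bleed-through fraction in `[0, 1)`.
#' @param yfp_rfp_only,rfp_rfp_only YFP- and RFP-channel images of the
#'   RFP-only control strain (background-subtracted).
#' @param autofluor_yfp Mean yellow-channel autofluorescence of the
#'   no-reporter strain.
#' @param mask Optional logical foreground mask; defaults to an Otsu
#'   foreground of the RFP image.
#' @return `correct_bleedthrough`: corrected YFP matrix;
#'   `estimate_bleedthrough`: the estimated fraction.
#' @export
correct_bleedthrough <- function(yfp, rfp, fraction) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  stopifnot(all(dim(yfp) == dim(rfp)))
  m <- pmax(yfp - fraction * rfp, 0)
  dim(m) <- dim(yfp)
  m
}

#' @rdname correct_bleedthrough
#' @export
estimate_bleedthrough <- function(yfp_rfp_only, rfp_rfp_only,
                                  autofluor_yfp = 0, mask = NULL) {
  stopifnot(all(dim(yfp_rfp_only) == dim(rfp_rfp_only)))
  if (is.null(mask)) {
    v <- rfp_rfp_only / max(rfp_rfp_only)
    mask <- v > EBImage::otsu(EBImage::Image(v))
  }
  if (!any(mask)) stop("empty foreground mask")
  (mean(yfp_rfp_only[mask]) - autofluor_yfp) / mean(rfp_rfp_only[mask])
}

#' Segment the biofilm from the constitutive channel
#'
#' Low-magnification biofilm segmentation:
#' 1. global Otsu threshold gives the initial foreground;
#' 2. the foreground is broken into sub-segments of similar intensity by a
#'    watershed seeded at local maxima of the Gaussian-smoothed channel
#'    (label propagation over the intensity landscape);
#' 3. each sub-segment is eroded with a disc of `erosion_radius_px`;
#'    sub-segments erased entirely are taken to be thin autofluorescent
#'    agar and discarded, all others are restored to their pre-erosion
#'    shape;
#' 4. surviving contiguous sub-segments are re-joined;
#' 5. connected components with area below `min_area_frac` of the image are
#'    removed as sectioning artifacts.
#' Every removal is recorded with the rule that triggered it.
#'
#' @param rfp_image Single-channel 2D numeric matrix (constitutive
#'   reporter).
#' @param erosion_radius_px Radius of the circular structuring element.
#' @param min_area_frac Minimum component area as a fraction of the image.
#' @param smooth_sigma Gaussian smoothing sigma (px) applied before the
#'   watershed; must stay below the width of the thinnest structure to be
#'   isolated.
#' @param watershed_tolerance Minimum intensity prominence (on the image
#'   normalised to its maximum) for a local maximum to found its own
#'   sub-segment; shallower maxima are merged with their neighbours, which
#'   keeps the near-homogeneous biofilm interior in a few large
#'   sub-segments while structures separated by a dim seam (agar strips)
#'   form their own.
#' @return A `biofilm_mask`: list with `mask` (logical matrix), `removed`
#'   (tibble: label, rule, area) and the parameters used.
#' @export
segment_biofilm <- function(rfp_image, erosion_radius_px = 25,
                            min_area_frac = 0.10,
                            smooth_sigma = erosion_radius_px / 2,
                            watershed_tolerance = 0.05) {
  stopifnot(is.matrix(rfp_image))
  v <- rfp_image / max(rfp_image)
  thr <- EBImage::otsu(EBImage::Image(v))
  mask0 <- v > thr
  if (!any(mask0)) stop("no biofilm detected: empty Otsu foreground")

  sm <- as.matrix(EBImage::gblur(EBImage::Image(v), sigma = smooth_sigma))
  sub <- as.matrix(EBImage::watershed(EBImage::Image(sm * mask0),
                                      tolerance = watershed_tolerance,
                                      ext = 1))
  sub[!mask0] <- 0

  brush <- EBImage::makeBrush(2L * erosion_radius_px + 1L, "disc")
  removed <- list()
  keep_mask <- matrix(FALSE, nrow(rfp_image), ncol(rfp_image))
  for (L in setdiff(sort(unique(as.vector(sub))), 0)) {
    bin <- sub == L
    er <- as.matrix(EBImage::erode(EBImage::Image(bin * 1), brush)) > 0
    if (!any(er)) {
      removed[[length(removed) + 1L]] <-
        tibble::tibble(label = L, rule = "erosion", area = sum(bin))
    } else {
      keep_mask <- keep_mask | bin
    }
  }

  cc <- as.matrix(EBImage::bwlabel(EBImage::Image(keep_mask * 1)))
  min_area <- min_area_frac * length(rfp_image)
  final <- matrix(FALSE, nrow(rfp_image), ncol(rfp_image))
  for (L in setdiff(sort(unique(as.vector(cc))), 0)) {
    comp <- cc == L
    if (sum(comp) < min_area) {
      removed[[length(removed) + 1L]] <-
        tibble::tibble(label = -L, rule = "min_area", area = sum(comp))
    } else {
      final <- final | comp
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    tibble::tibble(label = integer(), rule = character(), area = integer())
  out <- list(mask = final, removed = removed,
              otsu_threshold = thr * max(rfp_image),
              erosion_radius_px = erosion_radius_px,
              min_area_frac = min_area_frac)
  class(out) <- "biofilm_mask"
  out
}

#' @export
print.biofilm_mask <- function(x, ...) {
  cat(sprintf(
    "Biofilm mask: %d foreground px (%.1f%%), %d segments removed (%s)\n",
    sum(x$mask), 100 * mean(x$mask), nrow(x$removed),
    if (nrow(x$removed)) paste(x$removed$rule, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Biofilm extent from a sparse single-cell image
#'
#' High-magnification images resolve individual cells rather than a
#' continuous band, so the biofilm extent is estimated as the smoothed
#' support of the cell signal: heavy Gaussian blur, Otsu threshold, hole
#' filling, and retention of the largest connected component. The resulting
#' mask is the depth reference for single-cell analyses.
#'
#' @param image Constitutive-channel matrix.
#' @param blur_sigma Blur sigma in px (should exceed the typical cell
#'   spacing).
#' @return Logical matrix.
#' @export
biofilm_mask_from_cells <- function(image, blur_sigma = 50) {
  v <- image / max(image)
  # the Gaussian kernel (2 * ceiling(3 sigma) + 1 wide) must fit the image
  blur_sigma <- min(blur_sigma, floor((min(dim(image)) - 3) / 6))
  sm <- EBImage::gblur(EBImage::Image(v), sigma = blur_sigma)
  bin <- sm > EBImage::otsu(sm)
  filled <- EBImage::fillHull(EBImage::Image(as.matrix(bin) * 1))
  lab <- as.matrix(EBImage::bwlabel(filled))
  if (max(lab) == 0) stop("no biofilm detected")
  areas <- tabulate(lab[lab > 0])
  lab == which.max(areas)
}

#' Depth of every biofilm pixel from the air-facing surface
#'
#' The scene convention is air at the top edge (row 1 side) and agar below.
#' The air region is the background connected to the top image edge; the
#' air-facing surface is the set of foreground pixels 4-adjacent to it.
#' Depth is the Euclidean distance (um) from each foreground pixel to the
#' nearest surface pixel, so it is exactly zero on the surface and well
#' defined under wrinkled tops.
#'
#' @param mask A `biofilm_mask` or logical matrix.
#' @param pixel_size_um Pixel size.
#' @return Numeric matrix of depths (um); `NA` outside the mask.
#' @export
depth_map <- function(mask, pixel_size_um) {
  if (inherits(mask, "biofilm_mask")) mask <- mask$mask
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  touches <- c(any(mask[1, ]), any(mask[nrow(mask), ]),
               any(mask[, 1]), any(mask[, ncol(mask)]))
  if (all(touches)) {
    stop("mask touches all four image edges: top surface ambiguous")
  }
  bg <- EBImage::bwlabel(EBImage::Image((!mask) * 1))
  air_labels <- setdiff(unique(as.vector(as.matrix(bg)[1, ])), 0)
  if (length(air_labels) == 0) {
    stop("no air region touches the top edge: top surface ambiguous")
  }
  air <- matrix(as.matrix(bg) %in% air_labels, nrow(mask), ncol(mask))
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) - dr
    cs <- seq_len(ncol(m)) - dc
    okr <- rs >= 1 & rs <= nrow(m)
    okc <- cs >= 1 & cs <= ncol(m)
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  near_air <- shift(air, 1, 0) | shift(air, -1, 0) |
    shift(air, 0, 1) | shift(air, 0, -1)
  surface <- mask & near_air
  if (!any(surface)) stop("no air-facing surface found")
  src <- matrix(1, nrow(mask), ncol(mask))
  src[surface] <- 0
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(src),
                                           metric = "euclidean"))
  d <- matrix(as.numeric(d), nrow(mask), ncol(mask)) * pixel_size_um
  d[!mask] <- NA_real_
  d
}
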