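#' Configuration of a synthetic biofilm cross-section scene
#'
#' Describes a multi-channel confocal-like image of a biofilm slice with the
#' air interface at the top edge (row 1 side) and agar below. The rendered
#' scene consists of a biofilm band delimited by a (flat or sinusoidally
#' wrinkled) top boundary, anisotropic Gaussian-profiled elliptical cells, a
#' diffuse biomass base signal in the constitutive channel, optional spores
#' (bright discs in a dedicated spore-reporter channel, dim in the
#' constitutive channel), an optional autofluorescent agar strip attached to
#' the biofilm bottom, an optional isolated blob, additive background,
#' channel bleed-through and Gaussian noise. Per-cell ground truth (position,
#' depth from the top boundary, true channel amplitudes, spore flag) is
#' retained for every rendered object.
#'
#' Intensities are in arbitrary 16-bit-like units. The single-cell YFP
#' (stress-reporter) amplitude follows a long-tailed Gamma law whose scale
#' decays with depth, halving every `yfp_halflife_um` micrometres - the
#' expression gradient the quantification pipeline must recover. The
#' optional sporulation (CFP) amplitudes are mean-normalised values
#' anticorrelated with YFP at a configured ordinary-least-squares slope.
#'
#' @param width_px,height_px Image size in pixels (columns, rows).
#' @param pixel_size_um Pixel size; 0.59 (low magnification), 0.31 (live
#'   gradients) and 0.05 (single-cell) are the common settings.
#' @param top_offset_um Mean depth of the biofilm top boundary below the
#'   image top edge.
#' @param wrinkle_amplitude_um,wrinkle_period_um Sinusoidal modulation of
#'   the top boundary (amplitude 0 = flat).
#' @param band_thickness_um Vertical extent of the biofilm band.
#' @param cell_density Cells per square micrometre inside the band.
#' @param cell_length_um,cell_width_um Ellipse axes of a cell.
#' @param min_spacing_um Minimum distance between cell centres (0 = none);
#'   used in single-cell scenes to keep objects separable.
#' @param band_base_intensity Diffuse biomass intensity added to the
#'   constitutive channel inside the band (unresolved cells at low
#'   magnification).
#' @param rfp_mean,rfp_sd Normal law of the constitutive (RFP) cell
#'   amplitude.
#' @param rfp_dim_frac,rfp_dim_mean,rfp_dim_sd Optional second, dimmer
#'   mixture component emulating out-of-focal-plane cells (`rfp_dim_frac`
#'   0 disables it).
#' @param yfp_shape Gamma shape of the single-cell YFP amplitude (small
#'   shape = long tail).
#' @param yfp_scale_top Gamma scale at depth 0.
#' @param yfp_halflife_um Depth over which the YFP scale halves.
#' @param spore_prob_top,spore_decay_um Probability that an object at depth
#'   `d` is a spore: `spore_prob_top * exp(-d / spore_decay_um)` (0
#'   disables spores).
#' @param spore_radius_um,spore_intensity,spore_rfp_factor Spore disc
#'   radius, its brightness in the spore-reporter channel, and the dim
#'   fraction of `rfp_mean` it shows in the constitutive channel.
#' @param with_cfp Render a sporulation (CFP) channel whose per-cell values
#'   anticorrelate with YFP.
#' @param cfp_slope,cfp_noise OLS slope and residual noise of the
#'   mean-normalised CFP-on-YFP relation.
#' @param cfp_intensity Intensity unit for the rendered CFP channel.
#' @param agar_strip_px,agar_strip_frac,agar_intensity Thickness (rows),
#'   covered width fraction and brightness of an autofluorescent agar strip
#'   attached below the biofilm band (thickness 0 disables it).
#' @param agar_gap_px,agar_gap_intensity Thickness and brightness of the
#'   dim partial-volume seam joining the strip to the biofilm (the seam
#'   stays above typical Otsu thresholds so the strip is attached to the
#'   foreground, as in real cryosections).
#' @param blob_radius_px,blob_intensity Isolated bright disc rendered away
#'   from the band (radius 0 disables it); exercises the small-segment
#'   removal rule.
#' @param background Additive background offset (all channels).
#' @param noise_sd Gaussian noise standard deviation (all channels).
#' @param bleed_through Fraction of the constitutive-channel signal added
#'   into the YFP channel before noise.
#' @param seed Integer seed; scenes are deterministic given the seed.
#' @return A `scene_config` (validated named list).
#' @seealso [scene_preset()], [generate_scene()]
#' @export
scene_config <- function(width_px = 600, height_px = 400,
                         pixel_size_um = 0.59, top_offset_um = 20,
                         wrinkle_amplitude_um = 0, wrinkle_period_um = 120,
                         band_thickness_um = 150, cell_density = 0.3,
                         cell_length_um = 2.5, cell_width_um = 0.9,
                         min_spacing_um = 0, band_base_intensity = 1500,
                         rfp_mean = 3000, rfp_sd = 300, rfp_dim_frac = 0,
                         rfp_dim_mean = 1000, rfp_dim_sd = 200,
                         yfp_shape = 2, yfp_scale_top = 2000,
                         yfp_halflife_um = 20, spore_prob_top = 0,
                         spore_decay_um = 15, spore_radius_um = 0.5,
                         spore_intensity = 5000, spore_rfp_factor = 0.15,
                         with_cfp = FALSE, cfp_slope = -0.31,
                         cfp_noise = 0.1, cfp_intensity = 1500,
                         agar_strip_px = 0, agar_strip_frac = 0.6,
                         agar_intensity = 1200, agar_gap_px = 4,
                         agar_gap_intensity = 700, blob_radius_px = 0,
                         blob_intensity = 2500, background = 100,
                         noise_sd = 30, bleed_through = 0, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "scene_config"
  stopifnot(
    cfg$width_px >= 16, cfg$height_px >= 16, cfg$pixel_size_um > 0,
    cfg$cell_density >= 0, cfg$band_thickness_um > 0,
    cfg$noise_sd >= 0, cfg$background >= 0,
    cfg$bleed_through >= 0, cfg$bleed_through < 1,
    cfg$spore_prob_top >= 0, cfg$spore_prob_top <= 1
  )
  cover <- cfg$cell_density * pi * cfg$cell_length_um * cfg$cell_width_um / 4
  if (cover > 0.9) {
    stop("cell density implies > 90% overlap: unsegmentable by construction")
  }
  cfg
}

#' Preset scene configurations
#'
#' Three ready-made study conditions: `"lowmag"` (0.59 um/px band scene for
#' biofilm segmentation and ratiometric gradients), `"highmag"` (0.05 um/px
#' single-cell scene for cell segmentation and band histograms) and
#' `"sporedensity"` (0.1 um/px deep scene with cells and spores for the
#' spore-density profile). Any field can be overridden through `...`.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [scene_config()].
#' @return A `scene_config`.
#' @export
scene_preset <- function(preset = c("lowmag", "highmag", "sporedensity"),
                         ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    lowmag = list(
      width_px = 1000, height_px = 400, pixel_size_um = 0.59,
      top_offset_um = 20, band_thickness_um = 150, cell_density = 0.3,
      band_base_intensity = 2000, rfp_mean = 1200, rfp_sd = 150,
      yfp_shape = 2, yfp_scale_top = 2000,
      yfp_halflife_um = 20, background = 100, noise_sd = 30
    ),
    highmag = list(
      width_px = 1200, height_px = 600, pixel_size_um = 0.05,
      top_offset_um = 3, band_thickness_um = 26, cell_density = 0.06,
      min_spacing_um = 2.4, band_base_intensity = 0,
      yfp_shape = 1, yfp_scale_top = 2000, yfp_halflife_um = 20,
      background = 100, noise_sd = 30
    ),
    sporedensity = list(
      width_px = 600, height_px = 1100, pixel_size_um = 0.1,
      top_offset_um = 4, band_thickness_um = 100, cell_density = 0.08,
      min_spacing_um = 2.2, band_base_intensity = 0,
      spore_prob_top = 0.6, spore_decay_um = 15,
      background = 100, noise_sd = 30
    )
  )
  args <- utils::modifyList(base, list(...))
  do.call(scene_config, args)
}

# Row coordinate (1-based, fractional) of the biofilm top boundary per column.
top_boundary_px <- function(cfg) {
  px <- cfg$pixel_size_um
  cols <- seq_len(cfg$width_px)
  1 + cfg$top_offset_um / px +
    (cfg$wrinkle_amplitude_um / px) *
      sin(2 * pi * cols * px / cfg$wrinkle_period_um)
}

# Exact Euclidean distance (um) from points to the sampled top boundary.
boundary_depth_um <- function(rows, cols, top_px, pixel_size_um) {
  boundary_depth_cpp(rows, cols, top_px) * pixel_size_um
}

# Thin candidate centres so no two survive closer than min_dist (px).
thin_by_spacing <- function(rows, cols, min_dist) {
  keep <- logical(length(rows))
  kr <- kc <- numeric(0)
  for (i in seq_along(rows)) {
    if (length(kr) == 0 ||
        min((kr - rows[i])^2 + (kc - cols[i])^2) >= min_dist^2) {
      keep[i] <- TRUE
      kr <- c(kr, rows[i])
      kc <- c(kc, cols[i])
    }
  }
  keep
}

#' Render a synthetic biofilm scene with ground truth
#'
#' Deterministic given `cfg$seed`. Channels are built as background + sum of
#' cell kernels (+ biomass base, agar strip, blob), the YFP channel receives
#' `bleed_through` times the constitutive signal before noise, Gaussian
#' noise is added last and all intensities are clipped at zero.
#'
#' @param cfg A [scene_config()].
#' @return A `synthetic_scene`: list with `channels` (named list of numeric
#'   matrices: `rfp`, `yfp`, and when configured `spore`, `cfp`), `truth`
#'   (tibble of per-object ground truth: centre, depth from the top
#'   boundary, true amplitudes, `is_spore`, `is_dim`), `mask_truth` (logical
#'   band mask), `top_px` (boundary row per column) and `config`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(as.integer(cfg$seed))
  H <- cfg$height_px
  W <- cfg$width_px
  px <- cfg$pixel_size_um
  top <- top_boundary_px(cfg)
  thick_px <- cfg$band_thickness_um / px
  rows_m <- matrix(seq_len(H), H, W)
  top_m <- matrix(top, H, W, byrow = TRUE)
  mask_truth <- rows_m >= top_m & rows_m < top_m + thick_px

  # --- place cells -----------------------------------------------------
  band_depth_um <- min(cfg$band_thickness_um, (H - max(top)) * px)
  n_target <- round(cfg$cell_density * band_depth_um * W * px)
  n_cand <- if (cfg$min_spacing_um > 0) 2L * n_target else n_target
  ccol <- runif(n_cand, 1, W)
  cdep <- runif(n_cand, 0, band_depth_um / px)  # rows below local top
  crow <- top[pmin(W, pmax(1, round(ccol)))] + cdep
  ok <- crow < H - 1
  ccol <- ccol[ok]; crow <- crow[ok]
  if (cfg$min_spacing_um > 0) {
    keep <- thin_by_spacing(crow, ccol, cfg$min_spacing_um / px)
    crow <- crow[keep][seq_len(min(n_target, sum(keep)))]
    ccol <- ccol[keep][seq_len(min(n_target, sum(keep)))]
  }
  n <- length(crow)
  depth_um <- boundary_depth_um(crow, ccol, top, px)

  # --- per-cell ground truth -------------------------------------------
  is_dim <- runif(n) < cfg$rfp_dim_frac
  rfp_amp <- ifelse(is_dim,
    rnorm(n, cfg$rfp_dim_mean, cfg$rfp_dim_sd),
    rnorm(n, cfg$rfp_mean, cfg$rfp_sd)
  )
  rfp_amp <- pmax(rfp_amp, 0)
  yfp_scale <- cfg$yfp_scale_top * 2^(-depth_um / cfg$yfp_halflife_um)
  yfp_amp <- rgamma(n, shape = cfg$yfp_shape) * yfp_scale
  p_spore <- cfg$spore_prob_top * exp(-depth_um / cfg$spore_decay_um)
  is_spore <- runif(n) < p_spore
  cfp_amp <- rep(NA_real_, n)
  if (cfg$with_cfp) {
    ynorm <- yfp_amp / mean(yfp_amp)
    cfp_amp <- (1 - cfg$cfp_slope) + cfg$cfp_slope * ynorm +
      cfg$cfp_noise * rnorm(n)
  }
  angle <- runif(n, 0, pi)

  # --- render channels --------------------------------------------------
  sig_l <- cfg$cell_length_um / px / 4
  sig_s <- cfg$cell_width_um / px / 4
  rfp <- matrix(0, H, W) + cfg$band_base_intensity * mask_truth
  yfp <- matrix(0, H, W)
  spore_ch <- if (cfg$spore_prob_top > 0) matrix(0, H, W) else NULL
  cfp_ch <- if (cfg$with_cfp) matrix(0, H, W) else NULL
  sp_r <- cfg$spore_radius_um / px
  veg <- !is_spore
  rfp <- render_kernels_cpp(rfp, crow[veg], ccol[veg], rfp_amp[veg],
                            sig_l, sig_s, angle[veg])
  yfp <- render_kernels_cpp(yfp, crow[veg], ccol[veg], yfp_amp[veg],
                            sig_l, sig_s, angle[veg])
  if (cfg$with_cfp) {
    cfp_ch <- render_kernels_cpp(cfp_ch, crow[veg], ccol[veg],
                                 cfp_amp[veg] * cfg$cfp_intensity,
                                 sig_l, sig_s, angle[veg])
  }
  if (any(is_spore)) {
    rfp <- render_discs_cpp(rfp, crow[is_spore], ccol[is_spore],
                            rep(cfg$spore_rfp_factor * cfg$rfp_mean,
                                sum(is_spore)), sp_r)
    spore_ch <- render_discs_cpp(spore_ch, crow[is_spore], ccol[is_spore],
                                 rep(cfg$spore_intensity, sum(is_spore)),
                                 sp_r)
  }

  # --- agar strip and isolated blob ------------------------------------
  # The strip is separated from the biomass by a dim partial-volume seam
  # (as at the biofilm/agar interface of real cryosections); the seam stays
  # above the Otsu threshold so strip and biofilm form one connected
  # foreground, which is what makes the watershed/erosion step necessary.
  if (cfg$agar_strip_px > 0) {
    bot <- ceiling(max(top) + thick_px)
    c0 <- round(W * 0.2)
    c1 <- min(W, c0 + round(W * cfg$agar_strip_frac))
    g0 <- min(H, bot)
    g1 <- min(H, bot + cfg$agar_gap_px - 1L)
    rfp[g0:g1, c0:c1] <- rfp[g0:g1, c0:c1] + cfg$agar_gap_intensity
    r0 <- min(H, g1 + 1L)
    r1 <- min(H, g1 + cfg$agar_strip_px)
    rfp[r0:r1, c0:c1] <- rfp[r0:r1, c0:c1] + cfg$agar_intensity
  }
  if (cfg$blob_radius_px > 0) {
    blob_row <- min(H - cfg$blob_radius_px - 2,
                    ceiling(max(top) + thick_px) + 3 * cfg$blob_radius_px)
    rfp <- render_discs_cpp(rfp, blob_row, round(W * 0.85),
                            cfg$blob_intensity, cfg$blob_radius_px)
  }

  # --- bleed-through, background, noise --------------------------------
  yfp <- yfp + cfg$bleed_through * rfp
  addnoise <- function(m) {
    pmax(m + cfg$background + rnorm(length(m), 0, cfg$noise_sd), 0)
  }
  channels <- list(rfp = addnoise(rfp), yfp = addnoise(yfp))
  if (!is.null(spore_ch)) channels$spore <- addnoise(spore_ch)
  if (!is.null(cfp_ch)) channels$cfp <- addnoise(cfp_ch)

  truth <- tibble::tibble(
    id = seq_len(n), row = crow, col = ccol,
    x_um = ccol * px, y_um = crow * px, depth_um = depth_um,
    rfp = rfp_amp, yfp = yfp_amp, cfp = cfp_amp,
    is_spore = is_spore, is_dim = is_dim
  )
  out <- list(channels = channels, truth = truth, mask_truth = mask_truth,
              top_px = top, config = cfg)
  class(out) <- "synthetic_scene"
  out
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic biofilm scene: %d x %d px (%.2f um/px), %d objects (%d spores), channels: %s\n",
    x$config$height_px, x$config$width_px, x$config$pixel_size_um,
    nrow(x$truth), sum(x$truth$is_spore),
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Synthetic bivariate reporter table
#'
#' Per-cell `(yfp, cfp)` pairs emulating the mean-normalised co-expression
#' of a stress reporter and a sporulation reporter: `yfp` is Gamma with mean
#' 1, and `cfp = (1 - slope) + slope * yfp + noise * N(0,1)`, so both
#' columns have expectation 1 and the expected ordinary-least-squares slope
#' of `cfp` on `yfp` equals `slope`. Values are not clipped: they emulate
#' background-subtracted normalised intensities, for which noise can dip
#' below zero.
#'
#' @param n Number of cells (>= 10).
#' @param slope Configured OLS slope (negative = anticorrelated).
#' @param noise Residual noise standard deviation.
#' @param seed Integer seed.
#' @param shape Gamma shape of the `yfp` marginal.
#' @return Tibble with columns `yfp`, `cfp`.
#' @examples
#' tab <- generate_bivariate_cells(1000, slope = -0.31, seed = 1)
#' coef(lm(cfp ~ yfp, tab))[2]
#' @export
generate_bivariate_cells <- function(n, slope = -0.31, noise = 0.1,
                                     seed = 1, shape = 4) {
  if (n < 10) stop("n must be >= 10")
  set.seed(as.integer(seed))
  yfp <- rgamma(n, shape = shape, rate = shape)
  cfp <- (1 - slope) + slope * yfp + noise * rnorm(n)
  tibble::tibble(yfp = yfp, cfp = cfp)
}

#' Write a synthetic scene to disk
#'
#' Channels as 16-bit single-channel TIFFs (`<prefix>_<channel>.tif`,
#' intensities clipped to \[0, 65535\]), the truth table as CSV and the
#' ground-truth mask as TIFF.
#'
#' @param scene A `synthetic_scene`.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_scene <- function(scene, prefix) {
  stopifnot(inherits(scene, "synthetic_scene"))
  files <- character(0)
  for (ch in names(scene$channels)) {
    f <- paste0(prefix, "_", ch, ".tif")
    img <- pmin(pmax(scene$channels[[ch]], 0), 65535) / 65535
    EBImage::writeImage(EBImage::Image(img), f, type = "tiff",
                        bits.per.sample = 16L)
    files <- c(files, f)
  }
  f <- paste0(prefix, "_truth.csv")
  write.csv(scene$truth, f, row.names = FALSE)
  files <- c(files, f)
  f <- paste0(prefix, "_mask.tif")
  EBImage::writeImage(EBImage::Image(scene$mask_truth * 1), f, type = "tiff")
  files <- c(files, f)
  invisible(files)
}

#' Read a single-channel 16-bit TIFF written by [write_scene()]
#'
#' @param path TIFF file.
#' @return Numeric matrix on the original intensity scale.
#' @export
read_channel <- function(path) {
  img <- EBImage::readImage(path)
  as.matrix(EBImage::imageData(img)) * 65535
}
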