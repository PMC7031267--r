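#' Run configuration for a reproducible multi-stage analysis
#'
#' Bundles stage selection, model parameters, scene configuration and the
#' root seed for a staged run, and round-trips losslessly through YAML (or
#' JSON). Stochastic stages always take their seed from the config - there
#' is no silent entropy.
#'
#' @param stages Character vector drawn from `"sweep"`, `"synth"`,
#'   `"segment"`, `"gradient"`, `"spore_density"`; executed in dependency
#'   order.
#' @param out_dir Output directory (created if missing).
#' @param seed Root integer seed.
#' @param model A [model_params()] object (for `"sweep"`).
#' @param scene A [scene_config()] object (for the imaging stages).
#' @param sweep List of sweep options: `n_replicates`, `n_grid`.
#' @return A `run_config`.
#' @export
run_config <- function(stages = character(), out_dir = tempfile("run"),
                       seed = 1, model = model_params(),
                       scene = scene_config(),
                       sweep = list(n_replicates = 1000, n_grid = 10)) {
  known <- c("sweep", "synth", "segment", "gradient", "spore_density")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  cfg <- list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
              model = model, scene = scene, sweep = sweep)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lst <- list(stages = cfg$stages, out_dir = cfg$out_dir, seed = cfg$seed,
              model = unclass(cfg$model), scene = unclass(cfg$scene),
              sweep = cfg$sweep)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  run_config(
    stages = as.character(unlist(lst$stages)),
    out_dir = lst$out_dir, seed = lst$seed,
    model = do.call(model_params, lst$model),
    scene = do.call(scene_config, lst$scene),
    sweep = lst$sweep
  )
}

#' Execute the configured stages and return an artifact manifest
#'
#' Runs the requested stages in dependency order (`synth` before `segment`
#' before `gradient`/`spore_density`), writes every artifact under
#' `cfg$out_dir`, echoes the resolved configuration next to the outputs and
#' returns a manifest of all files with their MD5 content hashes. Identical
#' config and seed give identical hashes for the deterministic stages. A
#' stage whose upstream artifact is missing fails with an error naming the
#' stage to run first.
#'
#' @param cfg A [run_config()].
#' @return Tibble manifest: `stage`, `file`, `md5`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  order <- c("sweep", "synth", "segment", "gradient", "spore_density")
  stages <- order[order %in% cfg$stages]
  manifest <- list()
  add <- function(stage, files) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, file = basename(files),
      md5 = unname(tools::md5sum(files))
    )
  }
  path <- function(f) file.path(cfg$out_dir, f)
  need <- function(f, producer) {
    if (!file.exists(path(f))) {
      stop(sprintf("missing upstream artifact '%s': run stage '%s' first",
                   f, producer))
    }
  }
  if (length(stages)) {
    write_run_config(cfg, path("config.yaml"))
    add("config", path("config.yaml"))
  }
  for (stage in stages) {
    if (stage == "sweep") {
      sw <- run_sweep(cfg$model, n_replicates = cfg$sweep$n_replicates,
                      seed = cfg$seed,
                      zetas = zeta_grid(cfg$sweep$n_grid))
      write_sweep(sw, path("sweep.csv"))
      add("sweep", path("sweep.csv"))
    } else if (stage == "synth") {
      sc <- cfg$scene
      sc$seed <- cfg$seed
      scene <- generate_scene(sc)
      files <- write_scene(scene, path("scene"))
      add("synth", files)
    } else if (stage == "segment") {
      need("scene_rfp.tif", "synth")
      rfp <- read_channel(path("scene_rfp.tif"))
      rfp <- subtract_background(rfp, cfg$scene$background)
      bm <- segment_biofilm(rfp)
      EBImage::writeImage(EBImage::Image(bm$mask * 1), path("mask.tif"),
                          type = "tiff")
      write.csv(bm$removed, path("mask_removed.csv"), row.names = FALSE)
      add("segment", c(path("mask.tif"), path("mask_removed.csv")))
    } else if (stage == "gradient") {
      need("mask.tif", "segment")
      need("scene_yfp.tif", "synth")
      mask <- as.matrix(EBImage::imageData(
        EBImage::readImage(path("mask.tif")))) > 0.5
      rfp <- subtract_background(read_channel(path("scene_rfp.tif")),
                                 cfg$scene$background)
      yfp <- subtract_background(read_channel(path("scene_yfp.tif")),
                                 cfg$scene$background)
      yfp <- correct_bleedthrough(yfp, rfp, cfg$scene$bleed_through)
      dm <- depth_map(mask, cfg$scene$pixel_size_um)
      prof <- ratio_gradient(yfp, rfp, dm)
      write.csv(prof, path("gradient.csv"), row.names = FALSE)
      add("gradient", path("gradient.csv"))
    } else if (stage == "spore_density") {
      need("mask.tif", "segment")
      need("scene_spore.tif", "synth")
      mask <- as.matrix(EBImage::imageData(
        EBImage::readImage(path("mask.tif")))) > 0.5
      rfp <- subtract_background(read_channel(path("scene_rfp.tif")),
                                 cfg$scene$background)
      sp <- subtract_background(read_channel(path("scene_spore.tif")),
                                cfg$scene$background)
      dm <- depth_map(mask, cfg$scene$pixel_size_um)
      cells <- segment_cells(rfp, depthmap = dm,
                             pixel_size_um = cfg$scene$pixel_size_um)
      spores <- segment_spores(sp, median_cell_area_px = median(cells$area_px),
                               depthmap = dm,
                               pixel_size_um = cfg$scene$pixel_size_um)
      prof <- spore_density_profile(cells, spores, dm, mask)
      write.csv(cells, path("cells.csv"), row.names = FALSE)
      write.csv(spores, path("spores.csv"), row.names = FALSE)
      write.csv(prof, path("spore_profile.csv"), row.names = FALSE)
      add("spore_density", c(path("cells.csv"), path("spores.csv"),
                             path("spore_profile.csv")))
    }
  }
  if (length(manifest) == 0) {
    return(tibble::tibble(stage = character(), file = character(),
                          md5 = character()))
  }
  do.call(rbind, manifest)
}
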