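test_that("scenes are deterministic given the seed", {
  a <- generate_scene(scene_preset("highmag", seed = 5))
  b <- generate_scene(scene_preset("highmag", seed = 5))
  expect_identical(a$channels$rfp, b$channels$rfp)
  expect_identical(a$truth, b$truth)
  c <- generate_scene(scene_preset("highmag", seed = 6))
  expect_false(identical(a$channels$rfp, c$channels$rfp))
})

test_that("an empty noiseless scene is a constant background", {
  cfg <- scene_config(cell_density = 0, band_base_intensity = 0,
                      noise_sd = 0, background = 120, seed = 1)
  sc <- generate_scene(cfg)
  expect_equal(unique(as.vector(sc$channels$rfp)), 120)
  expect_equal(unique(as.vector(sc$channels$yfp)), 120)
  expect_equal(nrow(sc$truth), 0)
})

test_that("unsegmentable densities are refused at configuration time", {
  expect_error(scene_config(cell_density = 2), "overlap")
})

test_that("ground-truth depth equals the exact distance to the configured top boundary", {
  cfg <- scene_preset("lowmag", seed = 8, width_px = 120, height_px = 150,
                      wrinkle_amplitude_um = 6, wrinkle_period_um = 40,
                      band_thickness_um = 60)
  sc <- generate_scene(cfg)
  top <- sc$top_px
  # independent brute-force nearest-boundary-point search
  oracle <- vapply(seq_len(nrow(sc$truth)), function(i) {
    min(sqrt((sc$truth$row[i] - top)^2 +
             (sc$truth$col[i] - seq_along(top))^2)) * cfg$pixel_size_um
  }, numeric(1))
  expect_equal(sc$truth$depth_um, oracle, tolerance = 1e-10)
  expect_true(all(sc$truth$depth_um >= 0))
})

test_that("per-cell YFP decays with depth at the configured halving rate", {
  sc <- cached_scene("lowmag", seed = 31)
  tr <- sc$truth
  # E[log yfp] = const + log(scale(depth)): slope is -log(2)/halflife
  fit <- lm(log(yfp) ~ depth_um, data = tr[tr$yfp > 0, ])
  expect_equal(unname(coef(fit)[2]), -log(2) / 20, tolerance = 0.05)
})

test_that("the near-surface truth histogram is long-tailed and narrows with depth", {
  shallow <- deep <- c()
  for (seed in 71:82) {
    tr <- cached_scene("highmag", seed = seed)$truth
    shallow <- c(shallow, tr$yfp[tr$depth_um >= 5 & tr$depth_um <= 7])
    deep <- c(deep, tr$yfp[tr$depth_um >= 18 & tr$depth_um <= 20])
  }
  expect_gt(length(shallow), 50)
  expect_gt(sample_skewness(shallow), 1)
  expect_gt(sd(shallow), sd(deep))
})

test_that("bivariate tables carry the configured least-squares slope", {
  flat <- generate_bivariate_cells(1000, slope = 0, noise = 0, seed = 1)
  expect_equal(unique(flat$cfp), 1)
  tab <- generate_bivariate_cells(1e5, slope = -0.31, noise = 0.1, seed = 2)
  expect_equal(mean(tab$yfp), 1, tolerance = 0.02)
  expect_equal(unname(coef(lm(cfp ~ yfp, tab))[2]), -0.31,
               tolerance = 0.01)
  # exchangeability: permuting one column destroys the relation
  set.seed(3)
  shuf <- tab
  shuf$yfp <- sample(shuf$yfp)
  expect_equal(unname(coef(lm(cfp ~ yfp, shuf))[2]), 0, tolerance = 0.01)
  expect_error(generate_bivariate_cells(5), "n must be")
})

test_that("scenes round-trip through 16-bit TIFF and CSV", {
  sc <- generate_scene(scene_preset("highmag", seed = 9, width_px = 200,
                                    height_px = 150))
  pre <- file.path(tempdir(), "scene_rt")
  files <- write_scene(sc, pre)
  expect_true(all(file.exists(files)))
  back <- read_channel(paste0(pre, "_rfp.tif"))
  expect_equal(dim(back), dim(sc$channels$rfp))
  expect_lt(max(abs(back - sc$channels$rfp)), 1)  # 16-bit quantisation
  tr <- read.csv(paste0(pre, "_truth.csv"))
  expect_equal(nrow(tr), nrow(sc$truth))
  unlink(files)
})
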