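test_that("the Gamma approximation has burst-frequency shape and burst-size scale", {
  p <- model_params(zeta = 5e-3)
  ga <- gamma_approx(p)
  expect_equal(unname(ga), c(0.7, 10))
  # mean of the approximation equals the closed-form mean protein
  expect_equal(prod(ga), unname(two_stage_moments(p)["mean_protein"]))
  # doubling the transcription scale doubles the shape, not the scale
  ga2 <- gamma_approx(model_params(zeta = 5e-3, s_A = 1.4))
  expect_equal(unname(ga2), c(1.4, 10))
  expect_error(gamma_approx(model_params(epsilon = 0)), "epsilon")
})

test_that("the pulse threshold is the 20th Gamma percentile and rounds to 1", {
  p <- model_params(zeta = 5e-3)
  expect_equal(theta_rounded(p), 1)
  th <- compute_theta(p)
  # Monte-Carlo quantile oracle for the unrounded value
  set.seed(20)
  mc <- quantile(rgamma(1e6, shape = 0.7, scale = 10), 0.2, names = FALSE)
  expect_equal(th, mc, tolerance = 0.01)
  expect_equal(compute_theta(model_params(beta = 0)), 0)
  expect_error(compute_theta(p, percentile = 0), "percentile")
  expect_error(compute_theta(p, percentile = 1.2), "percentile")
})

test_that("the recomputed threshold is non-decreasing in stress", {
  th <- vapply(zeta_grid(10), function(z) {
    compute_theta(model_params(zeta = z))
  }, numeric(1))
  expect_true(all(diff(th) >= 0))
})

test_that("longest excursion measures a single contiguous interval, strictly above", {
  p <- model_params(transient = 0)
  never <- manual_trajectory(c(0, 50), A = c(0, 1), t_end = 100, p = p)
  expect_equal(longest_time_above(never, "A", 1), 0)  # A = 1 is not > 1

  single <- manual_trajectory(c(0, 100), A = c(2, 0), t_end = 500, p = p)
  expect_equal(longest_time_above(single, "A", 1), 100)

  # 600 s and 1200 s excursions separated by a dip: contiguous, not summed
  two <- manual_trajectory(c(0, 600, 700, 1900), A = c(5, 0, 3, 0),
                           t_end = 2500, p = p)
  expect_equal(longest_time_above(two, "A", 1), 1200)

  # an excursion still open at the end of the run is closed at t_end
  open <- manual_trajectory(c(0, 10), A = c(0, 4), t_end = 2000, p = p)
  expect_equal(longest_time_above(open, "A", 1), 1990)
})

test_that("the spore rule requires strictly more than 30 simulated minutes", {
  p <- model_params()
  expect_true(classify_spore(1860, p))
  expect_false(classify_spore(1800, p))
  expect_false(classify_spore(0, p))
  expect_error(classify_spore(-1, p), ">= 0")
  # monotone in duration
  d <- seq(0, 4000, by = 200)
  expect_true(all(diff(classify_spore(d, p)) >= 0))
})

test_that("spore_outcome ties the excursion rule to the trajectory", {
  p <- model_params(zeta = 5e-3, t_total = 8000)
  traj <- simulate_pulses(p, seed = 31)
  out <- spore_outcome(traj)
  expect_gte(out$longest_excursion, 0)
  expect_identical(out$is_spore, out$longest_excursion > 1800)
  expect_identical(out$final_B,
                   unname(traj$states[nrow(traj$states), "B"]))
})

test_that("without repression the spore fraction rises along the stress gradient", {
  p <- model_params(s_B = 0, b_B = 0, u_B = 0)
  zetas <- zeta_grid(6)
  sw <- run_sweep(p, n_replicates = 1000, seed = 77, zetas = zetas)
  ct <- suppressWarnings(
    cor.test(zetas, sw$spore_fraction, method = "spearman",
             alternative = "greater")
  )
  expect_lt(ct$p.value, 0.01)
})
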