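test_that("parameter validation enforces the model invariants", {
  expect_s3_class(model_params(), "model_params")
  expect_error(model_params(zeta = 0), "zeta")
  expect_error(model_params(delta = -1), "rates")
  expect_error(model_params(t_total = 2000), "t_total")
  expect_error(model_params(transient = -1), "transient")
})

test_that("propensities match the reaction rates at hand-checked states", {
  p <- model_params(zeta = 5e-3)
  init <- c(G_A = 1, BG_A = 0, G_B = 1, R_A = 0, R_B = 0, A = 0, B = 0)
  a <- propensities(init, p)
  expect_length(a, 10)
  expect_equal(unname(a[["tx_A"]]), 3.5e-3)
  expect_equal(unname(a[["tx_B"]]), 5e-3 * 0.25)
  expect_true(all(a[setdiff(names(a), c("tx_A", "tx_B"))] == 0))

  bound <- c(G_A = 0, BG_A = 1, G_B = 0, R_A = 0, R_B = 0, A = 0, B = 0)
  a2 <- propensities(bound, p)
  expect_equal(unname(a2[["unbind"]]), 0.1)
  expect_true(all(a2[setdiff(names(a2), "unbind")] == 0))

  a3 <- propensities(c(G_A = 1, BG_A = 0, G_B = 1, R_A = 0, R_B = 0,
                       A = 10, B = 0), p)
  expect_equal(unname(a3[["deg_A"]]), 0.05)

  expect_error(propensities(c(G_A = 1, BG_A = 0, G_B = 1, R_A = -1,
                              R_B = 0, A = 0, B = 0), p), "negative")
})

test_that("identical parameters and seed reproduce the trajectory exactly", {
  p <- model_params(zeta = 5e-3, t_total = 5000)
  t1 <- simulate_pulses(p, seed = 42)
  t2 <- simulate_pulses(p, seed = 42)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$states, t2$states)
  t3 <- simulate_pulses(p, seed = 43)
  expect_false(identical(t1$times, t3$times))
})

test_that("gene copy numbers are conserved at every event", {
  for (zeta in c(5e-5, 5e-4, 5e-3)) {
    traj <- simulate_pulses(model_params(zeta = zeta, t_total = 8000),
                            seed = round(1e4 * zeta) + 3L)
    expect_true(all(traj$states[, "G_A"] + traj$states[, "BG_A"] == 1))
    expect_true(all(traj$states[, "G_B"] == 1))
    expect_true(all(traj$states >= 0))
    expect_true(all(diff(traj$times) > 0))
  }
})

test_that("silencing the repressor module keeps B and its mRNA at zero", {
  p <- model_params(zeta = 5e-3, s_B = 0, b_B = 0, u_B = 0, t_total = 5000)
  traj <- simulate_pulses(p, seed = 9)
  expect_true(all(traj$states[, "B"] == 0))
  expect_true(all(traj$states[, "R_B"] == 0))
})

test_that("stationary mean of the isolated A module matches the closed form", {
  # zeta*s_A*beta/(delta*epsilon) = 7 at the top of the gradient
  p <- model_params(zeta = 5e-3, s_B = 0, b_B = 0, u_B = 0,
                    t_total = 50000, transient = 5000)
  means <- vapply(1:20, function(i) {
    set.seed(i)
    biofilmpulse:::ssa_summary_cpp(biofilmpulse:::param_vector(p),
                                   p$t_total, p$transient,
                                   p$theta)[["tavg_A"]]
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 7), 3 * se)
})

test_that("discarding the transient clips the time axis and keeps the boundary state", {
  p <- model_params(zeta = 5e-3, t_total = 5000)
  traj <- simulate_pulses(p, seed = 5)
  expect_identical(discard_transient(traj, 0), traj)
  post <- discard_transient(traj, 390)
  expect_equal(post$times[1], 390)
  expect_true(all(post$times[-1] > 390))
  # boundary state equals the state in force at t = 390 in the full path
  expect_equal(unname(post$states[1, ]),
               unname(traj$states[max(which(traj$times <= 390)), ]))
  expect_error(discard_transient(traj, 6000), "shorter")
})

test_that("trajectory lookup respects the piecewise-constant convention", {
  traj <- manual_trajectory(times = c(0, 10, 20), A = c(0, 3, 1),
                            t_end = 30)
  expect_equal(unname(trajectory_at(traj, c(0, 9.99, 10, 19.9, 25, 30), "A")),
               c(0, 0, 3, 3, 1, 1))
  expect_error(trajectory_at(traj, 31, "A"), "outside")
})
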