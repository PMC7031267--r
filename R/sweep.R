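#' Log-spaced stress gradient grid
#'
#' The simulated biofilm depth axis: `zeta = 10^g` with `g` evenly spaced on
#' `[log10(lower), log10(upper)]`, endpoints included and ascending. The
#' defaults put `zeta = 5e-5` at the biofilm bottom and `zeta = 5e-3` at the
#' top.
#'
#' @param n Number of grid points (>= 2); the full-scale experiment uses 20.
#' @param lower,upper Grid endpoints (both > 0).
#' @return Numeric vector of length `n`.
#' @examples
#' zeta_grid(20)[c(1, 20)]
#' @export
zeta_grid <- function(n = 20, lower = 5e-5, upper = 5e-3) {
  if (n < 2) stop("n must be >= 2")
  if (lower <= 0 || upper <= lower) stop("need 0 < lower < upper")
  10^seq(log10(lower), log10(upper), length.out = n)
}

#' Replicate ensembles across the stress gradient
#'
#' For every `zeta` in the grid, runs `n_replicates` independent exact
#' simulations, discards the transient, measures the longest excursion of
#' `A` above the threshold, applies the spore rule, and records the final
#' `B` count. Per-replicate seeds are derived from the root seed by a
#' counter scheme, so results are reproducible and independent of execution
#' order. The full-scale study profile is 20 grid points and 10,000
#' replicates per point; a scaled-down profile (10 x 1,000) is practical for
#' desk work.
#'
#' @param p A [model_params()] object (its `zeta` is overridden by the
#'   grid).
#' @param n_replicates Replicates per grid point (>= 1).
#' @param seed Root integer seed.
#' @param zetas Stress grid; defaults to [zeta_grid()] with 20 points.
#' @param theta Threshold for the excursion rule; defaults to `p$theta`.
#' @return A `sweep_result`: list with `zetas`, `spore_fraction`,
#'   `mean_final_B`, `sd_final_B`, `mean_A`, `n_replicates`, `s_B`, `seed`,
#'   `theta`.
#' @export
run_sweep <- function(p, n_replicates = 10000, seed = 1,
                      zetas = zeta_grid(20), theta = p$theta) {
  validate_params(p)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  nz <- length(zetas)
  spore_fraction <- mean_final_B <- sd_final_B <- mean_A <- numeric(nz)
  for (iz in seq_len(nz)) {
    pz <- p
    pz$zeta <- zetas[iz]
    pv <- param_vector(pz)
    long <- finB <- avgA <- numeric(n_replicates)
    for (i in seq_len(n_replicates)) {
      set.seed(derive_seed(seed, (iz - 1L) * n_replicates + i))
      s <- ssa_summary_cpp(pv, p$t_total, p$transient, theta)
      long[i] <- s[["longest_excursion"]]
      finB[i] <- s[["final_B"]]
      avgA[i] <- s[["tavg_A"]]
    }
    spore_fraction[iz] <- mean(classify_spore(long, p))
    mean_final_B[iz] <- mean(finB)
    sd_final_B[iz] <- sd(finB)
    mean_A[iz] <- mean(avgA)
  }
  res <- list(
    zetas = zetas, spore_fraction = spore_fraction,
    mean_final_B = mean_final_B, sd_final_B = sd_final_B, mean_A = mean_A,
    n_replicates = n_replicates, s_B = p$s_B, seed = as.integer(seed),
    theta = theta
  )
  class(res) <- "sweep_result"
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "Gradient sweep: %d zeta points x %d replicates (s_B = %g, seed %d)\n",
    length(x$zetas), x$n_replicates, x$s_B, x$seed
  ))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(
    zeta = x$zetas, n = x$n_replicates, spore_fraction = x$spore_fraction,
    mean_final_B = x$mean_final_B, sd_final_B = x$sd_final_B,
    mean_A = x$mean_A
  )
}

#' Write a sweep result as CSV
#'
#' Columns: `zeta, n, spore_fraction, mean_final_B, sd_final_B, mean_A`.
#'
#' @param x A `sweep_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(x, path) {
  stopifnot(inherits(x, "sweep_result"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- x / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

#' Compare two sweep conditions per gradient position
#'
#' Differences (condition 2 minus condition 1) in spore fraction and in mean
#' final `B` at every `zeta`, with Wilson score intervals for each
#' proportion, a Newcombe score interval for the proportion difference, and
#' a normal-theory interval for the final-`B` difference.
#'
#' @param r1,r2 `sweep_result` objects on identical `zeta` grids.
#' @param conf Confidence level.
#' @return A tibble with one row per `zeta`.
#' @importFrom stats qnorm
#' @export
compare_conditions <- function(r1, r2, conf = 0.95) {
  stopifnot(inherits(r1, "sweep_result"), inherits(r2, "sweep_result"))
  if (length(r1$zetas) != length(r2$zetas) ||
      any(abs(r1$zetas - r2$zetas) > 1e-12 * r1$zetas)) {
    stop("zeta grids differ between conditions")
  }
  z <- qnorm(1 - (1 - conf) / 2)
  n1 <- r1$n_replicates
  n2 <- r2$n_replicates
  x1 <- round(r1$spore_fraction * n1)
  x2 <- round(r2$spore_fraction * n2)
  w1 <- t(vapply(x1, wilson_interval, numeric(2), n = n1, conf = conf))
  w2 <- t(vapply(x2, wilson_interval, numeric(2), n = n2, conf = conf))
  p1 <- x1 / n1
  p2 <- x2 / n2
  # Newcombe hybrid score interval for p2 - p1
  d <- p2 - p1
  d_lo <- d - sqrt((p2 - w2[, 1])^2 + (w1[, 2] - p1)^2)
  d_hi <- d + sqrt((w2[, 2] - p2)^2 + (p1 - w1[, 1])^2)
  se_B <- sqrt(r1$sd_final_B^2 / n1 + r2$sd_final_B^2 / n2)
  dB <- r2$mean_final_B - r1$mean_final_B
  tibble::tibble(
    zeta = r1$zetas,
    spore_fraction_1 = p1, spore_fraction_2 = p2,
    sf_lower_1 = w1[, 1], sf_upper_1 = w1[, 2],
    sf_lower_2 = w2[, 1], sf_upper_2 = w2[, 2],
    diff_spore_fraction = d, diff_sf_lower = d_lo, diff_sf_upper = d_hi,
    diff_mean_final_B = dB,
    diff_B_lower = dB - z * se_B, diff_B_upper = dB + z * se_B
  )
}

#' Two-proportion test of spore fractions at one gradient position
#'
#' Convenience wrapper around [stats::prop.test()] comparing the spore
#' fraction of two conditions at a chosen `zeta` index.
#'
#' @param r1,r2 `sweep_result` objects on identical grids.
#' @param index Grid index (default: the top of the gradient).
#' @param ... Passed to [stats::prop.test()].
#' @return An `htest` object.
#' @importFrom stats prop.test
#' @export
spore_fraction_test <- function(r1, r2, index = length(r1$zetas), ...) {
  x <- c(round(r1$spore_fraction[index] * r1$n_replicates),
         round(r2$spore_fraction[index] * r2$n_replicates))
  n <- c(r1$n_replicates, r2$n_replicates)
  prop.test(x, n, ...)
}
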