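#' Gamma approximation of the isolated sporulation module
#'
#' With the repressor gene absent, species `A` follows the classic two-stage
#' (transcription--translation) bursty expression model whose stationary
#' protein distribution is well approximated by a Gamma law with shape equal
#' to the burst frequency per protein lifetime and scale equal to the mean
#' burst size:
#' `shape = zeta * s_A / epsilon`, `scale = beta / delta`.
#'
#' @param p A [model_params()] object.
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' gamma_approx(model_params(zeta = 5e-3)) # shape 0.7, scale 10
#' @export
gamma_approx <- function(p) {
  validate_params(p)
  if (p$epsilon == 0 || p$delta == 0) {
    stop("gamma approximation requires delta > 0 and epsilon > 0")
  }
  c(shape = p$zeta * p$s_A / p$epsilon, scale = p$beta / p$delta)
}

#' Pulse-detection threshold from the Gamma approximation
#'
#' The threshold is defined as the 20th-percentile of the stationary
#' distribution of `A` when the repressor gene is absent, taken from the
#' Gamma approximation of the two-stage model. `theta_rounded()` returns the
#' nearest integer, which is what the discrete spore rule uses. Note the
#' default analysis pipeline keeps the fixed value `theta = 1` stored in
#' [model_params()]; recomputation is opt-in.
#'
#' @param p A [model_params()] object.
#' @param percentile Quantile level in (0, 1); default 0.2.
#' @return `compute_theta`: the (unrounded) quantile; `theta_rounded`: the
#'   nearest integer.
#' @examples
#' compute_theta(model_params(zeta = 5e-3)) # ~0.92
#' theta_rounded(model_params(zeta = 5e-3)) # 1
#' @export
compute_theta <- function(p, percentile = 0.2) {
  if (percentile <= 0 || percentile >= 1) {
    stop("percentile must lie strictly inside (0, 1)")
  }
  ga <- gamma_approx(p)
  if (ga[["scale"]] == 0 || ga[["shape"]] == 0) return(0)
  qgamma(percentile, shape = ga[["shape"]], scale = ga[["scale"]])
}

#' @rdname compute_theta
#' @export
theta_rounded <- function(p, percentile = 0.2) {
  round(compute_theta(p, percentile))
}

#' Longest contiguous time a species spends strictly above a threshold
#'
#' Operates on the piecewise-constant sample path: the count in force on
#' `[times[i], times[i+1])` contributes that whole interval when it exceeds
#' the threshold ("exceeds" is strict, so for integer counts and
#' `threshold = 1` this means a count of at least 2). Excursions are
#' contiguous, not cumulative; an excursion still open at `t_end` is closed
#' there. The transient should already have been discarded.
#'
#' @param traj A `pulse_trajectory`.
#' @param species `"A"` or `"B"`.
#' @param threshold Numeric threshold (molecules).
#' @return Duration in seconds (0 if the species never exceeds the
#'   threshold).
#' @export
longest_time_above <- function(traj, species = c("A", "B"), threshold) {
  stopifnot(inherits(traj, "pulse_trajectory"))
  species <- match.arg(species)
  above <- traj$states[, species] > threshold
  if (!any(above)) return(0)
  seg <- diff(c(traj$times, traj$t_end))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max(vapply(which(r$values), function(k) {
    sum(seg[starts[k]:ends[k]])
  }, numeric(1)))
}

#' Spore classification rule
#'
#' A simulated cell is judged to have produced a spore when the longest
#' contiguous excursion of `A` above its threshold lasts strictly longer
#' than 30 simulated minutes (1800 s by default).
#'
#' @param duration Longest excursion duration (s), non-negative.
#' @param p A [model_params()] object supplying `spore_min_duration`.
#' @return Logical.
#' @examples
#' classify_spore(1860, model_params()) # TRUE
#' classify_spore(1800, model_params()) # FALSE (strict inequality)
#' @export
classify_spore <- function(duration, p) {
  if (any(duration < 0)) stop("duration must be >= 0")
  duration > p$spore_min_duration
}

#' Spore outcome of a simulated trajectory
#'
#' Discards the transient, measures the longest excursion of `A` above the
#' threshold, reads the final `B` count, and applies the spore rule.
#'
#' @param traj A `pulse_trajectory`.
#' @param p A [model_params()] object; defaults to the trajectory's own.
#' @param theta Threshold; defaults to `p$theta` (the fixed paper value 1).
#' @return List with `longest_excursion` (s), `final_B` (molecules),
#'   `is_spore` (logical).
#' @export
spore_outcome <- function(traj, p = traj$params, theta = p$theta) {
  post <- discard_transient(traj, p$transient)
  dur <- longest_time_above(post, "A", theta)
  final_B <- post$states[nrow(post$states), "B"]
  list(
    longest_excursion = dur,
    final_B = unname(final_B),
    is_spore = classify_spore(dur, p)
  )
}
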