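#' Reaction propensities of the pulsing network
#'
#' Computes the ten reaction rates of the two-regulator network at a given
#' state: transcription, translation and degradation for both modules plus
#' the two directions of the reversible repressor--operator reaction
#' (`B + G_A <-> BG_A`; binding sequesters one B molecule, unbinding
#' releases it).
#'
#' @param state Named numeric vector (or single-row data frame) with
#'   non-negative integer counts for `G_A`, `BG_A`, `G_B`, `R_A`, `R_B`,
#'   `A`, `B`.
#' @param p A [model_params()] object.
#' @return Named numeric vector of length 10:
#'   `c(tx_A, tl_A, deg_R_A, deg_A, tx_B, tl_B, deg_R_B, deg_B, bind, unbind)`.
#' @examples
#' p <- model_params(zeta = 5e-3)
#' propensities(c(G_A = 1, BG_A = 0, G_B = 1, R_A = 0, R_B = 0, A = 0, B = 0), p)
#' @export
propensities <- function(state, p) {
  validate_params(p)
  state <- unlist(state)[.species]
  if (anyNA(state)) stop("state must contain counts for: ",
                         paste(.species, collapse = ", "))
  if (any(state < 0)) stop("negative count in state")
  if (any(state != round(state))) stop("counts must be integers")
  s <- as.list(state)
  a <- c(
    tx_A    = p$zeta * p$s_A * s$G_A,
    tl_A    = p$beta * s$R_A,
    deg_R_A = p$delta * s$R_A,
    deg_A   = p$epsilon * s$A,
    tx_B    = p$zeta * p$s_B * s$G_B,
    tl_B    = p$beta * s$R_B,
    deg_R_B = p$delta * s$R_B,
    deg_B   = p$epsilon * s$B,
    bind    = p$b_B * s$B * s$G_A,
    unbind  = p$u_B * s$BG_A
  )
  a
}

#' Simulate the pulsing network exactly
#'
#' Draws one exact sample path of the reaction network with the
#' Doob--Gillespie stochastic simulation algorithm, starting from the
#' standard initial condition (all species absent except one free copy of
#' each gene, `G_A = G_B = 1`) and running until `p$t_total`. The path is
#' piecewise constant: the state in row `i` holds on
#' `[times[i], times[i+1])`, and the final state holds until `t_end`.
#'
#' @param p A [model_params()] object.
#' @param seed Integer seed; identical `(p, seed)` reproduce the trajectory
#'   exactly.
#' @return A `pulse_trajectory`: list with `times` (event times, starting at
#'   0), `states` (integer matrix, one row per event, columns
#'   `G_A, BG_A, G_B, R_A, R_B, A, B`), `t_end`, `params`, `seed`.
#' @examples
#' traj <- simulate_pulses(model_params(zeta = 5e-3, t_total = 3000), seed = 1)
#' head(traj$states)
#' @export
simulate_pulses <- function(p, seed) {
  validate_params(p)
  set.seed(as.integer(seed))
  res <- ssa_simulate_cpp(param_vector(p), p$t_total)
  states <- res$states
  colnames(states) <- .species
  traj <- list(times = res$times, states = states, t_end = res$t_end,
               params = p, seed = as.integer(seed))
  class(traj) <- "pulse_trajectory"
  traj
}

#' @export
print.pulse_trajectory <- function(x, ...) {
  cat(sprintf(
    "Pulse trajectory: %d events over [0, %g] s (seed %d)\n",
    length(x$times) - 1L, x$t_end, x$seed
  ))
  invisible(x)
}

#' Drop the initial transient of a trajectory
#'
#' Clips a trajectory to `t >= transient`, carrying over the state in force
#' at the cut as the new boundary state so downstream statistics use only
#' the stationary window.
#'
#' @param traj A `pulse_trajectory`.
#' @param transient Time to discard (s); defaults to the trajectory's own
#'   `params$transient`.
#' @return A `pulse_trajectory` starting at `t = transient`.
#' @export
discard_transient <- function(traj, transient = traj$params$transient) {
  stopifnot(inherits(traj, "pulse_trajectory"))
  if (transient < 0) stop("transient must be >= 0")
  if (traj$t_end < transient) stop("trajectory shorter than transient")
  if (transient == 0) return(traj)
  keep <- traj$times > transient
  boundary <- max(which(traj$times <= transient))
  traj$states <- rbind(traj$states[boundary, , drop = FALSE],
                       traj$states[keep, , drop = FALSE])
  traj$times <- c(transient, traj$times[keep])
  traj
}

#' Piecewise-constant species values of a trajectory at given times
#'
#' @param traj A `pulse_trajectory`.
#' @param times Query times within `[times[1], t_end]`.
#' @param species One of `"G_A"`, `"BG_A"`, `"G_B"`, `"R_A"`, `"R_B"`,
#'   `"A"`, `"B"`.
#' @return Integer vector of counts at `times`.
#' @export
trajectory_at <- function(traj, times, species = "A") {
  stopifnot(inherits(traj, "pulse_trajectory"))
  species <- match.arg(species, .species)
  idx <- findInterval(times, traj$times)
  if (any(idx < 1) || any(times > traj$t_end)) {
    stop("query times outside trajectory support")
  }
  traj$states[idx, species]
}

#' Write a trajectory as CSV
#'
#' Columns: `t, G_A, BG_A, G_B, R_A, R_B, A, B`, one row per event.
#'
#' @param traj A `pulse_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pulse_trajectory"))
  df <- data.frame(t = traj$times, traj$states, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
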