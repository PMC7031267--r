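#' Closed-form stationary moments of the two-stage expression model
#'
#' Standard birth--death moments for one transcription--translation module
#' in isolation (no repression): mean mRNA `zeta*s/delta`, mean protein
#' `zeta*s*beta/(delta*epsilon)`, and protein Fano factor
#' `1 + beta/(delta + epsilon)`. Used as an independent oracle for the
#' simulator.
#'
#' @param p A [model_params()] object.
#' @param s Transcription scale of the module (defaults to `p$s_A`).
#' @return Named vector `c(mean_mRNA, mean_protein, fano_protein)`.
#' @examples
#' two_stage_moments(model_params(zeta = 5e-3)) # 0.7, 7, 6
#' @export
two_stage_moments <- function(p, s = p$s_A) {
  validate_params(p)
  if (p$delta == 0 || p$epsilon == 0) {
    stop("moments require delta > 0 and epsilon > 0")
  }
  c(
    mean_mRNA = p$zeta * s / p$delta,
    mean_protein = p$zeta * s * p$beta / (p$delta * p$epsilon),
    fano_protein = 1 + p$beta / (p$delta + p$epsilon)
  )
}

#' Stationary distribution of the truncated chemical master equation
#'
#' Brute-force oracle for the single-gene two-stage subsystem: enumerates
#' states `(R, A)` with `R <= max_R`, `A <= max_X`, assembles the sparse
#' transition-rate generator (transcription at `zeta*s`, mRNA decay
#' `delta*R`, translation `beta*R`, protein decay `epsilon*A`), and solves
#' for its null space directly (one balance equation replaced by the
#' normalisation constraint). The truncation must be wide enough that the
#' stationary mass on the boundary is below `boundary_tol`, otherwise an
#' error instructs enlarging it.
#'
#' @param p A [model_params()] object (module rate `zeta*s`, `s = p$s_A`).
#' @param max_R,max_X Truncation bounds for mRNA and protein counts.
#' @param s Transcription scale (defaults to `p$s_A`).
#' @param boundary_tol Maximum stationary mass allowed on the truncation
#'   boundary (default `1e-6`).
#' @return A `truncated_cme`: list with `stationary` (matrix
#'   `(max_R+1) x (max_X+1)`, rows mRNA count 0..max_R, columns protein
#'   count 0..max_X), `max_R`, `max_X`, `boundary_mass`.
#' @export
cme_stationary <- function(p, max_R, max_X, s = p$s_A,
                           boundary_tol = 1e-6) {
  validate_params(p)
  k0 <- p$zeta * s
  nR <- max_R + 1L
  nA <- max_X + 1L
  n <- nR * nA
  idx <- function(r, a) r * nA + a + 1L  # 0-based counts -> 1-based index
  grid <- expand.grid(r = 0:max_R, a = 0:max_X)
  r <- grid$r
  a <- grid$a
  from <- to <- integer(0)
  rate <- numeric(0)
  add <- function(i, j, w) {
    keep <- w > 0
    from <<- c(from, i[keep]); to <<- c(to, j[keep])
    rate <<- c(rate, w[keep])
  }
  ok <- r < max_R
  add(idx(r, a)[ok], idx(r + 1L, a)[ok], rep(k0, sum(ok)))
  ok <- r > 0
  add(idx(r, a)[ok], idx(r - 1L, a)[ok], (p$delta * r)[ok])
  ok <- a < max_X
  add(idx(r, a)[ok], idx(r, a + 1L)[ok], (p$beta * r)[ok])
  ok <- a > 0
  add(idx(r, a)[ok], idx(r, a - 1L)[ok], (p$epsilon * a)[ok])
  G <- Matrix::sparseMatrix(i = from, j = to, x = rate, dims = c(n, n))
  Matrix::diag(G) <- Matrix::diag(G) - Matrix::rowSums(G)
  A <- Matrix::t(G)
  A[n, ] <- 1  # replace one balance equation by normalisation
  b <- c(rep(0, n - 1L), 1)
  pi <- as.numeric(Matrix::solve(A, b))
  pi[pi < 0 & pi > -1e-12] <- 0
  pi <- pi / sum(pi)
  stat <- matrix(pi, nrow = nR, ncol = nA, byrow = TRUE,
                 dimnames = list(R = 0:max_R, A = 0:max_X))
  bmass <- sum(stat[nR, ]) + sum(stat[, nA]) - stat[nR, nA]
  if (bmass >= boundary_tol) {
    stop(sprintf(
      "boundary mass %.2e >= %.0e: enlarge max_R/max_X", bmass, boundary_tol
    ))
  }
  out <- list(stationary = stat, max_R = max_R, max_X = max_X,
              boundary_mass = bmass)
  class(out) <- "truncated_cme"
  out
}

#' Moments of a truncated CME solution
#'
#' @param cme A `truncated_cme` object.
#' @return Named vector `c(mean_mRNA, mean_protein, fano_protein)`.
#' @export
cme_moments <- function(cme) {
  stopifnot(inherits(cme, "truncated_cme"))
  pR <- rowSums(cme$stationary)
  pA <- colSums(cme$stationary)
  r <- 0:cme$max_R
  a <- 0:cme$max_X
  mR <- sum(r * pR)
  mA <- sum(a * pA)
  vA <- sum(a^2 * pA) - mA^2
  c(mean_mRNA = mR, mean_protein = mA, fano_protein = vA / mA)
}

#' Total-variation distance between two distributions on the same grid
#'
#' @param p,q Non-negative arrays of identical dimension; each is
#'   normalised to sum to 1 before comparison.
#' @return `0.5 * sum(|p - q|)`.
#' @export
tv_distance <- function(p, q) {
  stopifnot(all(dim(p) == dim(q)))
  0.5 * sum(abs(p / sum(p) - q / sum(q)))
}

#' Empirical stationary occupancy of (mRNA, protein) from the simulator
#'
#' Runs the exact simulator with the repressor module silenced
#' (`s_B = b_B = u_B = 0`) and accumulates the time-weighted occupancy of
#' `(R_A, A)` over the stationary window. The companion of
#' [cme_stationary()] in the simulator-equivalence check.
#'
#' @param p A [model_params()] object; its `s_B`, `b_B`, `u_B` are forced
#'   to 0.
#' @param max_R,max_X Histogram bounds (mass outside is reported in
#'   `excess`).
#' @param t_total,transient Simulation horizon and discarded initial time
#'   (s); default to the values in `p`.
#' @param seed Integer seed.
#' @return List with `occupancy` (normalised matrix) and `excess` (fraction
#'   of time outside the bounds).
#' @export
ssa_occupancy <- function(p, max_R, max_X, t_total = p$t_total,
                          transient = p$transient, seed = 1) {
  validate_params(p)
  pz <- p
  pz$s_B <- 0
  pz$b_B <- 0
  pz$u_B <- 0
  set.seed(as.integer(seed))
  res <- ssa_occupancy_cpp(param_vector(pz), t_total, transient,
                           as.integer(max_R), as.integer(max_X))
  dimnames(res$occupancy) <- list(R = 0:max_R, A = 0:max_X)
  res
}
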