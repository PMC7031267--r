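#' Parameters of the two-regulator pulsing model
#'
#' Bundles every rate constant of the stochastic reaction network together
#' with the decision thresholds used downstream. The network has two
#' transcription--translation modules: species `A` stands for the sporulation
#' programme and species `B` for the general stress response sigma factor,
#' with `B` able to bind the `A` gene and block its transcription. The model
#' is phenomenological: it reproduces pulsatile expression, not the
#' biochemistry of either pathway. All times are in seconds.
#'
#' @param zeta Dimensionless stress multiplier standing in for position in
#'   the biofilm (`5e-5` = bottom, `5e-3` = top). Must be positive.
#' @param s_A Transcription rate scale for the sporulation mRNA (s^-1).
#' @param s_B Transcription rate scale for the stress-regulator mRNA (s^-1);
#'   the study conditions use 0.25 and the doubled 0.5.
#' @param beta Translation rate (s^-1 per mRNA).
#' @param delta mRNA degradation rate (s^-1 per molecule).
#' @param epsilon Protein degradation rate (s^-1 per molecule).
#' @param b_B Rate of repressor binding to the free `A` gene (s^-1 per B
#'   molecule).
#' @param u_B Repressor unbinding rate (s^-1).
#' @param theta Spore-detection threshold in molecules; the default pipeline
#'   uses the fixed value 1 (see [compute_theta()] for the Gamma-quantile
#'   recomputation).
#' @param spore_min_duration Minimum contiguous time `A` must spend strictly
#'   above `theta` for the run to count as a spore (s); default 1800 s
#'   (30 simulated minutes).
#' @param transient Initial simulated time discarded before any statistic is
#'   computed (s); default 390 s (6.5 simulated minutes).
#' @param t_total Total simulated time (s). Must exceed
#'   `transient + spore_min_duration`. Default 21,600 s (6 simulated hours),
#'   long enough for pulse trains to develop.
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params(zeta = 5e-3)
#' p$s_A
#' @export
model_params <- function(zeta = 5e-3, s_A = 0.7, s_B = 0.25, beta = 0.05,
                         delta = 0.005, epsilon = 0.005, b_B = 1.0,
                         u_B = 0.1, theta = 1, spore_min_duration = 1800,
                         transient = 390, t_total = 21600) {
  p <- list(
    zeta = zeta, s_A = s_A, s_B = s_B, beta = beta, delta = delta,
    epsilon = epsilon, b_B = b_B, u_B = u_B, theta = theta,
    spore_min_duration = spore_min_duration, transient = transient,
    t_total = t_total
  )
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate model parameters
#'
#' Checks the invariants: all rates non-negative, `zeta > 0`, and
#' `t_total > transient + spore_min_duration`.
#'
#' @param p A [model_params()] object.
#' @return `p`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all model parameters must be numeric")
  rates <- c("s_A", "s_B", "beta", "delta", "epsilon", "b_B", "u_B")
  if (any(unlist(p[rates]) < 0)) stop("all rates must be >= 0")
  if (p$zeta <= 0) stop("zeta must be > 0")
  if (p$theta < 0) stop("theta must be >= 0")
  if (p$transient < 0) stop("transient must be >= 0")
  if (p$t_total <= p$transient + p$spore_min_duration) {
    stop("t_total must exceed transient + spore_min_duration")
  }
  invisible(p)
}

# Parameter vector in the order the compiled core expects.
param_vector <- function(p) {
  c(p$zeta, p$s_A, p$s_B, p$beta, p$delta, p$epsilon, p$b_B, p$u_B)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-regulator pulsing model parameters (time unit: s)\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Read or write model parameters as a flat key/value config file
#'
#' Round-trips a [model_params()] object through YAML (or JSON, by file
#' extension) so a simulation run can be reproduced from its resolved config.
#'
#' @param p A `model_params` object.
#' @param path File path; `.yaml`/`.yml` or `.json`.
#' @return `write_params` returns `path` invisibly; `read_params` a
#'   `model_params` object.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  lst <- unclass(p)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(model_params, lst)
}
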