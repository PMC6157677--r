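#' Per-step nest-failure hazard model
#'
#' The per-step probability `h` that a nest is destroyed (by predation,
#' weather, or similar) is drawn fresh on every breeding time step from a
#' Beta(alpha, beta) distribution with `alpha = h_m / h_v`,
#' `beta = (1 - h_m) / h_v`, so that its mean is exactly `h_m`. Only
#' convex, positively skewed shapes (`1 < alpha < beta`) are admitted.
#' Optionally the sampled hazard is inflated for larger clutches
#' (clutch-size-dependent predation): each draw is multiplied by
#' `1 + gamma * (c - 1) / (c_ref - 1)` and clamped at 1, so `gamma = 0`
#' recovers the clutch-independent model exactly and a maximal clutch with
#' `gamma = 1` faces a doubled hazard.
#'
#' @param h_m mean per-step failure probability, in (0, 0.5).
#' @param h_v positive beta inverse-scale parameter.
#' @param mode `"independent"` or `"clutch_dependent"`.
#' @param gamma non-negative clutch-dependence strength.
#' @param c_ref reference (maximum) clutch size used to normalize the
#'   clutch dependence.
#' @return An object of class `"hazard_model"` with fields `alpha`, `beta`,
#'   `mode`, `gamma`, `c_ref`, and `h_const` (`NA` for the stochastic beta
#'   model; see [constant_hazard()]).
#' @seealso [constant_hazard()], [draw_hazard()], [expected_survival_beta()]
#' @examples
#' hz <- hazard_model(h_m = 0.03, h_v = 0.01)
#' hz$alpha  # 3
#' hz$beta   # 97
#' @export
hazard_model <- function(h_m = 0.03, h_v = 0.01,
                         mode = c("independent", "clutch_dependent"),
                         gamma = 0, c_ref = 10) {
  mode <- match.arg(mode)
  alpha <- h_m / h_v
  beta <- (1 - h_m) / h_v
  if (!(alpha > 1 && alpha < beta))
    stop("hazard shape must satisfy 1 < alpha < beta; got alpha=",
         signif(alpha, 4), ", beta=", signif(beta, 4))
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(alpha = alpha, beta = beta, mode = mode, gamma = gamma,
                 c_ref = as.integer(c_ref), h_const = NA_real_),
            class = "hazard_model")
}

#' Degenerate (constant) hazard model
#'
#' A point-mass hazard: every breeding step uses the same failure
#' probability `h`. Useful for deterministic traces (`h = 0`), for the
#' constant-hazard analytic formulas, and as the `h_v -> 0` limit of the
#' beta model.
#'
#' @param h per-step failure probability in \[0, 1\].
#' @inheritParams hazard_model
#' @return A `"hazard_model"` object with `h_const = h`.
#' @export
constant_hazard <- function(h, mode = c("independent", "clutch_dependent"),
                            gamma = 0, c_ref = 10) {
  mode <- match.arg(mode)
  stopifnot(h >= 0, h <= 1, gamma >= 0)
  structure(list(alpha = NA_real_, beta = NA_real_, mode = mode,
                 gamma = gamma, c_ref = as.integer(c_ref), h_const = h),
            class = "hazard_model")
}

#' Hazard model implied by a parameter set
#'
#' @param params a `clutch_params` object.
#' @return The `"hazard_model"` the simulator will use for those parameters.
#' @export
hazard_from_params <- function(params) {
  stopifnot(inherits(params, "clutch_params"))
  hazard_model(h_m = params$h_m, h_v = params$h_v,
               mode = params$predation_mode, gamma = params$predation_gamma,
               c_ref = params$c_max)
}

# Multiplier applied to each sampled hazard under clutch-dependent predation.
hazard_multiplier <- function(model, c) {
  if (model$mode != "clutch_dependent" || model$c_ref <= 1L) return(1)
  1 + model$gamma * (c - 1) / (model$c_ref - 1)
}

#' Draw per-step hazards
#'
#' Samples `n` independent hazard values for a breeder with clutch size `c`,
#' applying the clutch-dependence multiplier and clamping to \[0, 1\].
#' Uses R's global RNG stream.
#'
#' @param model a `hazard_model`.
#' @param c clutch size of the focal breeder.
#' @param n number of draws.
#' @return Numeric vector of `n` hazards in \[0, 1\].
#' @export
draw_hazard <- function(model, c = 1L, n = 1L) {
  stopifnot(inherits(model, "hazard_model"), c >= 1, c <= model$c_ref)
  h <- if (is.na(model$h_const)) stats::rbeta(n, model$alpha, model$beta)
       else rep_len(model$h_const, n)
  pmin(1, h * hazard_multiplier(model, c))
}

#' One Bernoulli nest-survival test
#'
#' Given the current hazard `h`, the nest fails on this step with
#' probability exactly `h`: a uniform number `u` is drawn and the attempt
#' fails iff `h > u`.
#'
#' @param h per-step failure probability (vectorized).
#' @return Logical vector: `TRUE` means the nest failed this step.
#' @export
step_failure <- function(h) {
  stopifnot(all(h >= 0), all(h <= 1))
  h > stats::runif(length(h))
}

#' Probability a breeding attempt fails on step k
#'
#' For a constant hazard `h`, the attempt survives each of the first
#' `k - 1` steps with probability `1 - h` and fails on the k-th:
#' `p_k = (1 - h)^(k - 1) * h`, for `1 <= k <= t_r`. Together with the
#' success probability `(1 - h)^t_r` these exhaust the outcome space.
#'
#' @param h per-step failure probability.
#' @param k failure step (vectorized), `1 <= k <= t_r`.
#' @param t_r attempt duration.
#' @return `(1 - h)^(k - 1) * h`.
#' @export
failure_time_pmf <- function(h, k, t_r) {
  stopifnot(h >= 0, h <= 1)
  if (any(k < 1 | k > t_r)) stop("k out of range 1..t_r")
  (1 - h)^(k - 1) * h
}

#' Probability a breeding attempt succeeds
#'
#' A nest must survive all `t_r` hazard tests to fledge:
#' `q = (1 - h)^t_r`. Even a modest per-step hazard compounds strongly:
#' at `h = 0.10` and `t_r = 25` only about 7.2% of attempts fledge.
#'
#' @param h per-step failure probability (vectorized).
#' @param t_r attempt duration.
#' @return `(1 - h)^t_r`.
#' @export
success_probability <- function(h, t_r) {
  stopifnot(all(h >= 0), all(h <= 1), t_r >= 1)
  (1 - h)^t_r
}

#' Expected attempt-success probability under the beta hazard
#'
#' When the hazard is redrawn from Beta(alpha, beta) on every step, the
#' expected probability that an attempt survives `t_r` steps under a fixed
#' draw is `E[(1 - h)^t_r]`, computed by the exact product form
#' `prod_{j=0}^{t_r - 1} (beta + j) / (alpha + beta + j)` (the t_r-th
#' falling moment of `1 - h`). By Jensen's inequality this exceeds the
#' plug-in value `(1 - h_m)^t_r`.
#'
#' @param model a beta `hazard_model` (for a constant model the plug-in
#'   value is returned).
#' @param t_r attempt duration.
#' @return `E[(1 - h)^t_r]`.
#' @export
expected_survival_beta <- function(model, t_r) {
  stopifnot(inherits(model, "hazard_model"), t_r >= 1)
  if (!is.na(model$h_const)) return((1 - model$h_const)^t_r)
  j <- seq_len(t_r) - 1
  prod((model$beta + j) / (model$alpha + model$beta + j))
}

#' Truncated-series approximation of the expected success probability
#'
#' Diagnostic companion to [expected_survival_beta()]: the second-order
#' binomial expansion `1 - t_r*<h> + choose(t_r, 2)*<h^2>` with
#' `<h^2> = h_m^2 + h_v^2`, which treats `h_v` as a standard deviation.
#' This reading of `h_v` is inconsistent with the beta parameterization
#' `alpha = h_m / h_v` (under which the variance is
#' `h_m (1 - h_m) h_v / (1 + h_v)`), so the exact product form is the
#' canonical expectation and this series is exposed only for comparison.
#'
#' @param h_m hazard mean.
#' @param h_v treated as the hazard standard deviation by the series.
#' @param t_r attempt duration.
#' @return The truncated series value (not guaranteed to lie in \[0, 1\]).
#' @export
expected_survival_series <- function(h_m, h_v, t_r) {
  1 - t_r * h_m + choose(t_r, 2) * (h_m^2 + h_v^2)
}

#' @export
print.hazard_model <- function(x, ...) {
  if (is.na(x$h_const))
    cat(sprintf("Hazard ~ Beta(%.4g, %.4g), mean %.4g\n", x$alpha, x$beta,
                x$alpha / (x$alpha + x$beta)))
  else
    cat(sprintf("Constant hazard h = %g\n", x$h_const))
  if (x$mode == "clutch_dependent")
    cat(sprintf("  clutch-dependent predation, gamma = %g (c_ref = %d)\n",
                x$gamma, x$c_ref))
  invisible(x)
}
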