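# Closed-form approximation of end-of-season wasted time.
#
# In the simplified (capital-breeding) model the breeder forages at f_f,
# then spends c*x per step while breeding with no foraging income. A failed
# attempt of k steps costs k*c*x, which takes k*c*x/f_f steps to recover,
# so attempts can only start on the lattice
#   t_n = c*x*t_r/f_f + n * (1 + c*x/f_f),   n = 0, 1, 2, ...
# The wasted time at season end is driven by where the last completable
# start falls relative to T, giving a mean of order (t_r/2)(1 + c*x/f_f):
# linear in clutch size, which is the analytic core of why large clutches
# are penalized in short seasons.

lattice_factor <- function(params) 1 + params$c * params$x / params$f_f

lattice_origin <- function(params)
  params$c * params$x * params$t_r / params$f_f

#' Lattice of possible attempt start times
#'
#' Returns `t_n = c*x*t_r/f_f + n * (1 + c*x/f_f)`: the n-th possible
#' start time of a breeding attempt in the simplified model, measured from
#' the start of the season.
#'
#' @param n lattice index (vectorized), `n >= 0`.
#' @param params a `clutch_params` object.
#' @return Real start time(s).
#' @export
start_time <- function(n, params) {
  stopifnot(inherits(params, "clutch_params"), all(n >= 0))
  lattice_origin(params) + n * lattice_factor(params)
}

#' Boundary indices of the start-time lattice
#'
#' Three lattice indices structure the end of the season:
#' `n1 = floor((T - c*x*t_r/f_f) / (1 + c*x/f_f))`, the last possible
#' start; `n2 = floor((T - c*x*t_r/f_f - t_r) / (1 + c*x/f_f))`, the last
#' start that can still complete successfully; and
#' `n3 = floor((T - c*x*t_r/f_f - t_r) / (1 + c*x/f_f) - t_r)`, the last
#' start that, should it fail, can still restart at or before `n2`.
#'
#' The counts satisfy `(n2 - n3) / (n1 - n2) ~ 1 + c*x/f_f` (up to floor
#' rounding), which is what makes the weighted waste formula close in
#' `h` alone.
#'
#' @param params a `clutch_params` object.
#' @param T season length (default `params$T`).
#' @return A list with integers `n1 >= n2 >= n3`.
#' @export
boundary_indices <- function(params, T = params$T) {
  stopifnot(inherits(params, "clutch_params"))
  origin <- lattice_origin(params)
  fac <- lattice_factor(params)
  if (T <= origin + params$t_r)
    stop("season_too_short: need T > c*x*t_r/f_f + t_r for one complete attempt")
  n1 <- floor((T - origin) / fac)
  n2 <- floor((T - origin - params$t_r) / fac)
  n3 <- floor((T - origin - params$t_r) / fac - params$t_r)
  list(n1 = as.integer(n1), n2 = as.integer(n2), n3 = as.integer(n3))
}

#' Zeroth-order expected wasted time
#'
#' Ignoring the never-completing late starts, the last successful attempt
#' starts uniformly on the lattice window of width `t_r * (1 + c*x/f_f)`,
#' so the expected wasted time is the window midpoint
#' `mean = (t_r / 2) (1 + c*x/f_f)` with
#' `sd = (t_r / sqrt(12)) (1 + c*x/f_f)` — both independent of the hazard
#' `h` and exactly linear in clutch size `c`. Relative to the season this
#' waste is the fraction `t_r / (2T) * (1 + c*x/f_f)`, and the implied
#' loss in breeding success is `rho_max` times that fraction, where
#' `rho_max` is the maximum breeding success possible.
#'
#' @param params a `clutch_params` object.
#' @param T season length (default `params$T`).
#' @param rho_max maximum breeding success (default 1, so the loss is
#'   reported as a fraction of the maximum).
#' @return A list with `mean`, `sd` (steps), `fraction` and `loss`.
#' @export
zeroth_order_waste <- function(params, T = params$T, rho_max = 1) {
  stopifnot(inherits(params, "clutch_params"))
  fac <- lattice_factor(params)
  tr <- params$t_r
  list(mean = tr / 2 * fac,
       sd = tr / sqrt(12) * fac,
       fraction = tr / (2 * T) * fac,
       loss = rho_max * tr / (2 * T) * fac)
}

#' Weighted expected wasted time under a constant hazard
#'
#' Refines the zeroth-order value by separating the late starts that can
#' never complete (indices `n2 < n <= n1`, wasting `T - t_n` with
#' certainty) from the last-success window (`n3 < n <= n2`, wasting
#' `T - t_n - t_r` with probability `q = (1 - h)^t_r`). With the count
#' ratio `(n2 - n3)/(n1 - n2) = 1 + c*x/f_f` the average collapses to the
#' mixture
#' `mean = w * t_r/2 + (1 - w) * (t_r/2)(1 + c*x/f_f)` with weight
#' `w = 1 / (1 + (1 + c*x/f_f) q)`, and
#' `sd = (t_r/sqrt(12)) (1 + c*x/f_f) * (1 + c*x/f_f) q / (1 + (1 + c*x/f_f) q)`
#' (only the second component is probabilistic). As `h -> 1` (q -> 0) the
#' mean drops to `t_r / 2`; as `h -> 0` it approaches the zeroth-order
#' value from below.
#'
#' @param params a `clutch_params` object.
#' @param T season length (unused by the closed form; kept for interface
#'   symmetry with [boundary_indices()]).
#' @param h constant per-step failure probability in \[0, 1\].
#' @return A list with `mean`, `sd` (steps) and mixture weight `w`.
#' @export
weighted_waste <- function(params, T = params$T, h = params$h_m) {
  stopifnot(inherits(params, "clutch_params"), h >= 0, h <= 1)
  waste_mixture(params, success_probability(h, params$t_r))
}

# Shared mixture form: q is the per-attempt success probability (or its
# expectation under the beta hazard).
waste_mixture <- function(params, q) {
  fac <- lattice_factor(params)
  tr <- params$t_r
  A <- fac * q
  w <- 1 / (1 + A)
  list(mean = w * tr / 2 + (1 - w) * tr / 2 * fac,
       sd = tr / sqrt(12) * fac * A / (1 + A),
       w = w)
}

#' Expected wasted time under the stochastic beta hazard
#'
#' The weighted waste with the per-attempt success probability
#' `(1 - h)^t_r` replaced by its exact expectation over `h ~ Beta(alpha,
#' beta)` (see [expected_survival_beta()]), which exceeds the plug-in
#' `(1 - h_m)^t_r`, so the stochastic hazard slightly increases the
#' expected waste relative to the constant-hazard value at `h = h_m`.
#'
#' @param params a `clutch_params` object.
#' @param T season length (interface symmetry).
#' @param hazard a `hazard_model` (default: implied by `params`).
#' @return A list with `mean` and `sd` (steps).
#' @export
stochastic_h_waste <- function(params, T = params$T,
                               hazard = hazard_from_params(params)) {
  stopifnot(inherits(params, "clutch_params"),
            inherits(hazard, "hazard_model"))
  out <- waste_mixture(params, expected_survival_beta(hazard, params$t_r))
  out[c("mean", "sd")]
}

#' Fold foraging-while-breeding into the analytic model
#'
#' The closed forms above assume no foraging income during breeding. When
#' the simulator forages at `f_b = f_f (1 - c/c_max)` during breeding
#' steps, its net per-step breeding outflow is `c*x - f_b`; this
#' substitution returns a parameter copy whose per-offspring cost is
#' rescaled (`x' = x - f_b / c`) so that `c * x'` equals that net flow and
#' the lattice spacing matches the simulator's actual recovery times. The
#' substitution changes the lattice spacing (an extra clutch-size
#' dependence of the waste) but not its overall `t_r / T` scaling.
#' `c = c_max` (where `f_b = 0`) is a fixed point.
#'
#' @param params a `clutch_params` object with `forage_while_breeding =
#'   TRUE` (returned unchanged when `f_b` is already 0).
#' @return A `clutch_params` copy with the rescaled cost and
#'   `forage_while_breeding = FALSE`; errors if the substitution would
#'   make the net breeding outflow non-positive (breeding would gain
#'   energy, outside the model).
#' @export
apply_fb_substitution <- function(params) {
  stopifnot(inherits(params, "clutch_params"))
  fb <- effective_fb(params)
  if (fb == 0) return(params)
  x_new <- params$x - fb / params$c
  if (params$c * x_new <= 0)
    stop("degenerate_substitution: net breeding outflow c*x - f_b must be positive")
  keep <- unclass(params)[c("T", "E_i", "c", "c_max", "f_f", "x", "t_r",
                            "h_m", "h_v", "n", "predation_mode",
                            "predation_gamma", "forage_while_breeding",
                            "seed")]
  keep$x <- x_new
  keep$forage_while_breeding <- FALSE
  validate_params(keep)
}

#' All closed-form waste quantities for one parameter set
#'
#' Bundles the start-time lattice, boundary indices, per-attempt success
#' probability, zeroth-order and weighted expectations of the wasted time,
#' the beta-hazard correction, and the fitness-loss fraction. When
#' `params` has foraging-while-breeding enabled, the net-flow substitution
#' of [apply_fb_substitution()] is applied first.
#'
#' @param params a `clutch_params` object.
#' @param T season length (default `params$T`).
#' @param h constant hazard used for `q` and the weighted form (default
#'   `h_m`).
#' @param rho_max maximum breeding success for the loss fraction.
#' @return An object of class `"analytic_waste"`.
#' @export
analytic_waste <- function(params, T = params$T, h = params$h_m,
                           rho_max = 1) {
  stopifnot(inherits(params, "clutch_params"))
  ap <- apply_fb_substitution(params)
  idx <- boundary_indices(ap, T)
  z <- zeroth_order_waste(ap, T, rho_max)
  wz <- weighted_waste(ap, T, h)
  bz <- stochastic_h_waste(ap, T)
  structure(list(
    lattice_origin = lattice_origin(ap),
    lattice_spacing = lattice_factor(ap),
    n1 = idx$n1, n2 = idx$n2, n3 = idx$n3,
    q = success_probability(h, ap$t_r),
    waste_mean_zeroth = z$mean, waste_sd_zeroth = z$sd,
    waste_mean_weighted = wz$mean, waste_sd_weighted = wz$sd,
    w = wz$w,
    waste_mean_beta = bz$mean, waste_sd_beta = bz$sd,
    loss_fraction = z$loss,
    params = ap, T = T, h = h, rho_max = rho_max
  ), class = "analytic_waste")
}

#' @export
print.analytic_waste <- function(x, ...) {
  cat(sprintf("Analytic end-of-season waste (c = %d, T = %d, h = %g)\n",
              x$params$c, x$T, x$h))
  cat(sprintf("  start lattice: origin %.4g, spacing %.4g; n1/n2/n3 = %d/%d/%d\n",
              x$lattice_origin, x$lattice_spacing, x$n1, x$n2, x$n3))
  cat(sprintf("  zeroth order: %.4g +/- %.4g steps (loss fraction %.4g)\n",
              x$waste_mean_zeroth, x$waste_sd_zeroth, x$loss_fraction))
  cat(sprintf("  weighted (q = %.4g): %.4g +/- %.4g;  beta hazard: %.4g +/- %.4g\n",
              x$q, x$waste_mean_weighted, x$waste_sd_weighted,
              x$waste_mean_beta, x$waste_sd_beta))
  invisible(x)
}

#' Closed-form waste table over a clutch-size grid
#'
#' @param params base `clutch_params`; every row overrides only `c`.
#' @param c_grid clutch sizes (default `1:c_max`).
#' @param T season length (default `params$T`).
#' @param rho_max maximum breeding success for the loss fraction.
#' @return A data.frame with one row per clutch size and columns `c`,
#'   `n1`, `n2`, `n3`, `q`, `waste_mean_zeroth`, `waste_sd_zeroth`,
#'   `waste_mean_weighted`, `waste_sd_weighted`, `waste_mean_beta`,
#'   `loss_fraction`.
#' @export
analytic_waste_table <- function(params, c_grid = seq_len(params$c_max),
                                 T = params$T, rho_max = 1) {
  rows <- lapply(c_grid, function(cc) {
    p <- params_with(params, c = cc)
    a <- analytic_waste(p, T = T, rho_max = rho_max)
    data.frame(c = cc, n1 = a$n1, n2 = a$n2, n3 = a$n3, q = a$q,
               waste_mean_zeroth = a$waste_mean_zeroth,
               waste_sd_zeroth = a$waste_sd_zeroth,
               waste_mean_weighted = a$waste_mean_weighted,
               waste_sd_weighted = a$waste_sd_weighted,
               waste_mean_beta = a$waste_mean_beta,
               loss_fraction = a$loss_fraction)
  })
  do.call(rbind, rows)
}

# Copy a parameter set with some primary fields overridden, re-validating.
params_with <- function(params, ...) {
  keep <- unclass(params)[c("T", "E_i", "c", "c_max", "f_f", "x", "t_r",
                            "h_m", "h_v", "n", "predation_mode",
                            "predation_gamma", "forage_while_breeding",
                            "seed")]
  validate_params(utils::modifyList(keep, list(...)))
}
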