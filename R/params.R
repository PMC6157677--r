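#' Model parameterization for the clutch-size simulator
#'
#' Constructs and validates the full parameter set of the breeding-season
#' model: season length, energy budget, clutch size, breeding duration, the
#' beta-distributed per-step nest-failure hazard, replicate count and RNG
#' seed. Defaults are the standard parameterization used throughout the
#' experiments (T = 500, E_i = 250, c_max = 10, f_f = 1, x = 1, t_r = 24,
#' h_m = 0.03, h_v = 0.01, n = 10,000).
#'
#' The hazard distribution is Beta(alpha, beta) with `alpha = h_m / h_v` and
#' `beta = (1 - h_m) / h_v`, so `h_m` is the mean and `h_v` an inverse-scale
#' ("related to variance"). Only convex, positively skewed shapes are
#' admitted: `1 < alpha < beta`, which together with `h_m < 0.5` keeps the
#' per-step failure rate concentrated below one half.
#'
#' @param T positive integer, breeding-season length in time steps.
#' @param E_i non-negative real, basic (lowest) energy reserve; also the
#'   initial reserve.
#' @param c integer clutch size, the strategy under evaluation (`1 <= c <=
#'   c_max`).
#' @param c_max integer, maximum clutch size.
#' @param f_f positive real, foraging efficiency per foraging step.
#' @param x positive real, per-offspring care cost per breeding step.
#' @param t_r positive integer, duration of a successful breeding attempt.
#' @param h_m mean of the per-step nest-failure distribution, in (0, 0.5).
#' @param h_v positive real, beta inverse-scale parameter.
#' @param n positive integer, number of replicate seasons.
#' @param predation_mode `"independent"` (hazard does not depend on clutch
#'   size) or `"clutch_dependent"`.
#' @param predation_gamma non-negative real, strength of the clutch-size
#'   dependence of the hazard (see [hazard_model()]).
#' @param forage_while_breeding logical; if `TRUE` the breeder forages at
#'   reduced efficiency `f_b = f_f * (1 - c / c_max)` during breeding steps,
#'   if `FALSE` it does not forage at all while breeding (`f_b = 0`).
#' @param seed integer master RNG seed.
#'
#' @return An object of class `"clutch_params"`: a validated list of the
#'   fields above plus the derived beta shapes `alpha`, `beta` and the
#'   effective breeding-time foraging efficiency `f_b`.
#' @seealso [validate_params()] for construction from a raw key-value
#'   mapping, [effective_fb()], [read_params()], [write_params()].
#' @examples
#' p <- clutch_params(c = 2)
#' p$alpha  # 3
#' p$beta   # 97
#' effective_fb(p)  # 0.8
#' @export
clutch_params <- function(T = 500, E_i = 250, c = 1, c_max = 10,
                          f_f = 1, x = 1, t_r = 24,
                          h_m = 0.03, h_v = 0.01, n = 10000,
                          predation_mode = c("independent", "clutch_dependent"),
                          predation_gamma = 0,
                          forage_while_breeding = TRUE,
                          seed = 1L) {
  predation_mode <- match.arg(predation_mode)
  raw <- list(T = T, E_i = E_i, c = c, c_max = c_max, f_f = f_f, x = x,
              t_r = t_r, h_m = h_m, h_v = h_v, n = n,
              predation_mode = predation_mode,
              predation_gamma = predation_gamma,
              forage_while_breeding = forage_while_breeding,
              seed = seed)
  validate_params(raw)
}

#' Validate a raw key-value mapping into model parameters
#'
#' Checks every model invariant and returns a `clutch_params` object, or
#' fails with a message naming each violated invariant
#' (e.g. `alpha_not_gt_1`, `mean_too_high`, `clutch_out_of_range`).
#' Missing keys take the package defaults; unknown keys are an error so
#' typos in config files cannot pass silently.
#'
#' @param raw named list of parameter values (any subset of the fields of
#'   [clutch_params()]).
#' @return A validated `clutch_params` object with derived `alpha`, `beta`
#'   and `f_b`.
#' @export
validate_params <- function(raw) {
  stopifnot(is.list(raw))
  defaults <- list(T = 500, E_i = 250, c = 1, c_max = 10, f_f = 1, x = 1,
                   t_r = 24, h_m = 0.03, h_v = 0.01, n = 10000,
                   predation_mode = "independent", predation_gamma = 0,
                   forage_while_breeding = TRUE, seed = 1L)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, raw)

  num_fields <- c("T", "E_i", "c", "c_max", "f_f", "x", "t_r", "h_m", "h_v",
                  "n", "predation_gamma", "seed")
  for (f in num_fields) {
    v <- suppressWarnings(as.numeric(p[[f]]))
    if (length(v) != 1L || is.na(v))
      stop("parameter ", f, " is not a single finite number")
    p[[f]] <- v
  }
  for (f in c("T", "c", "c_max", "t_r", "n", "seed")) {
    if (p[[f]] != round(p[[f]]))
      stop("parameter ", f, " must be an integer (not_integer)")
    p[[f]] <- as.integer(round(p[[f]]))
  }
  p$forage_while_breeding <- isTRUE(as.logical(p$forage_while_breeding))
  p$predation_mode <- match.arg(p$predation_mode,
                                c("independent", "clutch_dependent"))

  violations <- character()
  fail <- function(name, msg) violations <<- c(violations,
                                               paste0(name, ": ", msg))
  if (p$T < 1) fail("season_not_positive", "T must be >= 1")
  if (p$E_i < 0) fail("negative_reserve", "E_i must be >= 0")
  if (p$c < 1 || p$c > p$c_max)
    fail("clutch_out_of_range", sprintf("need 1 <= c <= c_max, got c=%d, c_max=%d",
                                        p$c, p$c_max))
  if (p$f_f <= 0) fail("nonpositive_forage", "f_f must be > 0")
  if (p$x <= 0) fail("nonpositive_cost", "x must be > 0")
  if (p$t_r < 1) fail("breeding_too_short", "t_r must be >= 1")
  if (p$n < 1) fail("no_replicates", "n must be >= 1")
  if (p$h_v <= 0) fail("nonpositive_scale", "h_v must be > 0")
  if (p$h_m >= 0.5)
    fail("mean_too_high", sprintf("h_m must be < 0.5, got %g", p$h_m))
  if (p$h_m <= 0) fail("mean_not_positive", "h_m must be > 0")
  if (p$predation_gamma < 0) fail("negative_gamma", "predation_gamma >= 0")
  if (p$h_v > 0 && p$h_m > 0 && p$h_m < 1) {
    alpha <- p$h_m / p$h_v
    beta <- (1 - p$h_m) / p$h_v
    if (alpha <= 1)
      fail("alpha_not_gt_1",
           sprintf("alpha = h_m/h_v = %g must exceed 1", alpha))
    if (alpha >= beta)
      fail("alpha_not_lt_beta",
           sprintf("need alpha < beta, got alpha=%g beta=%g", alpha, beta))
  }
  if (p$c * p$x * p$t_r <= 0)
    fail("degenerate_threshold", "c*x*t_r must be > 0")
  if (length(violations))
    stop("invalid parameters:\n  ", paste(violations, collapse = "\n  "))

  p$alpha <- p$h_m / p$h_v
  p$beta <- (1 - p$h_m) / p$h_v
  p$f_b <- if (p$forage_while_breeding) p$f_f * (1 - p$c / p$c_max) else 0
  structure(p, class = "clutch_params")
}

#' Foraging efficiency during breeding
#'
#' The breeder retains reduced foraging ability while caring for a clutch:
#' `f_b = f_f * (1 - c / c_max)` when foraging-while-breeding is enabled
#' (so a maximal clutch leaves no time to forage), and 0 when disabled.
#'
#' @param params a `clutch_params` object.
#' @return The per-breeding-step foraging income, a single real.
#' @export
effective_fb <- function(params) {
  stopifnot(inherits(params, "clutch_params"))
  if (params$forage_while_breeding)
    params$f_f * (1 - params$c / params$c_max)
  else 0
}

#' @export
print.clutch_params <- function(x, ...) {
  cat("Breeding-season model parameters\n")
  cat(sprintf("  season T = %d, reserve E_i = %g, clutch c = %d (max %d)\n",
              x$T, x$E_i, x$c, x$c_max))
  cat(sprintf("  foraging f_f = %g (f_b = %g), cost x = %g, t_r = %d\n",
              x$f_f, x$f_b, x$x, x$t_r))
  cat(sprintf("  hazard ~ Beta(%.4g, %.4g)  (h_m = %g, h_v = %g), mode = %s",
              x$alpha, x$beta, x$h_m, x$h_v, x$predation_mode))
  if (x$predation_mode == "clutch_dependent")
    cat(sprintf(" (gamma = %g)", x$predation_gamma))
  cat(sprintf("\n  replicates n = %d, seed = %d\n", x$n, x$seed))
  invisible(x)
}

#' Read model parameters from a YAML config file
#'
#' The config is one flat document of named scalars using the model's
#' field names (`T`, `E_i`, `c`, `c_max`, `f_f`, `x`, `t_r`, `h_m`, `h_v`,
#' `n`, `predation_mode`, `predation_gamma`, `forage_while_breeding`,
#' `seed`). Unknown keys are an error.
#'
#' @param path path to a YAML file.
#' @return A validated `clutch_params` object.
#' @export
read_params <- function(path) {
  validate_params(yaml::read_yaml(path))
}

#' Write model parameters to a YAML config file
#'
#' Writes only the primary fields (derived `alpha`, `beta`, `f_b` are
#' recomputed on read), so `read_params(write_params(p, f))` round-trips.
#'
#' @param params a `clutch_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "clutch_params"))
  keep <- c("T", "E_i", "c", "c_max", "f_f", "x", "t_r", "h_m", "h_v", "n",
            "predation_mode", "predation_gamma", "forage_while_breeding",
            "seed")
  yaml::write_yaml(unclass(params)[keep], path)
  invisible(path)
}

#' Run metadata sidecar
#'
#' Emits the parameters, seed, package version and any stated assumptions
#' as a JSON sidecar next to an output file, so every CSV is reproducible
#' from its metadata alone.
#'
#' @param params a `clutch_params` object.
#' @param path path of the JSON file to write.
#' @param assumptions optional named list of assumption notes.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(params, path, assumptions = NULL) {
  stopifnot(inherits(params, "clutch_params"))
  meta <- list(
    parameters = unclass(params)[c("T", "E_i", "c", "c_max", "f_f", "x",
                                   "t_r", "h_m", "h_v", "n",
                                   "predation_mode", "predation_gamma",
                                   "forage_while_breeding")],
    seed = params$seed,
    package = "clutchsim",
    version = as.character(utils::packageVersion("clutchsim"))
  )
  if (!is.null(assumptions)) meta$assumptions <- assumptions
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
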