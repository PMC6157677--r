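#' Foraging-versus-breeding decision
#'
#' The decision to start a clutch is purely energy-based: breeding starts
#' only once the reserve covers the full cost of a successful attempt,
#' `E >= E_i + c * x * t_r` (ties breed). Until then the individual
#' forages.
#'
#' @param E current energy reserve (vectorized).
#' @param params a `clutch_params` object.
#' @return Character vector, `"breed"` or `"forage"`.
#' @export
decide_action <- function(E, params) {
  stopifnot(inherits(params, "clutch_params"))
  ifelse(E >= params$E_i + params$c * params$x * params$t_r,
         "breed", "forage")
}

#' Simulate one breeding season
#'
#' Runs the T-step season loop: forage until the reserve reaches the
#' breeding threshold, then breed for up to `t_r` steps with a fresh
#' hazard draw each step; on failure or success, return to the decision.
#' The season never ends early, so a final attempt still open at step T is
#' truncated (its invested energy is sunk, its fledglings zero, and its
#' steps count as wasted time).
#'
#' Uses R's global RNG stream; call [set.seed()] (or use
#' [run_replicates()], which manages per-replicate streams) for
#' reproducibility.
#'
#' @param params a `clutch_params` object.
#' @param hazard a `hazard_model`; defaults to the one implied by `params`.
#' @param keep_trace if `TRUE`, attach the full per-step trace.
#' @return A list of class `"season_result"` with `fledglings`,
#'   `n_attempts`, `n_successes`, `acquired_energy`, `invested_energy`,
#'   `excessive_reserve_time` (steps after the last completed attempt; see
#'   [measure_excessive_reserve()]), `excessive_reserve_time_success`
#'   (steps after the last *successful* attempt),
#'   `excessive_reserve_energy` and `final_energy`. With `keep_trace = TRUE` it also carries a `trace`
#'   element of class `"season_trace"`: `energy_series` (length T + 1,
#'   starting at `E_i`), `phase_series` (length T, `"forage"`/`"breed"`),
#'   and `attempt_log` (one row per attempt with start, end, outcome).
#' @examples
#' p <- clutch_params(c = 10, n = 1)
#' res <- run_season(p, constant_hazard(0), keep_trace = TRUE)
#' res$fledglings               # 10: one successful clutch fits in T = 500
#' res$excessive_reserve_time   # 236 steps wasted after the last success
#' @export
run_season <- function(params, hazard = hazard_from_params(params),
                       keep_trace = FALSE) {
  stopifnot(inherits(params, "clutch_params"),
            inherits(hazard, "hazard_model"))
  raw <- season_core(params$T, params$E_i, params$c, params$f_f, params$x,
                     params$t_r, hazard$alpha, hazard$beta, hazard$h_const,
                     hazard_multiplier(hazard, params$c), params$f_b,
                     keep_trace)
  res <- raw[c("fledglings", "n_attempts", "n_successes", "acquired_energy",
               "invested_energy", "excessive_reserve_time",
               "excessive_reserve_time_success", "excessive_reserve_energy",
               "final_energy")]
  if (keep_trace) {
    res$trace <- structure(list(
      energy_series = raw$energy_series,
      phase_series = c("forage", "breed")[raw$phase_series + 1L],
      attempt_log = data.frame(
        start = raw$attempt_start,
        end = raw$attempt_end,
        outcome = c("truncated", "failure", "success")[raw$attempt_outcome + 2L]
      )
    ), class = "season_trace")
  }
  structure(res, class = "season_result")
}

#' Excessive reserve: wasted time and energy at season end
#'
#' The excessive reserve is the part of the season that cannot contribute
#' to any completed breeding attempt: the wasted time is `T` minus the end
#' step of the last attempt that ran to completion — success or failure —
#' (all of `T` if no attempt completed; steps of a final truncated attempt
#' count as wasted), and the wasted energy is the terminal reserve above
#' the basic level, `E_T - E_i`. This is the quantity the closed-form
#' approximation of [analytic_waste()] targets. The stricter variant that
#' measures from the last *successful* attempt — under which every failed
#' attempt after the final success is also waste — is available via
#' `from = "last_success"`.
#'
#' @param trace a `"season_trace"` (from `run_season(..., keep_trace =
#'   TRUE)`).
#' @param params the `clutch_params` used for the season.
#' @param from measure from the end of the `"last_attempt"` to complete
#'   (default) or from the `"last_success"`.
#' @return A list with integer `time` in \[0, T\] and real `energy`.
#' @export
measure_excessive_reserve <- function(trace, params,
                                      from = c("last_attempt",
                                               "last_success")) {
  stopifnot(inherits(trace, "season_trace"),
            inherits(params, "clutch_params"))
  from <- match.arg(from)
  log <- trace$attempt_log
  keep <- if (from == "last_success") log$outcome == "success"
          else log$outcome != "truncated"
  ends <- log$end[keep]
  time <- if (length(ends)) params$T - max(ends) else params$T
  energy <- trace$energy_series[length(trace$energy_series)] - params$E_i
  list(time = as.integer(time), energy = energy)
}

# L'Ecuyer-CMRG stream seeds: one independent stream per replicate index,
# spawned from the master seed, so replicate r is reproducible in isolation
# and results do not depend on evaluation order.
rng_streams <- function(seed, n) {
  set.seed(as.integer(seed %% 2147483647L), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

# Save the caller's RNG state and restore it when the calling frame exits.
preserve_rng <- function(env = parent.frame()) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  kind <- RNGkind()
  expr <- bquote({
    do.call(RNGkind, as.list(.(kind)))
    if (.(had)) assign(".Random.seed", .(old), envir = globalenv())
  })
  do.call(on.exit, list(expr, add = TRUE), envir = env)
}

#' Replicate engine: n independent seasons
#'
#' Simulates `n` seasons, each on its own L'Ecuyer-CMRG stream spawned from
#' the master seed, and summarizes every season statistic with its raw
#' mean, SD and SE as well as the season-length-standardized mean (divided
#' by `T`) and SD (divided by `sqrt(T)`) used to compare strategies across
#' season lengths. The caller's RNG state is left untouched.
#'
#' @param params a `clutch_params` object.
#' @param hazard a `hazard_model`; defaults to the one implied by `params`.
#' @param n number of replicate seasons (default `params$n`).
#' @param seed master seed (default `params$seed`).
#' @return A list of class `"replicate_summary"`: `replicates` (one row
#'   per season with every statistic), `summary` (one row per statistic
#'   with `mean`, `sd`, `se`, `std_mean`, `std_sd`), `params`, `n`,
#'   `seed`. With `n = 1` the SD is 0 by convention.
#' @export
run_replicates <- function(params, hazard = hazard_from_params(params),
                           n = params$n, seed = params$seed) {
  stopifnot(inherits(params, "clutch_params"), n >= 1)
  preserve_rng()
  streams <- rng_streams(seed, n)
  stats_names <- c("fledglings", "n_attempts", "n_successes",
                   "acquired_energy", "invested_energy",
                   "excessive_reserve_time", "excessive_reserve_energy")
  mat <- matrix(NA_real_, nrow = n, ncol = length(stats_names),
                dimnames = list(NULL, stats_names))
  for (r in seq_len(n)) {
    assign(".Random.seed", streams[[r]], envir = globalenv())
    res <- run_season(params, hazard)
    mat[r, ] <- unlist(res[stats_names], use.names = FALSE)
  }
  replicates <- data.frame(replicate = seq_len(n), mat, seed = seed)
  structure(list(replicates = replicates,
                 summary = summarize_replicates(mat, params$T, n),
                 params = params, n = n, seed = seed),
            class = "replicate_summary")
}

# Per-statistic raw and season-length-standardized summary.
summarize_replicates <- function(mat, T, n) {
  m <- colMeans(mat)
  s <- if (n > 1) apply(mat, 2, stats::sd) else rep(0, ncol(mat))
  data.frame(statistic = colnames(mat), mean = unname(m), sd = unname(s),
             se = unname(s) / sqrt(n), std_mean = unname(m) / T,
             std_sd = unname(s) / sqrt(T), n = n, row.names = NULL)
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("Replicate summary: n = %d seasons, c = %d, T = %d, seed = %d\n",
              x$n, x$params$c, x$params$T, x$seed))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf(paste0("Season: %d fledglings (%d/%d attempts successful), ",
                     "wasted %d steps and %.1f energy at season end\n"),
              x$fledglings, x$n_successes, x$n_attempts,
              x$excessive_reserve_time, x$excessive_reserve_energy))
  invisible(x)
}

#' Write per-replicate results to CSV with a JSON metadata sidecar
#'
#' @param rs a `"replicate_summary"`.
#' @param path output CSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param assumptions optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_replicates_csv <- function(rs, path, assumptions = NULL) {
  stopifnot(inherits(rs, "replicate_summary"))
  utils::write.csv(rs$replicates, path, row.names = FALSE)
  write_run_metadata(rs$params, paste0(path, ".json"),
                     assumptions = assumptions)
  invisible(path)
}

#' Write a single-season trace to CSV
#'
#' One row per step with the phase and the post-step reserve: enough to
#' redraw the energy-dynamics time series.
#'
#' @param trace a `"season_trace"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "season_trace"))
  T <- length(trace$phase_series)
  utils::write.csv(data.frame(step = seq_len(T), phase = trace$phase_series,
                              energy = trace$energy_series[-1]),
                   path, row.names = FALSE)
  invisible(path)
}
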