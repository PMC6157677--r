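# Experiment harness: factorial parameter sweeps with standardized
# summaries and the simulation-versus-analytic comparison.

sweep_axes_allowed <- c("c", "T", "h_m", "h_v", "f_f", "predation_gamma",
                        "predation_mode", "forage_while_breeding")

#' Specify a factorial parameter sweep
#'
#' A sweep is a base parameter set plus named axes (each a vector of
#' values for one of `c`, `T`, `h_m`, `h_v`, `f_f`, `predation_gamma`,
#' `predation_mode`, `forage_while_breeding`), a replicate count per cell
#' and a master seed. Every cell of the full factorial is validated up
#' front, so a sweep that would hit an invalid hazard shape fails before
#' any simulation starts, naming the offending cell.
#'
#' @param base a `clutch_params` object; every cell overrides only the
#'   swept axes.
#' @param axes named list of axis values.
#' @param n replicates per cell (default `base$n`).
#' @param seed master seed (default `base$seed`).
#' @param assumptions optional named list of assumption notes carried into
#'   output metadata.
#' @return An object of class `"sweep_spec"` with the validated cell grid.
#' @export
sweep_spec <- function(base = clutch_params(), axes = list(), n = base$n,
                       seed = base$seed, assumptions = NULL) {
  stopifnot(inherits(base, "clutch_params"), is.list(axes))
  bad <- setdiff(names(axes), sweep_axes_allowed)
  if (length(bad))
    stop("unsupported sweep axis: ", paste(bad, collapse = ", "))
  grid <- if (length(axes))
    expand.grid(axes, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  else data.frame(row.names = 1)
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, , drop = FALSE])
    ok <- try(do.call(params_with, c(list(base), cell)), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("invalid sweep cell (",
           paste(names(cell), unlist(cell), sep = "=", collapse = ", "),
           "): ", attr(ok, "condition")$message)
  }
  structure(list(base = base, axes = axes, grid = grid, n = n, seed = seed,
                 assumptions = assumptions),
            class = "sweep_spec")
}

# Deterministic per-cell seed: a rolling-polynomial hash of the cell's
# parameter values (in canonical name order) folded into the master seed,
# so cell seeds are independent of axis declaration and execution order.
cell_seed <- function(master, cell) {
  nm <- sort(names(cell))
  s <- paste(nm, vapply(cell[nm], function(v) format(v, digits = 15), ""),
             sep = "=", collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  as.integer((as.numeric(master) + h) %% 2147483647)
}

#' Run a factorial sweep
#'
#' Simulates every cell of the grid with [run_replicates()] and returns
#' one row per (cell, statistic) with the raw and season-length-
#' standardized summaries. Cell seeds derive from the master seed and the
#' cell's own parameter values, so results are identical regardless of
#' axis declaration or execution order.
#'
#' @param spec a `"sweep_spec"`.
#' @return A data.frame of class `"sweep_table"` with the cell's parameter
#'   values, `statistic`, `mean`, `sd`, `se`, `std_mean`, `std_sd`, `n`
#'   and `cell_seed`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  cells <- max(1L, nrow(spec$grid))
  rows <- vector("list", cells)
  for (i in seq_len(cells)) {
    cell <- if (ncol(spec$grid)) as.list(spec$grid[i, , drop = FALSE])
            else list()
    p <- do.call(params_with, c(list(spec$base), cell))
    cs <- cell_seed(spec$seed, cell)
    rs <- run_replicates(p, n = spec$n, seed = cs)
    cell_cols <- if (length(cell))
      as.data.frame(cell, stringsAsFactors = FALSE)[rep(1, nrow(rs$summary)), ,
                                                    drop = FALSE]
    else NULL
    row <- cbind(if (!is.null(cell_cols)) cell_cols, rs$summary,
                 cell_seed = cs)
    rownames(row) <- NULL
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Presets for the standard experiment designs
#'
#' Returns the sweep specification of each standard experiment:
#' * `"fig3"` — energy accounting (acquired and invested energy) over
#'   clutch sizes 1..10 and season lengths 500, 1,500 and 10,000;
#' * `"fig4"` — season length by hazard mean/variance grid (the
#'   alternative variance level 0.001 and mean 0.06 are package
#'   assumptions, recorded in the spec's metadata);
#' * `"fig5"` — clutch-size-independent (`gamma = 0`) versus dependent
#'   (`gamma = 1`) predation at low (0.03) and high (0.10, an assumption)
#'   hazard means, short and long seasons;
#' * `"fig6"` — food availability `f_f` in 1, 2, 3 at short and long
#'   seasons;
#' * `"fig8"` — simulation-versus-analytic comparison of the excessive
#'   reserve of time: clutch sizes 1..10 at `T = 10,000`, with and without
#'   foraging during breeding.
#'
#' @param name one of `"fig3"`, `"fig4"`, `"fig5"`, `"fig6"`, `"fig8"`.
#' @param n replicates per cell (default 10,000, the full design scale).
#' @param seed master seed.
#' @return A `"sweep_spec"`.
#' @export
preset <- function(name = c("fig3", "fig4", "fig5", "fig6", "fig8"),
                   n = 10000, seed = 1L) {
  name <- match.arg(name)
  base <- clutch_params(n = n, seed = seed)
  switch(name,
    fig3 = sweep_spec(base, axes = list(c = 1:10, T = c(500, 1500, 10000)),
                      n = n, seed = seed),
    fig4 = sweep_spec(base,
                      axes = list(c = 1:10, T = c(500, 1500, 10000),
                                  h_m = c(0.03, 0.06),
                                  h_v = c(0.01, 0.001)),
                      n = n, seed = seed,
                      assumptions = list(
                        h_v_levels = "alternative variance level 0.001 is a package assumption",
                        h_m_levels = "alternative mean level 0.06 is a package assumption")),
    fig5 = sweep_spec(params_with(base, predation_mode = "clutch_dependent"),
                      axes = list(c = 1:10, T = c(500, 10000),
                                  h_m = c(0.03, 0.10),
                                  predation_gamma = c(0, 1)),
                      n = n, seed = seed,
                      assumptions = list(
                        h_m_high = "high-predation mean 0.10 is a package assumption",
                        gamma = "clutch-dependence strength 1 is a package assumption")),
    fig6 = sweep_spec(base, axes = list(c = 1:10, f_f = c(1, 2, 3),
                                        T = c(500, 10000)),
                      n = n, seed = seed),
    fig8 = sweep_spec(params_with(base, T = 10000),
                      axes = list(c = 1:10,
                                  forage_while_breeding = c(TRUE, FALSE)),
                      n = n, seed = seed)
  )
}

#' Compare simulated and analytic end-of-season waste
#'
#' Runs the simulator over a clutch-size grid and sets the observed mean
#' and SD of the excessive reserve of time against the closed-form
#' zeroth-order, constant-hazard-weighted and beta-hazard expectations.
#' The `within_band` column flags whether the simulated mean falls inside
#' the zeroth-order mean +/- SD band.
#'
#' @param spec a `"sweep_spec"` whose axes are a subset of `c` and
#'   `forage_while_breeding`.
#' @param rho_max maximum breeding success for the loss fraction.
#' @return A data.frame of class `"sim_analytic_comparison"`, one row per
#'   cell.
#' @export
compare_sim_analytic <- function(spec, rho_max = 1) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (length(setdiff(names(spec$axes), c("c", "forage_while_breeding"))))
    stop("comparison sweeps may only vary c and forage_while_breeding")
  cells <- max(1L, nrow(spec$grid))
  rows <- vector("list", cells)
  for (i in seq_len(cells)) {
    cell <- if (ncol(spec$grid)) as.list(spec$grid[i, , drop = FALSE])
            else list()
    p <- do.call(params_with, c(list(spec$base), cell))
    cs <- cell_seed(spec$seed, cell)
    rs <- run_replicates(p, n = spec$n, seed = cs)
    s <- rs$summary[rs$summary$statistic == "excessive_reserve_time", ]
    a <- analytic_waste(p, rho_max = rho_max)
    rows[[i]] <- data.frame(
      c = p$c, forage_while_breeding = p$forage_while_breeding,
      sim_mean = s$mean, sim_sd = s$sd, sim_se = s$se,
      analytic_mean_zeroth = a$waste_mean_zeroth,
      analytic_sd_zeroth = a$waste_sd_zeroth,
      analytic_mean_weighted = a$waste_mean_weighted,
      analytic_sd_weighted = a$waste_sd_weighted,
      analytic_mean_beta = a$waste_mean_beta,
      loss_fraction = a$loss_fraction,
      within_band = abs(s$mean - a$waste_mean_zeroth) <= a$waste_sd_zeroth,
      n = spec$n, cell_seed = cs)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sim_analytic_comparison", "data.frame")
  out
}

#' Write a sweep or comparison table to CSV with a JSON sidecar
#'
#' @param table a `"sweep_table"` or `"sim_analytic_comparison"`.
#' @param spec the `"sweep_spec"` it came from (for the metadata sidecar).
#' @param path output CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(table, spec, path) {
  stopifnot(is.data.frame(table), inherits(spec, "sweep_spec"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  write_run_metadata(spec$base, paste0(path, ".json"),
                     assumptions = c(spec$assumptions,
                                     list(axes = spec$axes, n = spec$n,
                                          master_seed = spec$seed)))
  invisible(path)
}
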