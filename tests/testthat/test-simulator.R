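test_that("breeding starts exactly at the energy threshold", {
  p2 <- clutch_params(c = 2)
  expect_equal(decide_action(250, p2), "forage")   # threshold 298
  expect_equal(decide_action(298, p2), "breed")
  p10 <- clutch_params(c = 10)
  expect_equal(decide_action(489.9, p10), "forage") # threshold 490
  expect_equal(decide_action(490, p10), "breed")
})

test_that("a hazard-free season follows the hand-derived schedule", {
  p <- clutch_params(c = 10, n = 1)
  r <- run_season(p, constant_hazard(0), keep_trace = TRUE)
  # forage 240 steps, breed 241..264 (success), then forage out the season
  expect_equal(r$n_attempts, 1L)
  expect_equal(r$n_successes, 1L)
  expect_equal(r$fledglings, 10L)
  expect_equal(r$excessive_reserve_time, 236L)
  expect_equal(r$trace$attempt_log,
               data.frame(start = 241L, end = 264L, outcome = "success"))
  expect_equal(r$acquired_energy, 476)   # 240 + 236 foraging steps, f_b = 0
  expect_equal(r$invested_energy, 240)
  expect_equal(r$final_energy, 486)
  expect_equal(r$trace$energy_series[1], 250)
  expect_equal(min(r$trace$energy_series), 250)  # dips exactly to E_i
  expect_equal(sum(r$trace$phase_series == "breed"), 24)
  m <- measure_excessive_reserve(r$trace, p)
  expect_equal(m$time, 236L)
  expect_equal(m$energy, 236)
})

test_that("certain failure yields zero fledglings and single-step attempts", {
  p <- clutch_params(c = 2, n = 1)
  set.seed(5)
  r <- run_season(p, constant_hazard(1), keep_trace = TRUE)
  expect_equal(r$fledglings, 0L)
  expect_equal(r$n_successes, 0L)
  expect_gt(r$n_attempts, 0L)
  log <- r$trace$attempt_log
  expect_true(all(log$end[log$outcome == "failure"] ==
                    log$start[log$outcome == "failure"]))
  expect_equal(measure_excessive_reserve(r$trace, p,
                                         from = "last_success")$time, p$T)
})

test_that("waste measurements distinguish last completed attempt from last success", {
  p <- clutch_params(c = 4, T = 800, n = 1)
  set.seed(31)
  r <- run_season(p, keep_trace = TRUE)
  m_att <- measure_excessive_reserve(r$trace, p)
  m_suc <- measure_excessive_reserve(r$trace, p, from = "last_success")
  expect_identical(m_att$time, r$excessive_reserve_time)
  expect_identical(m_suc$time, r$excessive_reserve_time_success)
  expect_lte(m_att$time, m_suc$time)
})

test_that("energy is conserved and floored at E_i across random seasons", {
  set.seed(20)
  for (i in 1:20) {
    cc <- sample(1:10, 1)
    p <- clutch_params(c = cc, T = sample(c(200, 500, 1000), 1),
                       forage_while_breeding = sample(c(TRUE, FALSE), 1),
                       n = 1)
    r <- run_season(p, keep_trace = TRUE)
    expect_equal(r$final_energy - p$E_i,
                 r$acquired_energy - r$invested_energy, tolerance = 1e-9)
    expect_equal(r$excessive_reserve_energy, r$final_energy - p$E_i)
    expect_gte(min(r$trace$energy_series), p$E_i)
    expect_equal(r$fledglings, cc * r$n_successes)
    log <- r$trace$attempt_log
    if (nrow(log) > 1)
      expect_true(all(log$start[-1] > log$end[-nrow(log)]))
    expect_true(all(log$end - log$start + 1 <= p$t_r))
  }
})

test_that("attempt counts fall and energy income rises with clutch size", {
  sp <- sweep_spec(clutch_params(), axes = list(c = 1:10), n = 1000, seed = 3)
  tab <- run_sweep(sp)
  att <- tab[tab$statistic == "n_attempts", ]
  expect_true(all(diff(att$mean) < 0))
  acq <- tab[tab$statistic == "acquired_energy", ]
  # non-decreasing up to sampling noise (adjacent cells, 3 SE slack)
  slack <- 3 * sqrt(acq$se[-1]^2 + acq$se[-10]^2)
  expect_true(all(diff(acq$mean) > -slack))
  expect_gt(acq$mean[10], acq$mean[1])
})

test_that("season process matches an independent event-based reimplementation", {
  # constant h, f_b = 0: mean successes over replicate seasons agree
  p <- clutch_params(c = 1, forage_while_breeding = FALSE, n = 1)
  hz <- constant_hazard(0.03)
  n <- 2000
  set.seed(77)
  sim <- replicate(n, run_season(p, hz)$n_successes)
  set.seed(78)
  orc <- replicate(n, oracle_season(500, 250, 1, 1, 1, 24, 0.03)$n_successes)
  se <- sqrt(var(sim) / n + var(orc) / n)
  expect_lt(abs(mean(sim) - mean(orc)), 3 * se)
})

test_that("success-count distribution matches exhaustive enumeration at small T", {
  p <- clutch_params(c = 1, t_r = 5, T = 60, forage_while_breeding = FALSE,
                     n = 1)
  hz <- constant_hazard(0.3)
  n <- 40000
  set.seed(55)
  sim <- replicate(n, run_season(p, hz)$n_successes)
  exact <- enumerate_successes(T = 60, c = 1, x = 1, f_f = 1, t_r = 5,
                               h = 0.3)
  expect_equal(sum(exact), 1, tolerance = 1e-12)
  emp <- tabulate(sim + 1L, nbins = length(exact))
  tv <- sum(abs(emp / n - exact)) / 2
  expect_lt(tv, 0.01)
})

test_that("replicate engine is deterministic and stream-isolated", {
  p <- clutch_params(c = 3, n = 40, seed = 9L)
  a <- run_replicates(p)
  b <- run_replicates(p)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$summary, b$summary)
  # replicate streams do not disturb the caller's RNG
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(run_replicates(p, n = 5)); x2 <- runif(1)
  expect_identical(x1, x2)
  # n = 1: SD is zero by convention, mean is the single value
  one <- run_replicates(p, n = 1, seed = 2L)
  expect_true(all(one$summary$sd == 0))
  expect_equal(one$summary$mean[one$summary$statistic == "fledglings"],
               one$replicates$fledglings)
  # degenerate h = 0: no randomness, zero SD across replicates
  det <- run_replicates(p, hazard = constant_hazard(0), n = 10)
  expect_true(all(det$summary$sd == 0))
  expect_equal(det$summary$se, det$summary$sd / sqrt(10))
  expect_equal(det$summary$std_mean, det$summary$mean / p$T)
})
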