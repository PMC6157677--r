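test_that("attempt start times sit on the renewal lattice", {
  p10 <- clutch_params(c = 10, forage_while_breeding = FALSE)
  expect_equal(start_time(0, p10), 240)
  expect_equal(start_time(1, p10) - start_time(0, p10), 11)
  p1 <- clutch_params(c = 1, forage_while_breeding = FALSE)
  expect_equal(start_time(5, p1), 24 + 5 * 2)
})

test_that("boundary indices follow the floored closed forms and their count ratio", {
  p <- clutch_params(c = 1, forage_while_breeding = FALSE)
  idx <- boundary_indices(p)
  expect_equal(idx$n1, 238L)
  expect_equal(idx$n2, 226L)
  expect_equal(idx$n3, 202L)
  expect_equal(idx$n1 - idx$n2, 12L)       # ~ t_r / (1 + c*x/f_f)
  # (n2 - n3)/(n1 - n2) ~ 1 + c*x/f_f: n2 - n3 is exactly t_r, and
  # n1 - n2 is t_r / (1 + c*x/f_f) up to one unit of floor rounding,
  # so the ratio error is bounded by (1 + c*x/f_f)^2 / (t_r - (1 + c*x/f_f))
  for (cc in 1:10) {
    pc <- clutch_params(c = cc, T = 10000, forage_while_breeding = FALSE)
    i <- boundary_indices(pc)
    expect_true(i$n1 >= i$n2 && i$n2 >= i$n3)
    fac <- 1 + cc
    expect_equal(i$n2 - i$n3, 24L)
    expect_lte(abs((i$n1 - i$n2) - 24 / fac), 1)
    expect_lt(abs((i$n2 - i$n3) / (i$n1 - i$n2) - fac), fac^2 / (24 - fac))
  }
  expect_error(boundary_indices(clutch_params(c = 10, T = 200,
                                              forage_while_breeding = FALSE)),
               "season_too_short")
})

test_that("zeroth-order waste is linear in c and independent of the hazard", {
  p <- clutch_params(c = 10, forage_while_breeding = FALSE)
  z <- zeroth_order_waste(p)
  expect_equal(z$mean, 132)
  expect_equal(z$sd, 24 / sqrt(12) * 11)
  expect_equal(z$fraction, 24 / 1000 * 11)
  # exact linearity: mean(c) = t_r/2 + (t_r*x/(2*f_f)) * c
  m <- vapply(1:10, function(cc)
    zeroth_order_waste(clutch_params(c = cc,
                                     forage_while_breeding = FALSE))$mean, 0)
  expect_equal(m, 12 + 12 * (1:10))
  # Monte-Carlo uniform-offset oracle: mean/sd of U(0, t_r*(1+c*x/f_f))
  set.seed(3)
  u <- runif(2e5, 0, 24 * 11)
  expect_equal(z$mean, mean(u), tolerance = 0.01)
  expect_equal(z$sd, sd(u), tolerance = 0.01)
  # no h anywhere in the zeroth order
  expect_identical(zeroth_order_waste(p), zeroth_order_waste(p))
})

test_that("weighted waste interpolates between t_r/2 and the zeroth order", {
  p <- clutch_params(c = 10, forage_while_breeding = FALSE)
  expect_equal(weighted_waste(p, h = 1)$mean, 12)     # q = 0
  w0 <- weighted_waste(p, h = 0)                      # q = 1
  expect_equal(w0$mean, (1 / 12) * 12 + (11 / 12) * 132)
  expect_equal(w0$w, 1 / 12)
  for (h in seq(0, 1, by = 0.1)) {
    wh <- weighted_waste(p, h = h)
    expect_gte(wh$mean, 12)
    expect_lte(wh$mean, 132)
    expect_true(wh$w >= 0 && wh$w <= 1)
  }
  # monotone non-increasing in h: more failures, later restarts, less waste
  mh <- vapply(seq(0, 1, by = 0.05), function(h) weighted_waste(p, h = h)$mean, 0)
  expect_true(all(diff(mh) <= 1e-12))
  # count-weighted enumeration over the lattice reproduces the closed form
  idx <- boundary_indices(p, T = 10000)
  q <- success_probability(0.03, 24)
  n_late <- idx$n1 - idx$n2
  n_win <- idx$n2 - idx$n3
  t_late <- start_time((idx$n2 + 1):idx$n1, p)
  t_win <- start_time((idx$n3 + 1):idx$n2, p)
  direct <- (sum(10000 - t_late) + q * sum(10000 - t_win - 24)) /
    (n_late + q * n_win)
  expect_lt(abs(weighted_waste(p, h = 0.03)$mean - direct), 11)  # one spacing
})

test_that("beta-hazard correction converges to the constant-hazard value", {
  p <- clutch_params(c = 5, forage_while_breeding = FALSE)
  # h_v -> 0: point mass at h_m
  tight <- hazard_model(h_m = 0.03, h_v = 1e-6)
  expect_equal(stochastic_h_waste(p, hazard = tight)$mean,
               weighted_waste(p, h = 0.03)$mean, tolerance = 1e-3)
  # stochastic hazard raises expected survival, hence expected waste
  expect_gt(stochastic_h_waste(p)$mean, weighted_waste(p, h = 0.03)$mean)
})

test_that("net-flow substitution folds f_b into the per-offspring cost", {
  p <- clutch_params(c = 2)
  ap <- apply_fb_substitution(p)
  expect_equal(ap$c * ap$x, 2 * 1 - 0.8)   # net per-step outflow
  expect_false(ap$forage_while_breeding)
  # c = c_max is a fixed point
  pmax <- clutch_params(c = 10)
  expect_identical(apply_fb_substitution(pmax), pmax)
  # substitution changes lattice spacing but not the t_r/T waste scaling
  fr <- vapply(c(500, 1000, 5000), function(TT)
    zeroth_order_waste(ap, T = TT)$fraction * TT, 0)
  expect_equal(fr, rep(fr[1], 3))
})

test_that("the bundled analytic table is internally consistent", {
  p <- clutch_params(T = 10000, forage_while_breeding = FALSE)
  tab <- analytic_waste_table(p)
  expect_equal(nrow(tab), 10)
  expect_true(all(diff(tab$waste_mean_zeroth) > 0))
  expect_true(all(tab$waste_mean_weighted <= tab$waste_mean_zeroth))
  expect_true(all(tab$waste_mean_beta >= tab$waste_mean_weighted))
  a <- analytic_waste(clutch_params(c = 4, T = 10000,
                                    forage_while_breeding = FALSE))
  row <- tab[tab$c == 4, ]
  expect_equal(row$waste_mean_beta, a$waste_mean_beta)
  expect_equal(row$n2, a$n2)
  # zeroth mean sits at the midpoint of the last-success window
  mid <- 10000 - (start_time(a$n3 + 1, a$params) +
                    start_time(a$n2, a$params)) / 2 - 24
  expect_lt(abs(a$waste_mean_zeroth - mid), a$lattice_spacing)
})
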