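test_that("hazard reduces to the baseline under null association", {
  sp <- null_hazard(rate = 0.1)
  par <- simple_params()
  expect_equal(hazard_at(sp, numeric(0), par, c(0, 3, 50)), rep(0.1, 3))
  sp2 <- null_hazard(rate = 0.1, gamma = c(z = log(2)))
  expect_equal(hazard_at(sp2, c(z = 1), par, 5), 0.2)
})

test_that("level association scales the hazard as exp(alpha1 * mu)", {
  sp <- null_hazard(rate = 0.1, alpha1 = 0.8)
  par <- simple_params()
  t_half <- log(2) / (log(100) / 10)  # mu(t) = 0.5
  expect_equal(hazard_at(sp, numeric(0), par, t_half), 0.1 * exp(0.4),
               tolerance = 1e-12)
})

test_that("mis-scaled association raises an overflow error with the exponent", {
  sp <- null_hazard(rate = 0.1, alpha1 = 2000)
  expect_error(hazard_at(sp, numeric(0), simple_params(), 0), "overflow")
})

test_that("baseline families evaluate and invert their cumulative hazards", {
  par <- simple_params()
  wb <- hazard_spec("weibull", list(shape = 1.5, scale = 10), t_max = 50)
  pc <- hazard_spec("piecewise",
                    list(cuts = c(5, 12), rates = c(0.05, 0.2, 0.1)),
                    t_max = 50)
  for (sp in list(null_hazard(0.13, t_max = 50), wb, pc)) {
    for (t in c(2, 5, 12, 30)) {
      quad <- integrate(function(s) mrdsim:::baseline_hazard(sp, s), 0, t,
                        rel.tol = 1e-10)$value
      H <- mrdsim:::baseline_cumhaz(sp, t)
      expect_equal(H, quad, tolerance = 1e-7)
      expect_equal(mrdsim:::baseline_cumhaz_inv(sp, H), t, tolerance = 1e-7)
    }
  }
})

test_that("cumulative hazard has closed-form null value and zero at origin", {
  sp <- null_hazard(rate = 0.1)
  par <- simple_params()
  expect_equal(cumulative_hazard(sp, numeric(0), par, 10), 1.0,
               tolerance = 1e-8)
  expect_equal(cumulative_hazard(sp, numeric(0), par, 0), 0)
})

test_that("cumulative hazard matches a fine trapezoid oracle", {
  par <- simple_params(tr = 15, beta2 = 0.3, te = 6, beta0 = 0.8,
                       beta1 = 0.02)
  sp <- null_hazard(rate = 0.1, alpha3 = 0.05, t_max = 30)
  g <- seq(0, 25, length.out = 1e5)
  h <- hazard_at(sp, numeric(0), par, g)
  trap <- sum(diff(g) * (head(h, -1) + tail(h, -1)) / 2)
  expect_equal(cumulative_hazard(sp, numeric(0), par, 25), trap,
               tolerance = 1e-5)
})

test_that("cumulative hazard is monotone and increases with risk factors", {
  par <- simple_params(beta0 = 0.8, beta1 = 0.05, te = 6)
  grid <- c(2, 5, 10, 20)
  base <- vapply(grid, function(t)
    cumulative_hazard(null_hazard(0.1, alpha1 = 0.3, t_max = 50),
                      numeric(0), par, t), numeric(1))
  expect_true(all(diff(base) > 0))
  up_a <- vapply(grid, function(t)
    cumulative_hazard(null_hazard(0.1, alpha1 = 0.8, t_max = 50),
                      numeric(0), par, t), numeric(1))
  up_l <- vapply(grid, function(t)
    cumulative_hazard(null_hazard(0.2, alpha1 = 0.3, t_max = 50),
                      numeric(0), par, t), numeric(1))
  sp_g <- null_hazard(0.1, alpha1 = 0.3, gamma = c(z = 0.7), t_max = 50)
  up_g <- vapply(grid, function(t)
    cumulative_hazard(sp_g, c(z = 1), par, t), numeric(1))
  expect_true(all(up_a > base))
  expect_true(all(up_l > base))
  expect_true(all(up_g > base))
})

test_that("inversion solves the closed-form exponential null exactly", {
  par <- simple_params()
  res <- sample_event_time(null_hazard(0.1), numeric(0), par, u = 0.5)
  expect_equal(res$time, log(2) / 0.1, tolerance = 1e-10)
  expect_true(res$event)
  resq <- sample_event_time(null_hazard(0.1), numeric(0), par, u = 0.5,
                            method = "quadrature")
  expect_equal(resq$time, log(2) / 0.1, tolerance = 1e-7)
  cens <- sample_event_time(null_hazard(0.01, t_max = 10), numeric(0), par,
                            u = 0.5)
  expect_equal(cens$time, 10)
  expect_false(cens$event)
  expect_error(sample_event_time(null_hazard(0.1), numeric(0), par, u = 0),
               "inside \\(0, 1\\)")
  expect_error(sample_event_time(null_hazard(0.1), numeric(0), par, u = 1.2),
               "inside \\(0, 1\\)")
})

test_that("analytic and quadrature inversion paths agree", {
  par <- trajectory_params(beta0 = 0.8, beta1 = 0.02, beta2 = 0.3, te = 6,
                           tr = 15)
  sp <- hazard_spec(baseline_params = list(rate = 0.2), alpha1 = 0.5,
                    link_scale = "log10", t_max = 40)
  for (u in c(0.9, 0.5, 0.2, 0.05)) {
    a <- sample_event_time(sp, numeric(0), par, u, method = "analytic")
    q <- sample_event_time(sp, numeric(0), par, u, method = "quadrature")
    expect_equal(a$time, q$time, tolerance = 1e-7)
    expect_equal(a$event, q$event)
  }
  expect_error(
    sample_event_time(null_hazard(0.1, alpha2 = 0.3), numeric(0), par, 0.5,
                      method = "analytic"),
    "no analytic inversion path")
})

test_that("inversion root satisfies the contract tolerance in H units", {
  par <- trajectory_params(beta0 = 0.8, beta1 = 0.05, te = 6)
  sp <- null_hazard(0.08, alpha1 = 0.6, t_max = 60)
  for (u in c(0.7, 0.3, 0.1)) {
    res <- sample_event_time(sp, numeric(0), par, u, method = "quadrature")
    expect_lt(abs(cumulative_hazard(sp, numeric(0), par, res$time) + log(u)),
              1e-8)
  }
})

test_that("null-association event times have the exponential mean", {
  par <- simple_params()
  sp <- null_hazard(0.1, t_max = 1e6)
  set.seed(1)
  times <- vapply(runif(5000), function(u)
    sample_event_time(sp, numeric(0), par, u)$time, numeric(1))
  expect_lt(abs(mean(times) - 10), 3 * 10 / sqrt(5000))
})

test_that("thinning accepts every proposal under a constant hazard", {
  par <- simple_params()
  sp <- null_hazard(0.25, t_max = 1e6)
  # under h == h_sup the accepted time is the first proposal, so the draw
  # stream is rexp/runif pairs: reproduce it by hand
  set.seed(17)
  res <- sample_event_time_thinning(sp, numeric(0), par)
  set.seed(17)
  expect_equal(res$time, rexp(1, 0.25))
  expect_true(res$event)
})

test_that("majorizing bound sits at t_max for a growing relapse hazard", {
  # relapse regrows past the baseline level by t_max, so the sup is there
  par <- trajectory_params(beta0 = 0.5, beta1 = 0.05, beta2 = 0.25, te = 4,
                           tr = 8)
  sp <- null_hazard(0.1, alpha1 = 0.8, t_max = 20)
  sup <- mrdsim:::hazard_sup(sp, numeric(0), par)
  expect_equal(sup, hazard_at(sp, numeric(0), par, 20), tolerance = 1e-9)
  grid_max <- max(hazard_at(sp, numeric(0), par,
                            seq(0, 20, length.out = 20001)))
  expect_gte(sup * (1 + 1e-9), grid_max)
})

test_that("thinning refuses a non-finite hazard bound", {
  par <- trajectory_params(beta0 = 0.5, beta1 = 0.02, beta2 = 0.5, te = 4,
                           tr = 8)
  sp <- null_hazard(0.1, alpha1 = 50, t_max = 100)
  expect_error(sample_event_time_thinning(sp, numeric(0), par),
               "smaller t_max|not finite|overflow")
})
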