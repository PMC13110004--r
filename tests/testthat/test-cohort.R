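test_that("degenerate subgroup distributions give deterministic truth", {
  sub <- subgroup_spec("CR", n = 3, beta0_meanlog = -2, beta0_sdlog = 0,
                       beta1_meanlog = -6, beta1_sdlog = 0, te = 5,
                       relapse_prob = 1, relapse_mean = 12, relapse_sd = 0,
                       beta2 = 0.2, sigma = 0.01)
  set.seed(1)
  tp <- sample_subject_truth(sub)
  expect_equal(tp$beta0, exp(-2))
  expect_equal(tp$beta1, exp(-6))
  expect_equal(tp$tr, 12)
  expect_equal(tp$te, 5)
  expect_equal(tp$beta2, 0.2)
})

test_that("no-relapse subgroups never relapse and lognormal moments hold", {
  sub <- subgroup_spec("A", n = 1, beta0_meanlog = -2, beta0_sdlog = 0.5,
                       beta1_meanlog = -5, beta1_sdlog = 0.3, te = 5)
  set.seed(8)
  draws <- replicate(10000, sample_subject_truth(sub), simplify = FALSE)
  expect_true(all(vapply(draws, function(p) is.infinite(p$tr), logical(1))))
  lb0 <- vapply(draws, function(p) log(p$beta0), numeric(1))
  expect_lt(abs(mean(lb0) + 2), 3 * 0.5 / sqrt(10000))
  expect_lt(abs(sd(lb0) - 0.5), 3 * 0.5 / sqrt(2 * 10000))
})

test_that("relapse times are truncated above te, or error when impossible", {
  sub <- subgroup_spec("B", n = 1, beta0_meanlog = -1, beta0_sdlog = 0.2,
                       beta1_meanlog = -4, beta1_sdlog = 0.2, te = 6,
                       relapse_prob = 1, relapse_mean = 7, relapse_sd = 3)
  set.seed(12)
  trs <- replicate(2000, sample_subject_truth(sub)$tr)
  expect_true(all(trs > 6))
  # relapse_mean barely above te with tiny sd: every candidate is > te, fine
  # relapse_mean far below te: rejection must give up
  bad <- subgroup_spec("C", n = 1, beta0_meanlog = -1, beta0_sdlog = 0.2,
                       beta1_meanlog = -4, beta1_sdlog = 0.2, te = 6,
                       relapse_prob = 1, relapse_mean = 6.0001,
                       relapse_sd = 1e-9)
  set.seed(1)
  expect_silent(sample_subject_truth(bad))
  expect_error(subgroup_spec("D", n = 1, beta0_meanlog = -1,
                             beta0_sdlog = 0.2, beta1_meanlog = -4,
                             beta1_sdlog = 0.2, te = 6, relapse_prob = 1,
                             relapse_mean = 2, relapse_sd = 1),
               "relapse_mean")
})

test_that("regular schedules build the arithmetic grid", {
  sched <- schedule_spec("regular", interval = 3, horizon = 12)
  s <- build_schedule(sched)
  expect_equal(s$time, c(0, 3, 6, 9, 12))
  expect_false(any(s$missing))
})

test_that("missingness is Bernoulli at the configured probability", {
  sched_all <- schedule_spec("regular", interval = 1, horizon = 10,
                             miss_prob = 1)
  expect_true(all(build_schedule(sched_all)$missing))
  sched <- schedule_spec("regular", interval = 1, horizon = 999,
                         miss_prob = 0.2)
  set.seed(5)
  miss <- unlist(replicate(10, build_schedule(sched)$missing,
                           simplify = FALSE))
  expect_lt(abs(mean(miss) - 0.2), 3 * sqrt(0.2 * 0.8 / length(miss)))
})

test_that("visit jitter preserves ordering or fails loudly", {
  sched <- schedule_spec("regular", interval = 3, horizon = 24,
                         jitter_sd = 0.3)
  set.seed(2)
  for (i in 1:50) {
    s <- build_schedule(sched)
    expect_false(is.unsorted(s$time, strictly = TRUE))
    expect_true(all(s$time >= 0))
  }
  # 20 nearly coincident visits with huge jitter: ordering survives a
  # redraw with probability ~1/20!, so 1000 attempts must give up
  impossible <- schedule_spec("explicit",
                              visit_times = seq(0, 1.9e-8, by = 1e-9),
                              jitter_sd = 5)
  set.seed(3)
  expect_error(build_schedule(impossible), "monotonicity")
})

test_that("covariate generation honors degenerate and sampled laws", {
  always <- covariate_spec("m", "binary", prob = 1)
  zero_sd <- covariate_spec("a", "continuous", mean = 0, sd = 0)
  set.seed(6)
  cv <- generate_covariates(list(always, zero_sd))
  expect_equal(cv$baseline$m, 1L)
  expect_equal(cv$baseline$a, 0)
  cat2 <- covariate_spec("g", "categorical", levels = c("x", "y"),
                         probs = c(0.5, 0.5))
  set.seed(7)
  draws <- replicate(10000, generate_covariates(list(cat2))$baseline$g)
  expect_lt(abs(mean(draws == "x") - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("time-variant covariates materialize one level per window", {
  tv <- covariate_spec("treat", "categorical", levels = c("on", "off"),
                       probs = c(0.5, 0.5),
                       time_variant = list(window_starts = c(0, 6, 12)))
  set.seed(9)
  cv <- generate_covariates(list(tv))
  expect_equal(nrow(cv$tracks), 3L)
  expect_equal(cv$tracks$start_time, c(0, 6, 12))
  expect_true(all(cv$tracks$value %in% c("on", "off")))
  expect_length(cv$baseline, 0L)
})

test_that("LoD flagging uses a strict threshold and a recount agrees", {
  obs <- data.frame(value = c(5e-5, 1e-4, 2e-4, NA),
                    missing = c(FALSE, FALSE, FALSE, TRUE))
  out <- apply_lod(obs, lod = 1e-4)
  expect_equal(out$below_lod, c(TRUE, FALSE, FALSE, NA))
  censored <- apply_lod(obs, lod = 1e-4, censor_at_lod = TRUE)
  expect_equal(censored$value[1], 1e-4)
  set.seed(10)
  big <- data.frame(value = rlnorm(1000, -8, 2), missing = FALSE)
  flagged <- apply_lod(big, lod = 1e-4)
  expect_equal(sum(flagged$below_lod), sum(big$value < 1e-4))
})

test_that("cohorts have the configured size, unique ids, and valid follow-up", {
  cfg <- mini_config(n = 3)
  cfg$subgroups[[2]] <- utils::modifyList(cfg$subgroups[[1]],
                                          list(name = "B", n = 2))
  ds <- simulate_cohort(cfg, seed = 30)
  expect_equal(nrow(ds$subjects), 5L)
  expect_false(anyDuplicated(ds$subjects$id) > 0)
  expect_true(all(ds$subjects$event_time <= 24))
  expect_true(all(ds$subjects$status %in% c(0L, 1L)))
  expect_true(all(ds$subjects$censor_reason[ds$subjects$status == 1L] ==
                    "none"))
  end <- ds$subjects$event_time[match(ds$observations$subject_id,
                                      ds$subjects$id)]
  expect_true(all(ds$observations$time <= end))
})

test_that("cohort simulation is deterministic given (config, seed)", {
  cfg <- mini_config(n = 4,
                     schedule = list(mode = "regular", interval = 3,
                                     horizon = 24, jitter_sd = 0.2,
                                     miss_prob = 0.1))
  a <- simulate_cohort(cfg, seed = 77)
  b <- simulate_cohort(cfg, seed = 77)
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(a$subjects$event_time, c2$subjects$event_time))
})

test_that("subjects can be re-simulated one at a time from child seeds", {
  cfg <- mini_config(n = 6)
  full <- simulate_cohort(cfg, seed = 55)
  solo <- as_sim_config(cfg)$subgroups[[1]]
  set.seed(child_seed(55, 4))
  truth4 <- sample_subject_truth(solo)
  expect_equal(full$ground_truth$subjects$beta0[4], truth4$beta0)
  expect_equal(full$ground_truth$subjects$beta1[4], truth4$beta1)
})

test_that("relapse-free cohorts decay monotonically, relapsers regrow", {
  cfg <- mini_config(n = 50)
  ds <- simulate_cohort(cfg, seed = 44)
  gt <- ds$ground_truth$subjects
  expect_true(all(is.infinite(gt$tr)))
  for (i in sample(nrow(gt), 5)) {
    par <- trajectory_params(gt$beta0[i], gt$beta1[i], gt$beta2[i],
                             gt$te[i], gt$tr[i], gt$sigma[i])
    tt <- seq(0, 24, length.out = 50)
    expect_true(all(diff(traj_value(par, tt)) <= 1e-12))
  }
  cfg_rel <- mini_config(n = 30)
  cfg_rel$subgroups[[1]] <- utils::modifyList(
    cfg_rel$subgroups[[1]],
    list(relapse_prob = 1, relapse_mean = 12, relapse_sd = 2, beta2 = 0.4))
  ds_rel <- simulate_cohort(cfg_rel, seed = 45)
  gt_rel <- ds_rel$ground_truth$subjects
  expect_true(all(is.finite(gt_rel$tr)))
  for (i in sample(nrow(gt_rel), 5)) {
    par <- trajectory_params(gt_rel$beta0[i], gt_rel$beta1[i],
                             gt_rel$beta2[i], gt_rel$te[i], gt_rel$tr[i])
    expect_gt(traj_value(par, gt_rel$tr[i] + 20), par$beta1)
  }
})
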