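#' Kaplan--Meier product-limit estimate
#'
#' Computes the product-limit survival estimate
#' \eqn{\hat S(t) = \prod_{t_j \le t} (1 - d_j/n_j)} over the distinct event
#' times, via [survival::survfit()]. Censored subjects leave the risk set
#' after their censoring time; under the standard tie convention, events at
#' a time precede censorings at the same time. Greenwood standard errors of
#' \eqn{\hat S} are included.
#'
#' @param records Data.frame with columns `time` (positive) and `status`
#'   (1 = event, 0 = censored).
#' @return A `km_curve` object: list with `time` (distinct event times),
#'   `survival`, `std_err` (Greenwood), `n_risk`, `n_event`, and the sample
#'   size `n`.
#' @examples
#' km_estimate(data.frame(time = c(2, 4, 4, 6, 8),
#'                        status = c(1, 1, 1, 0, 1)))
#' @export
km_estimate <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data.frame", call. = FALSE)
  }
  if (!all(c("time", "status") %in% names(records))) {
    stop("`records` needs `time` and `status` columns", call. = FALSE)
  }
  if (any(records$time <= 0)) {
    stop("survival times must be > 0", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = records)
  keep <- fit$n.event > 0
  # Greenwood: Var(S) = S^2 * sum d / (n (n - d)); the last factor is 0/0
  # when d == n (curve hits zero) -- treat that term's variance as 0
  d <- fit$n.event[keep]; n <- fit$n.risk[keep]
  gw <- d / (n * (n - d))
  gw[!is.finite(gw)] <- 0
  surv <- fit$surv[keep]
  structure(
    list(time = fit$time[keep], survival = surv,
         std_err = surv * sqrt(cumsum(gw)),
         n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
         n = nrow(records)),
    class = "km_curve")
}

#' Evaluate a Kaplan--Meier curve at arbitrary times
#'
#' @param curve A `km_curve`.
#' @param t Vector of times.
#' @return `S(t)` as a right-continuous step function (1 before the first
#'   event).
#' @export
km_survival_at <- function(curve, t) {
  if (!inherits(curve, "km_curve")) {
    stop("`curve` must be a `km_curve`", call. = FALSE)
  }
  if (length(curve$time) == 0L) return(rep(1, length(t)))
  stats::stepfun(curve$time, c(1, curve$survival), right = FALSE)(t)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d distinct event time(s)\n",
              x$n, length(x$time)))
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   survival = x$survival, std_err = x$std_err))
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' Standard log-rank comparison via [survival::survdiff()]: at each distinct
#' event time, observed-minus-expected events per group under the
#' hypergeometric null; the statistic is chi-square distributed with
#' `k - 1` degrees of freedom for `k` groups.
#'
#' @param records Data.frame with columns `time`, `status`, and `group`.
#' @return A `logrank_test` object: list with `statistic`, `p_value`, `df`,
#'   and per-group `observed`/`expected` event counts.
#' @export
logrank_test <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("time", "status", "group") %in% names(records))) {
    stop("`records` needs `time`, `status`, and `group` columns",
         call. = FALSE)
  }
  groups <- unique(records$group)
  if (length(groups) < 2L) {
    stop("log-rank test needs at least two groups with records",
         call. = FALSE)
  }
  if (sum(records$status) < 1L) {
    stop("log-rank test needs at least one event", call. = FALSE)
  }
  fit <- survival::survdiff(survival::Surv(time, status) ~ group,
                            data = records)
  df <- length(fit$n) - 1L
  structure(
    list(statistic = unname(fit$chisq),
         p_value = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE),
         df = df, observed = fit$obs, expected = fit$exp),
    class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' MRD-negativity rate at a landmark time
#'
#' For each subject, finds the nearest non-missing MRD assessment to
#' `landmark_time` within a matching window (default: half the median
#' inter-visit gap in the dataset) and calls the subject MRD-negative when
#' that value is strictly below `lod`. Subjects with no qualifying visit
#' are excluded from the rate and counted separately.
#'
#' @param dataset An `mrd_dataset`.
#' @param lod Positive detection limit used for the negativity call (may
#'   differ from the LoD the dataset was simulated with).
#' @param landmark_time Non-negative landmark time.
#' @param window Optional matching half-window; defaults to half the median
#'   inter-visit gap.
#' @return Data.frame per subgroup: `subgroup`, `n_eligible`, `n_negative`,
#'   `rate`, `n_excluded`.
#' @export
mrd_negativity_rate <- function(dataset, lod, landmark_time,
                                window = NULL) {
  check_scalar(lod, "lod", positive = TRUE)
  check_scalar(landmark_time, "landmark_time", nonneg = TRUE)
  obs <- dataset$observations
  if (is.null(window)) {
    gaps <- unlist(lapply(split(obs$time, obs$subject_id), function(tt)
      diff(sort(tt))))
    window <- if (length(gaps)) stats::median(gaps) / 2 else Inf
  }
  subj <- dataset$subjects
  res <- lapply(split(subj, subj$subgroup), function(sg) {
    neg <- elig <- 0L
    for (id in sg$id) {
      o <- obs[obs$subject_id == id & !obs$missing &
                 abs(obs$time - landmark_time) <= window, , drop = FALSE]
      if (nrow(o) == 0L) next
      o <- o[order(abs(o$time - landmark_time), o$time), , drop = FALSE]
      elig <- elig + 1L
      if (o$value[1] < lod) neg <- neg + 1L
    }
    data.frame(subgroup = sg$subgroup[1], n_eligible = elig,
               n_negative = neg,
               rate = if (elig > 0) neg / elig else NA_real_,
               n_excluded = nrow(sg) - elig, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$subgroup), , drop = FALSE]
}

#' Monte-Carlo power analysis for a two-arm trial
#'
#' Simulates `n_reps` paired trials: in replicate r, a control cohort from
#' `config_control` with seed `child_seed(seed, 2r - 1)` and a treatment
#' cohort from `config_treatment` with seed `child_seed(seed, 2r)`. Each
#' replicate is analyzed with the per-replicate test (log-rank on the
#' event-free-survival endpoint by default; `test_fn` accepts any function
#' of the pooled records returning a p-value). Power is the fraction of
#' replicates with `p < alpha_level`.
#'
#' @param config_control,config_treatment Simulation configs for the two
#'   arms; their `t_max` (trial follow-up) must agree.
#' @param n_reps Number of replicates (>= 1).
#' @param alpha_level Nominal test level in (0, 1).
#' @param seed Master seed; the run is bit-reproducible given
#'   `(configs, n_reps, seed)`.
#' @param test_fn Optional function `(records) -> p-value`, where `records`
#'   has columns `time`, `status`, `group` (the arm).
#' @return An `mrd_power` object: `power`, binomial `mc_se`, per-arm mean
#'   event counts, and the replicate-level `p_values`.
#' @export
power_analysis <- function(config_control, config_treatment, n_reps,
                           alpha_level = 0.05, seed,
                           test_fn = NULL) {
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1 ||
      n_reps != round(n_reps)) {
    stop("`n_reps` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(alpha_level) || alpha_level <= 0 || alpha_level >= 1) {
    stop("`alpha_level` must lie strictly inside (0, 1)", call. = FALSE)
  }
  cc <- as_sim_config(config_control)
  ct <- as_sim_config(config_treatment)
  if (cc$hazard$t_max != ct$hazard$t_max) {
    abort_class(sprintf(
      "arm configs disagree on follow-up: control t_max = %g, treatment t_max = %g",
      cc$hazard$t_max, ct$hazard$t_max), "mrd_config_error")
  }
  if (is.null(test_fn)) {
    test_fn <- function(records) logrank_test(records)$p_value
  }
  p_values <- numeric(n_reps)
  ev_c <- ev_t <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    ds_c <- simulate_cohort(cc, seed = child_seed(seed, 2L * r - 1L))
    ds_t <- simulate_cohort(ct, seed = child_seed(seed, 2L * r))
    rec <- rbind(
      data.frame(time = ds_c$subjects$event_time,
                 status = ds_c$subjects$status, group = "control",
                 stringsAsFactors = FALSE),
      data.frame(time = ds_t$subjects$event_time,
                 status = ds_t$subjects$status, group = "treatment",
                 stringsAsFactors = FALSE))
    p_values[r] <- test_fn(rec)
    ev_c[r] <- sum(ds_c$subjects$status == 1L)
    ev_t[r] <- sum(ds_t$subjects$status == 1L)
  }
  power <- mean(p_values < alpha_level)
  structure(
    list(power = power,
         mc_se = sqrt(power * (1 - power) / n_reps),
         n_reps = as.integer(n_reps), alpha_level = alpha_level,
         mean_events_control = mean(ev_c),
         mean_events_treatment = mean(ev_t),
         events_control = ev_c, events_treatment = ev_t,
         p_values = p_values),
    class = "mrd_power")
}

#' @export
print.mrd_power <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo power: %.3f (MC SE %.3f) over %d replicates at alpha = %g\n",
    x$power, x$mc_se, x$n_reps, x$alpha_level))
  cat(sprintf("Mean events/arm: control %.1f, treatment %.1f\n",
              x$mean_events_control, x$mean_events_treatment))
  invisible(x)
}

#' Summary tables for a simulated dataset
#'
#' Per-subgroup counts (subjects, events, censorings), median follow-up,
#' median observed event time from the Kaplan--Meier curve (NA when not
#' reached), MRD level summaries, and the fraction of non-missing
#' measurements below the dataset's LoD; plus a per-visit table of mean and
#' median MRD by visit rank within subgroup.
#'
#' @param dataset A non-empty `mrd_dataset`.
#' @return An `mrd_summary` object: list with data.frames `subgroups` and
#'   `visits`.
#' @export
summarize_dataset <- function(dataset) {
  if (!inherits(dataset, "mrd_dataset") || nrow(dataset$subjects) == 0L) {
    stop("`dataset` must be a non-empty `mrd_dataset`", call. = FALSE)
  }
  lod <- dataset$metadata$config$lod
  subj <- dataset$subjects
  obs <- dataset$observations
  per_sub <- lapply(split(subj, subj$subgroup), function(sg) {
    o <- obs[obs$subject_id %in% sg$id & !obs$missing, , drop = FALSE]
    km <- km_estimate(data.frame(time = sg$event_time, status = sg$status))
    med_idx <- which(km$survival <= 0.5)
    data.frame(
      subgroup = sg$subgroup[1],
      n = nrow(sg),
      events = sum(sg$status == 1L),
      censored = sum(sg$status == 0L),
      median_followup = stats::median(sg$event_time),
      km_median_event_time = if (length(med_idx))
        km$time[min(med_idx)] else NA_real_,
      mean_mrd = if (nrow(o)) mean(o$value) else NA_real_,
      median_mrd = if (nrow(o)) stats::median(o$value) else NA_real_,
      frac_below_lod = if (nrow(o) && !is.null(lod))
        mean(o$value < lod) else NA_real_,
      stringsAsFactors = FALSE)
  })
  subgroups <- do.call(rbind, per_sub)
  rownames(subgroups) <- NULL

  obs_nm <- obs[!obs$missing, , drop = FALSE]
  obs_nm$subgroup <- subj$subgroup[match(obs_nm$subject_id, subj$id)]
  obs_nm <- obs_nm[order(obs_nm$subject_id, obs_nm$time), , drop = FALSE]
  obs_nm$visit <- stats::ave(obs_nm$time, obs_nm$subject_id,
                             FUN = seq_along)
  visits <- do.call(rbind, lapply(
    split(obs_nm, list(obs_nm$subgroup, obs_nm$visit), drop = TRUE),
    function(g) data.frame(
      subgroup = g$subgroup[1], visit = g$visit[1], n = nrow(g),
      mean_time = mean(g$time), mean_mrd = mean(g$value),
      median_mrd = stats::median(g$value),
      frac_below_lod = if (!is.null(lod)) mean(g$value < lod) else NA_real_,
      stringsAsFactors = FALSE)))
  visits <- visits[order(visits$subgroup, visits$visit), , drop = FALSE]
  rownames(visits) <- NULL
  structure(list(subgroups = subgroups, visits = visits),
            class = "mrd_summary")
}

#' @export
print.mrd_summary <- function(x, ...) {
  cat("Per-subgroup summary:\n")
  print(x$subgroups)
  invisible(x)
}

#' @export
summary.mrd_dataset <- function(object, ...) summarize_dataset(object)
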