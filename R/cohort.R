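#' Population specification for one response subgroup
#'
#' Describes how ground-truth trajectory parameters are drawn for one
#' response category (for example CR/PR/SD/PD). Baseline and plateau MRD
#' levels are lognormal; relapse occurs with probability `relapse_prob` per
#' subject and, when it occurs, the onset time is normal with mean
#' `relapse_mean` and sd `relapse_sd`, truncated below at the subgroup's
#' end-of-treatment time `te` (a relapse cannot precede end of treatment).
#' `te`, `beta2`, and `sigma` are subgroup constants.
#'
#' @param name Subgroup label.
#' @param n Positive integer cohort size.
#' @param beta0_meanlog,beta0_sdlog Lognormal parameters of the baseline MRD
#'   level (sdlog >= 0).
#' @param beta1_meanlog,beta1_sdlog Lognormal parameters of the plateau
#'   level.
#' @param te Positive end-of-treatment time.
#' @param relapse_prob Per-subject relapse probability in `[0, 1]`.
#' @param relapse_mean,relapse_sd Normal parameters of the relapse onset
#'   time; required when `relapse_prob > 0`, with `relapse_mean > te`.
#' @param beta2 Non-negative relapse growth rate shared within the subgroup.
#' @param sigma Non-negative measurement-error sd.
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, n, beta0_meanlog, beta0_sdlog,
                          beta1_meanlog, beta1_sdlog, te,
                          relapse_prob = 0, relapse_mean = NA_real_,
                          relapse_sd = NA_real_, beta2 = 0, sigma = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  check_scalar(beta0_meanlog, "beta0_meanlog")
  check_scalar(beta0_sdlog, "beta0_sdlog", nonneg = TRUE)
  check_scalar(beta1_meanlog, "beta1_meanlog")
  check_scalar(beta1_sdlog, "beta1_sdlog", nonneg = TRUE)
  check_scalar(te, "te", positive = TRUE)
  check_scalar(beta2, "beta2", nonneg = TRUE)
  check_scalar(sigma, "sigma", nonneg = TRUE)
  if (!is.numeric(relapse_prob) || relapse_prob < 0 || relapse_prob > 1) {
    stop("`relapse_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (relapse_prob > 0) {
    check_scalar(relapse_mean, "relapse_mean")
    check_scalar(relapse_sd, "relapse_sd", nonneg = TRUE)
    if (relapse_mean <= te) {
      stop("`relapse_mean` must exceed `te` when relapse_prob > 0",
           call. = FALSE)
    }
  }
  structure(
    list(name = name, n = as.integer(n),
         beta0_meanlog = beta0_meanlog, beta0_sdlog = beta0_sdlog,
         beta1_meanlog = beta1_meanlog, beta1_sdlog = beta1_sdlog,
         te = te, relapse_prob = relapse_prob,
         relapse_mean = relapse_mean, relapse_sd = relapse_sd,
         beta2 = beta2, sigma = sigma),
    class = "subgroup_spec"
  )
}

#' MRD assessment schedule
#'
#' Either an explicit sorted list of visit times or a regular grid
#' `0, interval, 2*interval, ...` up to `horizon`. Optional Gaussian visit
#' jitter (redrawn until the jittered schedule stays non-negative and
#' strictly increasing) and per-visit Bernoulli missingness emulate
#' real-world assessment patterns; missed visits are retained as records
#' with `missing = TRUE` so missingness patterns stay analyzable.
#'
#' @param mode `"regular"` or `"explicit"`.
#' @param visit_times Sorted non-negative visit times (explicit mode).
#' @param interval,horizon Positive grid step and end time (regular mode).
#' @param jitter_sd Non-negative sd of visit-time jitter.
#' @param miss_prob Per-visit missingness probability in `[0, 1]`.
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(mode = c("regular", "explicit"),
                          visit_times = NULL, interval = NULL,
                          horizon = NULL, jitter_sd = 0, miss_prob = 0) {
  mode <- match.arg(mode)
  check_scalar(jitter_sd, "jitter_sd", nonneg = TRUE)
  if (!is.numeric(miss_prob) || miss_prob < 0 || miss_prob > 1) {
    stop("`miss_prob` must lie in [0, 1]", call. = FALSE)
  }
  if (mode == "explicit") {
    if (is.null(visit_times) || !is.numeric(visit_times) ||
        any(visit_times < 0) || is.unsorted(visit_times, strictly = TRUE)) {
      stop("`visit_times` must be non-negative and strictly increasing",
           call. = FALSE)
    }
  } else {
    check_scalar(interval, "interval", positive = TRUE)
    check_scalar(horizon, "horizon", positive = TRUE)
  }
  structure(
    list(mode = mode, visit_times = visit_times, interval = interval,
         horizon = horizon, jitter_sd = jitter_sd, miss_prob = miss_prob),
    class = "schedule_spec"
  )
}

#' Baseline or time-variant covariate specification
#'
#' Baseline covariates are drawn once per subject: binary Bernoulli(`prob`),
#' categorical from `levels` with probabilities `probs`, or continuous
#' Normal(`mean`, `sd`). A covariate with a `time_variant` definition is
#' materialized instead as a piecewise-constant track (one level drawn per
#' time window); tracks are exported for visualization but do not feed the
#' hazard, which uses baseline covariates only.
#'
#' @param name Covariate label.
#' @param kind `"binary"`, `"categorical"`, or `"continuous"`.
#' @param prob Success probability (binary).
#' @param levels,probs Level labels and probabilities summing to 1
#'   (categorical).
#' @param mean,sd Normal parameters (continuous).
#' @param time_variant Optional list with `window_starts`, the sorted start
#'   times of the piecewise-constant windows (first must be 0).
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, kind = c("binary", "categorical",
                                          "continuous"),
                           prob = NULL, levels = NULL, probs = NULL,
                           mean = NULL, sd = NULL, time_variant = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("covariate `name` must be a non-empty string", call. = FALSE)
  }
  kind <- match.arg(kind)
  if (kind == "binary") {
    if (!is.numeric(prob) || length(prob) != 1L || prob < 0 || prob > 1) {
      stop(sprintf("covariate '%s': `prob` must lie in [0, 1]", name),
           call. = FALSE)
    }
  } else if (kind == "categorical") {
    if (is.null(levels) || is.null(probs) ||
        length(levels) != length(probs) || any(probs < 0) ||
        abs(sum(probs) - 1) > 1e-8) {
      stop(sprintf(
        "covariate '%s': `levels` and `probs` must match and probs must sum to 1",
        name), call. = FALSE)
    }
  } else {
    check_scalar(mean, sprintf("covariate '%s' mean", name))
    check_scalar(sd, sprintf("covariate '%s' sd", name), nonneg = TRUE)
  }
  if (!is.null(time_variant)) {
    ws <- time_variant$window_starts
    if (is.null(ws) || !is.numeric(ws) || ws[1] != 0 ||
        is.unsorted(ws, strictly = TRUE)) {
      stop(sprintf(
        "covariate '%s': time_variant$window_starts must start at 0 and be strictly increasing",
        name), call. = FALSE)
    }
  }
  structure(
    list(name = name, kind = kind, prob = prob, levels = levels,
         probs = probs, mean = mean, sd = sd, time_variant = time_variant),
    class = "covariate_spec"
  )
}

#' Draw one subject's ground-truth trajectory parameters
#'
#' Draw order (reproducibility contract): baseline level, plateau level,
#' relapse-occurrence uniform (always consumed), then relapse time by
#' rejection sampling above `te` (at most 1000 attempts) when relapse
#' occurs.
#'
#' @param sub A [subgroup_spec()] object.
#' @return A [trajectory_params()] object.
#' @export
sample_subject_truth <- function(sub) {
  if (!inherits(sub, "subgroup_spec")) {
    stop("`sub` must be a `subgroup_spec` object", call. = FALSE)
  }
  beta0 <- stats::rlnorm(1, sub$beta0_meanlog, sub$beta0_sdlog)
  beta1 <- stats::rlnorm(1, sub$beta1_meanlog, sub$beta1_sdlog)
  relapses <- stats::runif(1) < sub$relapse_prob
  tr <- Inf
  if (relapses) {
    for (i in seq_len(1000L)) {
      cand <- stats::rnorm(1, sub$relapse_mean, sub$relapse_sd)
      if (cand > sub$te) { tr <- cand; break }
    }
    if (!is.finite(tr) || tr <= sub$te) {
      stop(sprintf(
        "could not draw a relapse time above te = %g in 1000 attempts for subgroup '%s' (relapse_mean is far below te)",
        sub$te, sub$name), call. = FALSE)
    }
  }
  trajectory_params(beta0 = beta0, beta1 = beta1, beta2 = sub$beta2,
                    te = sub$te, tr = tr, sigma = sub$sigma)
}

#' Realize a visit schedule for one subject
#'
#' Applies jitter and missingness to the scheduled visit grid. Draw order:
#' one normal jitter draw per visit (redrawing the whole vector, at most
#' 1000 attempts, until order and non-negativity hold), then one Bernoulli
#' missingness draw per visit.
#'
#' @param sched A [schedule_spec()] object.
#' @return A data.frame with columns `time` and `missing`.
#' @export
build_schedule <- function(sched) {
  if (!inherits(sched, "schedule_spec")) {
    stop("`sched` must be a `schedule_spec` object", call. = FALSE)
  }
  base <- if (sched$mode == "explicit") sched$visit_times else
    seq(0, sched$horizon, by = sched$interval)
  times <- base
  if (sched$jitter_sd > 0) {
    ok <- FALSE
    for (i in seq_len(1000L)) {
      cand <- base + stats::rnorm(length(base), 0, sched$jitter_sd)
      if (all(cand >= 0) && !is.unsorted(cand, strictly = TRUE)) {
        times <- cand; ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("visit jitter violated schedule monotonicity in 1000 redraws; reduce `jitter_sd`",
           call. = FALSE)
    }
  }
  missing <- stats::runif(length(times)) < sched$miss_prob
  data.frame(time = times, missing = missing)
}

#' Draw covariate values for one subject
#'
#' @param specs List of [covariate_spec()] objects.
#' @return A list with `baseline` (named list of values) and `tracks`
#'   (data.frame `name`, `start_time`, `value` for time-variant covariates;
#'   zero rows when none are declared).
#' @export
generate_covariates <- function(specs) {
  baseline <- list()
  tracks <- data.frame(name = character(0), start_time = numeric(0),
                       value = character(0), stringsAsFactors = FALSE)
  draw_one <- function(sp) {
    switch(sp$kind,
      binary = as.integer(stats::runif(1) < sp$prob),
      categorical = sample(sp$levels, 1L, prob = sp$probs),
      continuous = stats::rnorm(1, sp$mean, sp$sd),
      stop(sprintf("unknown covariate kind '%s'", sp$kind), call. = FALSE)
    )
  }
  for (sp in specs) {
    if (!inherits(sp, "covariate_spec")) {
      stop("each covariate spec must be a `covariate_spec` object",
           call. = FALSE)
    }
    if (is.null(sp$time_variant)) {
      baseline[[sp$name]] <- draw_one(sp)
    } else {
      ws <- sp$time_variant$window_starts
      vals <- vapply(ws, function(w) as.character(draw_one(sp)), character(1))
      tracks <- rbind(tracks, data.frame(
        name = sp$name, start_time = as.numeric(ws), value = vals,
        stringsAsFactors = FALSE))
    }
  }
  list(baseline = baseline, tracks = tracks)
}

#' Flag observations below the limit of detection
#'
#' Sets `below_lod = (value < lod)` with a strict inequality (a value equal
#' to the LoD counts as detectable); missing observations get `NA`. Values
#' are not altered unless `censor_at_lod = TRUE`, which replaces below-LoD
#' values with `lod` for left-censored reporting.
#'
#' @param observations Data.frame with at least `value` and `missing`
#'   columns.
#' @param lod Positive limit of detection, in MRD units.
#' @param censor_at_lod Replace below-LoD values with `lod`?
#' @return The observations with a `below_lod` column set.
#' @export
apply_lod <- function(observations, lod, censor_at_lod = FALSE) {
  check_scalar(lod, "lod", positive = TRUE)
  below <- !observations$missing & observations$value < lod
  below[observations$missing] <- NA
  observations$below_lod <- below
  if (censor_at_lod) {
    idx <- which(!is.na(below) & below)
    observations$value[idx] <- lod
  }
  observations
}

#' Simulate a full joint MRD + survival cohort
#'
#' Orchestrates the whole generator: for each subgroup, `n` subjects are
#' simulated, each from its own counter-derived seed
#' (`child_seed(seed, k)` for the k-th subject overall), with a fixed
#' per-subject draw order: trajectory truth (baseline, plateau, relapse
#' occurrence, relapse time), covariates, event uniform, dropout uniform,
#' visit jitter and missingness, then one noise draw per retained
#' non-missing visit. Follow-up ends at the minimum of the sampled event
#' time, dropout time, and `t_max`; visits after follow-up end are
#' discarded. The result is byte-reproducible given `(config, seed)`.
#'
#' @param config A simulation configuration: the result of
#'   [load_sim_config()] or a raw list in the same shape (it is validated
#'   either way).
#' @param seed Integer master seed.
#' @return An object of class `mrd_dataset`: a list with `metadata`,
#'   `subjects`, `observations`, `tracks`, `covariates`, `endpoints`, and
#'   `ground_truth`.
#' @examples
#' cfg <- example_config(n_per_group = 5)
#' ds <- simulate_cohort(cfg, seed = 1)
#' nrow(ds$subjects)
#' @export
simulate_cohort <- function(config, seed) {
  config <- as_sim_config(config)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  seed <- as.integer(seed)
  hz <- config$hazard
  cov_specs <- config$covariates
  gamma_names <- names(hz$gamma)

  subjects <- list(); observations <- list(); truths <- list()
  tracks <- list()
  counter <- 0L
  for (sub in config$subgroups) {
    for (i in seq_len(sub$n)) {
      counter <- counter + 1L
      set.seed(child_seed(seed, counter))
      id <- sprintf("%s-%03d", sub$name, i)

      truth <- sample_subject_truth(sub)
      cv <- generate_covariates(cov_specs)
      x <- if (length(gamma_names)) {
        vapply(gamma_names, function(nm) {
          v <- cv$baseline[[nm]]
          if (is.null(v)) stop(sprintf(
            "hazard gamma refers to covariate '%s' which is not a numeric baseline covariate",
            nm), call. = FALSE)
          as.numeric(v)
        }, numeric(1))
      } else numeric(0)

      u_event <- stats::runif(1)
      u_drop <- stats::runif(1)
      evt <- sample_event_time(hz, x, truth, u_event)
      drop_time <- if (hz$dropout_rate > 0) -log(u_drop) / hz$dropout_rate
        else Inf
      if (evt$event && evt$time <= drop_time) {
        end_time <- evt$time; status <- 1L; reason <- "none"
      } else if (drop_time < evt$time) {
        end_time <- drop_time; status <- 0L; reason <- "dropout"
      } else {
        end_time <- evt$time; status <- 0L; reason <- "administrative"
      }

      sched <- build_schedule(config$schedule)
      sched <- sched[sched$time <= end_time, , drop = FALSE]
      value <- rep(NA_real_, nrow(sched))
      raw <- rep(NA_real_, nrow(sched))
      keep <- which(!sched$missing)
      if (length(keep)) {
        obs <- traj_observe(truth, sched$time[keep],
                            noise_mode = config$noise_mode)
        value[keep] <- obs$value
        raw[keep] <- obs$raw_value
      }
      obs_df <- data.frame(subject_id = rep(id, nrow(sched)),
                           time = sched$time,
                           value = value, raw_value = raw,
                           missing = sched$missing,
                           stringsAsFactors = FALSE)
      obs_df <- apply_lod(obs_df, config$lod, config$censor_at_lod)

      subj_row <- c(list(id = id, subgroup = sub$name), cv$baseline,
                    list(event_time = end_time, status = status,
                         censor_reason = reason))
      subjects[[counter]] <- subj_row
      observations[[counter]] <- obs_df
      if (nrow(cv$tracks)) {
        tracks[[counter]] <- cbind(subject_id = id, cv$tracks,
                                   stringsAsFactors = FALSE)
      }
      truths[[counter]] <- data.frame(
        subject_id = id, beta0 = truth$beta0, beta1 = truth$beta1,
        beta2 = truth$beta2, te = truth$te, tr = truth$tr,
        sigma = truth$sigma, stringsAsFactors = FALSE)
    }
  }

  subjects_df <- do.call(rbind, lapply(subjects, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  observations_df <- do.call(rbind, observations)
  rownames(observations_df) <- NULL
  tracks_df <- if (length(tracks)) do.call(rbind, tracks) else
    data.frame(subject_id = character(0), name = character(0),
               start_time = numeric(0), value = character(0),
               stringsAsFactors = FALSE)
  rownames(tracks_df) <- NULL
  truth_df <- do.call(rbind, truths)

  endpoints <- list(event_free_survival = data.frame(
    subject_id = subjects_df$id, time = subjects_df$event_time,
    status = subjects_df$status, stringsAsFactors = FALSE))

  structure(
    list(
      metadata = list(
        schema_version = dataset_schema_version(),
        time_unit = config$time_unit,
        seed = seed,
        generator = paste0("mrdsim ", as.character(utils::packageVersion("mrdsim"))),
        colormaps = config$colormaps,
        config = config_to_list(config)
      ),
      subjects = subjects_df,
      observations = observations_df,
      tracks = tracks_df,
      covariates = cov_specs,
      endpoints = endpoints,
      ground_truth = list(
        subjects = truth_df,
        hazard = hz,
        subgroups = config$subgroups
      )
    ),
    class = "mrd_dataset"
  )
}

#' @export
print.mrd_dataset <- function(x, ...) {
  cat(sprintf("<mrd_dataset> %d subjects, %d observations, %d subgroup(s)\n",
              nrow(x$subjects), nrow(x$observations),
              length(unique(x$subjects$subgroup))))
  cat(sprintf("  events: %d, censored: %d; time unit: %s; seed: %s\n",
              sum(x$subjects$status == 1L), sum(x$subjects$status == 0L),
              x$metadata$time_unit, x$metadata$seed))
  invisible(x)
}
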