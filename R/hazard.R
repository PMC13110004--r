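#' Specification of the joint Cox hazard
#'
#' Defines the hazard of the clinical event for a subject with baseline
#' covariates `x` and true trajectory `mu(t)`:
#' \deqn{h(t) = h_0(t) \exp\{\gamma^T x + \alpha_1 g(\mu(t)) +
#'   \alpha_2 g'(t) + \alpha_3 G(t)\}}
#' where `g` is the identity (`link_scale = "raw"`) or the base-10 log
#' (`link_scale = "log10"`), `g'` is the corresponding slope (d mu/dt, or
#' d log10 mu/dt), and `G` the corresponding running integral. The three
#' association parameters tie risk to the current MRD level, its
#' instantaneous rate of change, and the cumulative disease burden.
#'
#' @param baseline_family One of `"exponential"` (constant rate `rate`),
#'   `"weibull"` (`shape`, `scale`), or `"piecewise"` (piecewise-constant
#'   rates: `cuts`, increasing cut times, and `rates` of length
#'   `length(cuts) + 1`).
#' @param baseline_params Named list of family-specific positive parameters.
#' @param gamma Named numeric vector of log-hazard ratios for baseline
#'   covariates (may be empty).
#' @param alpha1,alpha2,alpha3 Association coefficients on the (transformed)
#'   MRD level, slope, and cumulative burden.
#' @param link_scale `"raw"` (default) or `"log10"`. The two scales are never
#'   mixed within one dataset.
#' @param t_max Positive administrative censoring time.
#' @param dropout_rate Non-negative rate of independent exponential dropout
#'   censoring; 0 disables dropout.
#' @return An object of class `hazard_spec`.
#' @examples
#' hazard_spec(baseline_params = list(rate = 0.1), alpha1 = 0.8, t_max = 36)
#' @export
hazard_spec <- function(baseline_family = c("exponential", "weibull",
                                            "piecewise"),
                        baseline_params = list(rate = 0.1),
                        gamma = numeric(0),
                        alpha1 = 0, alpha2 = 0, alpha3 = 0,
                        link_scale = c("raw", "log10"),
                        t_max, dropout_rate = 0) {
  baseline_family <- match.arg(baseline_family)
  link_scale <- match.arg(link_scale)
  check_scalar(t_max, "t_max", positive = TRUE)
  check_scalar(dropout_rate, "dropout_rate", nonneg = TRUE)
  check_scalar(alpha1, "alpha1")
  check_scalar(alpha2, "alpha2")
  check_scalar(alpha3, "alpha3")
  if (!is.numeric(gamma)) stop("`gamma` must be numeric", call. = FALSE)
  bp <- baseline_params
  if (baseline_family == "exponential") {
    check_scalar(bp$rate, "baseline_params$rate", positive = TRUE)
  } else if (baseline_family == "weibull") {
    check_scalar(bp$shape, "baseline_params$shape", positive = TRUE)
    check_scalar(bp$scale, "baseline_params$scale", positive = TRUE)
  } else {
    if (is.null(bp$cuts) || is.null(bp$rates) ||
        length(bp$rates) != length(bp$cuts) + 1L) {
      stop("piecewise baseline needs `cuts` and `rates` with length(rates) == length(cuts) + 1",
           call. = FALSE)
    }
    if (is.unsorted(bp$cuts, strictly = TRUE) || any(bp$cuts <= 0)) {
      stop("piecewise baseline `cuts` must be positive and strictly increasing",
           call. = FALSE)
    }
    if (any(bp$rates <= 0)) {
      stop("piecewise baseline `rates` must be > 0", call. = FALSE)
    }
  }
  structure(
    list(baseline_family = baseline_family, baseline_params = bp,
         gamma = gamma, alpha1 = as.numeric(alpha1),
         alpha2 = as.numeric(alpha2), alpha3 = as.numeric(alpha3),
         link_scale = link_scale, t_max = as.numeric(t_max),
         dropout_rate = as.numeric(dropout_rate)),
    class = "hazard_spec"
  )
}

check_spec <- function(spec) {
  if (!inherits(spec, "hazard_spec")) {
    stop("`spec` must be a `hazard_spec` object", call. = FALSE)
  }
  invisible(TRUE)
}

# h0(t), vectorized
baseline_hazard <- function(spec, t) {
  bp <- spec$baseline_params
  switch(spec$baseline_family,
    exponential = rep_len(bp$rate, length(t)),
    weibull = (bp$shape / bp$scale) * (t / bp$scale)^(bp$shape - 1),
    piecewise = bp$rates[findInterval(t, bp$cuts) + 1L]
  )
}

# H0(t) = int_0^t h0, closed form per family, vectorized
baseline_cumhaz <- function(spec, t) {
  bp <- spec$baseline_params
  switch(spec$baseline_family,
    exponential = bp$rate * t,
    weibull = (t / bp$scale)^bp$shape,
    piecewise = {
      bounds <- c(0, bp$cuts)
      widths <- diff(c(bounds, Inf))
      cum <- c(0, cumsum(bp$rates * widths)[-length(bp$rates)])
      idx <- findInterval(t, bp$cuts) + 1L
      cum[idx] + bp$rates[idx] * (t - bounds[idx])
    }
  )
}

# t such that H0(t) = H, closed form per family
baseline_cumhaz_inv <- function(spec, H) {
  bp <- spec$baseline_params
  switch(spec$baseline_family,
    exponential = H / bp$rate,
    weibull = bp$scale * H^(1 / bp$shape),
    piecewise = {
      bounds <- c(0, bp$cuts)
      widths <- diff(c(bounds, Inf))
      cum <- c(0, cumsum(bp$rates * widths)[-length(bp$rates)])
      idx <- findInterval(H, cum)
      bounds[idx] + (H - cum[idx]) / bp$rates[idx]
    }
  )
}

# gamma^T x with name-aware matching when both sides are named
gamma_term <- function(spec, covariates) {
  g <- spec$gamma
  if (length(g) == 0L) return(0)
  if (length(covariates) != length(g)) {
    stop("covariate vector length must match length(gamma)", call. = FALSE)
  }
  if (!is.null(names(g)) && !is.null(names(covariates))) {
    covariates <- covariates[names(g)]
    if (anyNA(covariates)) {
      stop("covariates are missing values for some names in `gamma`",
           call. = FALSE)
    }
  }
  sum(g * as.numeric(covariates))
}

# exponent gamma^T x + a1 g(mu) + a2 g'(t) + a3 G(t), vectorized over t
linear_predictor <- function(spec, covariates, params, t) {
  gx <- gamma_term(spec, covariates)
  if (spec$link_scale == "raw") {
    lev <- traj_value(params, t)
    slo <- traj_slope(params, t)
    cum <- traj_auc(params, t)
  } else {
    mu <- traj_value(params, t)
    lev <- log10(mu)
    slo <- traj_slope(params, t) / (mu * log(10))
    cum <- traj_log10_auc(params, t)
  }
  gx + spec$alpha1 * lev + spec$alpha2 * slo + spec$alpha3 * cum
}

#' Evaluate the joint hazard at given times
#'
#' @param spec A [hazard_spec()] object.
#' @param covariates Numeric vector of baseline covariate values matching
#'   `spec$gamma` (named matching is used when both are named).
#' @param params A [trajectory_params()] object.
#' @param t Vector of non-negative times.
#' @return Numeric vector of hazards, strictly positive and finite.
#' @export
hazard_at <- function(spec, covariates, params, t) {
  check_spec(spec)
  check_params(params)
  check_times(t)
  lp <- linear_predictor(spec, covariates, params, t)
  if (any(lp > 700)) {
    stop(sprintf(
      "hazard exponent overflow (max exponent %.3g); association parameters are mis-scaled for raw MRD units -- consider link_scale = 'log10' or a smaller t_max",
      max(lp)), call. = FALSE)
  }
  baseline_hazard(spec, t) * exp(lp)
}

# interior breakpoints of the integrand on (0, t): trajectory phase
# boundaries and baseline cut times
hazard_breakpoints <- function(spec, params, t) {
  b <- c(params$te, params$tr)
  if (spec$baseline_family == "piecewise") {
    b <- c(b, spec$baseline_params$cuts)
  }
  sort(unique(b[is.finite(b) & b > 0 & b < t]))
}

#' Cumulative hazard by phase-aware adaptive quadrature
#'
#' Integrates [hazard_at()] on `[0, t]` piecewise between the integrand's
#' phase boundaries (`te`, `tr`, baseline cut times) at relative tolerance
#' 1e-8. `H(0) = 0`; monotone non-decreasing in `t`.
#'
#' @inheritParams hazard_at
#' @param t Single non-negative time.
#' @return The cumulative hazard `H(t)`.
#' @export
cumulative_hazard <- function(spec, covariates, params, t) {
  check_spec(spec)
  check_params(params)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single finite non-negative value", call. = FALSE)
  }
  if (t == 0) return(0)
  knots <- c(0, hazard_breakpoints(spec, params, t), t)
  f <- function(s) hazard_at(spec, covariates, params, s)
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    piece <- tryCatch(
      stats::integrate(f, knots[i], knots[i + 1L], rel.tol = 1e-8,
                       subdivisions = 400L),
      error = function(e) {
        stop(sprintf(
          "cumulative-hazard quadrature failed on [%.6g, %.6g]: %s",
          knots[i], knots[i + 1L], conditionMessage(e)), call. = FALSE)
      })
    total <- total + piece$value
  }
  total
}

# TRUE when the hazard reduces to h0(t) * exp(gamma^T x)
is_null_association <- function(spec) {
  spec$alpha1 == 0 && spec$alpha2 == 0 && spec$alpha3 == 0
}

# TRUE when log h(t) is piecewise linear in t: exponential baseline, log10
# link, level-only association
is_loglinear <- function(spec) {
  spec$baseline_family == "exponential" && spec$link_scale == "log10" &&
    spec$alpha2 == 0 && spec$alpha3 == 0
}

# piecewise log-linear segments of h(t) on [0, t_max]:
# h(t) = A_j * exp(B_j * (t - t0_j)) on segment j
loglinear_segments <- function(spec, covariates, params) {
  gx <- gamma_term(spec, covariates)
  lam <- spec$baseline_params$rate
  l10 <- log(10)
  k <- decay_rate(params)
  tmax <- spec$t_max
  bounds <- sort(unique(c(0, pmin(c(params$te, params$tr), tmax), tmax)))
  bounds <- bounds[bounds <= tmax]
  segs <- vector("list", length(bounds) - 1L)
  for (j in seq_along(segs)) {
    t0 <- bounds[j]; t1 <- bounds[j + 1L]
    tm <- (t0 + t1) / 2
    if (tm < params$te) {
      L0 <- log10(params$beta0) - (k / l10) * t0
      slope <- -k / l10
    } else if (tm <= params$tr) {
      L0 <- log10(params$beta1)
      slope <- 0
    } else {
      L0 <- log10(params$beta1) + (params$beta2 / l10) * (t0 - params$tr)
      slope <- params$beta2 / l10
    }
    segs[[j]] <- list(t0 = t0, t1 = t1,
                      A = lam * exp(gx + spec$alpha1 * L0),
                      B = spec$alpha1 * slope)
  }
  segs
}

seg_increment <- function(seg) {
  w <- seg$t1 - seg$t0
  if (seg$B == 0) seg$A * w else seg$A * expm1(seg$B * w) / seg$B
}

#' Sample an event time by cumulative-hazard inversion
#'
#' Solves `H(T) = -log(u)` for `T` on `[0, t_max]`. When the target exceeds
#' `H(t_max)` the subject is administratively censored at `t_max`. The
#' generic path brackets the root with Brent's method on the quadrature
#' cumulative hazard and polishes it to `|H(T) + log(u)| < 1e-8`; exact
#' analytic paths are used automatically when the hazard admits them (null
#' association for any baseline family; exponential baseline with log10 link
#' and level-only association, where the log-hazard is piecewise linear).
#'
#' Independent dropout censoring is not applied here; [simulate_cohort()]
#' draws it separately and takes the minimum of event, dropout, and `t_max`.
#'
#' @inheritParams hazard_at
#' @param u A single uniform(0, 1) draw.
#' @param method `"auto"` (default), `"quadrature"` to force the generic
#'   path, or `"analytic"` to require an exact path (error if unavailable).
#' @return A list with `time` (positive) and `event` (logical; `FALSE`
#'   means administrative censoring at `t_max`).
#' @export
sample_event_time <- function(spec, covariates, params, u,
                              method = c("auto", "quadrature", "analytic")) {
  check_spec(spec)
  check_params(params)
  method <- match.arg(method)
  if (!is.numeric(u) || length(u) != 1L || is.na(u) || u <= 0 || u >= 1) {
    stop("`u` must be a single value strictly inside (0, 1)", call. = FALSE)
  }
  target <- -log(u)
  tmax <- spec$t_max

  analytic_ok <- is_null_association(spec) || is_loglinear(spec)
  if (method == "analytic" && !analytic_ok) {
    stop("no analytic inversion path exists for this hazard specification",
         call. = FALSE)
  }
  use_analytic <- analytic_ok && method != "quadrature"

  if (use_analytic && is_null_association(spec)) {
    scaled <- target / exp(gamma_term(spec, covariates))
    if (baseline_cumhaz(spec, tmax) < scaled) {
      return(list(time = tmax, event = FALSE))
    }
    return(list(time = baseline_cumhaz_inv(spec, scaled), event = TRUE))
  }

  if (use_analytic) {
    segs <- loglinear_segments(spec, covariates, params)
    acc <- 0
    for (seg in segs) {
      inc <- seg_increment(seg)
      if (acc + inc >= target) {
        rem <- target - acc
        dt <- if (seg$B == 0) rem / seg$A else
          log1p(seg$B * rem / seg$A) / seg$B
        return(list(time = seg$t0 + dt, event = TRUE))
      }
      acc <- acc + inc
    }
    return(list(time = tmax, event = FALSE))
  }

  H <- function(t) cumulative_hazard(spec, covariates, params, t)
  H_end <- H(tmax)
  if (H_end < target) return(list(time = tmax, event = FALSE))
  root <- stats::uniroot(function(t) H(t) - target, c(0, tmax),
                         f.lower = -target, f.upper = H_end - target,
                         tol = 1e-10)$root
  # Newton polish to the contract tolerance in H units
  for (i in 1:8) {
    err <- H(root) - target
    if (abs(err) < 1e-8) break
    h <- hazard_at(spec, covariates, params, root)
    root <- min(max(root - err / h, 0), tmax)
  }
  list(time = root, event = TRUE)
}

# sup of h(t) over [0, t_max]: per smooth piece, the log-hazard is either
# monotone or has a single interior extremum, so endpoints + optimize() give
# the maximum
hazard_sup <- function(spec, covariates, params) {
  tmax <- spec$t_max
  knots <- c(0, hazard_breakpoints(spec, params, tmax), tmax)
  f <- function(t) hazard_at(spec, covariates, params, t)
  best <- max(f(knots))
  for (i in seq_len(length(knots) - 1L)) {
    if (knots[i + 1L] - knots[i] < 1e-12) next
    opt <- stats::optimize(f, c(knots[i], knots[i + 1L]), maximum = TRUE)
    best <- max(best, opt$objective)
  }
  best
}

#' Sample an event time by Lewis--Shedler thinning
#'
#' Independent oracle sampler for the same hazard: proposes points from a
#' homogeneous Poisson process at the majorizing rate
#' `h_sup = sup h(t)` on `[0, t_max]` and accepts each with probability
#' `h(t)/h_sup`; the first accepted point is the event. Under a constant
#' (null-association, exponential-baseline) hazard every proposal is
#' accepted. Uses the current RNG stream: one exponential and one uniform
#' draw per proposal.
#'
#' @inheritParams hazard_at
#' @return A list with `time` and `event` as in [sample_event_time()].
#' @export
sample_event_time_thinning <- function(spec, covariates, params) {
  check_spec(spec)
  check_params(params)
  h_sup <- hazard_sup(spec, covariates, params)
  if (!is.finite(h_sup) || h_sup <= 0) {
    stop("majorizing hazard bound is not finite; use a smaller t_max, link_scale = 'log10', or rescaled association parameters",
         call. = FALSE)
  }
  t <- 0
  for (i in seq_len(1e6)) {
    t <- t + stats::rexp(1, rate = h_sup)
    if (t > spec$t_max) return(list(time = spec$t_max, event = FALSE))
    p <- hazard_at(spec, covariates, params, t) / h_sup
    if (stats::runif(1) <= p) return(list(time = t, event = TRUE))
  }
  stop("thinning sampler did not terminate within 1e6 proposals",
       call. = FALSE)
}
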