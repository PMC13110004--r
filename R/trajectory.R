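#' Ground-truth trajectory parameters for one subject
#'
#' Bundles the parameters of the three-phase piecewise MRD trajectory:
#' exponential decay from the baseline level `beta0` to the plateau level
#' `beta1` over `[0, te)`, a flat plateau on `[te, tr]`, and exponential
#' regrowth at rate `beta2` after the relapse onset time `tr`. `tr = Inf`
#' encodes a subject who never relapses. MRD units (variant-allele fraction,
#' copies/mL, ...) are user-declared dataset metadata; all parameters are in
#' those units and the dataset's common time unit.
#'
#' @param beta0 Positive baseline MRD level at `t = 0`.
#' @param beta1 Positive plateau MRD level reached at end of treatment.
#' @param beta2 Non-negative exponential relapse growth rate (1/time).
#' @param te Positive end-of-treatment time.
#' @param tr Relapse onset time, `>= te`; `Inf` means no relapse.
#' @param sigma Non-negative measurement-error standard deviation, in the
#'   same units as the MRD values.
#'
#' @return An object of class `trajectory_params`.
#' @examples
#' par <- trajectory_params(beta0 = 1, beta1 = 0.01, te = 10)
#' traj_value(par, c(0, 5, 10))
#' @export
trajectory_params <- function(beta0, beta1, beta2 = 0, te, tr = Inf,
                              sigma = 0) {
  check_scalar(beta0, "beta0", positive = TRUE)
  check_scalar(beta1, "beta1", positive = TRUE)
  check_scalar(beta2, "beta2", nonneg = TRUE)
  check_scalar(te, "te", positive = TRUE)
  check_scalar(sigma, "sigma", nonneg = TRUE)
  if (!is.numeric(tr) || length(tr) != 1L || is.na(tr)) {
    stop("`tr` must be a single numeric value (possibly Inf)", call. = FALSE)
  }
  if (tr < te) {
    stop("`tr` must satisfy tr >= te (relapse cannot precede end of treatment)",
         call. = FALSE)
  }
  structure(
    list(beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
         beta2 = as.numeric(beta2), te = as.numeric(te), tr = as.numeric(tr),
         sigma = as.numeric(sigma)),
    class = "trajectory_params"
  )
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite numeric value", name),
         call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(TRUE)
}

check_params <- function(params) {
  if (!inherits(params, "trajectory_params")) {
    stop("`params` must be a `trajectory_params` object", call. = FALSE)
  }
  invisible(TRUE)
}

check_times <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

# Decay rate k = ln(beta0/beta1)/te; 0 when beta0 == beta1 (constant phase,
# the parameter-continuity limit of the ratio form).
decay_rate <- function(params) {
  if (params$beta0 == params$beta1) return(0)
  log(params$beta0 / params$beta1) / params$te
}

#' Evaluate the true MRD trajectory
#'
#' Closed-form evaluation of the piecewise trajectory
#' \deqn{\mu(t) = \beta_0 e^{-kt} \ (t < t_e);\quad \beta_1 \ (t_e \le t \le
#' t_r);\quad \beta_1 e^{\beta_2 (t - t_r)} \ (t > t_r)}
#' with decay rate \eqn{k = \ln(\beta_0/\beta_1)/t_e}. The function is
#' continuous and strictly positive everywhere.
#'
#' @param params A [trajectory_params()] object.
#' @param t Vector of non-negative evaluation times.
#' @return Numeric vector of trajectory values, same length as `t`.
#' @export
traj_value <- function(params, t) {
  check_params(params)
  check_times(t)
  k <- decay_rate(params)
  out <- numeric(length(t))
  decay <- t < params$te
  relapse <- t > params$tr
  plateau <- !decay & !relapse
  out[decay] <- params$beta0 * exp(-k * t[decay])
  out[plateau] <- params$beta1
  out[relapse] <- params$beta1 * exp(params$beta2 * (t[relapse] - params$tr))
  out
}

#' Time derivative of the true MRD trajectory
#'
#' Phase-wise slope: `-k * mu(t)` during decay, `0` on the plateau, and
#' `beta2 * mu(t)` during relapse. The trajectory is not differentiable at
#' the phase boundaries `te` and `tr`; there the right-hand one-sided
#' derivative is returned, so a hazard evaluated at a boundary reflects the
#' upcoming phase.
#'
#' @inheritParams traj_value
#' @return Numeric vector of slopes.
#' @export
traj_slope <- function(params, t) {
  check_params(params)
  check_times(t)
  k <- decay_rate(params)
  out <- numeric(length(t))
  decay <- t < params$te
  relapse <- t >= params$tr & is.finite(params$tr)
  out[decay] <- -k * params$beta0 * exp(-k * t[decay])
  out[relapse] <- params$beta2 * params$beta1 *
    exp(params$beta2 * (t[relapse] - params$tr))
  out
}

#' Running integral of the true MRD trajectory
#'
#' Cumulative disease burden \eqn{\int_0^t \mu(s)\,ds}, assembled from the
#' closed-form contribution of each phase: the decay phase contributes
#' `beta0 * (1 - exp(-k u)) / k` up to `u = min(t, te)`, the plateau
#' `beta1 * (min(t, tr) - te)`, and the relapse phase
#' `beta1 * (exp(beta2 (t - tr)) - 1) / beta2`. Monotone non-decreasing with
#' `traj_auc(params, 0) == 0`.
#'
#' @inheritParams traj_value
#' @return Numeric vector of cumulative burdens.
#' @export
traj_auc <- function(params, t) {
  check_params(params)
  check_times(t)
  k <- decay_rate(params)
  u <- pmin(t, params$te)
  out <- if (k == 0) params$beta0 * u else
    params$beta0 * (1 - exp(-k * u)) / k
  plat <- pmax(pmin(t, params$tr) - params$te, 0)
  out <- out + params$beta1 * plat
  if (is.finite(params$tr)) {
    w <- pmax(t - params$tr, 0)
    rel <- if (params$beta2 == 0) params$beta1 * w else
      params$beta1 * (exp(params$beta2 * w) - 1) / params$beta2
    out <- out + rel
  }
  out
}

# Running integral of log10(mu(s)): log10 mu is piecewise linear in t, so the
# integral is piecewise quadratic. Used by the hazard's log10 link so that
# level, slope and cumulative terms are transformed consistently.
traj_log10_auc <- function(params, t) {
  check_params(params)
  check_times(t)
  k <- decay_rate(params)
  l10 <- log(10)
  u <- pmin(t, params$te)
  out <- log10(params$beta0) * u - (k / l10) * u^2 / 2
  plat <- pmax(pmin(t, params$tr) - params$te, 0)
  out <- out + log10(params$beta1) * plat
  if (is.finite(params$tr)) {
    w <- pmax(t - params$tr, 0)
    out <- out + log10(params$beta1) * w + (params$beta2 / l10) * w^2 / 2
  }
  out
}

#' Sample noisy MRD observations along a visit schedule
#'
#' Adds measurement error to the true trajectory at the requested times. The
#' default additive mode draws `value = mu(t) + eps` with
#' `eps ~ Normal(0, sigma^2)` and floors the reported value at 0 (a negative
#' concentration is not physically meaningful); the raw pre-floor draw is
#' kept in `raw_value`. The multiplicative mode draws
#' `value = mu(t) * exp(eps)`, a log-scale error that is positive by
#' construction. One normal draw is consumed per requested time, in the
#' order of `times` (reproducibility contract).
#'
#' @param params A [trajectory_params()] object; `params$sigma` is the error
#'   standard deviation.
#' @param times Sorted (non-decreasing) vector of non-negative visit times.
#' @param noise_mode `"additive"` (default) or `"multiplicative"`.
#' @return A data.frame with columns `time`, `value`, `raw_value`.
#' @export
traj_observe <- function(params, times,
                         noise_mode = c("additive", "multiplicative")) {
  check_params(params)
  check_times(times)
  noise_mode <- match.arg(noise_mode)
  if (is.unsorted(times)) {
    stop("`times` must be sorted in ascending order", call. = FALSE)
  }
  mu <- traj_value(params, times)
  eps <- stats::rnorm(length(times), mean = 0, sd = params$sigma)
  if (noise_mode == "additive") {
    raw <- mu + eps
    value <- pmax(raw, 0)
  } else {
    raw <- mu * exp(eps)
    value <- raw
  }
  data.frame(time = as.numeric(times), value = value, raw_value = raw)
}
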