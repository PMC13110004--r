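# shared fixture builders (everything generated in code)

null_hazard <- function(rate = 0.1, t_max = 100, ...) {
  hazard_spec(baseline_params = list(rate = rate), t_max = t_max, ...)
}

simple_params <- function(...) {
  args <- utils::modifyList(
    list(beta0 = 1, beta1 = 0.01, te = 10, tr = Inf, beta2 = 0, sigma = 0),
    list(...))
  do.call(trajectory_params, args)
}

# minimal one-subgroup raw-link config; override any top-level block
mini_config <- function(n = 5, ...) {
  cfg <- list(
    subgroups = list(list(
      name = "A", n = n, beta0_meanlog = log(0.5), beta0_sdlog = 0.3,
      beta1_meanlog = log(0.005), beta1_sdlog = 0.4, te = 6, sigma = 0.01)),
    hazard = list(baseline_family = "exponential",
                  baseline_params = list(rate = 0.05),
                  alpha1 = 0, t_max = 24, link_scale = "raw"),
    schedule = list(mode = "regular", interval = 3, horizon = 24)
  )
  utils::modifyList(cfg, list(...))
}

# random but structurally valid trajectory parameter sets, for property tests
random_params <- function(n, seed = 42, relapse_frac = 0.5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    te <- runif(1, 2, 12)
    beta0 <- rlnorm(1, -1, 0.8)
    beta1 <- beta0 * exp(-runif(1, 0.5, 6))
    has_relapse <- runif(1) < relapse_frac
    trajectory_params(
      beta0 = beta0, beta1 = beta1, beta2 = runif(1, 0.05, 0.5),
      te = te, tr = if (has_relapse) te + runif(1, 0.1, 15) else Inf,
      sigma = runif(1, 0, 0.05))
  })
}
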