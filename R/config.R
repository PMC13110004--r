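dataset_schema_version <- function() "1.0"

# classed errors so callers can distinguish failure modes
abort_class <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

is_hex_color <- function(x) {
  grepl("^#[0-9A-Fa-f]{6}$", x)
}

#' Validate and resolve a simulation configuration
#'
#' Accepts either an already-resolved `mrd_sim_config` or a raw list (as
#' parsed from YAML/JSON) and validates every component, collecting all
#' errors into a single aggregated report. Defaults are applied for omitted
#' optional fields: `time_unit = "months"`, `lod = 1e-4`,
#' `censor_at_lod = FALSE`, `noise_mode = "additive"`, no covariates, no
#' colormaps.
#'
#' @param x Raw config list or `mrd_sim_config`.
#' @return An `mrd_sim_config` object.
#' @export
as_sim_config <- function(x) {
  if (inherits(x, "mrd_sim_config")) return(x)
  if (!is.list(x)) {
    abort_class("config must be a list (parsed YAML or JSON)",
                "mrd_config_error")
  }
  errs <- character(0)
  note <- function(e) errs <<- c(errs, conditionMessage(e))

  known <- c("time_unit", "lod", "censor_at_lod", "noise_mode", "subgroups",
             "hazard", "schedule", "covariates", "colormaps")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown config key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }

  time_unit <- x$time_unit %||% "months"
  lod <- x$lod %||% 1e-4
  censor_at_lod <- isTRUE(x$censor_at_lod)
  noise_mode <- x$noise_mode %||% "additive"
  if (!noise_mode %in% c("additive", "multiplicative")) {
    errs <- c(errs, sprintf("noise_mode must be 'additive' or 'multiplicative', got '%s'",
                            noise_mode))
  }
  if (!is.numeric(lod) || length(lod) != 1L || lod <= 0) {
    errs <- c(errs, "lod must be a single positive number")
  }

  subgroups <- list()
  if (is.null(x$subgroups) || !length(x$subgroups)) {
    errs <- c(errs, "config must declare at least one subgroup")
  } else {
    for (i in seq_along(x$subgroups)) {
      sg <- x$subgroups[[i]]
      res <- tryCatch(
        if (inherits(sg, "subgroup_spec")) sg else do.call(subgroup_spec, sg),
        error = function(e) { note(e); NULL })
      if (!is.null(res)) subgroups[[length(subgroups) + 1L]] <- res
    }
  }

  covariates <- list()
  for (cvr in x$covariates %||% list()) {
    if (inherits(cvr, "covariate_spec")) {
      covariates[[length(covariates) + 1L]] <- cvr
      next
    }
    # parsed YAML/JSON may hand vectors over as lists
    for (f in c("prob", "probs", "mean", "sd")) {
      if (!is.null(cvr[[f]])) cvr[[f]] <- as.numeric(unlist(cvr[[f]]))
    }
    if (!is.null(cvr$levels)) cvr$levels <- as.character(unlist(cvr$levels))
    if (!is.null(cvr$time_variant) && !is.null(cvr$time_variant$window_starts)) {
      cvr$time_variant$window_starts <-
        as.numeric(unlist(cvr$time_variant$window_starts))
    }
    res <- tryCatch(do.call(covariate_spec, cvr),
                    error = function(e) { note(e); NULL })
    if (!is.null(res)) covariates[[length(covariates) + 1L]] <- res
  }

  hazard <- NULL
  if (is.null(x$hazard)) {
    errs <- c(errs, "config must declare a hazard block")
  } else if (inherits(x$hazard, "hazard_spec")) {
    hazard <- x$hazard
  } else {
    hz <- x$hazard
    if (!is.null(hz$gamma)) hz$gamma <- unlist(hz$gamma)
    if (!is.null(hz$baseline_params)) {
      hz$baseline_params <- lapply(hz$baseline_params, function(p)
        as.numeric(unlist(p)))
    }
    hazard <- tryCatch(do.call(hazard_spec, hz),
                       error = function(e) { note(e); NULL })
  }
  if (!is.null(hazard) && length(hazard$gamma)) {
    cov_names <- vapply(covariates, `[[`, character(1), "name")
    numeric_cov <- vapply(covariates, function(s)
      s$kind %in% c("binary", "continuous") && is.null(s$time_variant),
      logical(1))
    bad <- setdiff(names(hazard$gamma), cov_names[numeric_cov])
    if (is.null(names(hazard$gamma))) {
      errs <- c(errs, "hazard gamma must be named after baseline covariates")
    } else if (length(bad)) {
      errs <- c(errs, sprintf(
        "hazard gamma refers to '%s' which is not a declared numeric baseline covariate",
        paste(bad, collapse = "', '")))
    }
  }

  schedule <- NULL
  if (is.null(x$schedule)) {
    errs <- c(errs, "config must declare a schedule block")
  } else if (inherits(x$schedule, "schedule_spec")) {
    schedule <- x$schedule
  } else {
    sc <- x$schedule
    if (!is.null(sc$visit_times)) {
      sc$visit_times <- as.numeric(unlist(sc$visit_times))
    }
    schedule <- tryCatch(do.call(schedule_spec, sc),
                         error = function(e) { note(e); NULL })
  }

  colormaps <- x$colormaps
  if (!is.null(colormaps)) {
    for (nm in names(colormaps)) {
      cols <- unlist(colormaps[[nm]])
      if (!all(is_hex_color(cols))) {
        errs <- c(errs, sprintf(
          "colormap '%s' contains invalid hex codes: %s", nm,
          paste(cols[!is_hex_color(cols)], collapse = ", ")))
      }
      colormaps[[nm]] <- cols
    }
  }

  if (length(errs)) {
    abort_class(paste0("invalid simulation config:\n",
                       paste0("  - ", errs, collapse = "\n")),
                "mrd_config_error")
  }
  structure(
    list(time_unit = time_unit, lod = as.numeric(lod),
         censor_at_lod = censor_at_lod, noise_mode = noise_mode,
         subgroups = subgroups, hazard = hazard, schedule = schedule,
         covariates = covariates, colormaps = colormaps),
    class = "mrd_sim_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

# plain-list (YAML/JSON-shaped) echo of a resolved config; feeding the
# result back through as_sim_config() reproduces the same configuration
config_to_list <- function(config) {
  config <- as_sim_config(config)
  hz <- config$hazard
  list(
    time_unit = config$time_unit,
    lod = config$lod,
    censor_at_lod = config$censor_at_lod,
    noise_mode = config$noise_mode,
    subgroups = lapply(config$subgroups, function(s)
      drop_null(unclass(s))),
    hazard = drop_null(list(
      baseline_family = hz$baseline_family,
      baseline_params = hz$baseline_params,
      gamma = if (length(hz$gamma)) as.list(hz$gamma) else NULL,
      alpha1 = hz$alpha1, alpha2 = hz$alpha2, alpha3 = hz$alpha3,
      link_scale = hz$link_scale, t_max = hz$t_max,
      dropout_rate = hz$dropout_rate)),
    schedule = drop_null(unclass(config$schedule)),
    covariates = if (length(config$covariates))
      lapply(config$covariates, function(s) drop_null(unclass(s))) else NULL,
    colormaps = config$colormaps
  )
}

#' Load a simulation configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration and
#' validates it with [as_sim_config()], reporting all validation failures
#' at once. Unknown top-level keys produce a warning and are ignored.
#'
#' @param path Path to the configuration file.
#' @return An `mrd_sim_config` object.
#' @export
load_sim_config <- function(path) {
  if (!file.exists(path)) {
    abort_class(sprintf("config file not found: %s", path),
                "mrd_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    abort_class(sprintf("unsupported config extension '.%s' (use .yaml, .yml, or .json)",
                        ext), "mrd_config_error")
  }
  as_sim_config(raw)
}

#' Illustrative four-subgroup example configuration
#'
#' A ready-to-run configuration with CR/PR/SD/PD response subgroups, a
#' ctDNA-like MRD scale (variant-allele fractions, LoD 1e-4), a monthly
#' time unit, an exponential baseline hazard with a log10 level association,
#' and a quarterly assessment schedule. The subgroup distributions are
#' illustrative defaults for exploring the simulator, not estimates from any
#' study.
#'
#' @param n_per_group Optional single size overriding every subgroup's `n`.
#' @return A raw config list, suitable for [as_sim_config()] or
#'   [simulate_cohort()].
#' @export
example_config <- function(n_per_group = NULL) {
  cfg <- list(
    time_unit = "months",
    lod = 1e-4,
    noise_mode = "additive",
    subgroups = list(
      list(name = "CR", n = 40L,
           beta0_meanlog = log(0.05), beta0_sdlog = 0.6,
           beta1_meanlog = log(1e-5), beta1_sdlog = 0.8,
           te = 6, relapse_prob = 0.15, relapse_mean = 18, relapse_sd = 4,
           beta2 = 0.35, sigma = 0.002),
      list(name = "PR", n = 30L,
           beta0_meanlog = log(0.08), beta0_sdlog = 0.6,
           beta1_meanlog = log(5e-4), beta1_sdlog = 0.8,
           te = 6, relapse_prob = 0.4, relapse_mean = 14, relapse_sd = 3,
           beta2 = 0.3, sigma = 0.002),
      list(name = "SD", n = 20L,
           beta0_meanlog = log(0.10), beta0_sdlog = 0.5,
           beta1_meanlog = log(0.02), beta1_sdlog = 0.5,
           te = 6, relapse_prob = 0.7, relapse_mean = 10, relapse_sd = 2,
           beta2 = 0.25, sigma = 0.005),
      list(name = "PD", n = 10L,
           beta0_meanlog = log(0.15), beta0_sdlog = 0.5,
           beta1_meanlog = log(0.08), beta1_sdlog = 0.4,
           te = 4, relapse_prob = 0.95, relapse_mean = 6, relapse_sd = 1,
           beta2 = 0.4, sigma = 0.005)
    ),
    hazard = list(
      baseline_family = "exponential",
      baseline_params = list(rate = 0.25),
      gamma = list(tp53_mut = 0.4),
      alpha1 = 0.6, alpha2 = 0, alpha3 = 0,
      link_scale = "log10",
      t_max = 36,
      dropout_rate = 0.005
    ),
    schedule = list(mode = "regular", interval = 3, horizon = 36,
                    jitter_sd = 0.2, miss_prob = 0.05),
    covariates = list(
      list(name = "tp53_mut", kind = "binary", prob = 0.35),
      list(name = "age", kind = "continuous", mean = 62, sd = 9),
      list(name = "treatment", kind = "categorical",
           levels = c("on", "off"), probs = c(0.7, 0.3),
           time_variant = list(window_starts = c(0, 6, 12, 18, 24, 30)))
    ),
    colormaps = list(tp53_mut = c("#1B9E77", "#D95F02"))
  )
  if (!is.null(n_per_group)) {
    cfg$subgroups <- lapply(cfg$subgroups, function(s) {
      s$n <- as.integer(n_per_group); s
    })
  }
  cfg
}
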