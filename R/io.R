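#' Validate an `mrd_dataset` against its structural invariants
#'
#' Checks referential integrity (every observation and track references an
#' existing subject, every subject appears in every declared endpoint) and
#' that any colormap entries are valid 6-digit hex codes. All violations are
#' reported together.
#'
#' @param dataset An `mrd_dataset`.
#' @return Invisibly `TRUE`; signals an `mrd_validation_error` otherwise.
#' @export
validate_dataset <- function(dataset) {
  if (!inherits(dataset, "mrd_dataset")) {
    abort_class("`dataset` must be an `mrd_dataset`", "mrd_validation_error")
  }
  errs <- character(0)
  ids <- dataset$subjects$id
  if (anyDuplicated(ids)) errs <- c(errs, "subject ids are not unique")
  bad_obs <- setdiff(unique(dataset$observations$subject_id), ids)
  if (length(bad_obs)) {
    errs <- c(errs, sprintf("observations reference unknown subject(s): %s",
                            paste(bad_obs, collapse = ", ")))
  }
  if (nrow(dataset$tracks)) {
    bad_trk <- setdiff(unique(dataset$tracks$subject_id), ids)
    if (length(bad_trk)) {
      errs <- c(errs, sprintf("tracks reference unknown subject(s): %s",
                              paste(bad_trk, collapse = ", ")))
    }
  }
  for (nm in names(dataset$endpoints)) {
    ep <- dataset$endpoints[[nm]]
    missing_subj <- setdiff(ids, ep$subject_id)
    if (length(missing_subj)) {
      errs <- c(errs, sprintf("endpoint '%s' is missing subject(s): %s", nm,
                              paste(missing_subj, collapse = ", ")))
    }
  }
  cmaps <- dataset$metadata$colormaps
  if (!is.null(cmaps)) {
    for (nm in names(cmaps)) {
      cols <- unlist(cmaps[[nm]])
      if (!all(is_hex_color(cols))) {
        errs <- c(errs, sprintf("colormap '%s' has invalid hex code(s): %s",
                                nm, paste(cols[!is_hex_color(cols)],
                                          collapse = ", ")))
      }
    }
  }
  if (length(errs)) {
    abort_class(paste0("invalid dataset:\n",
                       paste0("  - ", errs, collapse = "\n")),
                "mrd_validation_error")
  }
  invisible(TRUE)
}

subject_meta_cols <- c("id", "subgroup", "event_time", "status",
                       "censor_reason")

# build the JSON-shaped list with a fixed key order
dataset_to_list <- function(dataset, blinded = FALSE) {
  cov_cols <- setdiff(names(dataset$subjects), subject_meta_cols)
  subjects <- lapply(seq_len(nrow(dataset$subjects)), function(i) {
    row <- dataset$subjects[i, , drop = FALSE]
    covs <- if (length(cov_cols)) as.list(row[1, cov_cols, drop = FALSE])
      else NULL
    trk <- dataset$tracks[dataset$tracks$subject_id == row$id, , drop = FALSE]
    tracks <- if (nrow(trk)) {
      lapply(split(trk, trk$name), function(tt) {
        tt <- tt[order(tt$start_time), , drop = FALSE]
        list(name = tt$name[1],
             windows = lapply(seq_len(nrow(tt)), function(j)
               list(start = tt$start_time[j], value = tt$value[j])))
      })
    } else NULL
    drop_null(list(
      id = row$id, subgroup = row$subgroup, covariates = covs,
      tracks = unname(tracks), event_time = row$event_time,
      status = row$status, censor_reason = row$censor_reason))
  })
  gt_list <- NULL
  if (!blinded && !is.null(dataset$ground_truth)) {
    truth <- dataset$ground_truth$subjects
    truth$tr[is.infinite(truth$tr)] <- NA_real_
    hz <- dataset$ground_truth$hazard
    gt_list <- list(
      subjects = truth,
      hazard = drop_null(list(
        baseline_family = hz$baseline_family,
        baseline_params = lapply(hz$baseline_params, function(p)
          if (length(p) > 1L) I(p) else p),
        gamma = if (length(hz$gamma)) as.list(hz$gamma) else NULL,
        alpha1 = hz$alpha1, alpha2 = hz$alpha2, alpha3 = hz$alpha3,
        link_scale = hz$link_scale, t_max = hz$t_max,
        dropout_rate = hz$dropout_rate)),
      subgroups = lapply(dataset$ground_truth$subgroups, function(s)
        drop_null(unclass(s)))
    )
  }
  out <- list(
    metadata = drop_null(dataset$metadata),
    subjects = subjects,
    observations = dataset$observations,
    covariates = lapply(dataset$covariates, function(s) {
      s <- drop_null(unclass(s))
      for (f in c("levels", "probs")) if (!is.null(s[[f]])) s[[f]] <- I(s[[f]])
      if (!is.null(s$time_variant)) {
        s$time_variant$window_starts <- I(s$time_variant$window_starts)
      }
      s
    }),
    endpoints = dataset$endpoints
  )
  if (!is.null(gt_list)) out$ground_truth <- gt_list
  out
}

#' Write a dataset as a single self-describing JSON document
#'
#' Serializes the dataset with fixed key order (`metadata`, `subjects`,
#' `observations`, `covariates`, `endpoints`, `ground_truth`), UTF-8
#' encoding, and full-precision numbers, so that a fixed dataset always
#' produces byte-identical files. An infinite relapse time (`tr`, "never
#' relapses") is serialized as JSON `null`; missing observation values are
#' `null` as well.
#'
#' @param dataset An `mrd_dataset` (validated before writing).
#' @param path Output file path.
#' @param blinded Omit the `ground_truth` key (for blinded method
#'   benchmarking)?
#' @return Invisibly, `path`.
#' @export
write_dataset_json <- function(dataset, path, blinded = FALSE) {
  validate_dataset(dataset)
  x <- dataset_to_list(dataset, blinded = blinded)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                           null = "null", dataframe = "rows", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

as_num <- function(x) {
  if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x[[1]])
}
as_chr <- function(x) {
  if (is.null(x) || length(x) == 0L) NA_character_ else as.character(x[[1]])
}
as_lgl <- function(x) {
  if (is.null(x) || length(x) == 0L) NA else as.logical(x[[1]])
}

#' Read a dataset JSON document
#'
#' Parses and validates a dataset written by [write_dataset_json()].
#' Distinct failure modes signal distinct condition classes: malformed JSON
#' (`mrd_json_error`), structural/schema problems (`mrd_schema_error`), and
#' referential-integrity violations such as an observation pointing at an
#' unknown subject (`mrd_integrity_error`). Unknown keys and a
#' schema-version mismatch produce warnings and a best-effort parse
#' (forward compatibility).
#'
#' @param path Path to the JSON file.
#' @return An `mrd_dataset`.
#' @export
read_dataset_json <- function(path) {
  if (!file.exists(path)) {
    abort_class(sprintf("dataset file not found: %s", path),
                "mrd_json_error")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort_class(
      sprintf("malformed JSON in %s: %s", path, conditionMessage(e)),
      "mrd_json_error"))
  required <- c("metadata", "subjects", "observations", "covariates",
                "endpoints")
  missing_keys <- setdiff(required, names(raw))
  if (length(missing_keys)) {
    abort_class(sprintf("dataset JSON is missing required key(s): %s",
                        paste(missing_keys, collapse = ", ")),
                "mrd_schema_error")
  }
  unknown <- setdiff(names(raw), c(required, "ground_truth"))
  if (length(unknown)) {
    warning(sprintf("ignoring unknown dataset key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ver <- raw$metadata$schema_version
  if (is.null(ver) || !identical(as.character(ver),
                                 dataset_schema_version())) {
    warning(sprintf(
      "dataset schema version '%s' differs from supported '%s'; attempting best-effort parse",
      as_chr(ver), dataset_schema_version()), call. = FALSE)
  }

  subj_rows <- lapply(raw$subjects, function(s) {
    base <- data.frame(id = as_chr(s$id), subgroup = as_chr(s$subgroup),
                       event_time = as_num(s$event_time),
                       status = as.integer(s$status),
                       censor_reason = as_chr(s$censor_reason),
                       stringsAsFactors = FALSE)
    if (!is.null(s$covariates)) {
      for (nm in names(s$covariates)) base[[nm]] <- s$covariates[[nm]]
    }
    base
  })
  # align covariate columns across subjects before binding
  all_cols <- unique(unlist(lapply(subj_rows, names)))
  subj_rows <- lapply(subj_rows, function(r) {
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- NA
    r[all_cols]
  })
  subjects <- do.call(rbind, subj_rows)
  meta_first <- c("id", "subgroup",
                  setdiff(all_cols, subject_meta_cols),
                  "event_time", "status", "censor_reason")
  subjects <- subjects[, meta_first, drop = FALSE]
  rownames(subjects) <- NULL

  tracks <- do.call(rbind, lapply(raw$subjects, function(s) {
    if (is.null(s$tracks)) return(NULL)
    do.call(rbind, lapply(s$tracks, function(tk)
      data.frame(subject_id = as_chr(s$id), name = as_chr(tk$name),
                 start_time = vapply(tk$windows, function(w)
                   as_num(w$start), numeric(1)),
                 value = vapply(tk$windows, function(w)
                   as_chr(w$value), character(1)),
                 stringsAsFactors = FALSE)))
  }))
  if (is.null(tracks)) {
    tracks <- data.frame(subject_id = character(0), name = character(0),
                         start_time = numeric(0), value = character(0),
                         stringsAsFactors = FALSE)
  }
  rownames(tracks) <- NULL

  observations <- do.call(rbind, lapply(raw$observations, function(o)
    data.frame(subject_id = as_chr(o$subject_id), time = as_num(o$time),
               value = as_num(o$value), raw_value = as_num(o$raw_value),
               missing = as_lgl(o$missing), below_lod = as_lgl(o$below_lod),
               stringsAsFactors = FALSE)))
  observations <- observations[, c("subject_id", "time", "value",
                                   "raw_value", "missing", "below_lod")]
  rownames(observations) <- NULL

  covariates <- lapply(raw$covariates, function(s) {
    tv <- if (!is.null(s[["time_variant"]])) {
      list(window_starts =
             as.numeric(unlist(s[["time_variant"]][["window_starts"]])))
    } else NULL
    covariate_spec(name = s[["name"]], kind = s[["kind"]],
                   prob = if (!is.null(s[["prob"]]))
                     as.numeric(unlist(s[["prob"]])),
                   levels = if (!is.null(s[["levels"]]))
                     unlist(s[["levels"]]),
                   probs = if (!is.null(s[["probs"]]))
                     as.numeric(unlist(s[["probs"]])),
                   mean = s[["mean"]], sd = s[["sd"]], time_variant = tv)
  })

  endpoints <- lapply(raw$endpoints, function(ep)
    do.call(rbind, lapply(ep, function(r)
      data.frame(subject_id = as_chr(r$subject_id), time = as_num(r$time),
                 status = as.integer(r$status), stringsAsFactors = FALSE))))
  endpoints <- lapply(endpoints, function(d) { rownames(d) <- NULL; d })

  ground_truth <- NULL
  if (!is.null(raw$ground_truth)) {
    gt <- raw$ground_truth
    truth <- do.call(rbind, lapply(gt$subjects, function(r)
      data.frame(subject_id = as_chr(r$subject_id),
                 beta0 = as_num(r$beta0), beta1 = as_num(r$beta1),
                 beta2 = as_num(r$beta2), te = as_num(r$te),
                 tr = if (is.null(r$tr)) Inf else as.numeric(r$tr),
                 sigma = as_num(r$sigma), stringsAsFactors = FALSE)))
    rownames(truth) <- NULL
    hz <- gt$hazard
    hazard <- hazard_spec(
      baseline_family = hz$baseline_family,
      baseline_params = lapply(hz$baseline_params, function(p)
        as.numeric(unlist(p))),
      gamma = if (!is.null(hz$gamma)) unlist(hz$gamma) else numeric(0),
      alpha1 = hz$alpha1, alpha2 = hz$alpha2, alpha3 = hz$alpha3,
      link_scale = hz$link_scale, t_max = hz$t_max,
      dropout_rate = hz$dropout_rate)
    subgroups <- lapply(gt$subgroups, function(s) {
      s$relapse_mean <- as_num(s$relapse_mean)
      s$relapse_sd <- as_num(s$relapse_sd)
      do.call(subgroup_spec, s)
    })
    ground_truth <- list(subjects = truth, hazard = hazard,
                         subgroups = subgroups)
  }

  metadata <- raw$metadata
  metadata$seed <- if (!is.null(metadata$seed))
    as.integer(metadata$seed) else NULL
  if (!is.null(metadata$colormaps)) {
    metadata$colormaps <- lapply(metadata$colormaps, unlist)
  }

  ds <- structure(
    list(metadata = metadata, subjects = subjects,
         observations = observations, tracks = tracks,
         covariates = covariates, endpoints = endpoints,
         ground_truth = ground_truth),
    class = "mrd_dataset")
  tryCatch(validate_dataset(ds), error = function(e)
    abort_class(conditionMessage(e), "mrd_integrity_error"))
  ds
}

fmt_csv_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v) || is.infinite(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Export tidy CSV tables for a dataset
#'
#' Writes three RFC-4180 CSV files into `dir`: `subjects.csv` (one row per
#' subject with baseline covariates and survival endpoint), the long-format
#' `observations.csv`, and `ground_truth.csv` (one row per subject of true
#' trajectory parameters; an infinite relapse time is an empty cell).
#' Numbers are printed with 17 significant digits so re-importing reproduces
#' them exactly.
#'
#' @param dataset An `mrd_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
export_dataset_csv <- function(dataset, dir) {
  validate_dataset(dataset)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", dir),
                  call. = FALSE)
  }
  subj <- dataset$subjects
  subj$event_time <- fmt_csv_num(subj$event_time)
  num_cols <- vapply(subj, is.numeric, logical(1))
  for (nm in names(subj)[num_cols & names(subj) != "status"]) {
    subj[[nm]] <- fmt_csv_num(as.numeric(subj[[nm]]))
  }
  obs <- dataset$observations
  for (nm in c("time", "value", "raw_value")) {
    obs[[nm]] <- fmt_csv_num(obs[[nm]])
  }
  paths <- file.path(dir, c("subjects.csv", "observations.csv"))
  utils::write.csv(subj, paths[1], row.names = FALSE)
  utils::write.csv(obs, paths[2], row.names = FALSE)
  if (!is.null(dataset$ground_truth)) {
    truth <- dataset$ground_truth$subjects
    for (nm in c("beta0", "beta1", "beta2", "te", "tr", "sigma")) {
      truth[[nm]] <- fmt_csv_num(truth[[nm]])
    }
    gt_path <- file.path(dir, "ground_truth.csv")
    utils::write.csv(truth, gt_path, row.names = FALSE)
    paths <- c(paths, gt_path)
  }
  invisible(paths)
}
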