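available_color_vars <- function(dataset) {
  c("subgroup", setdiff(names(dataset$subjects), subject_meta_cols))
}

check_color_by <- function(dataset, color_by) {
  avail <- available_color_vars(dataset)
  if (!color_by %in% avail) {
    stop(sprintf("unknown covariate '%s'; available: %s", color_by,
                 paste(avail, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Spaghetti plot of simulated MRD trajectories
#'
#' One line per subject over the non-missing observations, on a log10 MRD
#' axis, colored by subgroup or by any baseline covariate. A custom hex
#' colormap stored in the dataset metadata for the chosen variable is
#' honored.
#'
#' @param dataset An `mrd_dataset`.
#' @param color_by Name of the coloring variable (default `"subgroup"`).
#' @param show_lod Draw the simulated LoD as a dashed horizontal line?
#' @return A ggplot object.
#' @export
plot_trajectories <- function(dataset, color_by = "subgroup",
                              show_lod = TRUE) {
  check_color_by(dataset, color_by)
  obs <- dataset$observations[!dataset$observations$missing, , drop = FALSE]
  subj <- dataset$subjects
  obs$colorvar <- factor(
    if (color_by == "subgroup") subj$subgroup[match(obs$subject_id, subj$id)]
    else subj[[color_by]][match(obs$subject_id, subj$id)])
  obs$plot_value <- pmax(obs$value, 1e-12)
  p <- ggplot2::ggplot(obs, ggplot2::aes(
    x = .data$time, y = .data$plot_value, group = .data$subject_id,
    color = .data$colorvar)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("Time (%s)", dataset$metadata$time_unit),
                  y = "MRD level", color = color_by) +
    ggplot2::theme_minimal()
  cmap <- dataset$metadata$colormaps[[color_by]]
  if (!is.null(cmap)) p <- p + ggplot2::scale_color_manual(values = cmap)
  lod <- dataset$metadata$config$lod
  if (show_lod && !is.null(lod)) {
    p <- p + ggplot2::geom_hline(yintercept = lod, linetype = "dashed",
                                 color = "grey40")
  }
  p
}

#' Kaplan--Meier overlay by subgroup or binary covariate
#'
#' @param dataset An `mrd_dataset`.
#' @param by Grouping variable: `"subgroup"` (default) or the name of a
#'   baseline covariate.
#' @param endpoint Endpoint name (default the first declared endpoint).
#' @return A ggplot object.
#' @export
plot_km <- function(dataset, by = "subgroup", endpoint = NULL) {
  check_color_by(dataset, by)
  if (is.null(endpoint)) endpoint <- names(dataset$endpoints)[1]
  ep <- dataset$endpoints[[endpoint]]
  if (is.null(ep)) {
    stop(sprintf("unknown endpoint '%s'; available: %s", endpoint,
                 paste(names(dataset$endpoints), collapse = ", ")),
         call. = FALSE)
  }
  subj <- dataset$subjects
  grp <- if (by == "subgroup") subj$subgroup[match(ep$subject_id, subj$id)]
    else subj[[by]][match(ep$subject_id, subj$id)]
  steps <- do.call(rbind, lapply(split(seq_len(nrow(ep)), grp), function(i) {
    km <- km_estimate(data.frame(time = ep$time[i], status = ep$status[i]))
    data.frame(group = grp[i][1],
               time = c(0, km$time),
               survival = c(1, km$survival), stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(steps, ggplot2::aes(
    x = .data$time, y = .data$survival, color = factor(.data$group))) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = sprintf("Time (%s)", dataset$metadata$time_unit),
                  y = sprintf("S(t), %s", endpoint), color = by) +
    ggplot2::theme_minimal()
}
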