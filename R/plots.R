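# ggplot2 views of QC and benchmark results.

#' Plot the target depth distribution
#'
#' Cumulative fraction of target bases covered at or above each depth —
#' the capture panel's depth-of-coverage profile.
#'
#' @param profile A coverage profile from [compute_depth()].
#' @param thresholds Depths to mark.
#' @return A ggplot object.
#' @export
plot_depth_distribution <- function(profile, thresholds = c(30, 60, 100)) {
  d <- unlist(profile$depth)
  grid <- seq(0, max(d), length.out = min(512, max(d) + 1))
  df <- tibble(depth = grid,
               pct = vapply(grid, function(t) 100 * mean(d >= t), numeric(1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$pct)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "depth of coverage", y = "% target bases at or above",
                  title = "Target depth distribution") +
    ggplot2::theme_minimal()
}

#' Plot per-base depth across selected regions
#'
#' @param profile A coverage profile.
#' @param region_names Names of regions to show (default: first six).
#' @return A ggplot object.
#' @export
plot_region_coverage <- function(profile, region_names = NULL) {
  pr <- profile
  if (!is.null(region_names)) pr <- pr[pr$name %in% region_names, ]
  if (is.null(region_names)) pr <- utils::head(pr, 6)
  df <- purrr::map_dfr(seq_len(nrow(pr)), function(i) {
    label <- if (!is.null(pr$name) && !is.na(pr$name[i])) pr$name[i] else
      sprintf("%s:%d-%d", pr$chrom[i], pr$start[i], pr$end[i])
    tibble(region = label,
           pos = seq.int(pr$start[i] + 1L, pr$end[i]),
           depth = pr$depth[[i]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.7) +
    ggplot2::facet_wrap(~region, scales = "free_x") +
    ggplot2::labs(x = "reference position", y = "depth") +
    ggplot2::theme_minimal()
}

#' Plot the read length distribution
#'
#' @param reads A reads tibble.
#' @param binwidth Histogram bin width (bases).
#' @return A ggplot object.
#' @export
plot_read_lengths <- function(reads, binwidth = 100) {
  df <- tibble(length = nchar(reads$seq))
  n50_val <- n50(df$length)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = n50_val, linetype = "dashed") +
    ggplot2::labs(x = "read length (bp)", y = "reads",
                  title = sprintf("Read lengths (N50 = %d bp)", n50_val)) +
    ggplot2::theme_minimal()
}

#' Plot benchmark precision/recall/F1 by stratum
#'
#' @param object A `capcall_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.capcall_benchmark <- function(object, ...) {
  df <- object$result |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Benchmark by stratum") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
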