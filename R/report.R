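#' Write result tables and figures
#'
#' Emits the standard report for a set of pipeline results: CSV tables for
#' every provided component and matching figures (bar chart with SEM error
#' bars for colocalization, ECDF of per-spine signal areas, standardized
#' scatter plot annotated with the Spearman coefficient). Every figure's
#' underlying numbers are also written as CSV, and generation is
#' deterministic given the inputs. With no results at all, an explicit
#' `no_data.txt` marker is written instead.
#'
#' @param out_dir Output directory (created if missing).
#' @param coloc_summary Optional tibble from [summarize_coloc()].
#' @param quants Optional per-spine quantification tibble (areas for the
#'   ECDF figure).
#' @param correlations Optional tibble of [correlation_pipeline()]
#'   `result` rows.
#' @param scatter Optional tibble of standardized per-spine amounts.
#' @return Invisibly, the character vector of written file paths.
#' @export
report_results <- function(out_dir, coloc_summary = NULL, quants = NULL,
                           correlations = NULL, scatter = NULL) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(coloc_summary) && nrow(coloc_summary) > 0) {
    emit(coloc_summary, "colocalization_summary.csv")
    p <- ggplot2::ggplot(coloc_summary,
                         ggplot2::aes(x = .data$compartment, y = .data$mean_r)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_r - .data$sem,
                                          ymax = .data$mean_r + .data$sem),
                             width = 0.2, na.rm = TRUE) +
      ggplot2::labs(y = "mean non-zero Pearson r", x = NULL) +
      ggplot2::theme_classic()
    f <- file.path(out_dir, "colocalization.png")
    ggplot2::ggsave(f, p, width = 4, height = 3, dpi = 150)
    written <- c(written, f)
  }
  if (!is.null(quants) && nrow(quants) > 0) {
    emit(quants, "spine_quantifications.csv")
    q <- quants[!quants$excluded, , drop = FALSE]
    p <- ggplot2::ggplot(q, ggplot2::aes(x = .data$area_um2)) +
      ggplot2::stat_ecdf() +
      ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
      ggplot2::labs(x = expression("signal area per spine (" * mu * m^2 * ")"),
                    y = "cumulative fraction of spines") +
      ggplot2::theme_classic()
    f <- file.path(out_dir, "area_ecdf.png")
    ggplot2::ggsave(f, p, width = 4, height = 3, dpi = 150)
    written <- c(written, f)
    occ <- fraction_above_area(quants)
    emit(tibble::tibble(threshold_um2 = 0.1, fraction = occ$fraction,
                        se = occ$se, n = occ$n), "occupancy.csv")
  }
  if (!is.null(correlations) && nrow(correlations) > 0)
    emit(correlations, "correlation_results.csv")
  if (!is.null(scatter) && nrow(scatter) > 0) {
    emit(scatter, "scatter_data.csv")
    ann <- if (!is.null(correlations) && nrow(correlations) > 0)
      sprintf("rho = %.3f", correlations$rho[1]) else NULL
    p <- ggplot2::ggplot(scatter, ggplot2::aes(x = .data$z_marker,
                                               y = .data$z_nf)) +
      ggplot2::geom_point(alpha = 0.4, size = 0.8) +
      ggplot2::labs(x = "standardized marker amount",
                    y = "standardized NF amount", title = ann) +
      ggplot2::theme_classic()
    f <- file.path(out_dir, "scatter.png")
    ggplot2::ggsave(f, p, width = 4, height = 4, dpi = 150)
    written <- c(written, f)
  }
  if (length(written) == 0) {
    f <- file.path(out_dir, "no_data.txt")
    writeLines("no data: no results were provided to report_results()", f)
    written <- f
  }
  invisible(written)
}
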