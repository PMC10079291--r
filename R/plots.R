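#' Plot per-class temporal expression trends
#'
#' @param trends Output of [class_trend()].
#' @param zga_onset_hpf Optional vertical reference line at the onset
#'   of zygotic genome activation.
#' @return A ggplot object.
#' @export
plot_class_trend <- function(trends, zga_onset_hpf = 4) {
  p <- ggplot2::ggplot(trends, ggplot2::aes(x = .data$hpf, y = .data$mean_tpm,
                                            colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "hours post-fertilization", y = "mean TPM",
                  colour = "gene class") +
    ggplot2::theme_minimal()
  if (!is.null(zga_onset_hpf))
    p <- p + ggplot2::geom_vline(xintercept = zga_onset_hpf,
                                 linetype = "dotted", colour = "red")
  p
}

#' Plot per-cluster fold-change distributions
#'
#' Boxplots of per-CRM log2 fold changes (treated vs control) by
#' epigenetic cluster, with a reference line at zero.
#'
#' @param crm An annotated CRM tibble with a `cluster` column.
#' @param log2fc Per-CRM log2 fold-change vector aligned with `crm`.
#' @return A ggplot object.
#' @export
plot_fold_change <- function(crm, log2fc) {
  df <- dplyr::mutate(crm, log2fc = log2fc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$log2fc)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "red") +
    ggplot2::labs(x = "CRM cluster", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Plot localization proportions per CRM cluster
#'
#' Stacked proportions of localized (LC), non-localized (NL) and
#' unmarked (NP) pan-H3Kac status per epigenetic cluster.
#'
#' @param crm An annotated CRM tibble with `cluster` and `localization`.
#' @return A ggplot object.
#' @export
plot_localization <- function(crm) {
  ggplot2::ggplot(crm, ggplot2::aes(x = .data$cluster,
                                    fill = .data$localization)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::labs(x = "CRM cluster", y = "proportion",
                  fill = "pan-H3Kac") +
    ggplot2::theme_minimal()
}

#' Heatmap of a summit-centered signal matrix
#'
#' @param object A `signal_matrix` from [matrix_at_summits()].
#' @param ... Unused.
#' @return A ggplot object (rows ordered by decreasing row mean).
#' @method autoplot signal_matrix
#' @export
autoplot.signal_matrix <- function(object, ...) {
  ord <- order(rowMeans(object), decreasing = TRUE)
  m <- object[ord, , drop = FALSE]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(t(m))
  window <- attr(object, "window")
  bin <- attr(object, "bin")
  df$pos <- (df$col - 0.5) * bin - window / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "signal") +
    ggplot2::labs(x = "distance from summit (bp)", y = "region") +
    ggplot2::theme_minimal()
}

#' Plot a metagene profile
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = range(profile$position[profile$segment == "body"]) +
        c(-0.5, 0.5),
      linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "5' flank - gene body (scaled) - 3' flank",
                  y = "mean signal") +
    ggplot2::theme_minimal()
}
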