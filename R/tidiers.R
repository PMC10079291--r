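#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pipeline result into one row per CRM
#'
#' @param x A `crm_pipeline` object.
#' @param ... Unused.
#' @return The annotated CRM tibble (cluster, localization, spatial
#'   category, germ-layer signals, nearest gene).
#' @method tidy crm_pipeline
#' @export
tidy.crm_pipeline <- function(x, ...) {
  tibble::as_tibble(x$crm)
}

#' One-row summary of a pipeline result
#'
#' @param x A `crm_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble with counts and headline quantities.
#' @method glance crm_pipeline
#' @export
glance.crm_pipeline <- function(x, ...) {
  cl <- table(x$crm$cluster)
  tibble::tibble(
    n_crm = nrow(x$crm),
    n_cluster_I = as.integer(cl[["I"]]),
    n_cluster_II = as.integer(cl[["II"]]),
    n_cluster_III = as.integer(cl[["III"]]),
    n_cluster_IV = as.integer(cl[["IV"]]),
    n_genes = nrow(x$gene_classes),
    n_zygotic = length(x$zygotic),
    n_class2 = sum(x$gene_classes$class == "2"),
    premature_fraction = x$premature_fraction
  )
}

#' Tidy a signal matrix into long form
#'
#' @param x A `signal_matrix`.
#' @param ... Unused.
#' @return A tibble `region`, `bin`, `position`, `signal`.
#' @method tidy signal_matrix
#' @export
tidy.signal_matrix <- function(x, ...) {
  window <- attr(x, "window")
  bin <- attr(x, "bin")
  df <- tidyr::expand_grid(region = rownames(x) %||% seq_len(nrow(x)),
                           bin = seq_len(ncol(x)))
  df$position <- (df$bin - 0.5) * bin - window / 2
  df$signal <- as.vector(t(unclass(x)))
  df
}
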