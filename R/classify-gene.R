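#' Gene classes from CRM cluster peak sets
#'
#' Genes are first associated with each epigenetic CRM cluster by
#' nearest-gene assignment within `max_distance`. With G(X) the gene
#' set of cluster X: Class 1 = G(I) together with genes shared between
#' G(II) and G(III); Class 2 = G(II) minus Class 1; Class 3 = G(III)
#' minus Class 1. Classes 1-3 are pairwise disjoint by construction;
#' genes in none are `unclassified`.
#'
#' @param cluster_peaks Named list of peak tibbles for clusters
#'   `"I"`, `"II"`, `"III"` (e.g. split from [partition_by_marks()]).
#' @param genes Gene-model tibble.
#' @param max_distance Nearest-gene cutoff in bp (default 10000).
#'
#' @return A tibble `gene_id`, `class` (factor `1`,`2`,`3`,
#'   `unclassified`) covering all genes.
#' @export
gene_classes <- function(cluster_peaks, genes, max_distance = 10000) {
  stopifnot(all(c("I", "II", "III") %in% names(cluster_peaks)))
  genes <- validate_genes(genes)
  g <- lapply(cluster_peaks[c("I", "II", "III")], function(p) {
    if (nrow(p) == 0L) return(character())
    hits <- nearest_gene(p, genes, max_distance)$gene_id
    unique(hits[!is.na(hits)])
  })
  class1 <- union(g$I, intersect(g$II, g$III))
  class2 <- setdiff(g$II, class1)
  class3 <- setdiff(g$III, class1)
  cls <- rep("unclassified", nrow(genes))
  cls[genes$gene_id %in% class1] <- "1"
  cls[genes$gene_id %in% class2] <- "2"
  cls[genes$gene_id %in% class3] <- "3"
  tibble::tibble(gene_id = genes$gene_id,
                 class = factor(cls, levels = c("1", "2", "3", "unclassified")))
}

# hpf values encoded in the time-course column names
timecourse_hours <- function(timecourse) {
  cols <- setdiff(names(timecourse), "gene_id")
  h <- suppressWarnings(as.numeric(cols))
  if (anyNA(h)) stop("time-course columns must be named by hpf")
  h
}

#' Strictly zygotic genes from a TPM time course
#'
#' Keeps genes that are (1) at or below `tpm_threshold` at every time
#' point within the maternal window (no maternal contribution) and
#' (2) reach at least `tpm_threshold` somewhere before `horizon_hpf`
#' (expressed at all).
#'
#' @param timecourse Expression tibble: `gene_id` plus numeric columns
#'   named by hpf, sorted in time.
#' @param maternal_window_hpf Maternal window upper bound (default 2).
#' @param tpm_threshold Expression threshold in TPM (default 1).
#' @param horizon_hpf Horizon for the expressed-at-all rule (default 23).
#'
#' @return Character vector of strictly zygotic gene ids.
#' @export
zygotic_filter <- function(timecourse, maternal_window_hpf = 2,
                           tpm_threshold = 1, horizon_hpf = 23) {
  h <- timecourse_hours(timecourse)
  if (is.unsorted(h)) stop("time points must be sorted")
  m <- as.matrix(timecourse[, setdiff(names(timecourse), "gene_id")])
  maternal_cols <- which(h <= maternal_window_hpf)
  if (length(maternal_cols) == 0L)
    stop("no time point within the maternal window")
  horizon_cols <- which(h <= horizon_hpf)
  not_maternal <- apply(m[, maternal_cols, drop = FALSE] <= tpm_threshold, 1, all)
  expressed <- apply(m[, horizon_cols, drop = FALSE], 1, max) >= tpm_threshold
  timecourse$gene_id[not_maternal & expressed]
}

#' Per-class mean TPM trends over time
#'
#' @param timecourse Expression tibble (see [zygotic_filter()]).
#' @param classes A [gene_classes()] tibble.
#' @return A long tibble `class`, `hpf`, `mean_tpm`; empty classes are
#'   omitted with a warning.
#' @export
class_trend <- function(timecourse, classes) {
  joined <- dplyr::inner_join(timecourse, classes, by = "gene_id")
  present <- unique(as.character(joined$class))
  missing <- setdiff(setdiff(levels(classes$class), "unclassified"), present)
  if (length(missing))
    warning("empty class(es) omitted from trends: ", paste(missing, collapse = ", "))
  joined |>
    tidyr::pivot_longer(cols = -c("gene_id", "class"),
                        names_to = "hpf", values_to = "tpm") |>
    dplyr::mutate(hpf = as.numeric(.data$hpf)) |>
    dplyr::group_by(.data$class, .data$hpf) |>
    dplyr::summarise(mean_tpm = mean(.data$tpm), .groups = "drop") |>
    dplyr::arrange(.data$class, .data$hpf)
}

#' Germ-layer category of genes from five-tissue TPM
#'
#' Collapses the five dissected tissues to a germ-layer triple: AC,
#' MZ = mean of the three mesoderm explants (DMZ, LMZ, VMZ), VG. A gene
#' is NE (not expressed) when every collapsed value is below
#' `tpm_threshold`; NL (non-localized) when the coefficient of
#' variation (population SD / mean) over the triple is below
#' `cv_threshold`; otherwise it takes the germ layer with the maximum
#' TPM. `ne_rule = "any_tissue"` applies the literal reading where a
#' single raw tissue below threshold makes a gene NE.
#'
#' @param tissues Expression tibble with columns `gene_id`, `AC`,
#'   `DMZ`, `LMZ`, `VMZ`, `VG`.
#' @param tpm_threshold TPM floor for expression (default 1).
#' @param cv_threshold CV below which expression counts as even
#'   (default 0.1).
#' @param ne_rule `"all_collapsed"` (default) or `"any_tissue"`.
#'
#' @return A tibble `gene_id`, `ac`, `mz`, `vg`, `cv`, `category`
#'   (factor `AC`, `MZ`, `VG`, `NL`, `NE`).
#' @export
spatial_gene_category <- function(tissues, tpm_threshold = 1, cv_threshold = 0.1,
                                  ne_rule = c("all_collapsed", "any_tissue")) {
  ne_rule <- match.arg(ne_rule)
  need <- c("gene_id", "AC", "DMZ", "LMZ", "VMZ", "VG")
  if (!all(need %in% names(tissues)))
    stop("tissue table must contain columns ", paste(need, collapse = ", "))
  ac <- tissues$AC
  mz <- (tissues$DMZ + tissues$LMZ + tissues$VMZ) / 3
  vg <- tissues$VG
  triple <- cbind(ac, mz, vg)
  mu <- rowMeans(triple)
  sd_pop <- sqrt(rowMeans((triple - mu)^2))
  cv <- ifelse(mu > 0, sd_pop / mu, 0)
  ne <- if (ne_rule == "all_collapsed") {
    ac < tpm_threshold & mz < tpm_threshold & vg < tpm_threshold
  } else {
    apply(as.matrix(tissues[, c("AC", "DMZ", "LMZ", "VMZ", "VG")]) <
            tpm_threshold, 1, any)
  }
  maxlab <- c("AC", "MZ", "VG")[max.col(triple, ties.method = "first")]
  category <- dplyr::case_when(ne ~ "NE", cv < cv_threshold ~ "NL",
                               .default = maxlab)
  tibble::tibble(gene_id = tissues$gene_id, ac = ac, mz = mz, vg = vg, cv = cv,
                 category = factor(category,
                                   levels = c("AC", "MZ", "VG", "NL", "NE")))
}

#' Threshold a differential-expression table
#'
#' Applies the conventional strict cutoffs: up-regulated genes have
#' `log2FC > log2(min_fold)` and `FDR < max_fdr`; down-regulated genes
#' are symmetric with `log2FC < -log2(min_fold)`.
#'
#' @param de DE tibble with columns `gene_id`, `log2fc`, `fdr`.
#' @param min_fold Minimum fold change (default 2).
#' @param max_fdr FDR ceiling (default 0.05).
#' @return A list with character vectors `up` and `down`.
#' @export
de_threshold_filter <- function(de, min_fold = 2, max_fdr = 0.05) {
  need <- c("gene_id", "log2fc", "fdr")
  if (!all(need %in% names(de)))
    stop("DE table must contain columns ", paste(need, collapse = ", "))
  if (any(de$fdr < 0 | de$fdr > 1)) stop("FDR values must be in [0, 1]")
  lfc <- log2(min_fold)
  list(
    up = de$gene_id[de$log2fc > lfc & de$fdr < max_fdr],
    down = de$gene_id[de$log2fc < -lfc & de$fdr < max_fdr]
  )
}

#' Fraction of a gene class prematurely activated
#'
#' @param class2_genes Non-empty character vector of gene ids (the
#'   normally late-activating class).
#' @param up_set Character vector of up-regulated gene ids under HDAC
#'   inhibition.
#' @return Fraction in [0, 1] of `class2_genes` found in `up_set`.
#' @export
premature_activation_fraction <- function(class2_genes, up_set) {
  if (length(class2_genes) == 0L) stop("gene class is empty")
  length(intersect(class2_genes, up_set)) / length(unique(class2_genes))
}
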