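#' Analysis thresholds
#'
#' The categorical and filtering thresholds used throughout the
#' analysis, defaulting to the study-design conventions: twofold
#' spatial enrichment, 1 TPM expression floor, CV 0.1 for even
#' expression, 10 kb nearest-gene cutoff, top 30% enrichment fraction,
#' twofold / FDR 0.05 differential-expression cutoffs, pseudocount 1
#' and minimum-count spike-in reference. Unknown keys are rejected.
#'
#' @param ... Named overrides.
#' @return A named list of thresholds.
#' @export
pipeline_thresholds <- function(...) {
  thr <- list(spatial_fold = 2, tpm = 1, cv = 0.1, nearest_distance = 10000,
              top_fraction = 0.3, de_fold = 2, fdr = 0.05, pseudocount = 1,
              reference = "min", bin_size = 50,
              maternal_window_hpf = 2, horizon_hpf = 23)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(thr))
  if (length(unknown))
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "))
  thr[names(dots)] <- dots
  thr
}

#' Run the full CRM/gene analysis on a synthetic dataset
#'
#' Orchestrates every stage on a simulated experiment: CRM partition by
#' histone marks, pan-H3Kac localization and spatial categories,
#' spike-in normalized per-cluster signal with average log2 differences
#' (against a randomized-region negative control), per-cluster fold
#' changes with Welch t and Cohen's d, gene classes with temporal
#' trends, and spatial-category x differential-expression enrichment
#' tables. All stage outputs are pure functions of the configuration,
#' so a rerun reproduces every report byte for byte.
#'
#' @param config A [sim_config()] describing the dataset.
#' @param thresholds A [pipeline_thresholds()] list.
#' @param dir Optional output directory for the report TSVs and run log.
#'
#' @return An object of class `crm_pipeline`: a list with `crm`
#'   (annotated CRM tibble), `factors`, `delta`, `fc_stats`,
#'   `gene_classes`, `zygotic`, `trends`, `gene_categories`, `de`,
#'   `premature_fraction`, `enrichment`, `data` (the simulated inputs)
#'   and `log` (character lines).
#' @export
run_pipeline <- function(config = sim_config(), thresholds = pipeline_thresholds(),
                         dir = NULL) {
  log <- c(sprintf("crmkit %s on %s",
                   as.character(utils::packageVersion("crmkit")),
                   R.version.string),
           sprintf("seed = %d", config$seed),
           sprintf("threshold %s = %s", names(thresholds),
                   vapply(thresholds, paste, character(1), collapse = ",")))
  note <- function(...) log <<- c(log, sprintf(...))

  data <- simulate_dataset(config)
  note("simulated %d CRMs, %d genes, %d libraries", nrow(data$crm),
       nrow(data$genes), length(data$libraries))

  # stage 1: epigenetic clusters
  crm <- partition_by_marks(data$crm, data$k27ac, data$k27me3)
  stopifnot(sum(table(crm$cluster)) == nrow(crm))
  note("clusters: %s", paste(sprintf("%s=%d", levels(crm$cluster),
                                     table(crm$cluster)), collapse = " "))

  # stage 2: pan-H3Kac localization
  venn <- venn_two(data$pankac_ac, data$pankac_vg)
  crm <- localization_category(crm, venn)
  note("localization: %s",
       paste(sprintf("%s=%d", levels(crm$localization),
                     table(crm$localization)), collapse = " "))

  # stage 3: spike-in scaled quantification
  factors <- spikein_factors(data$libraries, data$spike_peaks,
                             reference = thresholds$reference)
  tracks <- purrr::map(data$libraries, function(lib) {
    tr <- binned_coverage(lib$fragments, data$genome,
                          bin_size = thresholds$bin_size)
    apply_factor(tr, factors$factor[factors$sample_id == lib$sample_id])
  })
  sig <- purrr::map(tracks, ~ quantify_regions(.x, crm, statistic = "sum")$signal)
  names(sig) <- purrr::map_chr(data$libraries, "sample_id")
  cond_mean <- function(tissue, treatment) {
    sel <- purrr::map_lgl(data$libraries, ~ .x$tissue == tissue &&
                            .x$treatment == treatment)
    rowMeans(do.call(cbind, sig[sel]))
  }
  ac_dmso <- cond_mean("AC", "DMSO")
  ac_tsa <- cond_mean("AC", "TSA")
  crm$ac_signal <- ac_dmso
  has_vg <- "VG" %in% config$tissues
  if (has_vg) crm$vg_signal <- cond_mean("VG", "DMSO")
  note("spike-in factors: %s",
       paste(sprintf("%s=%.3f", factors$sample_id, factors$factor),
             collapse = " "))

  # stage 4: per-cluster delta-bar and fold changes, with a
  # randomized-region negative control of matched widths
  pc <- thresholds$pseudocount
  rand <- random_regions(data$genome, data$crm$end - data$crm$start,
                         seed = config$seed + 909L)
  rand_sig <- purrr::map(tracks, ~ quantify_regions(.x, rand, statistic = "sum")$signal)
  names(rand_sig) <- names(sig)
  rsel <- function(treatment) {
    sel <- purrr::map_lgl(data$libraries, ~ .x$tissue == "AC" &&
                            .x$treatment == treatment)
    rowMeans(do.call(cbind, rand_sig[sel]))
  }
  delta <- dplyr::bind_rows(
    purrr::map_dfr(levels(crm$cluster), function(cl) {
      i <- crm$cluster == cl
      tibble::tibble(group = paste0("cluster_", cl), n = sum(i),
                     delta_bar = delta_bar(ac_dmso[i], ac_tsa[i], pc))
    }),
    tibble::tibble(group = "random", n = nrow(rand),
                   delta_bar = delta_bar(rsel("DMSO"), rsel("TSA"), pc)))
  fc_stats <- purrr::map_dfr(levels(crm$cluster), function(cl) {
    i <- crm$cluster == cl
    fc <- region_fold_change(ac_dmso[i], ac_tsa[i], pc)
    wt <- welch_t(ac_tsa[i], ac_dmso[i])
    tibble::tibble(cluster = cl, n = sum(i), mean_log2fc = mean(fc),
                   t = wt$statistic, df = wt$df, p_value = wt$p_value,
                   cohens_d = cohens_d(ac_tsa[i], ac_dmso[i]))
  })
  note("delta-bar: %s", paste(sprintf("%s=%.3f", delta$group, delta$delta_bar),
                              collapse = " "))

  # stage 5: spatial CRM categories from untreated germ-layer signals
  if (has_vg) {
    crm <- spatial_crm_category(crm, fold = thresholds$spatial_fold)
  }
  crm <- nearest_gene(crm, data$genes,
                      max_distance = thresholds$nearest_distance)
  note("CRMs assigned to a gene: %d / %d", sum(!is.na(crm$gene_id)), nrow(crm))

  # stage 6: gene classes and temporal trends
  cluster_peaks <- split(as.data.frame(crm), crm$cluster)
  gcl <- gene_classes(cluster_peaks, data$genes,
                      max_distance = thresholds$nearest_distance)
  zyg <- zygotic_filter(data$timecourse,
                        maternal_window_hpf = thresholds$maternal_window_hpf,
                        tpm_threshold = thresholds$tpm,
                        horizon_hpf = thresholds$horizon_hpf)
  trends <- suppressWarnings(
    class_trend(data$timecourse[data$timecourse$gene_id %in% zyg, ], gcl))
  note("gene classes: %s; strictly zygotic genes: %d",
       paste(sprintf("%s=%d", levels(gcl$class), table(gcl$class)),
             collapse = " "), length(zyg))

  # stage 7: spatial gene categories and DE enrichment
  gcat <- spatial_gene_category(data$tissues, tpm_threshold = thresholds$tpm,
                                cv_threshold = thresholds$cv)
  de <- list(
    ac = de_threshold_filter(data$de_ac, thresholds$de_fold, thresholds$fdr),
    vg = de_threshold_filter(data$de_vg, thresholds$de_fold, thresholds$fdr))
  class2 <- gcl$gene_id[gcl$class == "2"]
  premature <- if (length(class2))
    premature_activation_fraction(class2, union(de$ac$up, de$vg$up))
  else NA_real_
  class1_cat <- gcat[gcat$gene_id %in% gcl$gene_id[gcl$class == "1"], ]
  enrichment <- dplyr::bind_rows(
    dplyr::mutate(category_enrichment(class1_cat, de$ac$up),
                  contrast = "AC_up", .before = 1),
    dplyr::mutate(category_enrichment(class1_cat, de$ac$down),
                  contrast = "AC_down", .before = 1),
    dplyr::mutate(category_enrichment(class1_cat, de$vg$up),
                  contrast = "VG_up", .before = 1),
    dplyr::mutate(category_enrichment(class1_cat, de$vg$down),
                  contrast = "VG_down", .before = 1))
  note("premature activation of class 2 upon HDAC inhibition: %.3f",
       premature)

  result <- structure(
    list(crm = crm, factors = factors, delta = delta, fc_stats = fc_stats,
         gene_classes = gcl, zygotic = zyg, trends = trends,
         gene_categories = gcat, de = de, premature_fraction = premature,
         enrichment = enrichment, config = config, thresholds = thresholds,
         data = data, log = log),
    class = "crm_pipeline")
  if (!is.null(dir)) write_pipeline_reports(result, dir)
  result
}

#' @export
print.crm_pipeline <- function(x, ...) {
  cat("<crm_pipeline>\n")
  cat(" ", nrow(x$crm), "CRMs;", nrow(x$gene_classes), "genes;",
      length(x$zygotic), "strictly zygotic\n")
  cat("  clusters:", paste(sprintf("%s=%d", levels(x$crm$cluster),
                                   table(x$crm$cluster)), collapse = " "), "\n")
  cat(sprintf("  premature class-2 activation: %.3f\n", x$premature_fraction))
  invisible(x)
}

#' Write the pipeline report bundle
#'
#' Emits the six report tables as TSV plus the run log. Outputs are
#' deterministic given the configuration.
#'
#' @param result A `crm_pipeline` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) {
    x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.factor), as.character))
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  tsv(result$crm, "crm_clusters.tsv")
  loc <- result$crm |>
    dplyr::count(.data$cluster, .data$localization) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  tsv(loc, "crm_localization.tsv")
  tsv(result$delta, "cluster_delta_bar.tsv")
  tsv(result$fc_stats, "cluster_fold_change_stats.tsv")
  tsv(dplyr::left_join(result$gene_classes,
                       tibble::tibble(gene_id = result$zygotic, zygotic = TRUE),
                       by = "gene_id") |>
        dplyr::mutate(zygotic = !is.na(.data$zygotic)),
      "gene_classes.tsv")
  tsv(result$trends, "class_trends.tsv")
  tsv(result$gene_categories, "gene_categories.tsv")
  tsv(result$enrichment, "spatial_enrichment.tsv")
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Score a pipeline run against its simulation ground truth
#'
#' Compares recovered CRM clusters, localization and spatial categories,
#' the strictly zygotic gene set and germ-layer gene categories with the
#' generator's planted labels.
#'
#' @param result A `crm_pipeline` object.
#' @param recovery_threshold Pass mark for label-recovery rates
#'   (default 0.95).
#' @return A tibble: `metric`, `value`, `n`, `pass`.
#' @export
score_simulation <- function(result, recovery_threshold = 0.95) {
  truth <- result$data$crm_truth
  gt <- result$data$gene_truth
  crm <- result$crm
  stopifnot(identical(crm$name, truth$name))
  cluster_rec <- mean(as.character(crm$cluster) == truth$cluster)
  loc_rec <- mean(as.character(crm$localization) == truth$localization)
  hassp <- !is.na(truth$spatial)
  spatial_rec <- mean(as.character(crm$spatial[hassp]) == truth$spatial[hassp])
  zyg_rec <- mean((gt$gene_id %in% result$zygotic) == gt$zygotic)
  cat_tbl <- result$gene_categories
  cat_rec <- mean(as.character(cat_tbl$category) ==
                    gt$category[match(cat_tbl$gene_id, gt$gene_id)])
  out <- tibble::tibble(
    metric = c("crm_cluster_recovery", "crm_localization_recovery",
               "crm_spatial_recovery", "zygotic_set_recovery",
               "gene_category_recovery", "premature_activation_fraction"),
    value = c(cluster_rec, loc_rec, spatial_rec, zyg_rec, cat_rec,
              result$premature_fraction),
    n = c(nrow(crm), nrow(crm), sum(hassp), nrow(gt), nrow(cat_tbl),
          sum(result$gene_classes$class == "2")))
  out$pass <- c(out$value[1:5] >= recovery_threshold, NA)
  out
}
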