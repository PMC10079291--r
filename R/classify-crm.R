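#' Localization category of CRMs from a pan-H3Kac Venn
#'
#' A CRM shows localized acetylation (LC) when it overlaps any
#' tissue-specific pan-H3Kac peak (AC-only or VG-only in the Venn);
#' non-localized (NL) when it overlaps only peaks shared between the
#' two explants; NP when it overlaps no pan-H3Kac peak at all. LC takes
#' precedence on mixed overlap: the localized call is defined by
#' specific-peak overlap alone.
#'
#' @param crm CRM peak tibble.
#' @param pankac_venn Output of [venn_two()] over the AC and VG
#'   pan-H3Kac peak sets.
#'
#' @return `crm` with a `localization` factor column (`LC`, `NL`, `NP`).
#' @export
localization_category <- function(crm, pankac_venn) {
  crm <- validate_peaks(crm)
  specific <- pankac_venn[pankac_venn$label %in% c("a_only", "b_only"), ]
  shared <- pankac_venn[pankac_venn$label == "shared", ]
  lc <- overlap_flags(crm, specific)
  nl <- overlap_flags(crm, shared)
  loc <- dplyr::case_when(lc ~ "LC", nl ~ "NL", .default = "NP")
  dplyr::mutate(crm, localization = factor(loc, levels = c("LC", "NL", "NP")))
}

#' Spatial category of CRMs from paired germ-layer signals
#'
#' AC when the animal-cap signal is at least `fold` times the
#' vegetal-mass signal, VG for the symmetric case, ubiquitous otherwise
#' (boundary inclusive). Both signals zero is the documented degenerate
#' case and yields ubiquitous.
#'
#' @param x A data frame with per-CRM signal columns.
#' @param ac_signal,vg_signal Column names (character) of the spike-in
#'   scaled AC and VG signals. Defaults `"ac_signal"`/`"vg_signal"`.
#' @param fold Fold-enrichment threshold (> 1, default 2).
#'
#' @return `x` with a `spatial` factor column (`AC`, `VG`, `ubiquitous`).
#' @export
#' @examples
#' tibble::tibble(ac_signal = c(4, 1, 3), vg_signal = c(1, 4, 3)) |>
#'   spatial_crm_category()
spatial_crm_category <- function(x, ac_signal = "ac_signal",
                                 vg_signal = "vg_signal", fold = 2) {
  if (fold <= 1) stop("fold threshold must be > 1")
  ac <- x[[ac_signal]]
  vg <- x[[vg_signal]]
  if (is.null(ac) || is.null(vg))
    stop("signal columns not found: ", ac_signal, ", ", vg_signal)
  if (any(ac < 0, na.rm = TRUE) || any(vg < 0, na.rm = TRUE))
    stop("signals must be non-negative")
  lab <- dplyr::case_when(
    ac == 0 & vg == 0 ~ "ubiquitous",
    ac >= fold * vg ~ "AC",
    vg >= fold * ac ~ "VG",
    .default = "ubiquitous"
  )
  dplyr::mutate(x, spatial = factor(lab, levels = c("AC", "VG", "ubiquitous")))
}

#' Write a per-CRM annotation table
#'
#' Emits one row per CRM with BED coordinates and whatever category
#' columns are present (`cluster`, `localization`, `spatial`,
#' `gene_id`, signals), directly consumable for heatmap ordering.
#'
#' @param crm Annotated CRM tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_crm_annotation <- function(crm, path) {
  utils::write.table(
    dplyr::mutate(crm, dplyr::across(dplyr::where(is.factor), as.character)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
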