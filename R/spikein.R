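#' ChIP libraries with spike-in reads
#'
#' A `chip_library` bundles one sample's experimental fragments with its
#' exogenous spike-in fragments (which live on a disjoint genome layout)
#' plus the condition labels of the experimental design: tissue (AC
#' animal cap, VG vegetal mass, WE whole embryo), treatment (DMSO
#' solvent control or TSA HDAC inhibition) and replicate index.
#'
#' @param sample_id Sample identifier.
#' @param fragments Experimental-genome fragment tibble.
#' @param spike_fragments Spike-in-genome fragment tibble.
#' @param tissue,treatment,replicate Condition labels.
#'
#' @return An object of class `chip_library`.
#' @export
chip_library <- function(sample_id, fragments, spike_fragments,
                         tissue = "WE", treatment = "DMSO", replicate = 1L) {
  structure(
    list(sample_id = sample_id,
         fragments = validate_peaks(fragments),
         spike_fragments = validate_peaks(spike_fragments),
         tissue = tissue, treatment = treatment,
         replicate = as.integer(replicate)),
    class = "chip_library"
  )
}

#' @export
print.chip_library <- function(x, ...) {
  cat(sprintf("<chip_library> %s (%s, %s, rep %d): %d fragments + %d spike-in\n",
              x$sample_id, x$tissue, x$treatment, x$replicate,
              nrow(x$fragments), nrow(x$spike_fragments)))
  invisible(x)
}

#' Spike-in (ChIP-Rx) normalization factors
#'
#' Counts each library's spike-in fragments overlapping the spike-in
#' peak set (e.g. exogenous H2Av peaks) and derives per-sample scaling
#' factors `n_ref / n_i`. With the default `reference = "min"` the
#' sample with the fewest spike-in reads anchors the scale and all
#' factors are <= 1.
#'
#' @param libraries List of [chip_library()] objects.
#' @param spikein_peaks Peak tibble on the spike-in genome.
#' @param reference A sample id, or `"min"`.
#'
#' @return A tibble with columns `sample_id`, `spike_reads`, `factor`.
#' @export
spikein_factors <- function(libraries, spikein_peaks, reference = "min") {
  spikein_peaks <- validate_peaks(spikein_peaks)
  ids <- purrr::map_chr(libraries, "sample_id")
  n <- purrr::map_dbl(libraries, function(lib) {
    sum(overlap_flags(lib$spike_fragments, spikein_peaks))
  })
  if (any(n == 0))
    stop("no spike-in reads in peaks for sample(s): ",
         paste(ids[n == 0], collapse = ", "))
  n_ref <- if (identical(reference, "min")) min(n) else {
    if (!reference %in% ids) stop("unknown reference sample: ", reference)
    n[match(reference, ids)]
  }
  tibble::tibble(sample_id = ids, spike_reads = as.integer(n),
                 factor = n_ref / n)
}

#' Scale a raw track by a spike-in factor
#'
#' @param track A `raw` [signal_track()].
#' @param factor A positive scalar, or a one-row tibble from
#'   [spikein_factors()].
#' @return The scaled track, tagged `spikein`.
#' @export
apply_factor <- function(track, factor) {
  if (!identical(track$normalization, "raw"))
    stop("refusing to rescale a track already normalized as ",
         track$normalization)
  f <- if (is.data.frame(factor)) factor$factor[1] else factor
  if (!is.finite(f) || f <= 0) stop("scaling factor must be positive")
  track$values <- lapply(track$values, `*`, f)
  track$normalization <- "spikein"
  track
}

#' Downsample a library's reads
#'
#' Keeps each fragment (experimental and spike-in alike) independently
#' with probability `fraction` (Bernoulli thinning; `exact = TRUE`
#' instead keeps exactly `round(fraction * n)` fragments of each kind).
#' Used to equalize sequencing depth between replicates, e.g. the 25%
#' downsampling of deeper second replicates.
#'
#' @param library A [chip_library()].
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer RNG seed (fixed seed, identical output).
#' @param exact Use exact-count subsampling instead of Bernoulli.
#' @return A downsampled `chip_library`.
#' @export
downsample_reads <- function(library, fraction, seed, exact = FALSE) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  withr::with_seed(seed, {
    thin <- function(x) {
      if (nrow(x) == 0L) return(x)
      keep <- if (exact)
        sort(sample.int(nrow(x), round(fraction * nrow(x))))
      else which(stats::runif(nrow(x)) < fraction)
      x[keep, ]
    }
    library$fragments <- thin(library$fragments)
    library$spike_fragments <- thin(library$spike_fragments)
  })
  library
}

#' Per-region log2 fold change between scaled signals
#'
#' @param control,treated Equal-length non-negative per-region signal
#'   vectors (spike-in-scaled).
#' @param pseudocount Positive stabilizer added to both sides.
#' @return Numeric vector `log2((treated + pc) / (control + pc))`.
#' @export
region_fold_change <- function(control, treated, pseudocount = 1) {
  if (length(control) != length(treated))
    stop("control and treated must be paired vectors of equal length")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(control < 0) || any(treated < 0))
    stop("signals must be non-negative")
  log2(treated + pseudocount) - log2(control + pseudocount)
}

#' Average log2 signal difference over regions
#'
#' The summary statistic reported over a CRM cluster: by default the
#' mean of per-region log2 differences (the mean of
#' [region_fold_change()]). `method = "log_of_means"` instead takes the
#' log2 ratio of the region-mean signals.
#'
#' @inheritParams region_fold_change
#' @param method `"mean_of_logs"` (default) or `"log_of_means"`.
#' @return A scalar.
#' @export
delta_bar <- function(control, treated, pseudocount = 1,
                      method = c("mean_of_logs", "log_of_means")) {
  method <- match.arg(method)
  if (length(control) == 0L) stop("empty region set")
  if (method == "mean_of_logs") {
    mean(region_fold_change(control, treated, pseudocount))
  } else {
    if (any(control < 0) || any(treated < 0)) stop("signals must be non-negative")
    log2(mean(treated) + pseudocount) - log2(mean(control) + pseudocount)
  }
}

#' @rdname spikein_factors
#' @param factors A factors tibble.
#' @param path Output TSV path (sample id, spike-in reads, factor).
#' @export
write_factors <- function(factors, path) {
  utils::write.table(factors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
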