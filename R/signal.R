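#' Fixed-bin signal tracks
#'
#' A `signal_track` holds per-chromosome fixed-bin coverage values plus
#' its normalization state. Bin values are mean per-bp fragment coverage
#' within the bin (identical to per-bp depth at bin size 1); the last
#' bin of a chromosome may be truncated. Normalization tags: `raw`,
#' `RPGC` (genome-wide per-bp mean scaled to 1), `BPM` (bin values sum
#' to 1e6), `spikein` (raw values scaled by a spike-in factor).
#'
#' @param values Named list (per chromosome) of numeric bin values.
#' @param genome Genome layout tibble.
#' @param bin_size Bin size in bp.
#' @param normalization One of `"raw"`, `"RPGC"`, `"BPM"`, `"spikein"`.
#' @param total_reads Number of fragments used to build the track.
#'
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(values, genome, bin_size, normalization = "raw",
                         total_reads = NA_integer_) {
  validate_genome(genome)
  stopifnot(bin_size >= 1)
  nbins <- ceiling(genome$size / bin_size)
  if (!setequal(names(values), genome$chrom))
    stop("track values must cover exactly the layout's chromosomes")
  values <- values[genome$chrom]
  ok <- purrr::map2_lgl(values, nbins, ~ length(.x) == .y &&
                          all(is.finite(.x)) && all(.x >= 0))
  if (!all(ok)) stop("bin values must be finite, >= 0, one per bin")
  structure(
    list(values = values, genome = genome, bin_size = bin_size,
         normalization = normalization, total_reads = total_reads),
    class = "signal_track"
  )
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d chromosome(s), bin %d bp, %s normalization\n",
              nrow(x$genome), as.integer(x$bin_size), x$normalization))
  invisible(x)
}

#' @export
#' @method as_tibble signal_track
#' @rdname signal_track
#' @param x A `signal_track`.
#' @param ... Unused.
as_tibble.signal_track <- function(x, ...) {
  purrr::map2_dfr(x$genome$chrom, x$genome$size, function(ch, sz) {
    v <- x$values[[ch]]
    start <- (seq_along(v) - 1) * x$bin_size
    tibble::tibble(chrom = ch, start = start,
                   end = pmin(start + x$bin_size, sz), value = v)
  })
}

# bin bp widths for one chromosome (last bin may be truncated)
bin_widths <- function(size, bin_size) {
  nb <- ceiling(size / bin_size)
  w <- rep(bin_size, nb)
  w[nb] <- size - (nb - 1) * bin_size
  w
}

#' Build a binned coverage track from fragments
#'
#' Raw values are the mean per-bp fragment coverage within each bin.
#' `BPM` rescales so bin values sum to 1e6; `RPGC` rescales so the
#' genome-wide mean per-bp coverage is 1 (effective genome size = sum of
#' layout lengths).
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`); intervals
#'   are clipped to chromosome bounds.
#' @param genome Genome layout.
#' @param bin_size Bin size in bp (>= 1).
#' @param mode `"raw"`, `"RPGC"` or `"BPM"`.
#'
#' @return A [signal_track()].
#' @export
binned_coverage <- function(fragments, genome, bin_size = 50,
                            mode = c("raw", "RPGC", "BPM")) {
  mode <- match.arg(mode)
  validate_genome(genome)
  stopifnot(bin_size >= 1)
  if (!all(fragments$chrom %in% genome$chrom))
    stop("fragments on chromosomes absent from the genome layout")
  values <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]; sz <- genome$size[i]
    f <- fragments[fragments$chrom == ch, ]
    w <- bin_widths(sz, bin_size)
    if (nrow(f) == 0L) return(rep(0, length(w)))
    s <- pmax(f$start, 0) + 1
    e <- pmin(f$end, sz)
    keep <- e >= s
    cov <- IRanges::coverage(IRanges::IRanges(s[keep], e[keep]), width = sz)
    sums <- IRanges::viewSums(IRanges::Views(cov, IRanges::successiveIRanges(w)))
    as.numeric(sums) / w
  })
  names(values) <- genome$chrom
  tr <- signal_track(values, genome, bin_size, "raw", nrow(fragments))
  if (mode == "raw") return(tr)
  tot <- track_bp_integral(tr)
  if (tot <= 0) stop("zero total signal: cannot ", mode, "-normalize")
  if (mode == "RPGC") {
    scale <- sum(genome$size) / tot
  } else {
    scale <- 1e6 / sum(unlist(tr$values))
  }
  tr$values <- lapply(tr$values, `*`, scale)
  tr$normalization <- mode
  tr
}

# genome-wide integral of per-bp signal (sum of value * bin bp width)
track_bp_integral <- function(track) {
  sum(purrr::map2_dbl(track$genome$chrom, track$genome$size, function(ch, sz) {
    sum(track$values[[ch]] * bin_widths(sz, track$bin_size))
  }))
}

# cumulative per-bp integral of a piecewise-constant track from 0 to x
# (x real-valued, clipped to [0, chromosome length]); vectorized over x
track_cumulative <- function(values, bin_size, size, x) {
  nb <- length(values)
  w <- bin_widths(size, bin_size)
  pref <- c(0, cumsum(values * w))
  x <- pmin(pmax(x, 0), size)
  k <- pmin(floor(x / bin_size), nb - 1)
  pref[k + 1] + values[k + 1] * pmin(x - k * bin_size, w[k + 1])
}

# integral of per-bp signal over [s, e) for regions on one chromosome
region_integral <- function(track, chrom, s, e) {
  v <- track$values[[chrom]]
  sz <- chrom_size(track$genome, chrom)
  track_cumulative(v, track$bin_size, sz, e) -
    track_cumulative(v, track$bin_size, sz, s)
}

#' Summit-centered signal matrix
#'
#' One row per peak covering `[summit - window/2, summit + window/2)`
#' in `window / bin` columns; out-of-chromosome positions contribute
#' zero. Defaults give the conventional 100-column, 5 kb / 50 bp view.
#'
#' @param track A `signal_track` whose bin size divides `bin`.
#' @param peaks Peak tibble (summit falls back to the midpoint).
#' @param window Window width in bp, divisible by `bin`.
#' @param bin Output bin size in bp.
#'
#' @return A `signal_matrix`: numeric matrix with peak names as
#'   rownames and attributes `window` and `bin`.
#' @export
matrix_at_summits <- function(track, peaks, window = 5000, bin = 50) {
  peaks <- validate_peaks(peaks, track$genome)
  if (window %% bin != 0) stop("window must be divisible by bin")
  if (bin %% track$bin_size != 0) stop("track bin size must divide bin")
  ncol <- window %/% bin
  pos <- summit_position(peaks)
  out <- matrix(0, nrow(peaks), ncol,
                dimnames = list(peaks$name, NULL))
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    v <- track$values[[ch]]
    sz <- chrom_size(track$genome, ch)
    w0 <- pos[idx] - window / 2
    bounds <- outer(w0, bin * (0:ncol), `+`)
    cum <- matrix(track_cumulative(v, track$bin_size, sz, as.vector(bounds)),
                  nrow = length(idx))
    out[idx, ] <- (cum[, -1, drop = FALSE] - cum[, -(ncol + 1), drop = FALSE]) / bin
  }
  structure(out, window = window, bin = bin, class = c("signal_matrix", "matrix"))
}

#' Length-normalized metagene profile
#'
#' Averages strand-oriented signal over genes: an upstream flank rebinned
#' to 50 bp, the gene body rescaled to `body_bins` bins, and a downstream
#' flank. Genes shorter than `body_bins` bp are skipped with a warning.
#'
#' @param track A `signal_track`.
#' @param genes Gene-model tibble (non-empty).
#' @param flank Flank width in bp on each side (multiple of 50).
#' @param body_bins Number of gene-body bins.
#'
#' @return A tibble with columns `position` (bin index along the
#'   composite axis), `segment` (`upstream`/`body`/`downstream`) and
#'   `signal` (mean over genes).
#' @export
metagene_profile <- function(track, genes, flank = 5000, body_bins = 100) {
  genes <- validate_genes(genes)
  if (nrow(genes) == 0L) stop("gene models must be non-empty")
  if (flank %% 50 != 0) stop("flank must be a multiple of the 50 bp flank bin")
  nf <- flank %/% 50
  keep <- (genes$end - genes$start) >= body_bins
  if (any(!keep))
    warning(sum(!keep), " gene(s) shorter than one body bin skipped")
  genes <- genes[keep, ]
  if (nrow(genes) == 0L) stop("no genes long enough for the requested body bins")
  total <- 2 * nf + body_bins
  acc <- matrix(0, nrow(genes), total)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    v <- track$values[[g$chrom]]
    sz <- chrom_size(track$genome, g$chrom)
    L <- g$end - g$start
    if (g$strand == "+") {
      bounds <- c(g$start - flank + 50 * (0:nf),
                  g$start + (L / body_bins) * (1:body_bins),
                  g$end + 50 * (1:nf))
    } else {
      bounds <- c(g$end + flank - 50 * (0:nf),
                  g$end - (L / body_bins) * (1:body_bins),
                  g$start - 50 * (1:nf))
    }
    cum <- track_cumulative(v, track$bin_size, sz, bounds)
    widths <- c(rep(50, nf), rep(L / body_bins, body_bins), rep(50, nf))
    acc[i, ] <- abs(diff(cum)) / widths
  }
  tibble::tibble(
    position = seq_len(total),
    segment = rep(c("upstream", "body", "downstream"), c(nf, body_bins, nf)),
    signal = colMeans(acc)
  )
}

#' Quantify track signal over regions
#'
#' Partial bins are weighted by overlap fraction; region order is
#' preserved.
#'
#' @param track A `signal_track`.
#' @param regions Peak tibble within the track's layout.
#' @param statistic `"mean"` (per-bp mean) or `"sum"` (per-bp integral).
#'
#' @return `regions` with a numeric `signal` column.
#' @export
quantify_regions <- function(track, regions, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  regions <- validate_peaks(regions, track$genome)
  signal <- rep(NA_real_, nrow(regions))
  for (ch in unique(regions$chrom)) {
    idx <- which(regions$chrom == ch)
    ints <- region_integral(track, ch, regions$start[idx], regions$end[idx])
    signal[idx] <- if (statistic == "sum") ints else
      ints / (regions$end[idx] - regions$start[idx])
  }
  dplyr::mutate(regions, signal = signal)
}

#' Keep the top-scoring fraction of peaks
#'
#' Retains peaks whose score is at least the score of the
#' `ceiling(fraction * n)`-th highest peak; ties at the threshold are all
#' kept, so the output may slightly exceed the requested fraction.
#'
#' @param peaks Peak tibble; every peak must carry a score.
#' @param fraction Fraction in (0, 1].
#' @return The filtered peak tibble (input order preserved).
#' @export
top_fraction <- function(peaks, fraction) {
  peaks <- validate_peaks(peaks)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (anyNA(peaks$score)) stop("all peaks must carry scores")
  if (nrow(peaks) == 0L) return(peaks)
  thr <- sort(peaks$score, decreasing = TRUE)[ceiling(fraction * nrow(peaks))]
  dplyr::filter(peaks, .data$score >= thr)
}

#' Pearson correlation of two tracks over regions
#'
#' Correlates the paired per-region mean signals of two tracks sharing a
#' bin size and layout.
#'
#' @param track_a,track_b `signal_track`s on the same layout/bin size.
#' @param regions Peak tibble with at least two regions.
#' @return The Pearson correlation coefficient.
#' @export
pearson_at_regions <- function(track_a, track_b, regions) {
  if (track_a$bin_size != track_b$bin_size ||
      !identical(track_a$genome, track_b$genome))
    stop("tracks must share bin size and genome layout")
  if (nrow(regions) < 2L) stop("at least two regions are required")
  a <- quantify_regions(track_a, regions)$signal
  b <- quantify_regions(track_b, regions)$signal
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance across regions: correlation undefined")
  stats::cor(a, b)
}

#' Write and read bedGraph tracks
#'
#' Zero-valued bins are omitted on write and restored on read.
#'
#' @param track A `signal_track`.
#' @param path File path.
#' @return `path` (write) or a `signal_track` (read).
#' @export
write_bedgraph <- function(track, path) {
  x <- as_tibble.signal_track(track)
  x <- x[x$value != 0, ]
  utils::write.table(
    data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE),
               formatC(x$value, format = "g", digits = 15)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param genome Genome layout for the track being read.
#' @param bin_size Bin size the file was written at.
#' @param normalization Normalization tag to record.
#' @export
read_bedgraph <- function(path, genome, bin_size, normalization = "raw") {
  validate_genome(genome)
  values <- lapply(genome$size, function(sz) rep(0, ceiling(sz / bin_size)))
  names(values) <- genome$chrom
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric", "numeric"))
  if (any(x$start %% bin_size != 0)) stop("bedGraph rows not aligned to bin size")
  for (ch in unique(x$chrom)) {
    rows <- x[x$chrom == ch, ]
    values[[ch]][rows$start / bin_size + 1] <- rows$value
  }
  signal_track(values, genome, bin_size, normalization)
}
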