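#' Construct a peak table
#'
#' Peaks (ChIP-seq intervals, CRMs, fragments) are plain tibbles with
#' 0-based half-open coordinates. `summit` is the offset in bp from
#' `start` to the point of highest enrichment (NA when unknown; interval
#' midpoint is then used wherever a point location is needed).
#'
#' @param chrom Character chromosome names.
#' @param start,end Integer 0-based half-open interval bounds, `start < end`.
#' @param name Peak identifiers; generated (`peak_00001`, ...) when NULL.
#' @param score Non-negative enrichment scores or NA.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param summit Offset of the summit from `start` in bp, or NA.
#' @param genome Optional genome layout; when supplied, intervals are
#'   validated against chromosome bounds.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit`.
#' @export
#' @examples
#' peak_table("chr1", 100, 200, summit = 50)
peak_table <- function(chrom, start, end, name = NULL, score = NA_real_,
                       strand = ".", summit = NA_integer_, genome = NULL) {
  n <- length(start)
  if (is.null(name)) name <- sprintf("peak_%05d", seq_len(n))
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.double(start),
    end = as.double(end),
    name = as.character(name),
    score = as.double(score),
    strand = if (length(strand) == 1L) rep(as.character(strand), n) else as.character(strand),
    summit = as.double(summit)
  )
  validate_peaks(x, genome)
}

#' Validate a peak table
#'
#' @param x A peak-like data frame (needs at least `chrom`, `start`, `end`).
#' @param genome Optional genome layout for bounds checking.
#' @return `x` as a tibble, invisibly checked.
#' @export
validate_peaks <- function(x, genome = NULL) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop("peaks must be a data frame with columns `chrom`, `start`, `end`")
  x <- tibble::as_tibble(x)
  if (!"name" %in% names(x)) x$name <- sprintf("peak_%05d", seq_len(nrow(x)))
  if (!"score" %in% names(x)) x$score <- NA_real_
  if (!"strand" %in% names(x)) x$strand <- "."
  if (!"summit" %in% names(x)) x$summit <- NA_real_
  if (any(x$start < 0)) stop("peak starts must be >= 0")
  if (any(x$end <= x$start)) stop("peaks must satisfy start < end (0-based half-open)")
  bad <- !is.na(x$summit) & (x$summit < 0 | x$summit >= x$end - x$start)
  if (any(bad)) stop("summit offsets must lie within the peak interval")
  if (!is.null(genome)) {
    validate_genome(genome)
    sz <- chrom_size(genome, x$chrom)
    if (anyNA(sz)) stop("peaks on chromosomes absent from the genome layout: ",
                        paste(unique(x$chrom[is.na(sz)]), collapse = ", "))
    if (any(x$end > sz)) stop("peak intervals exceed chromosome length")
  }
  core <- c("chrom", "start", "end", "name", "score", "strand", "summit")
  x[, c(core, setdiff(names(x), core))]
}

# absolute summit position, midpoint fallback (floor)
summit_position <- function(x) {
  ifelse(is.na(x$summit), x$start + floor((x$end - x$start) / 2), x$start + x$summit)
}

# 0-based half-open peaks -> GRanges (1-based closed); `levels` fixes a
# common seqlevel universe so cross-set comparisons stay silent
peaks_to_granges <- function(x, genome = NULL, levels = NULL) {
  seqlengths <- NULL
  if (!is.null(genome)) seqlengths <- stats::setNames(genome$size, genome$chrom)
  if (is.null(levels)) levels <- unique(x$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = levels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    seqlengths = seqlengths
  )
}
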