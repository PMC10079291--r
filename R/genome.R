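#' Construct a genome layout
#'
#' A genome layout is the coordinate universe for all interval operations:
#' a tibble with one row per chromosome and its length in base pairs.
#' All coordinates in the package are 0-based, half-open (BED convention).
#'
#' @param chrom Character vector of unique chromosome names.
#' @param size Integer vector of chromosome lengths (bp), all > 0.
#'
#' @return A tibble with columns `chrom` and `size`.
#' @export
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2e6, 1e6))
genome_layout <- function(chrom, size) {
  chrom <- as.character(chrom)
  size <- as.double(size)
  if (length(chrom) == 0L) stop("genome layout must contain at least one chromosome")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(size)) || any(size <= 0)) stop("chromosome lengths must be positive")
  tibble::tibble(chrom = chrom, size = size)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a tab-separated file with columns chromosome name
#'   and length (no header), as emitted by common genome browsers.
#'
#' @return A genome layout tibble (see [genome_layout()]).
#' @export
read_genome <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  genome_layout(x$chrom, x$size)
}

#' @rdname read_genome
#' @param genome A genome layout tibble.
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  utils::write.table(genome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_genome <- function(genome) {
  if (!is.data.frame(genome) || !all(c("chrom", "size") %in% names(genome)))
    stop("genome layout must be a data frame with columns `chrom` and `size`")
  if (anyDuplicated(genome$chrom)) stop("chromosome names must be unique")
  if (any(genome$size <= 0)) stop("chromosome lengths must be positive")
  invisible(genome)
}

chrom_size <- function(genome, chrom) {
  genome$size[match(chrom, genome$chrom)]
}
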