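#' Read peaks from BED3, BED6 or narrowPeak files
#'
#' narrowPeak column 10 (summit offset from the interval start) populates
#' `summit`; the conventional `-1` sentinel becomes NA. Malformed lines
#' raise an error naming the offending line number.
#'
#' @param path File path.
#' @param dialect One of `"auto"`, `"bed3"`, `"bed6"`, `"narrowPeak"`.
#'   `"auto"` infers the dialect from the column count (3, 6, 10).
#' @param genome Optional genome layout; intervals are validated
#'   against it when supplied.
#'
#' @return A peak tibble (see [peak_table()]).
#' @export
read_peaks <- function(path, dialect = c("auto", "bed3", "bed6", "narrowPeak"),
                       genome = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(peak_table(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  want <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L,
                 auto = ncol[1])
  if (dialect == "auto" && !want %in% c(3L, 6L, 10L))
    stop("cannot infer dialect from ", want, " columns in ", path)
  bad <- which(ncol < want)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path, ": expected >= ", want,
         " fields, found ", ncol[bad[1]])
  m <- do.call(rbind, lapply(fields, `[`, seq_len(want)))
  start <- suppressWarnings(as.double(m[, 2]))
  end <- suppressWarnings(as.double(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path, ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path,
         ": empty or inverted interval (start >= end)")
  name <- if (want >= 6L) m[, 4] else sprintf("peak_%05d", seq_along(start))
  score <- if (want >= 6L) suppressWarnings(as.double(m[, 5])) else NA_real_
  strand <- if (want >= 6L) m[, 6] else "."
  summit <- NA_real_
  if (want == 10L) {
    score <- suppressWarnings(as.double(m[, 7]))  # signalValue
    summit <- suppressWarnings(as.double(m[, 10]))
    summit[!is.na(summit) & summit < 0] <- NA_real_
  }
  peak_table(m[, 1], start, end, name = name, score = score,
             strand = strand, summit = summit, genome = genome)
}

#' Write peaks to BED3, BED6 or narrowPeak
#'
#' @param x A peak tibble.
#' @param path Output file path.
#' @param dialect Output dialect. narrowPeak writes the summit offset in
#'   column 10 (`-1` when absent).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, dialect = c("narrowPeak", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  x <- validate_peaks(x)
  score <- ifelse(is.na(x$score), 0, x$score)
  out <- switch(dialect,
    bed3 = data.frame(x$chrom, x$start, x$end),
    bed6 = data.frame(x$chrom, x$start, x$end, x$name, score, x$strand),
    narrowPeak = data.frame(x$chrom, x$start, x$end, x$name, 0L, x$strand,
                            score, -1, -1,
                            ifelse(is.na(x$summit), -1, x$summit))
  )
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a gene-model table
#'
#' Gene models are tibbles with one row per gene and list-columns of
#' absolute exon bounds. The TSS is `start` on `+` genes and `end` on
#' `-` genes; the TTS is the opposite terminus.
#'
#' @param gene_id Gene identifiers (unique).
#' @param chrom,strand,start,end Gene span (0-based half-open) and strand.
#' @param exon_starts,exon_ends Lists of integer vectors: sorted,
#'   non-overlapping exons contained in the gene span. Defaults to the
#'   single-exon gene span.
#'
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `exon_starts`, `exon_ends`.
#' @export
gene_table <- function(gene_id, chrom, strand, start, end,
                       exon_starts = NULL, exon_ends = NULL) {
  n <- length(gene_id)
  if (is.null(exon_starts)) exon_starts <- as.list(as.double(start))
  if (is.null(exon_ends)) exon_ends <- as.list(as.double(end))
  x <- tibble::tibble(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    start = as.double(start),
    end = as.double(end),
    exon_starts = lapply(exon_starts, as.double),
    exon_ends = lapply(exon_ends, as.double)
  )
  validate_genes(x)
}

#' @rdname gene_table
#' @param x A gene-model data frame to validate.
#' @export
validate_genes <- function(x) {
  need <- c("gene_id", "chrom", "strand", "start", "end", "exon_starts", "exon_ends")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("gene models must contain columns ", paste(need, collapse = ", "))
  x <- tibble::as_tibble(x)
  if (anyDuplicated(x$gene_id)) stop("gene ids must be unique")
  if (!all(x$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(x$end <= x$start)) stop("gene span must satisfy start < end")
  ok <- purrr::pmap_lgl(
    list(x$exon_starts, x$exon_ends, x$start, x$end),
    function(es, ee, s, e) {
      length(es) == length(ee) && length(es) >= 1L &&
        all(es < ee) && all(es >= s) && all(ee <= e) &&
        !is.unsorted(es) && all(utils::head(ee, -1) <= utils::tail(es, -1))
    }
  )
  if (!all(ok)) stop("exons must be sorted, non-overlapping and within the gene span")
  x[, need]
}

#' Read gene models from BED12 or GTF-lite files
#'
#' BED12 block fields define exons. GTF-lite means a GTF whose `exon`
#' features carry a `gene_id` attribute; 1-based closed GTF coordinates
#' are converted to 0-based half-open on read.
#'
#' @param path File path.
#' @param format `"bed12"` or `"gtf"`.
#' @return A gene-model tibble (see [gene_table()]).
#' @export
read_genes <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "bed12") {
    m <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
    if (ncol(m) < 12L) stop("BED12 requires 12 columns, found ", ncol(m))
    start <- as.double(m[, 2]); end <- as.double(m[, 3])
    sizes <- strsplit(sub(",$", "", m[, 11]), ",")
    offs <- strsplit(sub(",$", "", m[, 12]), ",")
    es <- purrr::map2(offs, start, ~ as.double(.x) + .y)
    ee <- purrr::map2(es, sizes, ~ .x + as.double(.y))
    gene_table(m[, 4], m[, 1], m[, 6], start, end, es, ee)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 9L)) stop("malformed GTF line: fewer than 9 fields")
    m <- do.call(rbind, lapply(f, `[`, 1:9))
    keep <- m[, 3] == "exon"
    if (!any(keep)) stop("GTF contains no exon features")
    m <- m[keep, , drop = FALSE]
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", m[, 9])
    ex <- tibble::tibble(
      gene_id = gid, chrom = m[, 1], strand = m[, 7],
      start = as.double(m[, 4]) - 1, end = as.double(m[, 5])
    ) |>
      dplyr::arrange(.data$gene_id, .data$start) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(
        chrom = dplyr::first(.data$chrom), strand = dplyr::first(.data$strand),
        exon_starts = list(.data$start), exon_ends = list(.data$end),
        gstart = min(.data$start), gend = max(.data$end), .groups = "drop"
      )
    gene_table(ex$gene_id, ex$chrom, ex$strand, ex$gstart, ex$gend,
               ex$exon_starts, ex$exon_ends)
  }
}

#' @rdname read_genes
#' @param x A gene-model tibble.
#' @export
write_genes_bed12 <- function(x, path) {
  x <- validate_genes(x)
  sizes <- purrr::map2_chr(x$exon_starts, x$exon_ends,
                           ~ paste0(paste(.y - .x, collapse = ","), ","))
  offs <- purrr::map2_chr(x$exon_starts, x$start,
                          ~ paste0(paste(.x - .y, collapse = ","), ","))
  out <- data.frame(x$chrom, x$start, x$end, x$gene_id, 0L, x$strand,
                    x$start, x$end, "0,0,0", lengths(x$exon_starts),
                    sizes, offs)
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}
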