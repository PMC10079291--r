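#' Flag query peaks that overlap any subject peak
#'
#' Overlap means at least one shared base pair under 0-based half-open
#' semantics; adjacent intervals (`end == start`) do not overlap.
#'
#' @param query,subject Peak tibbles on a shared genome layout.
#'
#' @return The query tibble with a logical `hit` column, row order
#'   preserved.
#' @export
#' @examples
#' a <- peak_table("chr1", c(10, 40), c(20, 50))
#' b <- peak_table("chr1", 19, 30)
#' overlap_any(a, b)$hit
overlap_any <- function(query, subject) {
  query <- validate_peaks(query)
  subject <- validate_peaks(subject)
  dplyr::mutate(query, hit = overlap_flags(query, subject))
}

overlap_flags <- function(query, subject) {
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  if (nrow(query) == 0L) return(logical(0))
  lv <- union(unique(query$chrom), unique(subject$chrom))
  IRanges::overlapsAny(peaks_to_granges(query, levels = lv),
                       peaks_to_granges(subject, levels = lv))
}

#' Partition peaks into four histone-mark clusters
#'
#' Classifies each CRM peak by overlap with H3K27ac and H3K27me3 peak
#' sets: cluster I overlaps both marks (heterogeneous CRMs), II only
#' H3K27me3 (repressive), III only H3K27ac (active), IV neither. The
#' labels always partition the input; on the study design this package
#' emulates, the external data yielded 3548 + 1389 + 13669 + 4836 =
#' 23442 peaks over clusters I-IV.
#'
#' @param crm CRM peak tibble.
#' @param k27ac,k27me3 Mark peak tibbles (merge multiple stages with
#'   [merge_union()] first if desired).
#'
#' @return `crm` with a `cluster` factor column with levels I-IV.
#' @export
partition_by_marks <- function(crm, k27ac, k27me3) {
  crm <- validate_peaks(crm)
  ac <- overlap_flags(crm, validate_peaks(k27ac))
  me <- overlap_flags(crm, validate_peaks(k27me3))
  cluster <- dplyr::case_when(
    ac & me ~ "I",
    !ac & me ~ "II",
    ac & !me ~ "III",
    .default = "IV"
  )
  dplyr::mutate(crm, cluster = factor(cluster, levels = c("I", "II", "III", "IV")))
}

#' Two-set Venn labels over peak lists
#'
#' Labels every peak of both inputs: a peak is `shared` when it overlaps
#' any peak of the other set, otherwise `a_only`/`b_only`. Peaks are
#' counted once in their own set; reciprocally overlapping pairs are not
#' re-merged.
#'
#' @param a,b Peak tibbles on a shared layout.
#' @return A tibble of all peaks with columns `set` (`"a"`/`"b"`) and
#'   `label` (`shared`, `a_only`, `b_only`).
#' @export
venn_two <- function(a, b) {
  a <- validate_peaks(a)
  b <- validate_peaks(b)
  la <- ifelse(overlap_flags(a, b), "shared", "a_only")
  lb <- ifelse(overlap_flags(b, a), "shared", "b_only")
  dplyr::bind_rows(
    dplyr::mutate(a, set = "a", label = la),
    dplyr::mutate(b, set = "b", label = lb)
  )
}

#' Merge peak sets into maximal disjoint intervals
#'
#' Overlapping or book-ended (zero-gap) intervals across all inputs are
#' collapsed. The merged peak inherits the summit of its highest-score
#' constituent (leftmost summit when scores are all absent) and the
#' maximum constituent score.
#'
#' @param ... Peak tibbles, or a single list of them.
#' @return A merged peak tibble, sorted by chromosome and start.
#' @export
merge_union <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !is.data.frame(sets[[1]])) sets <- sets[[1]]
  x <- dplyr::bind_rows(lapply(sets, validate_peaks))
  if (nrow(x) == 0L) return(validate_peaks(x))
  gr <- peaks_to_granges(x)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  x$merged <- grp
  x$abs_summit <- summit_position(x)
  pick <- x |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$merged) |>
    dplyr::arrange(dplyr::desc(dplyr::coalesce(.data$score, -Inf)),
                   .data$abs_summit, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$merged)
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = as.double(GenomicRanges::end(red)),
    name = sprintf("merged_%05d", seq_along(red)),
    score = pick$score,
    strand = ".",
    summit = pick$abs_summit - (GenomicRanges::start(red) - 1)
  )
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  validate_peaks(out)
}

# distance from a point to a gene span: 0 inside, else gap to the
# nearer terminus (point at `end` is 1 bp away)
point_gene_distance <- function(pos, gstart, gend) {
  dplyr::case_when(
    pos >= gstart & pos < gend ~ 0,
    pos < gstart ~ gstart - pos,
    .default = pos - (gend - 1)
  )
}

#' Assign each peak to its nearest gene within a distance cutoff
#'
#' Distance is measured from the peak summit (interval midpoint when the
#' summit is absent) to the gene span: zero inside the span, otherwise
#' the bp gap to the nearer terminus. Peaks farther than `max_distance`
#' from every gene are left unassigned. Ties resolve to the smallest
#' distance, then the lexicographically smallest gene id.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble (non-empty).
#' @param max_distance Maximum assignment distance in bp (default
#'   10000, the 10 kb convention for CRM-gene association).
#'
#' @return `peaks` with `gene_id` (NA when unassigned) and `gene_distance`.
#' @export
nearest_gene <- function(peaks, genes, max_distance = 10000) {
  peaks <- validate_peaks(peaks)
  genes <- validate_genes(genes)
  if (nrow(genes) == 0L) stop("gene models must be non-empty")
  pos <- summit_position(peaks)
  gene_id <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    g <- genes[genes$chrom == ch, ]
    if (nrow(g) == 0L) next
    g <- g[order(g$gene_id), ]
    d <- outer(pos[pi], g$start, function(p, s) s - p)
    inside <- outer(pos[pi], seq_len(nrow(g)),
                    function(p, j) p >= g$start[j] & p < g$end[j])
    d_right <- outer(pos[pi], g$end, function(p, e) p - (e - 1))
    dmat <- ifelse(inside, 0, pmax(d, d_right))
    best <- apply(dmat, 1L, which.min)  # first index = smallest gene_id on ties
    bd <- dmat[cbind(seq_along(pi), best)]
    ok <- bd <= max_distance
    gene_id[pi[ok]] <- g$gene_id[best[ok]]
    dist[pi[ok]] <- bd[ok]
  }
  dplyr::mutate(peaks, gene_id = gene_id, gene_distance = dist)
}

#' Annotate peaks with genomic features
#'
#' Classifies the summit point (midpoint fallback) of each peak into one
#' of five features. The promoter is the strand-aware window from 1 kb
#' upstream to 100 bp downstream of the TSS; the TTS window runs from
#' 100 bp upstream to 1 kb downstream of the transcription termination
#' site. A point matching several features takes the highest-priority
#' label: promoter > TTS > exon > intron > intergenic.
#'
#' @param peaks Peak tibble.
#' @param genes Gene-model tibble with strand and exons.
#' @param promoter_upstream,promoter_downstream Promoter window in bp
#'   around the TSS (defaults 1000 and 100).
#' @param tts_upstream,tts_downstream TTS window in bp (defaults 100 and
#'   1000).
#'
#' @return `peaks` with a `feature` factor column.
#' @export
annotate_features <- function(peaks, genes,
                              promoter_upstream = 1000, promoter_downstream = 100,
                              tts_upstream = 100, tts_downstream = 1000) {
  peaks <- validate_peaks(peaks)
  genes <- validate_genes(genes)
  pos <- summit_position(peaks)
  levels <- c("promoter", "TTS", "exon", "intron", "intergenic")
  prio <- rep(5L, nrow(peaks))
  plus <- genes$strand == "+"
  win <- tibble::tibble(
    chrom = rep(genes$chrom, 4),
    start = c(ifelse(plus, genes$start - promoter_upstream, genes$end - promoter_downstream),
              ifelse(plus, genes$end - tts_upstream, genes$start - tts_downstream),
              genes$start, genes$start),
    end = c(ifelse(plus, genes$start + promoter_downstream, genes$end + promoter_upstream),
            ifelse(plus, genes$end + tts_downstream, genes$start + tts_upstream),
            genes$end, genes$end),
    prio = rep(c(1L, 2L, 4L, 4L), each = nrow(genes))
  )
  # exon windows (priority 3) expanded from list-columns
  ex <- tibble::tibble(
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = unlist(genes$exon_starts),
    end = unlist(genes$exon_ends),
    prio = 3L
  )
  win <- dplyr::bind_rows(win[seq_len(2 * nrow(genes)), ], ex,
                          win[2 * nrow(genes) + seq_len(nrow(genes)), ])
  win <- dplyr::filter(win, .data$end > .data$start)
  win$start <- pmax(win$start, 0)
  if (nrow(win) > 0L && nrow(peaks) > 0L) {
    lv <- union(unique(peaks$chrom), unique(win$chrom))
    pgr <- GenomicRanges::GRanges(factor(peaks$chrom, levels = lv),
                                  IRanges::IRanges(pos + 1, pos + 1))
    wgr <- GenomicRanges::GRanges(factor(win$chrom, levels = lv),
                                  IRanges::IRanges(win$start + 1, win$end))
    hit <- GenomicRanges::findOverlaps(pgr, wgr)
    if (length(hit)) {
      q <- S4Vectors::queryHits(hit)
      p <- win$prio[S4Vectors::subjectHits(hit)]
      best <- tapply(p, q, min)
      prio[as.integer(names(best))] <- as.integer(best)
    }
  }
  dplyr::mutate(peaks, feature = factor(levels[prio], levels = levels))
}

#' Draw random regions uniformly over a genome
#'
#' Each requested length is placed uniformly over all valid start
#' positions genome-wide (chromosomes weighted by the number of valid
#' starts). Used as the negative control for region-level signal
#' comparisons. A fixed seed gives byte-identical output.
#'
#' @param genome Genome layout tibble.
#' @param lengths Integer vector of region lengths (bp).
#' @param seed Integer RNG seed.
#'
#' @return A peak tibble of `length(lengths)` regions.
#' @export
random_regions <- function(genome, lengths, seed) {
  validate_genome(genome)
  if (length(lengths) == 0L)
    return(peak_table(character(), integer(), integer()))
  if (any(lengths <= 0)) stop("region lengths must be positive")
  if (any(lengths > max(genome$size)))
    stop("region length exceeds the longest chromosome")
  withr::with_seed(seed, {
    chrom <- character(length(lengths))
    start <- double(length(lengths))
    for (L in unique(lengths)) {
      idx <- which(lengths == L)
      w <- pmax(genome$size - L + 1, 0)
      ci <- sample.int(nrow(genome), length(idx), replace = TRUE, prob = w)
      chrom[idx] <- genome$chrom[ci]
      start[idx] <- floor(stats::runif(length(idx)) * w[ci])
    }
    peak_table(chrom, start, start + lengths,
               name = sprintf("random_%05d", seq_along(lengths)),
               genome = genome)
  })
}
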