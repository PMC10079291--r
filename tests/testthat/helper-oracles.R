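# Shared fixtures and brute-force oracles. The oracles deliberately use
# naive per-element scans so they stay independent of the interval code
# they check.

test_genome <- function(sizes = c(chrA = 100000, chrB = 60000)) {
  genome_layout(names(sizes), sizes)
}

rand_peaks <- function(n, genome, seed, max_width = 500, with_summit = FALSE) {
  withr::with_seed(seed, {
    ci <- sample.int(nrow(genome), n, replace = TRUE)
    w <- sample.int(max_width, n, replace = TRUE)
    start <- floor(runif(n) * (genome$size[ci] - w))
    summit <- if (with_summit) floor(runif(n) * w) else NA_real_
    peak_table(genome$chrom[ci], start, start + w,
               score = round(runif(n) * 100, 3), summit = summit,
               genome = genome)
  })
}

rand_genes <- function(n, genome, seed, max_len = 3000) {
  withr::with_seed(seed, {
    ci <- sample.int(nrow(genome), n, replace = TRUE)
    len <- 100 + sample.int(max_len, n, replace = TRUE)
    start <- floor(runif(n) * (genome$size[ci] - len))
    nex <- sample.int(3, n, replace = TRUE)
    ex <- purrr::pmap(list(start, start + len, nex), function(s, e, k) {
      if (k == 1) return(list(starts = s, ends = e))
      cuts <- sort(sample(seq(s + 10, e - 10, by = 10), 2 * (k - 1)))
      list(starts = c(s, cuts[seq(2, length(cuts), 2)]),
           ends = c(cuts[seq(1, length(cuts), 2)], e))
    })
    gene_table(sprintf("g%03d", sample.int(9 * n, n)), genome$chrom[ci],
               sample(c("+", "-"), n, replace = TRUE), start, start + len,
               purrr::map(ex, "starts"), purrr::map(ex, "ends"))
  })
}

# half-open single-pair overlap predicate
pair_overlaps <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 < e2 & s2 < e1
}

oracle_overlap_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(pair_overlaps(query$chrom[i], query$start[i], query$end[i],
                      subject$chrom, subject$start, subject$end))
  }, logical(1))
}

oracle_partition <- function(crm, k27ac, k27me3) {
  ac <- oracle_overlap_any(crm, k27ac)
  me <- oracle_overlap_any(crm, k27me3)
  ifelse(ac & me, "I", ifelse(me, "II", ifelse(ac, "III", "IV")))
}

oracle_summit <- function(x) {
  ifelse(is.na(x$summit), x$start + floor((x$end - x$start) / 2),
         x$start + x$summit)
}

oracle_nearest <- function(peaks, genes, max_distance = 10000) {
  pos <- oracle_summit(peaks)
  out_id <- rep(NA_character_, nrow(peaks))
  out_d <- rep(NA_real_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    best_d <- Inf; best_id <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      p <- pos[i]; s <- genes$start[j]; e <- genes$end[j]
      d <- if (p >= s && p < e) 0 else if (p < s) s - p else p - (e - 1)
      if (d < best_d || (d == best_d && genes$gene_id[j] < best_id)) {
        best_d <- d; best_id <- genes$gene_id[j]
      }
    }
    if (best_d <= max_distance) {
      out_id[i] <- best_id; out_d[i] <- best_d
    }
  }
  list(gene_id = out_id, distance = out_d)
}

oracle_annotate <- function(peaks, genes) {
  pos <- oracle_summit(peaks)
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- pos[i]; ch <- peaks$chrom[i]
    label <- "intergenic"
    prio <- 5
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != ch) next
      s <- genes$start[j]; e <- genes$end[j]
      if (genes$strand[j] == "+") {
        prom <- c(s - 1000, s + 100); tts <- c(e - 100, e + 1000)
      } else {
        prom <- c(e - 100, e + 1000); tts <- c(s - 1000, s + 100)
      }
      in_win <- function(w) p >= max(w[1], 0) && p < w[2]
      if (in_win(prom) && prio > 1) { label <- "promoter"; prio <- 1 }
      if (in_win(tts) && prio > 2) { label <- "TTS"; prio <- 2 }
      exon <- any(p >= genes$exon_starts[[j]] & p < genes$exon_ends[[j]])
      if (exon && prio > 3) { label <- "exon"; prio <- 3 }
      if (p >= s && p < e && !exon && prio > 4) { label <- "intron"; prio <- 4 }
    }
    label
  }, character(1))
}

# sweep-line merge of possibly overlapping/book-ended intervals
oracle_merge <- function(x) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    xi <- x[x$chrom == ch, ]
    xi <- xi[order(xi$start, xi$end), ]
    cs <- xi$start[1]; ce <- xi$end[1]
    for (i in seq_len(nrow(xi))[-1]) {
      if (xi$start[i] <= ce) ce <- max(ce, xi$end[i])
      else { out[[length(out) + 1]] <- c(ch, cs, ce); cs <- xi$start[i]; ce <- xi$end[i] }
    }
    out[[length(out) + 1]] <- c(ch, cs, ce)
  }
  m <- do.call(rbind, out)
  tibble::tibble(chrom = m[, 1], start = as.numeric(m[, 2]),
                 end = as.numeric(m[, 3]))
}

# upper-tail hypergeometric p by direct enumeration over all tables
# compatible with the margins
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  sum(probs[xs >= a])
}

# per-bp expansion oracle for region quantification
oracle_region_mean <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  per_bp <- rep(v, each = track$bin_size)
  per_bp <- per_bp[seq_len(chrom_size_helper(track$genome, chrom))]
  mean(per_bp[(start + 1):end])
}

chrom_size_helper <- function(genome, chrom) {
  genome$size[match(chrom, genome$chrom)]
}
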