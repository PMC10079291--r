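# uniform 1x fragment tiling of a genome
tile_fragments <- function(genome, width = 100) {
  purrr::map2_dfr(genome$chrom, genome$size, function(ch, sz) {
    starts <- seq(0, sz - width, by = width)
    tibble::tibble(chrom = ch, start = starts, end = starts + width)
  })
}

test_that("RPGC scales uniform 1x coverage to 1 everywhere", {
  g <- test_genome(c(c1 = 10000, c2 = 4000))
  tr <- binned_coverage(tile_fragments(g), g, bin_size = 50, mode = "RPGC")
  expect_true(all(abs(unlist(tr$values) - 1) < 1e-12))
})

test_that("BPM bin values always sum to one million", {
  g <- test_genome(c(c1 = 9973, c2 = 5011))  # truncated last bins
  frags <- rand_peaks(400, g, seed = 2, max_width = 300)
  tr <- binned_coverage(frags, g, bin_size = 50, mode = "BPM")
  expect_equal(sum(unlist(tr$values)), 1e6, tolerance = 1e-9)
  # duplicating every fragment leaves BPM values unchanged
  tr2 <- binned_coverage(dplyr::bind_rows(frags, frags), g,
                         bin_size = 50, mode = "BPM")
  expect_equal(tr2$values, tr$values, tolerance = 1e-12)
})

test_that("normalizing an empty track errors while raw succeeds", {
  g <- test_genome(c(c1 = 1000))
  empty <- tibble::tibble(chrom = character(), start = double(),
                          end = double())
  expect_error(binned_coverage(empty, g, mode = "BPM"), "zero total")
  expect_equal(sum(unlist(binned_coverage(empty, g)$values)), 0)
})

test_that("summit matrices have the documented shape and center behavior", {
  g <- test_genome(c(c1 = 100000))
  frags <- rand_peaks(300, g, seed = 9, max_width = 400)
  tr <- binned_coverage(frags, g, bin_size = 50)
  peaks <- rand_peaks(20, g, seed = 10, with_summit = TRUE)
  m <- matrix_at_summits(tr, peaks)
  expect_equal(dim(m), c(20, 100))
  # constant track -> constant matrix away from edges
  const <- signal_track(list(c1 = rep(3, 2000)), g, 50)
  mc <- matrix_at_summits(const, peak_table("c1", 50000, 50200, summit = 100))
  expect_true(all(mc == 3))
  # a point mass at the summit maximizes the central bin
  pk <- peak_table("c1", 50000, 50200, summit = 100)
  point <- tibble::tibble(chrom = "c1", start = 50095, end = 50115)
  tp <- binned_coverage(point, g, bin_size = 50)
  row <- matrix_at_summits(tp, pk)[1, ]
  expect_equal(which.max(row), 51)  # bin covering [summit, summit + 50)
  # out-of-chromosome window positions are zero-filled
  edge <- matrix_at_summits(const, peak_table("c1", 0, 200, summit = 100))
  expect_true(any(edge[1, ] == 0))
  expect_equal(unname(edge[1, 100]), 3)
})

test_that("metagene profiles are flat on constant tracks and strand-mirrored", {
  g <- test_genome(c(c1 = 100000))
  const <- signal_track(list(c1 = rep(2, 2000)), g, 50)
  gp <- gene_table("g1", "c1", "+", 40000, 50000)
  prof <- metagene_profile(const, gp)
  expect_equal(nrow(prof), 300)
  expect_true(all(abs(prof$signal - 2) < 1e-12))
  # asymmetric signal: a - strand gene mirrors the + strand readout
  v <- rep(0, 2000); v[801:1000] <- 5  # [40000, 50000) left half hot
  tr <- signal_track(list(c1 = v), g, 50)
  pp <- metagene_profile(tr, gene_table("g1", "c1", "+", 40000, 50000))
  pm <- metagene_profile(tr, gene_table("g1", "c1", "-", 40000, 50000))
  expect_equal(pm$signal, rev(pp$signal), tolerance = 1e-12)
})

test_that("gene bodies rescale equivariantly with gene length", {
  g <- test_genome(c(c1 = 100000))
  # pattern at 20 bp blocks on a length-L gene, stretched 2x on a 2L gene
  vals <- rep(0, 5000)
  pattern <- rep(c(1, 4, 2, 5), each = 5)       # 20 bins of 10 bp = 200 bp? no:
  # gene1: [10000, 12000), 2000 bp, pattern blocks of 100 bp
  block <- c(1, 4, 2, 5, 3, 6, 2, 8, 1, 7, 4, 2, 5, 9, 3, 1, 6, 2, 4, 8)
  v1 <- rep(0, 5000)
  v1[(10000 / 20 + 1):(12000 / 20)] <- rep(block, each = 5)
  v1[(30000 / 20 + 1):(34000 / 20)] <- rep(block, each = 10)
  tr <- signal_track(list(c1 = v1), g, 20)
  genes <- gene_table(c("a", "b"), "c1", "+", c(10000, 30000),
                      c(12000, 34000))
  pa <- metagene_profile(tr, genes[1, ], flank = 1000, body_bins = 100)
  pb <- metagene_profile(tr, genes[2, ], flank = 1000, body_bins = 100)
  expect_equal(pa$signal[pa$segment == "body"],
               pb$signal[pb$segment == "body"], tolerance = 1e-12)
})

test_that("short genes are skipped with a warning", {
  g <- test_genome(c(c1 = 10000))
  tr <- signal_track(list(c1 = rep(1, 200)), g, 50)
  genes <- gene_table(c("tiny", "ok"), "c1", "+", c(100, 2000), c(150, 4000))
  expect_warning(p <- metagene_profile(tr, genes, flank = 100), "skipped")
  expect_equal(nrow(p), 2 * 2 + 100)
})

test_that("region quantification matches a per-bp oracle with partial bins", {
  g <- test_genome(c(c1 = 10007))
  frags <- rand_peaks(300, g, seed = 4, max_width = 150)
  tr <- binned_coverage(frags, g, bin_size = 50)
  regions <- rand_peaks(50, g, seed = 5, max_width = 333)
  got <- quantify_regions(tr, regions)
  for (i in seq_len(10)) {
    expect_equal(got$signal[i],
                 oracle_region_mean(tr, regions$chrom[i], regions$start[i],
                                    regions$end[i]),
                 tolerance = 1e-9)
  }
  # constant track -> the constant, for every region
  const <- signal_track(list(c1 = rep(7, ceiling(10007 / 50))), g, 50)
  expect_true(all(quantify_regions(const, regions)$signal == 7))
  # additivity of sums over split regions
  s <- quantify_regions(tr, peak_table("c1", 1000, 2000), "sum")$signal
  s1 <- quantify_regions(tr, peak_table("c1", 1000, 1500), "sum")$signal
  s2 <- quantify_regions(tr, peak_table("c1", 1500, 2000), "sum")$signal
  expect_equal(s, s1 + s2, tolerance = 1e-9)
})

test_that("summit-matrix row means agree with window quantification", {
  g <- test_genome(c(c1 = 100000))
  frags <- rand_peaks(500, g, seed = 6, max_width = 300)
  tr <- binned_coverage(frags, g, bin_size = 50)
  peaks <- peak_table("c1", c(30000, 60000), c(30200, 60200),
                      summit = c(100, 100))
  m <- matrix_at_summits(tr, peaks, window = 2000, bin = 50)
  pos <- peaks$start + peaks$summit
  windows <- peak_table("c1", pos - 1000, pos + 1000)
  q <- quantify_regions(tr, windows)$signal
  expect_equal(rowMeans(m), q, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("top_fraction keeps the highest-scoring peaks with inclusive ties", {
  p <- peak_table("chr1", 0:9 * 100, 0:9 * 100 + 50, score = 1:10)
  expect_equal(nrow(top_fraction(p, 1)), 10)
  expect_equal(sort(top_fraction(p, 0.3)$score), c(8, 9, 10))
  ties <- peak_table("chr1", 0:9 * 100, 0:9 * 100 + 50, score = rep(5, 10))
  expect_equal(nrow(top_fraction(ties, 0.3)), 10)
  expect_error(top_fraction(peak_table("chr1", 0, 10), 0.3), "scores")
  expect_error(top_fraction(p, 0), "fraction")
})

test_that("track correlation at regions matches the covariance formula", {
  g <- test_genome(c(c1 = 50000))
  a <- binned_coverage(rand_peaks(400, g, seed = 7, max_width = 200), g, 50)
  b <- binned_coverage(rand_peaks(400, g, seed = 8, max_width = 200), g, 50)
  regions <- rand_peaks(60, g, seed = 9)
  expect_equal(pearson_at_regions(a, a, regions), 1)
  r <- pearson_at_regions(a, b, regions)
  va <- quantify_regions(a, regions)$signal
  vb <- quantify_regions(b, regions)$signal
  expect_equal(r, sum((va - mean(va)) * (vb - mean(vb))) /
                 sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2)),
               tolerance = 1e-12)
  # anti-correlation with a complemented track
  comp <- a; comp$values <- lapply(a$values, function(v) max(v) + 1 - v)
  expect_equal(pearson_at_regions(a, comp, regions), -1, tolerance = 1e-9)
  const <- signal_track(list(c1 = rep(1, 1000)), g, 50)
  expect_error(pearson_at_regions(a, const, regions), "variance")
})

test_that("quantifications are invariant to chromosome order in the input", {
  g <- test_genome()
  frags <- rand_peaks(300, g, seed = 12, max_width = 200)
  tr1 <- binned_coverage(frags, g, 50)
  tr2 <- binned_coverage(frags[order(frags$chrom, decreasing = TRUE), ], g, 50)
  expect_equal(tr1$values, tr2$values)
})
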