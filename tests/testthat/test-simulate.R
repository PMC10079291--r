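# compact configuration keeps generator tests fast
small_config <- function(seed = 2, ...) {
  sim_config(seed = seed, n_genes = 120, reads_per_library = 2e4,
             crm_per_cluster = c(I = 90, II = 40, III = 350, IV = 120), ...)
}

test_that("simulated genes are in bounds, non-overlapping, deterministic", {
  cfg <- small_config()
  gen <- simulate_genome(cfg)
  genes <- gen$genes
  expect_equal(nrow(genes), 120)
  expect_true(all(genes$start >= 0))
  expect_true(all(genes$end <= chrom_size_helper(gen$genome, genes$chrom)))
  expect_s3_class(validate_genes(genes), "tbl_df")  # exon invariants hold
  for (ch in unique(genes$chrom)) {
    gi <- genes[genes$chrom == ch, ]
    gi <- gi[order(gi$start), ]
    if (nrow(gi) > 1) expect_true(all(gi$start[-1] >= gi$end[-nrow(gi)]))
  }
  expect_identical(simulate_genome(cfg), gen)
  expect_false(identical(simulate_genome(small_config(seed = 3)), gen))
})

test_that("gene lengths follow the configured distribution", {
  lens <- (simulate_genome(small_config(seed = 4))$genes |>
             dplyr::mutate(len = end - start))$len
  ref <- withr::with_seed(1234, pmin(8000, pmax(500, round(
    rlnorm(20000, log(3000), 0.4)))))
  expect_gt(suppressWarnings(stats::ks.test(lens, ref)$p.value), 0.01)
})

test_that("planted CRM clusters are consistent with emitted mark peaks", {
  cfg <- small_config()
  gen <- simulate_genome(cfg)
  crms <- simulate_crms(cfg, gen)
  expect_equal(unname(table(factor(crms$truth$cluster,
                                   levels = c("I", "II", "III", "IV")))[1:4]),
               unname(cfg$crm_per_cluster), ignore_attr = TRUE)
  # CRMs are mutually disjoint
  m <- crms$crm[order(crms$crm$chrom, crms$crm$start), ]
  for (ch in unique(m$chrom)) {
    mi <- m[m$chrom == ch, ]
    if (nrow(mi) > 1) expect_true(all(mi$start[-1] >= mi$end[-nrow(mi)]))
  }
  # cluster IV CRMs overlap no emitted mark peak
  iv <- crms$crm[crms$truth$cluster == "IV", ]
  expect_false(any(overlap_any(iv, crms$k27ac)$hit))
  expect_false(any(overlap_any(iv, crms$k27me3)$hit))
  # recovery by the classifier is exact on the noiseless geometry
  part <- partition_by_marks(crms$crm, crms$k27ac, crms$k27me3)
  expect_equal(as.character(part$cluster), crms$truth$cluster)
})

test_that("attached CRMs resolve to their planted gene within 10 kb", {
  cfg <- small_config(seed = 6)
  gen <- simulate_genome(cfg)
  crms <- simulate_crms(cfg, gen)
  has_gene <- !is.na(crms$truth$gene_id)
  ng <- nearest_gene(crms$crm, gen$genes)
  expect_equal(ng$gene_id[has_gene], crms$truth$gene_id[has_gene])
  expect_true(all(is.na(ng$gene_id[!has_gene])))
})

test_that("spike-in reads make up ~1/36 of untreated libraries", {
  cfg <- small_config()
  gen <- simulate_genome(cfg)
  crms <- simulate_crms(cfg, gen)
  libs <- simulate_chip(cfg, gen, crms)
  expect_length(libs, 8)  # 2 tissues x 2 treatments x 2 replicates
  dmso <- purrr::keep(libs, ~ .x$treatment == "DMSO")
  frac <- purrr::map_dbl(dmso, ~ nrow(.x$spike_fragments) /
                           (nrow(.x$fragments) + nrow(.x$spike_fragments)))
  expect_true(all(abs(frac - 1 / 36) < 0.005))
  # every fragment respects its genome layout
  for (l in libs[1:2]) {
    expect_no_error(validate_peaks(l$fragments, gen$genome))
    expect_no_error(validate_peaks(l$spike_fragments, gen$spike_genome))
  }
})

test_that("a unit treatment multiplier gives exchangeable conditions", {
  cfg <- small_config(seed = 8, tissues = "AC", tsa_multiplier = 1,
                      background_tsa_multiplier = 1)
  gen <- simulate_genome(cfg)
  crms <- simulate_crms(cfg, gen)
  libs <- simulate_chip(cfg, gen, crms)
  sig <- purrr::map(libs, function(l)
    quantify_regions(binned_coverage(l$fragments, gen$genome, 50),
                     crms$crm, statistic = "sum")$signal)
  trt <- purrr::map_chr(libs, "treatment")
  d <- do.call(cbind, sig[trt == "DMSO"])
  t <- do.call(cbind, sig[trt == "TSA"])
  # per-CRM Welch test between treatments: null should rarely reject
  p <- vapply(seq_len(nrow(d)), function(i) {
    if (stats::sd(c(d[i, ], t[i, ])) == 0) return(1)
    tryCatch(stats::t.test(d[i, ], t[i, ])$p.value, error = function(e) 1)
  }, numeric(1))
  expect_gte(mean(p > 0.01), 0.95)
})

test_that("expression tables encode the planted temporal structure", {
  cfg <- small_config()
  gen <- simulate_genome(cfg)
  crms <- simulate_crms(cfg, gen)
  expr <- simulate_expression(cfg, gen, crms$truth)
  tc <- expr$timecourse
  truth <- expr$truth
  m <- as.matrix(tc[, -1])
  h <- as.numeric(colnames(m))
  maternal <- truth$temporal_class == "maternal"
  expect_true(all(m[maternal, h == 1] > 1))
  zyg <- truth$zygotic
  expect_true(all(m[zyg, h < 2] <= 1))
  # the filter recovers exactly the planted zygotic set
  expect_setequal(zygotic_filter(tc), truth$gene_id[truth$zygotic])
  # late-class genes are silent at gastrula but active by the horizon
  late <- truth$class == "2"
  expect_true(all(m[late, h == 10] < 1))
  expect_true(all(apply(m[late, , drop = FALSE], 1, max) >= 1))
})

test_that("tissue tables and DE tables honor their planted labels", {
  cfg <- small_config(seed = 9, gene_sigma = 0, cell_sigma = 0)
  gen <- simulate_genome(cfg)
  crms <- simulate_crms(cfg, gen)
  expr <- simulate_expression(cfg, gen, crms$truth)
  got <- spatial_gene_category(expr$tissues)
  expect_equal(as.character(got$category), expr$truth$category)
  up <- de_threshold_filter(expr$de_ac)$up
  expect_setequal(intersect(up, expr$truth$gene_id[expr$truth$class == "2"]),
                  expr$truth$gene_id[expr$truth$activated])
})

test_that("the full dataset is deterministic and file outputs re-read", {
  cfg <- small_config()
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$crm, d2$crm)
  expect_identical(d1$timecourse, d2$timecourse)
  expect_identical(d1$libraries[[1]]$fragments, d2$libraries[[1]]$fragments)
  dir <- withr::local_tempdir()
  write_dataset(d1, dir)
  genome_all <- read_genome(file.path(dir, "chrom.sizes"))
  expect_equal(genome_all[1:2, ], d1$genome)
  genes <- read_genes(file.path(dir, "genes.bed12"))
  expect_equal(genes, d1$genes)
  crm <- read_peaks(file.path(dir, "crm.narrowPeak"), genome = d1$genome)
  expect_equal(crm[, c("chrom", "start", "end", "summit")],
               d1$crm[, c("chrom", "start", "end", "summit")])
  tr <- read_bedgraph(file.path(dir, paste0(d1$libraries[[1]]$sample_id,
                                            ".bedGraph")),
                      d1$genome, bin_size = 50)
  ref <- binned_coverage(d1$libraries[[1]]$fragments, d1$genome, 50)
  expect_equal(tr$values, ref$values, tolerance = 1e-12)
})
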