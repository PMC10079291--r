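make_timecourse <- function(...) {
  rows <- list(...)
  out <- tibble::tibble(gene_id = names(rows))
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

test_that("gene classes follow the cluster set algebra", {
  genes <- gene_table(paste0("g", 1:5), "chr1", "+",
                      (1:5) * 50000, (1:5) * 50000 + 2000)
  near <- function(i) peak_table("chr1", i * 50000 - 3000, i * 50000 - 2800)
  cluster_peaks <- list(
    I = near(1),
    II = dplyr::bind_rows(near(2), near(3)),
    III = dplyr::bind_rows(near(3), near(4)))
  got <- gene_classes(cluster_peaks, genes)
  expect_equal(as.character(got$class),
               c("1", "2", "1", "3", "unclassified"))
  # classes 1-3 pairwise disjoint by construction
  expect_equal(anyDuplicated(got$gene_id), 0)
})

test_that("gene classes match an independent set-algebra evaluation", {
  g <- test_genome(c(chrA = 1e6))
  genes <- rand_genes(60, g, seed = 21)
  cluster_peaks <- list(I = rand_peaks(30, g, seed = 22),
                        II = rand_peaks(25, g, seed = 23),
                        III = rand_peaks(40, g, seed = 24))
  got <- gene_classes(cluster_peaks, genes)
  sets <- lapply(cluster_peaks, function(p) {
    o <- oracle_nearest(p, genes)
    unique(o$gene_id[!is.na(o$gene_id)])
  })
  c1 <- union(sets$I, intersect(sets$II, sets$III))
  c2 <- setdiff(sets$II, c1)
  c3 <- setdiff(sets$III, c1)
  expect_setequal(got$gene_id[got$class == "1"], c1)
  expect_setequal(got$gene_id[got$class == "2"], c2)
  expect_setequal(got$gene_id[got$class == "3"], c3)
  expect_length(intersect(c2, c3), 0)
})

test_that("the zygotic filter removes maternal and never-expressed genes", {
  tc <- make_timecourse(
    maternal = c(5, 3, 1, 0.2, 0.1),
    silent = c(0, 0, 0, 0.5, 0.9),
    zygotic = c(0.2, 0.5, 0.8, 4, 9),
    boundary = c(1, 1, 1, 1, 1))
  names(tc)[-1] <- c("0", "1", "4", "8", "23")
  kept <- zygotic_filter(tc)
  # maternal: 5 TPM at 0 hpf -> removed; silent: never reaches 1 -> removed;
  # boundary: exactly 1 TPM passes both rules (<= maternal cap, >= floor)
  expect_setequal(kept, c("zygotic", "boundary"))
  expect_error(zygotic_filter(tc, maternal_window_hpf = -1), "maternal window")
})

test_that("zygotic filtering is monotone in the TPM threshold", {
  g <- test_genome()
  cfg <- sim_config(seed = 5, n_genes = 100,
                    crm_per_cluster = c(I = 60, II = 30, III = 250, IV = 60))
  gen <- simulate_genome(cfg)
  crms <- simulate_crms(cfg, gen)
  expr <- simulate_expression(cfg, gen, crms$truth)
  thresholds <- c(0.5, 1, 2, 5)
  removed_maternal <- removed_floor <- integer(length(thresholds))
  h <- as.numeric(setdiff(names(expr$timecourse), "gene_id"))
  m <- as.matrix(expr$timecourse[, -1])
  for (i in seq_along(thresholds)) {
    thr <- thresholds[i]
    removed_maternal[i] <- sum(apply(m[, h <= 2, drop = FALSE] > thr, 1, any))
    removed_floor[i] <- sum(apply(m[, h <= 23], 1, max) < thr)
  }
  expect_true(all(diff(removed_maternal) <= 0))  # rule 1 shrinks
  expect_true(all(diff(removed_floor) >= 0))     # rule 2 grows
  # and the filter itself agrees with the two rules combined
  kept <- zygotic_filter(expr$timecourse, tpm_threshold = 2)
  manual <- expr$timecourse$gene_id[
    apply(m[, h <= 2, drop = FALSE] <= 2, 1, all) &
      apply(m[, h <= 23], 1, max) >= 2]
  expect_setequal(kept, manual)
})

test_that("class trends are per-time means, invariant to gene order", {
  tc <- make_timecourse(a = c(1, 2, 3), b = c(3, 4, 5), c = c(10, 10, 10))
  names(tc)[-1] <- c("0", "4", "8")
  cls <- tibble::tibble(gene_id = c("a", "b", "c"),
                        class = factor(c("1", "1", "2"),
                                       levels = c("1", "2", "3", "unclassified")))
  tr <- suppressWarnings(class_trend(tc, cls))
  expect_equal(tr$mean_tpm[tr$class == "1"], c(2, 3, 4))
  expect_equal(tr$mean_tpm[tr$class == "2"], c(10, 10, 10))
  shuffled <- suppressWarnings(class_trend(tc[c(3, 1, 2), ], cls))
  expect_equal(shuffled, tr)
  expect_warning(class_trend(tc, cls), "empty class")
})

test_that("germ-layer categories collapse mesoderm and apply CV rules", {
  tt <- tibble::tibble(
    gene_id = c("even", "ac", "mzcollapse", "ne", "vg"),
    AC = c(5, 10, 1, 0.4, 1),
    DMZ = c(5, 1, 3, 0.4, 1),
    LMZ = c(5, 1, 6, 0.4, 1),
    VMZ = c(5, 1, 9, 0.4, 1),
    VG = c(5, 1, 1, 0.4, 8))
  got <- spatial_gene_category(tt)
  expect_equal(as.character(got$category), c("NL", "AC", "MZ", "NE", "VG"))
  expect_equal(got$mz[3], 6)  # (3 + 6 + 9) / 3
  # invariant to the order of the mesoderm columns
  reord <- spatial_gene_category(tt[, c("gene_id", "AC", "VMZ", "DMZ",
                                        "LMZ", "VG")])
  expect_equal(got$category, reord$category)
  # literal reading: any raw tissue below threshold makes a gene NE
  lit <- spatial_gene_category(
    tibble::tibble(gene_id = "x", AC = 10, DMZ = 0.9, LMZ = 5, VMZ = 5,
                   VG = 5), ne_rule = "any_tissue")
  expect_equal(as.character(lit$category), "NE")
  expect_error(spatial_gene_category(tt[, -2]), "columns")
})

test_that("DE thresholding applies strict fold and FDR cutoffs", {
  de <- tibble::tibble(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(0.9, 1.5, -2, 1.5, -0.5),
    fdr = c(0.01, 0.049, 0.001, 0.05, 0.2))
  got <- de_threshold_filter(de)
  expect_equal(got$up, "b")     # 0.9 below log2(2); d at FDR boundary fails
  expect_equal(got$down, "c")
  empty <- de_threshold_filter(de[0, ])
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
  expect_error(de_threshold_filter(dplyr::mutate(de, fdr = fdr * 30)), "FDR")
})

test_that("premature activation fraction is the class overlap share", {
  expect_equal(premature_activation_fraction(c("a", "b"), c("x")), 0)
  expect_equal(premature_activation_fraction(c("a", "b"), c("a", "b", "c")), 1)
  expect_error(premature_activation_fraction(character(), "a"), "empty")
  # planted 0.9 activation over 500 genes falls in the binomial band
  de <- simulate_de_table(sprintf("g%03d", 1:500), 0.9, seed = 31)
  up <- de_threshold_filter(de)$up
  frac <- premature_activation_fraction(de$gene_id, up)
  expect_gte(frac, qbinom(0.005, 500, 0.9) / 500)
  expect_lte(frac, qbinom(0.995, 500, 0.9) / 500)
  # thresholding recovers exactly the planted activation flags
  expect_setequal(up, de$gene_id[attr(de, "activated")])
})
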