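#' Simulation configuration
#'
#' Builds the configuration for the synthetic-data generator, which
#' emulates the full experimental design: a small multi-chromosome
#' genome with gene models, ~2000 HDAC-bound CRMs in four histone-mark
#' clusters (counts proportional to the published cluster sizes),
#' tissue-dissected pan-H3Kac ChIP libraries with an exogenous spike-in
#' chromosome at a 1:35 mass ratio, HDAC-inhibitor (TSA) treatment
#' effects, TPM time courses spanning zygotic genome activation, and
#' five-tissue spatial expression with differential-expression tables.
#' Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, reads_per_library = 2e4)
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
    spike_chrom_length = c(spike = 1e5),
    n_genes = 400L,
    gene_length_meanlog = log(3000), gene_length_sdlog = 0.4,
    max_exons = 8L,
    gene_class_fractions = c("1" = 0.3, "2" = 0.1, "3" = 0.4, none = 0.2),
    crm_per_cluster = c(I = 300L, II = 120L, III = 1170L, IV = 410L),
    crm_width = 300L,
    spatial_fractions = c(AC = 0.375, VG = 0.375, ubiquitous = 0.25),
    ac_vg_ratio = 4,
    noise_sigma = 0.2,
    spike_ratio = 1 / 35,
    reads_per_library = 1e5L,
    fragment_length = 200L,
    background_fraction = 0.3,
    tissues = c("AC", "VG"),
    treatments = c("DMSO", "TSA"),
    replicates = 2L,
    tsa_multiplier = c(I = 3, II = 5, III = 2, IV = 3),
    background_tsa_multiplier = 1,
    n_spike_peaks = 40L, spike_peak_width = 500L,
    hpf = 0:23,
    zga_onset_hpf = 4, late_onset_hpf = 12,
    maternal_fraction = 0.4, silent_fraction = 0.1,
    tissue_fold = 5,
    spatial_gene_fractions = c(AC = 0.2, MZ = 0.2, VG = 0.2, NL = 0.25, NE = 0.15),
    gene_sigma = 0.2, cell_sigma = 0.05,
    activation_prob = 0.9,
    de_lfc_mean = 2.5, de_lfc_sd = 0.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (length(cfg$tsa_multiplier) == 1L)
    cfg$tsa_multiplier <- stats::setNames(rep(cfg$tsa_multiplier, 4),
                                          c("I", "II", "III", "IV"))
  stopifnot(cfg$spike_ratio > 0, cfg$ac_vg_ratio > 1,
            all(cfg$crm_per_cluster >= 0), cfg$reads_per_library > 0)
  structure(cfg, class = "sim_config")
}

# place non-overlapping intervals of given widths uniformly over the
# genome with a minimum inter-interval gap (caller manages the seed)
place_intervals <- function(genome, widths, min_gap) {
  n <- length(widths)
  chrom_idx <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$size)
  out <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    idx <- which(chrom_idx == i)
    if (!length(idx)) next
    w <- widths[idx]
    k <- length(w)
    free <- genome$size[i] - sum(w) - (k + 1) * min_gap
    if (free < 0)
      stop("cannot place ", k, " intervals on ", genome$chrom[i],
           " without overlap at the requested density")
    u <- stats::runif(k + 1)
    extra <- free * u / sum(u)
    gaps <- min_gap + extra
    starts <- floor(cumsum(gaps[seq_len(k)]) + cumsum(c(0, w[-k])))
    out[[i]] <- tibble::tibble(chrom = genome$chrom[i], start = starts,
                               end = starts + w, .idx = idx)
  }
  res <- dplyr::bind_rows(out)
  res[order(res$.idx), c("chrom", "start", "end")]
}

# split a gene span into 1..max_exons exons with intervening introns
make_exons <- function(start, end, n_exons) {
  L <- end - start
  if (n_exons == 1L) return(list(starts = start, ends = end))
  k <- 2L * n_exons - 1L
  p <- stats::runif(k, 0.5, 1.5)
  bounds <- start + round(cumsum(p) / sum(p) * L)
  bounds <- c(start, bounds[-k])
  starts <- bounds[seq(1L, k, by = 2L)]
  ends <- c(bounds[seq(2L, k, by = 2L)], end)
  keep <- ends > starts
  list(starts = starts[keep], ends = ends[keep])
}

#' Simulate a genome with gene models
#'
#' Places non-overlapping genes (1-8 exons each) on the configured
#' chromosomes; deterministic under the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (layout tibble, experimental
#'   chromosomes only), `spike_genome` (layout of the spike-in
#'   chromosome) and `genes` (gene-model tibble).
#' @export
simulate_genome <- function(config) {
  genome <- genome_layout(names(config$chrom_lengths), config$chrom_lengths)
  withr::with_seed(config$seed + 101L, {
    len <- pmin(8000, pmax(500, round(stats::rlnorm(config$n_genes,
                                                    config$gene_length_meanlog,
                                                    config$gene_length_sdlog))))
    # wide gaps keep each gene's attached CRMs unambiguous under the
    # 10 kb nearest-gene convention
    pos <- place_intervals(genome, len, min_gap = 26000)
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    nex <- sample.int(config$max_exons, config$n_genes, replace = TRUE)
    ex <- purrr::pmap(list(pos$start, pos$end, nex), make_exons)
    genes <- gene_table(sprintf("gene_%04d", seq_len(config$n_genes)),
                        pos$chrom, strand, pos$start, pos$end,
                        purrr::map(ex, "starts"), purrr::map(ex, "ends"))
  })
  list(genome = genome,
       spike_genome = genome_layout(names(config$spike_chrom_length),
                                    config$spike_chrom_length),
       genes = genes)
}

# free genomic segments at least `buffer` bp away from every gene
free_segments <- function(genome, genes, buffer) {
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    bounds <- c(0, rbind(g$start - buffer, g$end + buffer), genome$size[i])
    seg <- matrix(bounds, ncol = 2, byrow = TRUE)
    tibble::tibble(chrom = ch, start = pmax(seg[, 1], 0),
                   end = pmin(seg[, 2], genome$size[i]))
  }) |> dplyr::filter(.data$end > .data$start)
}

# place intervals into fixed slots carved out of free segments; slots
# are disjoint and separated by min_gap, so placements never collide
slot_place <- function(segments, widths, min_gap, slot_w) {
  k <- pmax(0, floor((segments$end - segments$start - min_gap) /
                       (slot_w + min_gap)))
  slots <- tibble::tibble(
    chrom = rep(segments$chrom, k),
    sstart = unlist(purrr::pmap(list(segments$start, k), function(s, kk)
      s + min_gap + (seq_len(kk) - 1) * (slot_w + min_gap))))
  if (nrow(slots) < length(widths))
    stop("not enough intergenic space to place ", length(widths), " regions")
  pick <- slots[sample.int(nrow(slots), length(widths)), ]
  start <- pick$sstart + floor(stats::runif(length(widths)) *
                                 (slot_w - widths + 1))
  tibble::tibble(chrom = pick$chrom, start = start, end = start + widths)
}

#' Simulate CRMs, histone-mark peaks and ground truth
#'
#' Plants gene classes first: each gene draws a class (1, 2, 3 or none)
#' and class-bearing genes get 1-2 CRMs of the corresponding histone
#' clusters placed within 10 kb of the gene (class 1 genes carry either
#' a cluster I CRM or a cluster II + cluster III pair, mirroring the
#' set-algebra definition). The remaining per-cluster CRM budget is
#' placed in intergenic space more than 10 kb from every gene. Each
#' acetylated CRM (clusters I/III) also draws a spatial class with the
#' configured AC:VG signal ratio. Mark peak sets are emitted jittered
#' around each CRM, consistent with the true clusters, together with
#' tissue-specific pan-H3Kac peak sets and the spike-in peak set.
#'
#' @param config A [sim_config()].
#' @param gen Output of [simulate_genome()].
#' @return A list: `crm` (peak tibble), `k27ac`, `k27me3`, `pankac_ac`,
#'   `pankac_vg` (peak tibbles), `spike_peaks` (on the spike genome),
#'   `truth` (per-CRM tibble: `name`, `cluster`, `spatial`,
#'   `localization`, `gene_id`, `ac_rate`, `vg_rate`) and `gene_class`
#'   (per-gene planted class).
#' @export
simulate_crms <- function(config, gen) {
  genes <- gen$genes
  ng <- nrow(genes)
  withr::with_seed(config$seed + 202L, {
    gclass <- sample(names(config$gene_class_fractions), ng, replace = TRUE,
                     prob = config$gene_class_fractions)
    att <- purrr::map_dfr(which(gclass != "none"), function(i) {
      cl <- switch(gclass[i],
        "1" = if (stats::runif(1) < 0.2) c("II", "III") else
          rep("I", 1 + (stats::runif(1) < 0.3)),
        "2" = rep("II", 1 + (stats::runif(1) < 0.2)),
        "3" = rep("III", 1 + (stats::runif(1) < 0.4)))
      side <- if (length(cl) == 2L) c("up", "down") else
        sample(c("up", "down"), 1)
      tibble::tibble(gene = i, cluster = cl, side = side)
    })
    w_att <- round(stats::runif(nrow(att), 0.7, 1.3) * config$crm_width)
    d <- floor(stats::runif(nrow(att), 500, 8000))
    gs <- genes$start[att$gene]
    ge <- genes$end[att$gene]
    start_att <- ifelse(att$side == "up", gs - d - w_att, ge + d)
    att_tbl <- tibble::tibble(
      chrom = genes$chrom[att$gene], start = start_att,
      end = start_att + w_att, cluster = att$cluster,
      gene_id = genes$gene_id[att$gene])
    used <- table(factor(att_tbl$cluster,
                         levels = names(config$crm_per_cluster)))
    if (any(used > config$crm_per_cluster))
      stop("per-cluster CRM budget too small for the planted gene classes;",
           " raise crm_per_cluster or lower n_genes")
    remaining <- config$crm_per_cluster - as.vector(used)
    nrem <- sum(remaining)
    w_rem <- round(stats::runif(nrem, 0.7, 1.3) * config$crm_width)
    free <- free_segments(gen$genome, genes, buffer = 10400)
    rpos <- slot_place(free, w_rem, min_gap = 400,
                       slot_w = ceiling(1.3 * config$crm_width))
    rem_tbl <- dplyr::mutate(
      rpos,
      cluster = sample(rep(names(config$crm_per_cluster), remaining)),
      gene_id = NA_character_)
    all_tbl <- dplyr::bind_rows(att_tbl, rem_tbl)
    all_tbl <- all_tbl[order(all_tbl$chrom, all_tbl$start), ]
    n <- nrow(all_tbl)
    cluster <- all_tbl$cluster
    crm <- peak_table(all_tbl$chrom, all_tbl$start, all_tbl$end,
                      name = sprintf("crm_%05d", seq_len(n)),
                      score = round(stats::rlnorm(n, log(10), 0.5), 3),
                      summit = floor((all_tbl$end - all_tbl$start) / 2),
                      genome = gen$genome)
    acetylated <- cluster %in% c("I", "III")
    spatial <- rep(NA_character_, n)
    spatial[acetylated] <- sample(names(config$spatial_fractions),
                                  sum(acetylated), replace = TRUE,
                                  prob = config$spatial_fractions)
    r <- config$ac_vg_ratio
    ac_rate <- vg_rate <- rep(0, n)
    ac_rate[acetylated] <- dplyr::case_when(
      spatial[acetylated] == "AC" ~ r,
      spatial[acetylated] == "VG" ~ 1,
      .default = sqrt(r))
    vg_rate[acetylated] <- dplyr::case_when(
      spatial[acetylated] == "AC" ~ 1,
      spatial[acetylated] == "VG" ~ r,
      .default = sqrt(r))
    # weak residual acetylation on clusters II/IV keeps them detectable
    # as background without crossing pan-H3Kac peak-calling thresholds
    ac_rate[!acetylated] <- vg_rate[!acetylated] <- 0.1
    # per-CRM multiplicative lognormal noise, shared across replicates
    noise_ac <- stats::rlnorm(n, 0, config$noise_sigma)
    noise_vg <- stats::rlnorm(n, 0, config$noise_sigma)
    ac_rate <- ac_rate * noise_ac
    vg_rate <- vg_rate * noise_vg
    jitter_peaks <- function(sel, prefix) {
      k <- sum(sel)
      if (!k) return(peak_table(character(), integer(), integer()))
      s <- pmax(0, crm$start[sel] - round(stats::runif(k, 0, 100)))
      e <- pmin(chrom_size(gen$genome, crm$chrom[sel]),
                crm$end[sel] + round(stats::runif(k, 0, 100)))
      peak_table(crm$chrom[sel], s, e,
                 name = sprintf("%s_%05d", prefix, seq_len(k)),
                 score = round(stats::rlnorm(k, log(10), 0.5), 3),
                 genome = gen$genome)
    }
    k27ac <- jitter_peaks(cluster %in% c("I", "III"), "k27ac")
    k27me3 <- jitter_peaks(cluster %in% c("I", "II"), "k27me3")
    pankac_ac <- jitter_peaks(!is.na(spatial) & spatial %in% c("AC", "ubiquitous"),
                              "pankac_ac")
    pankac_vg <- jitter_peaks(!is.na(spatial) & spatial %in% c("VG", "ubiquitous"),
                              "pankac_vg")
    sw <- rep(config$spike_peak_width, config$n_spike_peaks)
    spos <- place_intervals(gen$spike_genome, sw, min_gap = 200)
    spike_peaks <- peak_table(spos$chrom, spos$start, spos$end,
                              name = sprintf("h2av_%03d", seq_len(nrow(spos))),
                              genome = gen$spike_genome)
  })
  localization <- dplyr::case_when(
    is.na(spatial) ~ "NP",
    spatial == "ubiquitous" ~ "NL",
    .default = "LC")
  truth <- tibble::tibble(
    name = crm$name, cluster = cluster, spatial = spatial,
    localization = localization, gene_id = all_tbl$gene_id,
    ac_rate = ac_rate, vg_rate = vg_rate)
  list(crm = crm, k27ac = k27ac, k27me3 = k27me3,
       pankac_ac = pankac_ac, pankac_vg = pankac_vg,
       spike_peaks = spike_peaks, truth = truth,
       gene_class = tibble::tibble(gene_id = genes$gene_id, class = gclass))
}

#' Simulate spike-in ChIP libraries
#'
#' Draws each library's fragments from per-CRM rates (spatial class
#' ratio x treatment multiplier x per-CRM noise) plus uniform
#' background, with spike-in fragments over the spike-in peak set at
#' the configured mass ratio and constant recovery across treatments:
#' under HDAC inhibition the experimental immunoprecipitated mass
#' rises, so the spike-in read share falls accordingly, which is what
#' spike-in scaling corrects for.
#'
#' @param config A [sim_config()].
#' @param gen Output of [simulate_genome()].
#' @param crms Output of [simulate_crms()].
#' @return A list of [chip_library()] objects (tissue x treatment x
#'   replicate).
#' @export
simulate_chip <- function(config, gen, crms) {
  truth <- crms$truth
  crm <- crms$crm
  fl <- config$fragment_length
  total_size <- sum(gen$genome$size)
  libraries <- list()
  seed0 <- config$seed + 303L
  li <- 0L
  for (tissue in config$tissues) {
    base_rate <- if (tissue == "VG") truth$vg_rate else truth$ac_rate
    # spike mass calibrated against the untreated IP mass of this tissue
    bg_weight0 <- sum(base_rate) * config$background_fraction /
      (1 - config$background_fraction)
    spike_weight <- (sum(base_rate) + bg_weight0) * config$spike_ratio
    for (treatment in config$treatments) {
      mult <- if (treatment == "TSA") config$tsa_multiplier[truth$cluster] else 1
      bg_mult <- if (treatment == "TSA") config$background_tsa_multiplier else 1
      rate <- base_rate * mult
      bg_weight <- bg_weight0 * bg_mult
      for (rep_i in seq_len(config$replicates)) {
        li <- li + 1L
        libraries[[li]] <- withr::with_seed(seed0 + li, {
          prob <- c(rate, bg_weight, spike_weight)
          counts <- as.vector(stats::rmultinom(1, config$reads_per_library, prob))
          ncrm <- nrow(crm)
          crm_counts <- counts[seq_len(ncrm)]
          idx <- rep(seq_len(ncrm), crm_counts)
          centers <- crm$start[idx] +
            floor(stats::runif(length(idx)) * (crm$end[idx] - crm$start[idx]))
          fs <- pmax(0, centers - fl %/% 2)
          fe <- pmin(chrom_size(gen$genome, crm$chrom[idx]), fs + fl)
          frag <- tibble::tibble(chrom = crm$chrom[idx], start = fs, end = fe)
          nbg <- counts[ncrm + 1L]
          bg_pos <- floor(stats::runif(nbg) * total_size)
          cum <- cumsum(gen$genome$size)
          bg_ci <- findInterval(bg_pos, c(0, cum), rightmost.closed = TRUE)
          bg_start <- bg_pos - c(0, cum)[bg_ci]
          bg <- tibble::tibble(
            chrom = gen$genome$chrom[bg_ci],
            start = bg_start,
            end = pmin(bg_start + fl, gen$genome$size[bg_ci]))
          nsp <- counts[ncrm + 2L]
          in_peak <- stats::runif(nsp) < 0.8
          sp_chrom <- gen$spike_genome$chrom[1]
          sp_size <- gen$spike_genome$size[1]
          pk <- sample.int(nrow(crms$spike_peaks), nsp, replace = TRUE)
          sp_start <- ifelse(
            in_peak,
            crms$spike_peaks$start[pk] +
              floor(stats::runif(nsp) *
                      (crms$spike_peaks$end[pk] - crms$spike_peaks$start[pk])),
            floor(stats::runif(nsp) * (sp_size - fl)))
          spike <- tibble::tibble(
            chrom = rep(sp_chrom, nsp),
            start = sp_start,
            end = pmin(sp_size, sp_start + fl))
          frag <- validate_peaks(dplyr::bind_rows(frag, bg))
          chip_library(sprintf("%s_%s_rep%d", tissue, treatment, rep_i),
                       frag, validate_peaks(spike),
                       tissue = tissue, treatment = treatment,
                       replicate = rep_i)
        })
      }
    }
  }
  libraries
}

#' Simulate expression tables with ground truth
#'
#' Generates a TPM time course (maternal transcripts decay from high
#' initial levels; zygotic genes rise after the activation onset;
#' late-class genes stay silent until the late onset), a five-tissue
#' spatial TPM table with the configured germ-layer fold separation,
#' and TSA-vs-control differential-expression tables in which each
#' late-class gene is prematurely activated with the configured
#' probability.
#'
#' @param config A [sim_config()].
#' @param gen Output of [simulate_genome()].
#' @param crm_truth The `truth` tibble from [simulate_crms()]; used to
#'   derive the true gene classes (late-class genes are those whose
#'   CRMs are exclusively repressive).
#' @return A list: `timecourse`, `tissues`, `de_ac`, `de_vg` (tibbles)
#'   and `truth` (per-gene tibble with `temporal_class`, `onset_hpf`,
#'   `class`, `category`, `activated`, `zygotic`).
#' @export
simulate_expression <- function(config, gen, crm_truth) {
  genes <- gen$genes
  ng <- nrow(genes)
  assigned <- crm_truth[!is.na(crm_truth$gene_id), ]
  gsets <- lapply(c(I = "I", II = "II", III = "III"), function(cl)
    unique(assigned$gene_id[assigned$cluster == cl]))
  class1 <- union(gsets$I, intersect(gsets$II, gsets$III))
  class2 <- setdiff(gsets$II, class1)
  class3 <- setdiff(gsets$III, class1)
  gclass <- rep("unclassified", ng)
  gclass[genes$gene_id %in% class1] <- "1"
  gclass[genes$gene_id %in% class2] <- "2"
  gclass[genes$gene_id %in% class3] <- "3"
  hpf <- config$hpf
  withr::with_seed(config$seed + 404L, {
    temporal <- ifelse(
      gclass == "2", "zygotic",
      sample(c("maternal", "silent", "zygotic"), ng, replace = TRUE,
             prob = c(config$maternal_fraction, config$silent_fraction,
                      1 - config$maternal_fraction - config$silent_fraction)))
    onset <- ifelse(gclass == "2", config$late_onset_hpf, config$zga_onset_hpf)
    tpm0 <- 10 + stats::rlnorm(ng, log(40), 0.5)
    plateau <- 5 + stats::rlnorm(ng, log(20), 0.5)
    base <- matrix(0, ng, length(hpf))
    for (j in seq_along(hpf)) {
      t <- hpf[j]
      base[, j] <- dplyr::case_when(
        temporal == "maternal" ~ tpm0 * exp(-t / 3),
        temporal == "zygotic" & t >= onset ~
          plateau * (1 - exp(-(t - onset) / 2)),
        .default = 0)
    }
    gene_noise <- stats::rlnorm(ng, 0, config$gene_sigma)
    tc <- base * gene_noise *
      matrix(stats::rlnorm(length(base), 0, config$cell_sigma), ng)
    timecourse <- tibble::as_tibble(
      stats::setNames(as.data.frame(tc), as.character(hpf)))
    timecourse <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                                   timecourse)
    category <- ifelse(
      temporal == "silent", "NE",
      sample(names(config$spatial_gene_fractions), ng, replace = TRUE,
             prob = config$spatial_gene_fractions))
    B <- 3 + stats::rlnorm(ng, log(20), 0.5)
    lo <- B / config$tissue_fold
    five <- cbind(
      AC = ifelse(category == "AC", B, lo),
      DMZ = ifelse(category == "MZ", B, lo),
      LMZ = ifelse(category == "MZ", B, lo),
      VMZ = ifelse(category == "MZ", B, lo),
      VG = ifelse(category == "VG", B, lo))
    five[category == "NL", ] <- B[category == "NL"]
    five[category == "NE", ] <- 0.3
    five <- five * stats::rlnorm(ng, 0, config$gene_sigma) *
      matrix(stats::rlnorm(length(five), 0, config$cell_sigma), ng)
    tissues <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id),
                                tibble::as_tibble(five))
    activated <- gclass == "2" & stats::runif(ng) < config$activation_prob
    # localized genes lose expression in their own germ layer under
    # HDAC inhibition with some probability (dynamic-acetylation arm)
    down_ac <- category == "AC" & stats::runif(ng) < 0.3
    down_vg <- category == "VG" & stats::runif(ng) < 0.3
    make_de <- function(down) {
      lfc <- stats::rnorm(ng, 0, 0.3)
      fdr <- stats::runif(ng, 0.1, 1)
      # affected genes clear the conventional twofold cutoff by design
      lfc[activated] <- pmax(stats::rnorm(sum(activated), config$de_lfc_mean,
                                          config$de_lfc_sd), 1.1)
      fdr[activated] <- stats::runif(sum(activated), 0, 0.049)
      lfc[down] <- pmin(stats::rnorm(sum(down), -config$de_lfc_mean,
                                     config$de_lfc_sd), -1.1)
      fdr[down] <- stats::runif(sum(down), 0, 0.049)
      tibble::tibble(gene_id = genes$gene_id, log2fc = lfc,
                     fdr = pmin(pmax(fdr, 0), 1))
    }
    de_ac <- make_de(down_ac)
    de_vg <- make_de(down_vg)
  })
  truth <- tibble::tibble(
    gene_id = genes$gene_id, temporal_class = temporal, onset_hpf = onset,
    class = gclass, category = category, activated = activated,
    zygotic = temporal == "zygotic")
  list(timecourse = timecourse, tissues = tissues,
       de_ac = de_ac, de_vg = de_vg, truth = truth)
}

#' Simulate differential-expression tables alone
#'
#' A lightweight generator for calibration studies of the premature
#' activation estimator: each gene is activated with probability
#' `activation_prob` (clear fold change, FDR below threshold), others
#' stay null.
#'
#' @param gene_ids Character vector of gene ids.
#' @param activation_prob Per-gene activation probability.
#' @param seed Integer RNG seed.
#' @param lfc_mean,lfc_sd Log2 fold-change distribution for activated
#'   genes.
#' @return A DE tibble (`gene_id`, `log2fc`, `fdr`) with attribute
#'   `activated` (logical ground truth).
#' @export
simulate_de_table <- function(gene_ids, activation_prob, seed,
                              lfc_mean = 2.5, lfc_sd = 0.5) {
  n <- length(gene_ids)
  withr::with_seed(seed, {
    act <- stats::runif(n) < activation_prob
    lfc <- stats::rnorm(n, 0, 0.3)
    fdr <- stats::runif(n, 0.1, 1)
    lfc[act] <- pmax(stats::rnorm(sum(act), lfc_mean, lfc_sd), 1.1)
    fdr[act] <- stats::runif(sum(act), 0, 0.049)
    structure(tibble::tibble(gene_id = gene_ids, log2fc = lfc, fdr = fdr),
              activated = act)
  })
}

#' Simulate the full synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_crms()], [simulate_chip()] and
#' [simulate_expression()] under one configuration; optionally writes
#' every output to disk in its standard text format (chromosome sizes,
#' BED12 gene models, narrowPeak peak sets, bedGraph coverage, TSV
#' expression/DE/ground-truth tables, and the configuration echo).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if missing).
#' @return A list with components `config`, `genome`, `spike_genome`,
#'   `genes`, `crm`, `k27ac`, `k27me3`, `pankac_ac`, `pankac_vg`,
#'   `spike_peaks`, `libraries`, `timecourse`, `tissues`, `de_ac`,
#'   `de_vg`, `crm_truth`, `gene_truth`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  gen <- simulate_genome(config)
  crms <- simulate_crms(config, gen)
  libraries <- simulate_chip(config, gen, crms)
  expr <- simulate_expression(config, gen, crms$truth)
  data <- list(config = config, genome = gen$genome,
               spike_genome = gen$spike_genome, genes = gen$genes,
               crm = crms$crm, k27ac = crms$k27ac, k27me3 = crms$k27me3,
               pankac_ac = crms$pankac_ac, pankac_vg = crms$pankac_vg,
               spike_peaks = crms$spike_peaks, libraries = libraries,
               timecourse = expr$timecourse, tissues = expr$tissues,
               de_ac = expr$de_ac, de_vg = expr$de_vg,
               crm_truth = crms$truth, gene_truth = expr$truth)
  if (!is.null(dir)) write_dataset(data, dir)
  data
}

write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_genome(dplyr::bind_rows(data$genome, data$spike_genome),
               p("chrom.sizes"))
  write_genes_bed12(data$genes, p("genes.bed12"))
  for (nm in c("crm", "k27ac", "k27me3", "pankac_ac", "pankac_vg"))
    write_peaks(data[[nm]], p(paste0(nm, ".narrowPeak")))
  write_peaks(data$spike_peaks, p("spike_peaks.bed"), dialect = "bed6")
  for (lib in data$libraries) {
    tr <- binned_coverage(lib$fragments, data$genome, bin_size = 50)
    write_bedgraph(tr, p(paste0(lib$sample_id, ".bedGraph")))
  }
  tsv <- function(x, f) utils::write.table(x, p(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  tsv(data$timecourse, "timecourse_tpm.tsv")
  tsv(data$tissues, "tissue_tpm.tsv")
  tsv(data$de_ac, "de_tsa_vs_dmso_ac.tsv")
  tsv(data$de_vg, "de_tsa_vs_dmso_vg.tsv")
  tsv(data$crm_truth, "truth_crm.tsv")
  tsv(data$gene_truth, "truth_genes.tsv")
  cfg <- data$config
  keys <- names(cfg)
  vals <- vapply(cfg, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(keys, " = ", vals), p("config.txt"))
  invisible(dir)
}
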