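#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param x,y Numeric samples with at least two values each.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least two values")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both samples: t statistic undefined")
  fit <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value)
}

#' Cohen's d effect size (pooled SD)
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the n-1 weighted pooled
#' standard deviation; the sign follows `x - y`.
#'
#' @param x,y Numeric samples with at least two values each.
#' @return The effect size d.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each sample needs at least two values")
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) stop("zero pooled standard deviation: d undefined")
  (mean(x) - mean(y)) / sp
}

#' One-sided (greater) Fisher exact test on a 2x2 table
#'
#' Upper-tail hypergeometric probability of observing at least `a`
#' successes given the table margins, as used for proportional
#' enrichment between groups.
#'
#' @param a,b,c,d Non-negative integer counts (rows: in-category vs
#'   not; columns: in-group vs not). Alternatively `a` may be a 2x2
#'   matrix.
#' @return The one-sided p-value.
#' @export
#' @examples
#' fisher_greater(3, 1, 1, 3)  # 17/70
fisher_greater <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L, 2L)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (sum(m) == 0) stop("table total must be positive")
  stats::fisher.test(m, alternative = "greater")$p.value
}

#' Error propagation for a ratio
#'
#' `r = a / b` with `sigma_r = |r| * sqrt((sigma_a/a)^2 + (sigma_b/b)^2)`
#' (first-order propagation for independent errors). When both sigmas
#' are zero the result is exact (`sigma_r = 0`).
#'
#' @param a,b Numerator and denominator (`b != 0`).
#' @param sigma_a,sigma_b Non-negative standard errors.
#' @return A one-row tibble: `ratio`, `sigma`.
#' @export
propagate_ratio_error <- function(a, sigma_a, b, sigma_b) {
  if (b == 0) stop("denominator must be nonzero")
  if (sigma_a < 0 || sigma_b < 0) stop("sigmas must be >= 0")
  if (a == 0 && sigma_a > 0)
    stop("relative error undefined for a = 0 with sigma_a > 0")
  r <- a / b
  rel_a <- if (a == 0) 0 else sigma_a / a
  s <- abs(r) * sqrt(rel_a^2 + (sigma_b / b)^2)
  tibble::tibble(ratio = r, sigma = s)
}

#' qPCR percent input with propagated error
#'
#' Converts replicate Ct values of an immunoprecipitation and its input
#' (measured at `dilution` times less chromatin) into DNA recovery as a
#' percentage of input. The input Ct is first adjusted by
#' `-log2(dilution)`; recovery is `100 * 2^(adjusted input Ct - IP Ct)`.
#' Replicate spread propagates through the exponentials by the ratio
#' rule (`sigma(2^Ct) = ln(2) * 2^Ct * sem(Ct)`). With a single
#' replicate on either side the error is reported as NA.
#'
#' @param ip_ct Numeric IP replicate Ct values.
#' @param input_ct Numeric input replicate Ct values.
#' @param dilution Input dilution factor (> 0; 1 means input measured
#'   at the same chromatin equivalency).
#' @return A one-row tibble: `percent`, `se`.
#' @export
percent_input <- function(ip_ct, input_ct, dilution = 1) {
  if (length(ip_ct) < 1L || length(input_ct) < 1L)
    stop("at least one replicate per side is required")
  if (dilution <= 0) stop("dilution factor must be positive")
  adj_input <- mean(input_ct) - log2(dilution)
  pct <- 100 * 2^(adj_input - mean(ip_ct))
  se <- NA_real_
  if (length(ip_ct) >= 2L && length(input_ct) >= 2L) {
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    a <- 2^(-mean(ip_ct))
    b <- 2^(-adj_input)
    sig_a <- log(2) * a * sem(ip_ct)
    sig_b <- log(2) * b * sem(input_ct)
    se <- 100 * propagate_ratio_error(a, sig_a, b, sig_b)$sigma
  }
  tibble::tibble(percent = pct, se = se)
}

#' Fisher enrichment across categories with BH adjustment
#'
#' For each category, tests whether members of `group` are
#' over-represented in that category (one-sided Fisher on the 2x2 table
#' category-membership x group-membership). Raw p-values are primary;
#' Benjamini-Hochberg adjusted values are reported alongside.
#'
#' @param categories A tibble with `gene_id` and `category`.
#' @param group Character vector of gene ids (e.g. an up-regulated set).
#' @return A tibble: `category`, `in_group`, `in_category`, `total`,
#'   `p_value`, `p_adj`.
#' @export
category_enrichment <- function(categories, group) {
  total <- nrow(categories)
  ing <- categories$gene_id %in% group
  out <- categories |>
    dplyr::mutate(in_group = ing) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(in_group = sum(.data$in_group), in_category = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(total = total)
  out$p_value <- purrr::pmap_dbl(out, function(category, in_group, in_category,
                                               total, ...) {
    fisher_greater(in_group, sum(ing) - in_group,
                   in_category - in_group,
                   total - in_category - (sum(ing) - in_group))
  })
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
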