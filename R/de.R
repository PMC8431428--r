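# Self-contained pairwise differential expression on counts: median-of-ratios
# normalisation, method-of-moments NB dispersion, Wald test, BH adjustment,
# and the conventional |log2FC| >= 1 & adjusted p < .05 DEG call.

.alpha_min <- 1e-8

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over genes with
#' positive counts in every sample, of the ratio of the sample's count to the
#' gene's geometric mean across samples.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' estimate_size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has positive counts in every sample; ",
         "median-of-ratios is undefined (consider a pseudo-reference fallback)")
  }
  logc <- log(counts[all_pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - loggeo)))
  sf
}

#' Normalised counts
#'
#' @param counts genes x samples count matrix.
#' @param size_factors per-sample size factors; estimated with
#'   [estimate_size_factors()] when omitted.
#' @return matrix of counts divided column-wise by the size factors.
#' @export
normalized_counts <- function(counts, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (any(size_factors <= 0)) stop("size factors must be positive")
  sweep(as.matrix(counts), 2, size_factors, "/")
}

.group_samples <- function(design, group, time_point = NULL) {
  keep <- design$genotype == group
  if (!is.null(time_point)) keep <- keep & design$time_point == time_point
  ids <- design$sample_id[keep]
  if (length(ids) == 0) stop("no samples found for group '", group, "'",
                             if (!is.null(time_point)) paste0(" at time point '", time_point, "'"))
  ids
}

#' Method-of-moments per-gene NB dispersion
#'
#' Pools the within-group variance of normalised counts across the replicate
#' groups (each genotype x time-point cell of the selected genotypes, centred
#' at its own mean) and solves `Var = mu + alpha * mu^2` for `alpha`, floored
#' at 1e-8. Genes with zero mean get the floor. Dispersion is a property of
#' the gene, not of a comparison, so pooling over more cells (e.g. all three
#' genotypes of a triad at both time points) uses the available degrees of
#' freedom and stabilises the estimate; restricting to the two groups of one
#' comparison reproduces the plain two-group estimator.
#'
#' @param counts genes x samples count matrix.
#' @param design sample sheet data frame with columns `sample_id`, `genotype`
#'   and `time_point`.
#' @param groupA,groupB genotype labels of the two groups of a comparison.
#' @param time_point optional time-point label restricting the samples; when
#'   `NULL` every time point contributes its own centred cell.
#' @param size_factors optional size factors (estimated from the full matrix
#'   when omitted).
#' @param groups optional character vector of genotype labels overriding
#'   `groupA`/`groupB`, e.g. all genotypes of the design.
#' @return named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, design, groupA, groupB,
                                time_point = NULL, size_factors = NULL,
                                groups = NULL) {
  counts <- as.matrix(counts)
  if (is.null(groups)) groups <- c(groupA, groupB)
  for (g in groups) {
    if (!any(design$genotype == g)) stop("unknown group label '", g, "'")
  }
  tps <- if (is.null(time_point)) unique(design$time_point) else time_point
  cells <- list()
  for (g in groups) {
    for (tp in tps) {
      ids <- design$sample_id[design$genotype == g & design$time_point == tp]
      if (length(ids) >= 2) cells[[paste(g, tp)]] <- ids
    }
  }
  if (length(cells) == 0) stop("each group needs >= 2 replicates")
  n_tot <- sum(lengths(cells))
  if (n_tot - length(cells) < 1) stop("not enough residual degrees of freedom")
  norm <- normalized_counts(counts, size_factors)
  ss <- 0
  mu_sum <- 0
  for (ids in cells) {
    sub <- norm[, ids, drop = FALSE]
    m <- rowMeans(sub)
    ss <- ss + rowSums((sub - m)^2)
    mu_sum <- mu_sum + m * length(ids)
  }
  s2 <- ss / (n_tot - length(cells))
  mu <- mu_sum / n_tot
  alpha <- ifelse(mu > 0, (s2 - mu) / mu^2, .alpha_min)
  alpha <- pmax(alpha, .alpha_min)
  names(alpha) <- rownames(counts)
  alpha
}

#' Mean-dispersion trend across genes
#'
#' Smooths genewise method-of-moments dispersions against the log normalised
#' mean with a robust lowess fit, returning the trend value at each gene's
#' mean (floored at 1e-8). At two or three replicates per group a genewise
#' dispersion estimate has so few residual degrees of freedom that its noise
#' dominates the Wald statistic; sharing information across the thousands of
#' genes at a similar expression level is the standard remedy and is how the
#' established count-based DE engines stabilise their variance estimates.
#' Genes whose true dispersion sits far above the trend will have optimistic
#' standard errors; with adequate replication the genewise estimate can be
#' used directly instead.
#'
#' @param alpha_hat genewise dispersions from [estimate_dispersion()].
#' @param base_mean per-gene mean of normalised counts.
#' @param span lowess span (default 0.3).
#' @return numeric vector of trended dispersions, same order as `alpha_hat`.
#' @export
dispersion_trend <- function(alpha_hat, base_mean, span = 0.3) {
  if (length(alpha_hat) != length(base_mean)) {
    stop("alpha_hat and base_mean must have equal length")
  }
  if (length(alpha_hat) < 10) return(pmax(alpha_hat, .alpha_min))
  lx <- log10(base_mean + .alpha_min)
  lo <- stats::lowess(lx, alpha_hat, f = span)
  tr <- stats::approx(lo$x, lo$y, xout = lx, rule = 2, ties = mean)$y
  pmax(tr, .alpha_min)
}

#' Negative-binomial Wald test for a pairwise comparison
#'
#' Tests each gene for differential expression between `groupA` and `groupB`
#' on normalised counts. For a comparison named "A vs B" the reported
#' log2 fold change is `log2(B/A)`, so with the hybrid as B, "up" means
#' higher in the hybrid. When either group mean is zero a pseudo-count of 0.5
#' is added to both means before the ratio, keeping the fold change finite
#' without biasing genes observed in both groups. The standard error of the
#' log fold change comes from the delta method under `Var = mu + alpha*mu^2`
#' with the sample library factors entering the Poisson term; the Wald
#' statistic is referred to the standard normal and adjusted by
#' Benjamini-Hochberg across all genes of the comparison.
#'
#' @inheritParams estimate_dispersion
#' @param dispersion optional per-gene dispersion vector; estimated by
#'   [estimate_dispersion()] when omitted.
#' @return data frame (one row per gene) with columns `gene_id`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `p_value`, `p_adj`, and attribute `comparison`
#'   set to `"A vs B"`.
#' @export
nb_wald_test <- function(counts, design, groupA, groupB, time_point = NULL,
                         size_factors = NULL, dispersion = NULL) {
  counts <- as.matrix(counts)
  sA <- .group_samples(design, groupA, time_point)
  sB <- .group_samples(design, groupB, time_point)
  if (length(intersect(sA, sB))) stop("groups must be disjoint")
  if (length(sA) < 2 || length(sB) < 2) stop("each group needs >= 2 replicates")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (length(size_factors) != ncol(counts)) {
    stop("need one size factor per sample")
  }
  if (is.null(names(size_factors))) names(size_factors) <- colnames(counts)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, design, groupA, groupB,
                                      time_point, size_factors)
  }
  dispersion <- rep_len(dispersion, nrow(counts))

  norm <- normalized_counts(counts, size_factors)
  mA <- rowMeans(norm[, sA, drop = FALSE])
  mB <- rowMeans(norm[, sB, drop = FALSE])
  z <- as.numeric(mA == 0 | mB == 0)
  muA <- mA + 0.5 * z
  muB <- mB + 0.5 * z
  log2fc <- log2(muB / muA)

  var_mean <- function(mu, samples) {
    L <- size_factors[samples]
    n <- length(samples)
    (mu * sum(1 / L) + dispersion * mu^2 * n) / n^2
  }
  vA <- var_mean(muA, sA) / (muA^2 * log(2)^2)
  vB <- var_mean(muB, sB) / (muB^2 * log(2)^2)
  se <- sqrt(vA + vB)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))

  both_zero <- mA == 0 & mB == 0
  log2fc[both_zero] <- 0
  stat[both_zero] <- 0
  se[both_zero] <- NA_real_
  p[both_zero] <- 1

  out <- data.frame(
    gene_id = if (is.null(rownames(counts))) paste0("g", seq_len(nrow(counts))) else rownames(counts),
    base_mean = rowMeans(norm[, c(sA, sB), drop = FALSE]),
    log2fc = log2fc, se = se, stat = stat,
    p_value = p, p_adj = adjust_bh(p),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "comparison") <- paste(groupA, "vs", groupB)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, mapped back to
#' the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order as `p`.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Three-valued DEG call
#'
#' A gene is called `up` when `p_adj < alpha` and `log2fc >= lfc`, `down`
#' when `p_adj < alpha` and `log2fc <= -lfc`, otherwise `ns`. With the
#' default thresholds this is the conventional DEG rule: |log2 fold change|
#' of at least 1 with adjusted p below 0.05.
#'
#' @param de DE table from [nb_wald_test()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc log2-fold-change threshold (default 1).
#' @return `de` with an added `call` column; attribute `"counts"` holds the
#'   up/down/total tallies.
#' @export
call_degs <- function(de, alpha = 0.05, lfc = 1) {
  stopifnot(is.data.frame(de), all(c("log2fc", "p_adj") %in% names(de)))
  call <- rep("ns", nrow(de))
  sig <- !is.na(de$p_adj) & de$p_adj < alpha
  call[sig & de$log2fc >= lfc] <- "up"
  call[sig & de$log2fc <= -lfc] <- "down"
  de$call <- call
  attr(de, "counts") <- c(up = sum(call == "up"), down = sum(call == "down"),
                          total = sum(call != "ns"))
  de
}
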