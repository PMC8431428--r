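# Phenotypic heterosis: mid-/high-parent indices, the mid-parent t-test,
# and one-way ANOVA with Tukey HSD plus a compact-letter display.

#' Mid-parent and high-parent heterosis for a triad
#'
#' For every (trait, time point) present for all three genotypes, computes
#' the replicate means, the mid-parent value `MP = (mean_F + mean_M)/2`, the
#' high-parent value `HP = max(mean_F, mean_M)`, and the percentage indices
#' `MPH = (F1 - MP)/MP * 100` and `HPH = (F1 - HP)/HP * 100`, together with
#' the mid-parent t-test of [test_heterosis()]. `MP = 0` or `HP = 0` leaves
#' the affected indices `NA` with a warning.
#'
#' @param pheno phenotype data frame with columns `genotype`, `trait`,
#'   `time_point`, `replicate`, `value`.
#' @param triad named character vector with entries `female`, `male`,
#'   `hybrid` giving the genotype labels.
#' @param method mid-parent test construction, see [test_heterosis()].
#' @return data frame with one row per (trait, time_point): `f1_mean`, `mp`,
#'   `hp`, `mph_pct`, `hph_pct`, `t_stat`, `p_value`, `degenerate`.
#' @examples
#' ph <- simulate_phenotypes(c(F = 8, M = 10, H = 12), 0, 5)
#' compute_heterosis(ph, c(female = "F", male = "M", hybrid = "H"))
#' @export
compute_heterosis <- function(pheno, triad, method = c("welch-pseudo", "one-sample")) {
  method <- match.arg(method)
  stopifnot(all(c("female", "male", "hybrid") %in% names(triad)))
  need <- c("genotype", "trait", "time_point", "replicate", "value")
  if (!all(need %in% names(pheno))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  combos <- unique(pheno[pheno$genotype == triad[["hybrid"]],
                         c("trait", "time_point")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    tr <- combos$trait[i]; tp <- combos$time_point[i]
    grab <- function(g) {
      v <- pheno$value[pheno$genotype == g & pheno$trait == tr &
                         pheno$time_point == tp]
      if (length(v) < 2) stop("need >= 2 replicates for genotype '", g,
                              "', trait '", tr, "', time point '", tp, "'")
      v
    }
    vF <- grab(triad[["female"]]); vM <- grab(triad[["male"]])
    vH <- grab(triad[["hybrid"]])
    f1 <- mean(vH); mp <- (mean(vF) + mean(vM)) / 2
    hp <- max(mean(vF), mean(vM))
    mph <- if (mp == 0) NA_real_ else (f1 - mp) / mp * 100
    hph <- if (hp == 0) NA_real_ else (f1 - hp) / hp * 100
    if (mp == 0 || hp == 0) {
      warning("zero mid- or high-parent mean for trait '", tr,
              "'; heterosis undefined, reported as NA")
    }
    tt <- test_heterosis(vH, vF, vM, method = method)
    data.frame(trait = tr, time_point = tp, f1_mean = f1, mp = mp, hp = hp,
               mph_pct = mph, hph_pct = hph, t_stat = tt$t_stat,
               p_value = tt$p_value, degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Test the hybrid mean against the mid-parent value
#'
#' Default construction (`"welch-pseudo"`): parent replicates are paired by
#' index to form per-replicate mid-parent pseudo-values
#' `MP_i = (F_i + M_i)/2` (pairing up to the shorter parent, with a warning
#' when the counts differ) and the hybrid replicates are compared to them by
#' a Welch two-sample t-test, so parental variability propagates into the
#' test. The `"one-sample"` alternative treats the mid-parent value as a
#' constant. With zero variance in both samples the test degenerates: p = 1
#' when the means agree, p = 0 (flagged) when they differ.
#'
#' @param hybrid,female,male numeric replicate vectors (>= 2 each).
#' @param method `"welch-pseudo"` (default) or `"one-sample"`.
#' @return list with `t_stat`, `p_value`, `degenerate`.
#' @export
test_heterosis <- function(hybrid, female, male,
                           method = c("welch-pseudo", "one-sample")) {
  method <- match.arg(method)
  if (length(hybrid) < 2 || length(female) < 2 || length(male) < 2) {
    stop("need >= 2 replicates per genotype")
  }
  if (length(female) != length(male)) {
    warning("unbalanced parent replicate counts; pairing up to the minimum")
  }
  k <- min(length(female), length(male))
  mp_i <- (female[seq_len(k)] + male[seq_len(k)]) / 2
  if (method == "one-sample") {
    if (stats::sd(hybrid) == 0) {
      eq <- mean(hybrid) == mean(mp_i)
      return(list(t_stat = if (eq) 0 else Inf * sign(mean(hybrid) - mean(mp_i)),
                  p_value = if (eq) 1 else 0, degenerate = TRUE))
    }
    tt <- stats::t.test(hybrid, mu = mean(mp_i))
    return(list(t_stat = unname(tt$statistic), p_value = tt$p.value,
                degenerate = FALSE))
  }
  if (stats::sd(hybrid) == 0 && stats::sd(mp_i) == 0) {
    eq <- mean(hybrid) == mean(mp_i)
    return(list(t_stat = if (eq) 0 else Inf * sign(mean(hybrid) - mean(mp_i)),
                p_value = if (eq) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(hybrid, mp_i)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value, degenerate = FALSE)
}

#' One-way ANOVA with Tukey HSD and compact-letter display
#'
#' Fits `value ~ group`, reports the overall F test, all Tukey honest
#' significant difference pairwise comparisons at level `alpha`, and a
#' compact-letter display in which groups sharing a letter are not
#' significantly different (greedy insert-and-absorb; groups ordered by
#' decreasing mean, ties broken by input order).
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values` (>= 2 groups, >= 2
#'   replicates each).
#' @param alpha family-wise level of the HSD test (default 0.05).
#' @return list with `f_stat`, `p_value`, `tukey` (data frame: pair, diff,
#'   lwr, upr, p_adj, different) and `letters` (named character vector).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("need >= 2 replicates per group")
  if (stats::var(values) == 0) {
    stop("zero within-group variance with identical means: F is undefined")
  }
  d <- data.frame(value = values, group = groups)
  fit <- stats::aov(value ~ group, data = d)
  an <- summary(fit)[[1]]
  rownames(an) <- trimws(rownames(an))
  f_stat <- an["group", "F value"]
  p_value <- an["group", "Pr(>F)"]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairs <- rownames(tk)
  tukey <- data.frame(pair = pairs, diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      different = tk[, "p adj"] < alpha,
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  letters_out <- .compact_letters(levels(groups),
                                  tapply(values, groups, mean), tukey)
  list(f_stat = f_stat, p_value = p_value, tukey = tukey,
       letters = letters_out)
}

# Greedy insert-and-absorb compact-letter display. diff_pairs rows are
# "B-A" as emitted by TukeyHSD.
.compact_letters <- function(group_levels, group_means, tukey) {
  g <- group_levels[order(-group_means, seq_along(group_levels))]
  diff_mat <- matrix(FALSE, length(g), length(g), dimnames = list(g, g))
  for (i in seq_len(nrow(tukey))) {
    ab <- strsplit(tukey$pair[i], "-", fixed = TRUE)[[1]]
    diff_mat[ab[1], ab[2]] <- diff_mat[ab[2], ab[1]] <- tukey$different[i]
  }
  sets <- list()
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (j <= i || diff_mat[g[i], g[j]]) next
      covered <- any(vapply(sets, function(s) all(c(g[i], g[j]) %in% s),
                            logical(1)))
      if (covered) next
      s <- c(g[i], g[j])
      for (h in g) {
        if (h %in% s) next
        if (!any(diff_mat[h, s])) s <- c(s, h)
      }
      sets[[length(sets) + 1]] <- s
    }
  }
  lonely <- g[!g %in% unlist(sets)]
  for (h in lonely) sets[[length(sets) + 1]] <- h
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[i]]) < length(sets[[j]])) keep[i] <- FALSE
    }
  }
  sets <- sets[keep]
  sets <- sets[order(vapply(sets, function(s) min(match(s, g)), numeric(1)))]
  out <- stats::setNames(rep("", length(group_levels)), group_levels)
  for (i in seq_along(sets)) {
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  }
  out[g]
}
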