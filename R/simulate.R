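# Negative-binomial triad simulator with planted inheritance modes, plus
# phenotype and annotation generators. The planted truth table is the oracle
# used throughout the test suite.

.sim_modes <- c("conserved", "additive", "eldF", "eldM", "od_up", "od_down")

#' Simulation configuration for a hybrid-parent triad experiment
#'
#' Bundles and validates every knob of the count simulator. Defaults mirror
#' a typical diallel-derived triad sequencing design: three biological
#' replicates per genotype, two sampling time points, parent expression
#' centred at `2^7` counts with 2 log2 units of between-gene spread,
#' moderate overdispersion, and a two-log2-unit planted effect for both the
#' parent-parent gap and the overdominance offset.
#'
#' @param n_genes number of genes (> 0).
#' @param n_replicates biological replicates per genotype and time point
#'   (>= 2).
#' @param time_points number of time points (each gets its own replicate set;
#'   planted means are shared across time points).
#' @param genotypes named character vector giving the genotype label of each
#'   role `female_parent`, `male_parent`, `hybrid`.
#' @param baseline_mean_log2,baseline_sd_log2 mean and sd (log2 scale) of the
#'   per-gene baseline expression.
#' @param dispersion NB dispersion `alpha` (`Var = mu + alpha mu^2`); scalar
#'   or per-gene vector; 0 degenerates to Poisson.
#' @param libsize_factor_range range of the log-uniform per-sample library
#'   size factors.
#' @param class_proportions named fractions over the six inheritance modes
#'   `conserved`, `additive`, `eldF`, `eldM`, `od_up`, `od_down`; must be
#'   non-negative and sum to 1.
#' @param effect_log2 planted parent-vs-parent gap and overdominance offset,
#'   in log2 units (> 0).
#' @param seed integer seed governing the whole bundle.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000, n_replicates = 3, time_points = 2,
                       genotypes = c(female_parent = "F", male_parent = "M",
                                     hybrid = "H"),
                       baseline_mean_log2 = 7, baseline_sd_log2 = 2,
                       dispersion = 0.05,
                       libsize_factor_range = c(0.7, 1.4),
                       class_proportions = c(conserved = 0.5, additive = 0.1,
                                             eldF = 0.1, eldM = 0.1,
                                             od_up = 0.1, od_down = 0.1),
                       effect_log2 = 2, seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be positive")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (!(length(dispersion) %in% c(1L, as.integer(n_genes)))) {
    stop("dispersion must be a scalar or one value per gene")
  }
  if (!all(.sim_modes %in% names(class_proportions))) {
    stop("class_proportions must name all of: ", paste(.sim_modes, collapse = ", "))
  }
  class_proportions <- class_proportions[.sim_modes]
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must be non-negative and sum to 1")
  }
  if (!all(c("female_parent", "male_parent", "hybrid") %in% names(genotypes))) {
    stop("genotypes must name female_parent, male_parent and hybrid")
  }
  if (length(libsize_factor_range) != 2 || any(libsize_factor_range <= 0) ||
      diff(libsize_factor_range) < 0) {
    stop("libsize_factor_range must be an increasing positive interval")
  }
  if (effect_log2 <= 0) stop("effect_log2 must be > 0")
  structure(list(
    n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
    time_points = as.integer(time_points), genotypes = genotypes,
    baseline_mean_log2 = baseline_mean_log2, baseline_sd_log2 = baseline_sd_log2,
    dispersion = dispersion, libsize_factor_range = libsize_factor_range,
    class_proportions = class_proportions, effect_log2 = effect_log2,
    seed = as.integer(seed)
  ), class = "sim_config")
}

.true_relation <- function(a, b) ifelse(a > b, "gt", ifelse(a < b, "lt", "eq"))

#' Simulate triad count data with planted inheritance modes
#'
#' Draws independent negative-binomial counts with
#' `mu[g, s] = mu_role(g) * L_s` and `Var = mu + alpha * mu^2`, where the
#' role means implement the planted mode of each gene:
#' conserved (`mu_H = mu_F = mu_M`), additive (parents `effect_log2` apart,
#' hybrid at the arithmetic mid-parent), ELD-F / ELD-M (hybrid equal to one
#' parent), up-overdominant (`mu_H = max(mu_F, mu_M) * 2^effect_log2`) and
#' down-overdominant (`mu_H = min(mu_F, mu_M) * 2^-effect_log2`). Within a
#' mode the parent-order sub-pattern (female-high, male-high, and for the
#' overdominant modes parents-equal) is drawn uniformly. The truth table
#' records the expected normalised means and the class index obtained by
#' applying the rule table of [classify_gene()] to them.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (genes x samples integer matrix), `design`
#'   (sample sheet data frame: sample_id, genotype, role, triad_id,
#'   time_point, replicate), `truth` (gene_id, planted_mode, class, category,
#'   mu_F, mu_M, mu_H), and `size_factors_true` (the planted library factors).
#' @export
simulate_triad_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  e <- config$effect_log2

  mode <- sample(.sim_modes, ng, replace = TRUE, prob = config$class_proportions)
  x <- stats::rnorm(ng, config$baseline_mean_log2, config$baseline_sd_log2)

  # parent sub-pattern: +1 female-high, -1 male-high, 0 parents-equal
  sub <- integer(ng)
  two_way <- mode %in% c("additive", "eldF", "eldM")
  three_way <- mode %in% c("od_up", "od_down")
  sub[two_way] <- sample(c(1L, -1L), sum(two_way), replace = TRUE)
  sub[three_way] <- sample(c(1L, -1L, 0L), sum(three_way), replace = TRUE)

  half <- e / 2
  xF <- x + ifelse(sub == 1L, half, ifelse(sub == -1L, -half, 0))
  xM <- x + ifelse(sub == -1L, half, ifelse(sub == 1L, -half, 0))
  muF <- 2^xF
  muM <- 2^xM
  muH <- numeric(ng)
  muH[mode == "conserved"] <- muF[mode == "conserved"]
  muH[mode == "additive"] <- (muF[mode == "additive"] + muM[mode == "additive"]) / 2
  muH[mode == "eldF"] <- muF[mode == "eldF"]
  muH[mode == "eldM"] <- muM[mode == "eldM"]
  muH[mode == "od_up"] <- pmax(muF, muM)[mode == "od_up"] * 2^e
  muH[mode == "od_down"] <- pmin(muF, muM)[mode == "od_down"] * 2^-e

  gt <- config$genotypes
  role_of <- c(stats::setNames("female_parent", gt[["female_parent"]]),
               stats::setNames("male_parent", gt[["male_parent"]]),
               stats::setNames("hybrid", gt[["hybrid"]]))
  tps <- paste0("T", seq_len(config$time_points))
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        genotype = unname(gt), time_point = tps,
                        stringsAsFactors = FALSE)
  design$role <- unname(role_of[design$genotype])
  design$triad_id <- paste0(gt[["female_parent"]], "x", gt[["male_parent"]])
  design$sample_id <- paste(design$genotype, design$time_point,
                            paste0("r", design$replicate), sep = "_")
  design <- design[, c("sample_id", "genotype", "role", "triad_id",
                       "time_point", "replicate")]

  ns <- nrow(design)
  lr <- log(config$libsize_factor_range)
  L <- exp(stats::runif(ns, lr[1], lr[2]))
  names(L) <- design$sample_id

  alpha <- rep_len(config$dispersion, ng)
  mu_role <- cbind(female_parent = muF, male_parent = muM, hybrid = muH)
  counts <- matrix(0L, nrow = ng, ncol = ns,
                   dimnames = list(sprintf("gene_%04d", seq_len(ng)),
                                   design$sample_id))
  for (s in seq_len(ns)) {
    mu_s <- mu_role[, design$role[s]] * L[s]
    pois <- alpha == 0
    draw <- integer(ng)
    if (any(pois)) draw[pois] <- stats::rpois(sum(pois), mu_s[pois])
    if (any(!pois)) {
      draw[!pois] <- stats::rnbinom(sum(!pois), mu = mu_s[!pois],
                                    size = 1 / alpha[!pois])
    }
    counts[, s] <- draw
  }
  storage.mode(counts) <- "integer"

  class <- classify_gene(.true_relation(muF, muM),
                         .true_relation(muH, muF),
                         .true_relation(muH, muM))
  truth <- data.frame(
    gene_id = rownames(counts), planted_mode = mode, class = class,
    category = pattern_category(class),
    mu_F = muF, mu_M = muM, mu_H = muH, dispersion = alpha,
    stringsAsFactors = FALSE
  )
  list(counts = counts, design = design, truth = truth, size_factors_true = L)
}

#' Simulate replicated phenotype measurements for a triad
#'
#' Normal per-plant draws around genotype means; with `trait_sd = 0` the
#' computed mid-parent heterosis equals the planted
#' `((mu_H - (mu_F + mu_M)/2) / ((mu_F + mu_M)/2)) * 100` exactly.
#'
#' @param trait_means named numeric vector of genotype means (one entry per
#'   genotype, e.g. female parent, male parent, hybrid).
#' @param trait_sd common within-genotype standard deviation (>= 0).
#' @param n_plants plants (replicates) per genotype (>= 2).
#' @param trait trait label (default "root_length").
#' @param time_point time-point label (default "T1").
#' @param seed integer seed.
#' @return data frame with columns `genotype`, `trait`, `time_point`,
#'   `replicate`, `value`.
#' @export
simulate_phenotypes <- function(trait_means, trait_sd, n_plants,
                                trait = "root_length", time_point = "T1",
                                seed = 1L) {
  if (trait_sd < 0) stop("trait_sd must be >= 0")
  if (n_plants < 2) stop("n_plants must be >= 2")
  if (is.null(names(trait_means))) stop("trait_means must be named by genotype")
  set.seed(seed)
  out <- do.call(rbind, lapply(names(trait_means), function(g) {
    data.frame(genotype = g, trait = trait, time_point = time_point,
               replicate = seq_len(n_plants),
               value = stats::rnorm(n_plants, trait_means[[g]], trait_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a gene-to-term annotation map
#'
#' Random term memberships of sizes drawn uniformly from `term_size_range`;
#' an optional planted term is set to exactly the given gene subset so that
#' downstream over-representation of that subset is guaranteed by
#' construction.
#'
#' @param genes character vector of gene ids (non-empty).
#' @param n_terms number of random terms (may be 0).
#' @param term_size_range integer interval of term sizes (each <= number of
#'   genes).
#' @param enriched_term optional `list(term_id =, genes =)` planting a term
#'   that contains exactly the stated subset.
#' @param seed integer seed.
#' @return named list mapping term ids to character vectors of gene ids
#'   (an annotation map).
#' @export
simulate_annotation <- function(genes, n_terms, term_size_range = c(5, 50),
                                enriched_term = NULL, seed = 1L) {
  if (length(genes) == 0) stop("gene list must be non-empty")
  if (max(term_size_range) > length(genes)) {
    stop("term sizes must not exceed the number of genes")
  }
  set.seed(seed)
  anno <- list()
  if (n_terms > 0) {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms,
                    replace = TRUE)
    anno <- lapply(sizes, function(k) sample(genes, k))
    names(anno) <- sprintf("term_%03d", seq_len(n_terms))
  }
  if (!is.null(enriched_term)) {
    if (!all(enriched_term$genes %in% genes)) {
      stop("enriched_term genes must be a subset of the gene list")
    }
    anno[[enriched_term$term_id]] <- enriched_term$genes
  }
  anno
}
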