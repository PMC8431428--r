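test_that("simulators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 120, seed = 5)
  a <- simulate_triad_counts(cfg)
  b <- simulate_triad_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$design, b$design)

  p1 <- simulate_phenotypes(c(F = 8, M = 10, H = 12), 0.5, 10, seed = 3)
  p2 <- simulate_phenotypes(c(F = 8, M = 10, H = 12), 0.5, 10, seed = 3)
  expect_identical(p1, p2)

  g <- sprintf("g%02d", 1:40)
  a1 <- simulate_annotation(g, 5, c(3, 10), seed = 9)
  a2 <- simulate_annotation(g, 5, c(3, 10), seed = 9)
  expect_identical(a1, a2)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(class_proportions = c(conserved = 0.9, additive = 0.2,
                                                eldF = 0, eldM = 0,
                                                od_up = 0, od_down = 0)),
               "sum to 1")
  expect_error(sim_config(effect_log2 = 0), "effect_log2")
})

test_that("all-conserved Poisson config gives agreeing group means", {
  cfg <- sim_config(n_genes = 60, seed = 2, dispersion = 0,
                    libsize_factor_range = c(1, 1),
                    class_proportions = c(conserved = 1, additive = 0, eldF = 0,
                                          eldM = 0, od_up = 0, od_down = 0))
  sim <- simulate_triad_counts(cfg)
  for (g in c("F", "M", "H")) {
    ids <- sim$design$sample_id[sim$design$genotype == g]
    m <- rowMeans(sim$counts[, ids])
    # Poisson mean of 6 replicates: |m - mu| < 5 sd(mean) for every gene
    expect_true(all(abs(m - sim$truth$mu_F) < 5 * sqrt(sim$truth$mu_F / 6)))
  }
  expect_true(all(sim$truth$class == "conserved"))
})

test_that("empirical mode counts match the planted proportions (binomial 3-sigma)", {
  cfg <- sim_config(n_genes = 2000, seed = 4)
  sim <- simulate_triad_counts(cfg)
  tab <- table(factor(sim$truth$planted_mode,
                      levels = names(cfg$class_proportions)))
  for (mode in names(cfg$class_proportions)) {
    p <- cfg$class_proportions[[mode]]
    tol <- 3 * sqrt(2000 * p * (1 - p))
    expect_lt(abs(tab[[mode]] - 2000 * p), tol + 1e-9)
  }
})

test_that("count moments match Var = mu + alpha mu^2 at alpha 0 and 0.1", {
  for (alpha in c(0, 0.1)) {
    cfg <- sim_config(n_genes = 600, seed = 8, dispersion = alpha,
                      baseline_sd_log2 = 0, libsize_factor_range = c(1, 1),
                      class_proportions = c(conserved = 1, additive = 0,
                                            eldF = 0, eldM = 0,
                                            od_up = 0, od_down = 0))
    sim <- simulate_triad_counts(cfg)
    draws <- as.numeric(sim$counts)  # iid NB(mu, alpha), 600 x 18 > 1e4 draws
    n <- length(draws)
    mu <- 2^cfg$baseline_mean_log2
    s2 <- mu + alpha * mu^2
    # exact NB fourth central moment for the Var(s^2) Monte-Carlo tolerance
    ks <- 0:qnbinom(1 - 1e-12, mu = mu, size = if (alpha > 0) 1 / alpha else Inf)
    pk <- if (alpha > 0) dnbinom(ks, mu = mu, size = 1 / alpha) else dpois(ks, mu)
    mu4 <- sum(pk * (ks - mu)^4)
    expect_lt(abs(mean(draws) - mu), 3 * sqrt(s2 / n))
    expect_lt(abs(var(draws) - s2), 3 * sqrt((mu4 - s2^2 * (n - 3) / (n - 1)) / n))
  }
})

test_that("planted truth classes round-trip through the rule table", {
  sim <- small_sim(seed = 13, n_genes = 500)
  rel <- function(a, b) ifelse(a > b, "gt", ifelse(a < b, "lt", "eq"))
  with(sim$truth, {
    expect_identical(classify_gene(rel(mu_F, mu_M), rel(mu_H, mu_F),
                                   rel(mu_H, mu_M)),
                     class)
  })
  # planted category labels agree with the class-to-category map
  expect_identical(pattern_category(sim$truth$class), sim$truth$category)
  # a hybrid strictly above both parents is never additive in truth
  above <- sim$truth$mu_H > pmax(sim$truth$mu_F, sim$truth$mu_M)
  expect_true(all(sim$truth$category[above] == "up-overdominant"))
  below <- sim$truth$mu_H < pmin(sim$truth$mu_F, sim$truth$mu_M)
  expect_true(all(sim$truth$category[below] == "down-overdominant"))
})

test_that("planted hybrid means implement the stated mode arithmetic", {
  sim <- small_sim(seed = 21, n_genes = 800)
  tr <- sim$truth
  e <- 2
  expect_equal(tr$mu_H[tr$planted_mode == "additive"],
               ((tr$mu_F + tr$mu_M) / 2)[tr$planted_mode == "additive"])
  expect_equal(tr$mu_H[tr$planted_mode == "eldF"],
               tr$mu_F[tr$planted_mode == "eldF"])
  expect_equal(tr$mu_H[tr$planted_mode == "eldM"],
               tr$mu_M[tr$planted_mode == "eldM"])
  expect_equal(tr$mu_H[tr$planted_mode == "od_up"],
               (pmax(tr$mu_F, tr$mu_M) * 2^e)[tr$planted_mode == "od_up"])
  expect_equal(tr$mu_H[tr$planted_mode == "od_down"],
               (pmin(tr$mu_F, tr$mu_M) * 2^-e)[tr$planted_mode == "od_down"])
  # parents differ by exactly effect_log2 where the sub-pattern orders them
  gap <- abs(log2(tr$mu_F) - log2(tr$mu_M))
  differing <- tr$planted_mode %in% c("additive", "eldF", "eldM")
  expect_equal(gap[differing], rep(e, sum(differing)))
})

test_that("zero-noise phenotypes reproduce the planted heterosis exactly", {
  ph <- simulate_phenotypes(c(F = 8, M = 10, H = 12), 0, 5, seed = 1)
  het <- compute_heterosis(ph, c(female = "F", male = "M", hybrid = "H"))
  expect_equal(het$mph_pct, (12 - 9) / 9 * 100)   # 33.33%
  expect_equal(het$hph_pct, 20)
  # hybrid exactly at the high parent: HPH = 0
  ph2 <- simulate_phenotypes(c(F = 8, M = 10, H = 10), 0, 5, seed = 1)
  het2 <- compute_heterosis(ph2, c(female = "F", male = "M", hybrid = "H"))
  expect_equal(het2$hph_pct, 0)
})

test_that("noisy phenotype group means stay within the normal CI of the design", {
  mu <- c(F = 8, M = 10, H = 12)
  ph <- simulate_phenotypes(mu, 0.5, 30, seed = 6)
  for (g in names(mu)) {
    m <- mean(ph$value[ph$genotype == g])
    expect_lt(abs(m - mu[[g]]), 3 * 0.5 / sqrt(30))
  }
  expect_error(simulate_phenotypes(mu, -1, 10), "trait_sd")
})

test_that("annotation generator honours sizes, planted terms and edge cases", {
  g <- sprintf("g%03d", 1:100)
  expect_identical(simulate_annotation(g, 0, seed = 1), list())
  anno <- simulate_annotation(g, 20, c(5, 15), seed = 2)
  expect_length(anno, 20)
  expect_true(all(lengths(anno) >= 5 & lengths(anno) <= 15))
  expect_true(all(unlist(anno) %in% g))
  planted <- simulate_annotation(g, 10, c(5, 15),
                                 enriched_term = list(term_id = "hit",
                                                      genes = g[1:8]),
                                 seed = 2)
  expect_setequal(planted$hit, g[1:8])
  expect_error(simulate_annotation(character(0), 3), "non-empty")
  expect_error(simulate_annotation(g[1:4], 2, c(5, 10)), "exceed")
})
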