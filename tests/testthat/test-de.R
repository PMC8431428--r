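test_that("size factors follow the median-of-ratios convention", {
  m <- cbind(s1 = c(5L, 8L, 12L), s2 = c(5L, 8L, 12L))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # three samples with mixed ratios: direct arithmetic oracle
  m3 <- rbind(g1 = c(4, 8, 16), g2 = c(9, 3, 3), g3 = c(5, 10, 5))
  colnames(m3) <- paste0("s", 1:3)
  geo <- apply(m3, 1, function(x) prod(x)^(1 / 3))
  expected <- apply(m3, 2, function(col) median(col / geo))
  expect_equal(unname(estimate_size_factors(m3)), unname(expected))

  expect_error(estimate_size_factors(rbind(c(0, 1), c(2, 0))), "no gene")
})

test_that("scaling one sample rescales its factor and preserves normalised ratios", {
  set.seed(42)
  m <- matrix(rpois(60, 50) + 1L, nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  for (c_fac in c(2, 0.5, 3.7)) {
    m2 <- m
    m2[, 2] <- m[, 2] * c_fac
    sf1 <- estimate_size_factors(m)
    sf2 <- estimate_size_factors(m2)
    # the geometric-mean reference absorbs a common c^(1/n): depth changes
    # move the scaled sample's factor relative to the others by exactly c
    expect_equal((sf2[2] / sf2[1]) / (sf1[2] / sf1[1]), c_fac,
                 tolerance = 1e-12, ignore_attr = TRUE)
    n1 <- normalized_counts(m, sf1)
    n2 <- normalized_counts(m2, sf2)
    ratio <- n2 / n1
    expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
  }
})

.toy_design <- function(n_per_group, groups = c("A", "B"), tp = "T1") {
  do.call(rbind, lapply(groups, function(g) {
    data.frame(sample_id = paste0(g, "_", seq_len(n_per_group)),
               genotype = g, role = "hybrid", triad_id = "t",
               time_point = tp, replicate = seq_len(n_per_group),
               stringsAsFactors = FALSE)
  }))
}

test_that("method-of-moments dispersion matches the defining formula", {
  des <- .toy_design(3)
  # Poisson boundary: within-group variance equals the mean -> floor
  m <- cbind(A_1 = c(0L, 5L), A_2 = c(1L, 5L), A_3 = c(2L, 5L),
             B_1 = c(0L, 5L), B_2 = c(1L, 5L), B_3 = c(2L, 5L))
  rownames(m) <- c("g1", "g2")
  a <- estimate_dispersion(m, des, "A", "B", size_factors = rep(1, 6))
  expect_equal(unname(a[1]), 1e-8)  # s2 == mu exactly
  expect_equal(unname(a[2]), 1e-8)  # zero variance

  # direct formula: mu = 100, pooled s2 = 250 -> alpha = 0.0150
  m2 <- rbind(g1 = c(90L, 100L, 110L, 80L, 100L, 120L))
  colnames(m2) <- des$sample_id
  a2 <- estimate_dispersion(m2, des, "A", "B", size_factors = rep(1, 6))
  expect_equal(unname(a2), (250 - 100) / 100^2)

  expect_error(estimate_dispersion(m2, des, "A", "nope"), "unknown group")
})

test_that("dispersion recovered from NB data at alpha = 0.1 (Monte-Carlo)", {
  set.seed(99)
  n <- 50
  des <- .toy_design(n)
  mu <- 200
  m <- matrix(rnbinom(400 * 2 * n, mu = mu, size = 10), nrow = 400,
              dimnames = list(paste0("g", 1:400), des$sample_id))
  a <- estimate_dispersion(m, des, "A", "B", size_factors = rep(1, 2 * n))
  expect_gt(median(a), 0.05)
  expect_lt(median(a), 0.2)
})

test_that("Wald test is symmetric, antisymmetric and handles zeros", {
  des <- .toy_design(3)
  set.seed(1)
  base <- matrix(rpois(30 * 3, 40), nrow = 30)
  m <- cbind(base, base)  # group B identical to group A, replicate-wise
  dimnames(m) <- list(paste0("g", 1:30), des$sample_id)
  de <- nb_wald_test(m, des, "A", "B", size_factors = rep(1, 6))
  expect_equal(de$log2fc, rep(0, 30))
  expect_equal(de$p_value, rep(1, 30))

  set.seed(2)
  m2 <- matrix(rpois(30 * 6, 40), nrow = 30,
               dimnames = list(paste0("g", 1:30), des$sample_id))
  ab <- nb_wald_test(m2, des, "A", "B", size_factors = rep(1, 6))
  ba <- nb_wald_test(m2, des, "B", "A", size_factors = rep(1, 6))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_value, ba$p_value)
  expect_identical(attr(ab, "comparison"), "A vs B")

  # all-zero gene in both groups: reported flat, p = 1
  m3 <- m2
  m3[1, ] <- 0L
  z <- nb_wald_test(m3, des, "A", "B", size_factors = rep(1, 6))
  expect_equal(z$log2fc[1], 0)
  expect_equal(z$p_value[1], 1)
  # one group zero: finite fold change via the conditional pseudo-count
  m4 <- m2
  m4[2, 1:3] <- 0L
  z2 <- nb_wald_test(m4, des, "A", "B", size_factors = rep(1, 6))
  expect_true(is.finite(z2$log2fc[2]) && z2$log2fc[2] > 0)
})

test_that("planted log2 fold changes are recovered with power", {
  set.seed(11)
  n_genes <- 800
  des <- .toy_design(3)
  x <- rnorm(n_genes, 7, 1.5)
  muA <- 2^x
  muB <- muA * ifelse(seq_len(n_genes) <= 400, 4, 1)  # first half planted lfc 2
  m <- cbind(
    matrix(rnbinom(n_genes * 3, mu = rep(muA, 3), size = 20), nrow = n_genes),
    matrix(rnbinom(n_genes * 3, mu = rep(muB, 3), size = 20), nrow = n_genes)
  )
  dimnames(m) <- list(paste0("g", seq_len(n_genes)), des$sample_id)
  de <- nb_wald_test(m, des, "A", "B", size_factors = rep(1, 6))
  planted <- seq_len(400)
  expect_lt(abs(mean(de$log2fc[planted]) - 2), 0.2)
  calls <- call_degs(de)$call
  expect_gte(mean(calls[planted] == "up"), 0.8)     # power
  expect_lte(mean(calls[-planted] != "ns"), 0.02)   # specificity
})

test_that("BH step-up matches its defining formula and reference implementation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.037), 0.037)            # m = 1 identity
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5)) # all equal: q = p m/m
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- adjust_bh(p)
    expect_equal(q, bh_naive(p))
    expect_equal(q, p.adjust(p, "BH"))  # independent reference
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p
  }
})

test_that("DEG calls follow the two-threshold rule", {
  de <- data.frame(gene_id = paste0("g", 1:4),
                   log2fc = c(1.5, 0.9, -2.0, -1.0),
                   p_adj = c(0.01, 0.001, 0.06, 0.04))
  calls <- call_degs(de)
  expect_equal(calls$call, c("up", "ns", "ns", "down"))
  expect_equal(attr(calls, "counts"), c(up = 1L, down = 1L, total = 2L))
})
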