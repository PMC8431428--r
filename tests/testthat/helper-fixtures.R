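# Shared fixtures, built in code.

# small default simulation reused by several files
small_sim <- function(seed = 7, n_genes = 300, ...) {
  simulate_triad_counts(sim_config(n_genes = n_genes, seed = seed, ...))
}

# pipeline-style dispersion: pooled over all triad cells, smoothed on the mean
pooled_trended_dispersion <- function(sim) {
  sf <- estimate_size_factors(sim$counts)
  gw <- estimate_dispersion(sim$counts, sim$design, size_factors = sf,
                            groups = unique(sim$design$genotype))
  dispersion_trend(gw, rowMeans(normalized_counts(sim$counts, sf)))
}

classify_sim <- function(sim, time_point = "T1", ...) {
  disp <- pooled_trended_dispersion(sim)
  de_fm <- nb_wald_test(sim$counts, sim$design, "F", "M",
                        time_point = time_point, dispersion = disp)
  de_fh <- nb_wald_test(sim$counts, sim$design, "F", "H",
                        time_point = time_point, dispersion = disp)
  de_mh <- nb_wald_test(sim$counts, sim$design, "M", "H",
                        time_point = time_point, dispersion = disp)
  classify_triad(de_fm, de_fh, de_mh, ...)
}

# brute-force upper-tail hypergeometric by binomial-coefficient arithmetic
hyper_upper_bruteforce <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# naive min-over-suffix BH oracle (quadratic on purpose)
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}
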