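# Balding-Nichols frequency generator, founder-mosaic haplotypes and the
# pooled-sequencing emulator.

test_that("zero drift returns the ancestral frequencies exactly", {
  m <- population_model(n_populations = 3, drift_F = 0, n_sites = 50, seed = 1)
  f <- simulate_population_frequencies(m)
  anc <- attr(f, "ancestral")
  for (j in 1:3) expect_identical(unname(f[, j]), anc)
})

test_that("frequency table has one row per site and is deterministic by seed", {
  m <- population_model(n_populations = 4, n_sites = 1, seed = 3)
  f <- simulate_population_frequencies(m)
  expect_identical(dim(f), c(1L, 4L))
  m2 <- population_model(n_populations = 2, n_sites = 300, seed = 5)
  expect_identical(simulate_population_frequencies(m2),
                   simulate_population_frequencies(m2))
  m3 <- population_model(n_populations = 2, n_sites = 300, seed = 6)
  expect_false(identical(simulate_population_frequencies(m2),
                         simulate_population_frequencies(m3)))
})

test_that("realized differentiation matches the Balding-Nichols expectation", {
  # Independent oracle: for two demes with the same F, the ratio-of-sums
  # G_ST over many loci converges to (F/2) / (1 - F/2), i.e. 0.0526 at
  # F = 0.1 (HT subtracts only half the between-deme variance).
  m <- population_model(n_populations = 2, drift_F = 0.1, n_sites = 20000,
                        seed = 42)
  f <- simulate_population_frequencies(m)
  fst <- fst_pairwise(f[, 1], f[, 2])
  expect_equal(fst, 0.05 / 0.95, tolerance = 0.02 / (0.05 / 0.95))
})

test_that("sampled haplotypes recover the model frequencies", {
  m <- population_model(n_populations = 1, drift_F = 0, n_sites = 60,
                        n_founder_haplotypes = 1000, seed = 9)
  f <- simulate_population_frequencies(m)
  f[] <- 0.3
  haps <- simulate_haplotypes(f, 500, model = m) # H = 1000 haplotypes
  obs <- rowMeans(haps$alleles)
  # binomial bound inflated for founder-template collisions: with K founders
  # Var(mean) = p(1-p)(1 + (H-1)/K)/H
  H <- 1000; K <- 1000
  bound <- 4 * sqrt(0.3 * 0.7 * (1 + (H - 1) / K) / H)
  expect_true(all(abs(obs - 0.3) <= bound))
})

test_that("degenerate frequencies and zero switch rate behave as limits", {
  m <- population_model(n_populations = 1, n_sites = 40,
                        n_founder_haplotypes = 4, mosaic_switch_rate = 0,
                        seed = 13)
  f <- simulate_population_frequencies(m)
  f[1:10, 1] <- 1 # fixed sites
  haps <- simulate_haplotypes(f, 8, model = m)
  expect_true(all(haps$alleles[1:10, ] == 1L))
  # no recombination: every haplotype is an exact copy of one founder, so at
  # most n_founder_haplotypes distinct haplotypes exist
  distinct <- unique(apply(haps$alleles, 2, paste, collapse = ""))
  expect_lte(length(distinct), 4)
})

test_that("mosaic switching produces decaying LD along the map", {
  m <- population_model(n_populations = 1, drift_F = 0, n_sites = 400,
                        n_founder_haplotypes = 8, mosaic_switch_rate = 0.5,
                        seed = 21)
  f <- simulate_population_frequencies(m)
  haps <- simulate_haplotypes(f, 150, model = m)
  a <- haps$alleles
  keep <- apply(a, 1, sd) > 0
  a <- a[keep, ]
  r_adj <- mean(abs(diag(cor(t(a[-nrow(a), ]), t(a[-1, ])))), na.rm = TRUE)
  far <- sample(which(keep), 100, replace = TRUE)
  r_far <- mean(abs(diag(cor(t(a[seq_len(100), ]), t(a[nrow(a) - seq_len(100) + 1, ])))),
                na.rm = TRUE)
  expect_gt(r_adj, r_far + 0.1) # neighbours in LD, distant sites not
})

test_that("haplotype panel and genotype matrix stay consistent", {
  w <- small_world(seed = 31, n_pops = 3, n_sites = 100, n_ind = 5)
  h <- w$haps$alleles
  expect_identical(w$geno$dosage,
                   h[, seq(1, ncol(h), 2)] + h[, seq(2, ncol(h), 2)],
                   ignore_attr = TRUE)
  expect_identical(unname(w$geno$pop[w$haps$individuals]),
                   unname(w$haps$pop[w$haps$individuals]))
})

test_that("pooled sequencing emulation honours its degenerate cases", {
  # all-1 pool with positive depth estimates exactly 1
  a <- matrix(1L, 5, 20)
  haps <- toy_haplotypes(a)
  ps <- simulate_pool_seq(haps, n_pool = 10, mean_depth = 50, seed = 1)
  expect_true(all(ps$freq[ps$depth > 0] == 1))
  # zero-coverage sites are missing
  ps2 <- simulate_pool_seq(haps, n_pool = 10, mean_depth = 0.05, seed = 2)
  expect_true(any(ps2$depth == 0))
  expect_true(all(is.na(ps2$freq[ps2$depth == 0])))
  expect_error(simulate_pool_seq(haps, n_pool = 21, mean_depth = 5),
               "exceeds available")
})

test_that("pooling bias follows the finite-pool and finite-depth factors", {
  # Oracle (derived before implementation): with a source population of
  # i.i.d. Bernoulli(p) haplotypes, a pool of n of them and Poisson(depth)
  # coverage, E[2 phat (1 - phat)] = 2 p (1-p) * (n-1)/n * (1 - E[1/d | d > 0]).
  # The n/(n-1) correction removes the pool factor only; the finite-depth
  # attenuation remains.
  p <- 0.5; n_pool <- 20; depth <- 30; L <- 6000
  set.seed(77)
  haps <- toy_haplotypes(matrix(rbinom(L * 400, 1L, p), L, 400),
                         map = genetic_map("1", seq_len(L), seq_len(L) * 1e-3))
  ps <- simulate_pool_seq(haps, n_pool = n_pool, mean_depth = depth, seed = 79)
  d <- 1:200
  e_inv_d <- sum((1 / d) * dpois(d, depth)) / (1 - dpois(0, depth))
  truth <- 2 * p * (1 - p)
  he_hat <- expected_heterozygosity(ps$freq)
  expect_equal(he_hat / truth, (1 - e_inv_d) * (n_pool - 1) / n_pool,
               tolerance = 0.01)
  corrected <- pool_correct_he(he_hat, n_pool)
  expect_equal(corrected / truth, 1 - e_inv_d, tolerance = 0.01)
})
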