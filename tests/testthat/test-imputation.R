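# Li-Stephens imputation engine: recombination parameterisation, exact
# forward-backward vs path enumeration, conservation, and DR2.

test_that("recombination weights follow the Li-Stephens scaling", {
  m <- genetic_map("1", c(1L, 2L, 3L), c(0, 0, 0.01))
  rho <- recombination_weights(m, ne = 1000, n_ref_haplotypes = 20)
  expect_equal(rho[1], 0)                      # zero distance
  expect_equal(rho[2], 1 - exp(-0.02), tolerance = 1e-12)
  # saturation: large ne approaches but never exceeds 1
  rho_big <- recombination_weights(m, ne = 1e12, n_ref_haplotypes = 20)
  expect_true(all(rho_big <= 1))
  expect_gt(rho_big[2], 1 - 1e-9)
  # chromosome boundary forces a switch
  m2 <- genetic_map(c("1", "1", "2"), c(1L, 2L, 1L), c(0, 1, 0))
  expect_equal(recombination_weights(m2, 1000, 10)[2], 1)
  expect_error(recombination_weights(m, 1000, 0), "zero reference")
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(2024)
  for (i in 1:40) {
    L <- sample(1:4, 1)
    K <- sample(1:3, 1)
    ref <- matrix(rbinom(L * K, 1, 0.5), L, K)
    obs <- rbinom(L, 1, 0.5)
    obs[runif(L) < 0.35] <- NA
    eps <- runif(1, 0.01, 0.3)
    map <- genetic_map("1", seq_len(L) * 10L, cumsum(c(0, runif(L - 1, 0, 0.3))))
    cfg <- imputer_config(ne = runif(1, 10, 2000), error_rate = eps)
    rho <- if (L > 1) recombination_weights(map, cfg$ne, K) else numeric(0)
    oracle <- enumerate_ls_posterior(ref, obs, rho, eps)
    got <- impute_haplotype(obs, ref, map, cfg, return_states = TRUE)
    expect_equal(got$allele, oracle$allele, tolerance = 1e-10)
    expect_equal(unclass(got$states), oracle$states, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(rowSums(got$states), rep(1, L), tolerance = 1e-9)
  }
})

test_that("the worked 3-site/2-haplotype example matches enumeration", {
  ref <- cbind(c(0L, 1L, 0L), c(1L, 1L, 1L))
  obs <- c(0L, NA, 0L) # middle site masked
  map <- genetic_map("1", 1:3 * 100L, c(0, 0.5, 1))
  cfg <- imputer_config(ne = 500, error_rate = 0.1)
  rho <- recombination_weights(map, 500, 2)
  oracle <- enumerate_ls_posterior(ref, obs, rho, 0.1)
  expect_equal(impute_haplotype(obs, ref, map, cfg), oracle$allele,
               tolerance = 1e-10)
})

test_that("perfect-match and no-recombination limits behave", {
  set.seed(5)
  L <- 30
  ref <- matrix(rbinom(L * 4, 1, 0.5), L, 4)
  target <- ref[, 2]
  obs <- target
  masked <- c(7, 15, 23)
  obs[masked] <- NA
  # make haplotype 2 uniquely identifiable; dense map so the copying state
  # persists across the masked sites
  ref[, -2] <- 1L - ref[, 2]
  map <- toy_map(L, spacing_cM = 0.001)
  post <- impute_haplotype(obs, ref, map, imputer_config(ne = 100, error_rate = 1e-6))
  expect_true(all(abs(post[masked] - target[masked]) < 0.01))
  # zero-length map: no recombination, state posterior constant across sites
  map0 <- genetic_map("1", seq_len(L) * 10L, rep(0, L))
  r <- impute_haplotype(obs, ref, map0, imputer_config(error_rate = 0.05),
                        return_states = TRUE)
  expect_equal(apply(r$states, 2, function(col) max(col) - min(col)),
               rep(0, 4), tolerance = 1e-9)
})

test_that("a window without typed sites falls back to reference frequencies", {
  L <- 10
  set.seed(9)
  ref <- matrix(rbinom(L * 6, 1, 0.4), L, 6)
  obs <- rep(NA_integer_, L)
  post <- impute_haplotype(obs, ref, toy_map(L), imputer_config())
  expect_equal(post, rowMeans(ref), tolerance = 1e-9)
})

test_that("window stitching agrees with a single-window run on dense maps", {
  set.seed(33)
  L <- 120
  ref <- matrix(rbinom(L * 8, 1, 0.5), L, 8)
  obs <- rbinom(L, 1, 0.5)
  obs[sample(L, 40)] <- NA
  map <- toy_map(L, spacing_cM = 0.05) # ~6 cM span
  single <- impute_haplotype(obs, ref, map, imputer_config(window_cM = 200))
  split <- impute_haplotype(obs, ref, map, imputer_config(window_cM = 2))
  # stitching is an approximation near window edges only; the error must
  # shrink quickly as the overlap grows relative to the HMM memory
  expect_true(all(abs(single - split) < 0.15))
  expect_true(all(split >= 0 & split <= 1))
  split2 <- impute_haplotype(obs, ref, map,
                             imputer_config(window_cM = 5, overlap_frac = 0.25))
  expect_true(all(abs(single - split2) < 0.005))
})

test_that("DR2 matches its closed form on hand cases", {
  expect_equal(compute_dr2(c(0, 1, 1, 0)), 1)
  expect_equal(compute_dr2(rep(0.37, 8)), 0)
  expect_equal(compute_dr2(c(0.9, 0.1)), 0.64, tolerance = 1e-12)
  expect_true(is.na(compute_dr2(c(0, 0, 0))))   # denominator 0
  expect_error(compute_dr2(0.5), "at least 2")
})

test_that("impute_genotypes conserves typed entries and flags site classes", {
  w <- small_world(seed = 61, n_pops = 3, n_sites = 250, n_ind = 8)
  g <- w$geno
  mask <- design_array(g, "P01", 0.05)
  panel <- filter_reference_sites(g, sample_reference(g, "allPop", 2, seed = 3))
  study_ids <- setdiff(w$haps$individuals, panel$individuals)
  study <- ascbias:::subset_individuals(apply_mask(w$haps, mask), study_ids)
  refh <- ascbias:::subset_individuals(w$haps, panel$individuals)
  res <- impute_genotypes(study, refh, panel)
  # conservation, cell-exact
  typed <- res$typed
  expect_identical(res$best_guess[typed], g$dosage[, study_ids][typed])
  expect_true(all(res$dosage[typed] == g$dosage[, study_ids][typed]))
  # masked sites outside the reference retained set stay missing
  if (length(res$unimputable_sites)) {
    expect_true(all(is.na(res$dosage[res$unimputable_sites, ])))
  }
  expect_true(all(res$dosage >= 0 & res$dosage <= 2, na.rm = TRUE))
  expect_true(all(res$dr2 >= 0 & res$dr2 <= 1, na.rm = TRUE))
  # posterior-dosage consistency: dosage = hap1 + hap2 posterior
  h1 <- res$posterior[, seq(1, ncol(res$posterior), 2)]
  h2 <- res$posterior[, seq(2, ncol(res$posterior), 2)]
  imp <- setdiff(res$imputed_sites, which(rowSums(is.na(res$posterior)) > 0))
  expect_equal(unname(res$dosage[imp, ]), unname((h1 + h2)[imp, ]),
               tolerance = 1e-12)
})

test_that("self-reference imputation is perfect", {
  w <- small_world(seed = 71, n_pops = 2, n_sites = 200, n_ind = 6)
  g <- w$geno
  mask <- design_array(g, "P01", 0.1)
  panel <- sample_reference(g, "randSamp", length(w$haps$individuals), seed = 1)
  panel <- filter_reference_sites(g, panel, 0)
  study <- apply_mask(w$haps, mask)
  res <- impute_genotypes(study, w$haps, panel,
                          imputer_config(ne = 5, error_rate = 1e-6))
  acc <- per_animal_accuracy(g, res)
  expect_true(all(acc$r > 0.999, na.rm = TRUE))
})

test_that("no masked sites means output equals input", {
  w <- small_world(seed = 81, n_pops = 2, n_sites = 120, n_ind = 5)
  panel <- filter_reference_sites(w$geno, sample_reference(w$geno, "allPop", 1, seed = 2))
  study_ids <- setdiff(w$haps$individuals, panel$individuals)
  study <- ascbias:::subset_individuals(w$haps, study_ids) # nothing masked
  refh <- ascbias:::subset_individuals(w$haps, panel$individuals)
  res <- impute_genotypes(study, refh, panel)
  expect_identical(unname(res$best_guess), unname(w$geno$dosage[, study_ids]))
  expect_length(res$imputed_sites, 0)
})
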