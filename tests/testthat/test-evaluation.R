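# Group assignment, bias regression, mean overestimation, accuracy and
# leave-one-out validation.

test_that("group assignment applies precedence and the collapse rule", {
  pops <- paste0("P", 1:5)
  # panel covering every population: reference label collapses away
  g1 <- assign_groups(pops, "P3", panel = pops)
  expect_identical(unname(g1["P3"]), "discovery")
  expect_true(all(g1[setdiff(pops, "P3")] == "application"))
  # partial panel: three-way split
  g2 <- assign_groups(pops, "P3", panel = c("P1", "P2"))
  expect_identical(unname(g2[c("P1", "P2", "P3", "P4", "P5")]),
                   c("reference", "reference", "discovery", "application", "application"))
  # discovery takes precedence over reference
  g3 <- assign_groups(pops, "P1", panel = c("P1", "P2"))
  expect_identical(unname(g3["P1"]), "discovery")
  expect_error(assign_groups(pops, "P9"), "unknown discovery")
  # pair labels are unordered
  expect_identical(pair_group("discovery", "application"),
                   pair_group("application", "discovery"))
})

test_that("mean overestimation matches direct evaluation", {
  expect_equal(mean_overestimation(c(0.5, 0.25), c(0.5, 0.25)), 0)
  expect_equal(mean_overestimation(c(0.6, 0.3), c(0.5, 0.25)), 0.2, tolerance = 1e-12)
  tr <- c(0.2, 0.4, 0.1)
  expect_equal(mean_overestimation(1.3 * tr, tr), 0.3, tolerance = 1e-12)
  expect_warning(mo <- mean_overestimation(c(0.5, 0.2), c(0.5, 0)), "true value 0")
  expect_equal(mo, 0)
})

test_that("group regression recovers the identity line and hand-computed OLS", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  id <- group_regression(x, x, rep(c("a", "b"), 2))
  expect_equal(id$groups$slope, c(1, 1), tolerance = 1e-12)
  expect_equal(id$groups$intercept, c(0, 0), tolerance = 1e-12)
  expect_equal(id$groups$r, c(1, 1), tolerance = 1e-12)
  fit <- group_regression(x, c(0.25, 0.40, 0.55, 0.70), rep("g", 4))
  expect_equal(unname(coef(fit)["g", "slope"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["g", "intercept"]), 0.10, tolerance = 1e-9)
  expect_equal(fit$groups$mean_overestimation,
               mean((c(0.25, 0.40, 0.55, 0.70) - x) / x), tolerance = 1e-12)
})

test_that("groups are fitted independently and non-finite pairs dropped with counts", {
  x <- c(1, 2, 3, 1, 2, 3)
  y <- c(1.1, 2.1, 3.3, 1.1, 2.1, 3.3)
  two <- group_regression(x, y, rep(c("a", "b"), each = 3))
  expect_equal(two$groups$slope[1], two$groups$slope[2], tolerance = 1e-12)
  y2 <- c(y[1:5], Inf)
  fit <- group_regression(x, y2, rep(c("a", "b"), each = 3))
  expect_identical(fit$groups$n_dropped, c(0L, 1L))
  expect_identical(fit$groups$n, c(3L, 2L))
  expect_false(fit$groups$reliable[2]) # < 3 points
  # constant x: slope undefined, flagged
  fit2 <- group_regression(rep(1, 4), rnorm(4), rep("c", 4))
  expect_true(is.na(fit2$groups$slope))
  expect_false(fit2$groups$reliable)
})

test_that("regression recovers known group-specific coefficients within 3 SE", {
  set.seed(12)
  x <- runif(60, 0.1, 0.5)
  groups <- rep(c("g1", "g2"), each = 30)
  truth <- list(g1 = c(0.05, 1.4), g2 = c(-0.02, 0.9))
  y <- ifelse(groups == "g1", 0.05 + 1.4 * x, -0.02 + 0.9 * x) + rnorm(60, 0, 0.01)
  fit <- group_regression(x, y, groups)
  for (g in c("g1", "g2")) {
    d <- data.frame(x = x[groups == g], y = y[groups == g])
    se <- summary(lm(y ~ x, d))$coefficients[, "Std. Error"]
    expect_lt(abs(coef(fit)[g, "intercept"] - truth[[g]][1]), 3 * se[1])
    expect_lt(abs(coef(fit)[g, "slope"] - truth[[g]][2]), 3 * se[2])
  }
  # proportional bias: mean overestimation equals slope - 1 at zero intercept
  yc <- 1.25 * x
  fitc <- group_regression(x, yc, rep("g", 60))
  expect_equal(fitc$groups$mean_overestimation, fitc$groups$slope - 1,
               tolerance = 1e-9)
})

test_that("per-animal accuracy reproduces the textbook Pearson formula", {
  truth_vec <- c(0, 1, 2, 1)
  imp_vec <- c(0.2, 1.0, 1.8, 0.6)
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  w <- small_world(seed = 55, n_pops = 2, n_sites = 4, n_ind = 3)
  g <- w$geno
  g$dosage[, 1] <- as.integer(truth_vec)
  res <- structure(list(
    posterior = NULL,
    dosage = matrix(imp_vec, 4, 6,
                    dimnames = list(NULL, colnames(g$dosage))),
    imputed_sites = 1:4, individuals = colnames(g$dosage), pop = g$pop),
    class = "imputation_result")
  res$dosage[, 1] <- imp_vec
  acc <- per_animal_accuracy(g, res)
  expect_equal(acc$r[1], pearson(truth_vec, imp_vec), tolerance = 1e-12)
  # r = 1 when imputation equals truth, r = -1 under a systematic flip
  res$dosage[, 1] <- truth_vec
  expect_equal(per_animal_accuracy(g, res)$r[1], 1)
  res$dosage[, 1] <- 2 - truth_vec
  expect_equal(per_animal_accuracy(g, res)$r[1], -1)
  # zero variance is a missing value with a reason, not an error
  g$dosage[, 2] <- 1L
  acc2 <- per_animal_accuracy(g, res)
  expect_true(is.na(acc2$r[2]))
  expect_identical(acc2$reason[2], "zero variance")
})

test_that("leave-one-out scores duplicates perfectly and annotates lone populations", {
  w <- small_world(seed = 66, n_pops = 3, n_sites = 200, n_ind = 6)
  # identical twins: duplicate one individual's haplotypes into another
  haps <- w$haps
  haps$alleles[, 3:4] <- haps$alleles[, 1:2]
  g <- as_genotypes(haps)
  mask <- design_array(g, "P01", 0.05)
  # panel: the twin pair plus one individual from each other population, so
  # the reduced panels stay informative
  panel <- sample_reference(g, "allPop", 1, seed = 1)
  panel$individuals <- c(haps$individuals[1:2],
                         haps$individuals[match(c("P02", "P03"), haps$pop)])
  panel$pop <- unname(haps$pop[panel$individuals])
  cfg <- imputer_config(ne = 5, error_rate = 1e-6) # dense-information limit
  loo <- leave_one_out(haps, panel, mask, cfg)
  twins <- haps$individuals[1:2]
  expect_true(all(loo$r[loo$individual %in% twins] > 0.99))
  expect_true(all(loo$same_pop_in_panel[loo$individual %in% twins]))
  # one individual per population: no same-population mate ever remains
  p1 <- sample_reference(g, "allPop", 1, seed = 9)
  loo1 <- leave_one_out(w$haps, p1, mask, cfg)
  expect_true(all(!loo1$same_pop_in_panel))
  expect_error(leave_one_out(w$haps, panel[["none"]], mask), "reference_panel")
})
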