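# Scenario orchestration: simulate truth, design arrays per discovery
# population, build reference panels, impute, estimate and tabulate —
# fully reproducible from a configuration plus a master seed. Each cell
# (repetition x discovery population x strategy) derives its own child seed
# from the master seed and its identifiers, so cells are independently
# reproducible.

#' Scenario configuration
#'
#' Bundles every knob of a simulation sweep. Defaults are the package's
#' reference study conditions: 10 populations spanning drift 0.05-0.25,
#' 5000 sites on a 100 cM chromosome, 20 diploid individuals per population,
#' a discovery MAF filter of 0.05 and a reference MAF filter of 0.01.
#'
#' @param model a [population_model].
#' @param n_individuals_per_pop diploid study individuals per population.
#' @param maf_discovery discovery-population MAF threshold (strict `>`).
#' @param maf_reference reference-panel MAF threshold (strict `>`).
#' @param strategies list of strategy cells, each a list with elements
#'   `strategy` and `size` (and optionally `samples_per_pop`); may be empty
#'   when `impute = FALSE`.
#' @param discovery_pops either `"all"` (every population serves as
#'   discovery population in every repetition) or an integer: how many
#'   discovery populations to rotate through per repetition.
#' @param repetitions number of repetitions (fresh truth simulation each).
#' @param imputer an [imputer_config].
#' @param impute run the imputation arm?
#' @param seed master seed.
#' @param output_dir optional directory for tidy TSV output.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(model = population_model(),
                            n_individuals_per_pop = 20,
                            maf_discovery = 0.05,
                            maf_reference = 0.01,
                            strategies = list(list(strategy = "allPop", size = 1)),
                            discovery_pops = 1,
                            repetitions = 3,
                            imputer = imputer_config(),
                            impute = TRUE,
                            seed = 1,
                            output_dir = NULL) {
  stopifnot(inherits(model, "population_model"), repetitions >= 1,
            n_individuals_per_pop >= 1, maf_discovery >= 0, maf_reference >= 0)
  for (s in strategies) {
    if (is.null(s$strategy) || !s$strategy %in% REF_STRATEGIES) {
      stop("each strategy cell needs a 'strategy' field in: ",
           paste(REF_STRATEGIES, collapse = ", "))
    }
    if (is.null(s$size) || s$size < 1) stop("each strategy cell needs a positive 'size'")
  }
  if (!identical(discovery_pops, "all")) {
    stopifnot(is.numeric(discovery_pops), discovery_pops >= 1,
              discovery_pops <= model$n_populations)
  }
  structure(list(model = model, n_individuals_per_pop = n_individuals_per_pop,
                 maf_discovery = maf_discovery, maf_reference = maf_reference,
                 strategies = strategies, discovery_pops = discovery_pops,
                 repetitions = as.integer(repetitions), imputer = imputer,
                 impute = isTRUE(impute), seed = seed, output_dir = output_dir),
            class = "scenario_config")
}

# Per-population H_E/H_O over a site subset. he from a (possibly fractional)
# dosage matrix; ho from an integer genotype matrix.
pop_estimates <- function(dos_he, dos_ho, pops, sites) {
  labels <- sort(unique(unname(pops)))
  he <- ho <- numeric(length(labels))
  for (i in seq_along(labels)) {
    cols <- which(pops == labels[i])
    p <- rowMeans(dos_he[sites, cols, drop = FALSE], na.rm = TRUE) / 2
    he[i] <- expected_heterozygosity(p)
    g <- dos_ho[sites, cols, drop = FALSE]
    ho[i] <- sum(g == 1, na.rm = TRUE) / max(sum(!is.na(g)), 1L)
  }
  data.frame(pop = labels, he = he, ho = ho, stringsAsFactors = FALSE)
}

# Pairwise D / F_ST between population sample frequencies over a site subset.
pairwise_estimates <- function(dos, pops, sites) {
  labels <- sort(unique(unname(pops)))
  freqs <- vapply(labels, function(p) {
    rowMeans(dos[sites, pops == p, drop = FALSE], na.rm = TRUE) / 2
  }, numeric(length(sites)))
  pairs <- utils::combn(labels, 2)
  n <- ncol(pairs)
  d <- fst <- numeric(n)
  for (k in seq_len(n)) {
    x <- freqs[, pairs[1, k]]
    y <- freqs[, pairs[2, k]]
    d[k] <- suppressWarnings(nei_distance(x, y))
    fst[k] <- fst_pairwise(x, y)
  }
  data.frame(pop1 = pairs[1, ], pop2 = pairs[2, ], d = d, fst = fst,
             stringsAsFactors = FALSE)
}

#' Run a full ascertainment-bias scenario sweep
#'
#' For every repetition: simulate truth haplotypes/genotypes; for every
#' scheduled discovery population: design the in-silico array
#' (discovery-MAF filter) and compute ascertained estimates; for every
#' reference-panel strategy: sample the panel, filter reference sites,
#' impute the masked study set and compute imputed estimates and per-animal
#' accuracies. Population-group labels (discovery/reference/application)
#' are attached throughout. Cell failures are caught and recorded; the
#' remaining cells proceed.
#'
#' @param config a [scenario_config].
#' @return object of class `scenario_result`: list of tidy data.frames
#'   `estimates` (rep x discovery_pop x dataset x pop), `pairwise`
#'   (distances D/F_ST per population pair), `accuracy` (per-animal Pearson
#'   r), and `cells` (run records incl. seeds and failures).
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  model <- config$model
  pops <- model$populations
  npop <- length(pops)
  est <- list(); pw <- list(); acc <- list(); cells <- list()
  ei <- pi_ <- ai <- ci <- 0L

  for (rep_i in seq_len(config$repetitions)) {
    sim_seed <- child_seed(config$seed, "sim", rep_i)
    freqs <- simulate_population_frequencies(model, seed = sim_seed)
    haps <- simulate_haplotypes(freqs, config$n_individuals_per_pop,
                                model = model, seed = sim_seed)
    geno <- as_genotypes(haps)
    L <- nrow(geno$dosage)
    all_sites <- seq_len(L)

    true_est <- pop_estimates(geno$dosage, geno$dosage, geno$pop, all_sites)
    true_pw <- pairwise_estimates(geno$dosage, geno$pop, all_sites)
    # true-frequency distance matrix for minPop/maxPop panel choice: in the
    # in-silico design the experimenter holds the full genotype matrix
    dist_mat <- pairwise_distance_matrix(
      vapply(pops, function(p) allele_frequencies(geno, pop = p),
             numeric(L)), "nei")

    disc_set <- if (identical(config$discovery_pops, "all")) pops else {
      k <- config$discovery_pops
      pops[((rep_i - 1L) * k + seq_len(k) - 1L) %% npop + 1L]
    }

    for (dpop in disc_set) {
      cell_id <- list(rep = rep_i, discovery_pop = dpop)
      res <- tryCatch({
        mask <- design_array(geno, dpop, config$maf_discovery)
        asc_est <- pop_estimates(geno$dosage, geno$dosage, geno$pop, mask$sites)
        asc_pw <- pairwise_estimates(geno$dosage, geno$pop, mask$sites)
        groups0 <- assign_groups(pops, dpop, panel = NULL)

        ei <- ei + 1L
        est[[ei]] <- rbind(
          cbind(rep = rep_i, discovery_pop = dpop, dataset = "true",
                strategy = NA_character_, true_est,
                group = unname(groups0[true_est$pop])),
          cbind(rep = rep_i, discovery_pop = dpop, dataset = "ascertained",
                strategy = NA_character_, asc_est,
                group = unname(groups0[asc_est$pop])))
        pi_ <- pi_ + 1L
        pw[[pi_]] <- rbind(
          cbind(rep = rep_i, discovery_pop = dpop, dataset = "true",
                strategy = NA_character_, true_pw,
                group = pair_group(groups0[true_pw$pop1], groups0[true_pw$pop2])),
          cbind(rep = rep_i, discovery_pop = dpop, dataset = "ascertained",
                strategy = NA_character_, asc_pw,
                group = pair_group(groups0[asc_pw$pop1], groups0[asc_pw$pop2])))

        if (config$impute) {
          masked_haps <- apply_mask(haps, mask)
          for (strat in config$strategies) {
            strat_id <- sprintf("%s_%d", strat$strategy, strat$size)
            panel_seed <- child_seed(config$seed, "panel", rep_i, dpop, strat_id)
            panel <- sample_reference(
              geno, strat$strategy, strat$size, discovery_pop = dpop,
              distances = dist_mat,
              samples_per_pop = strat$samples_per_pop %||% 5,
              seed = panel_seed)
            panel <- filter_reference_sites(geno, panel, config$maf_reference)
            groups <- assign_groups(pops, dpop, panel)

            study_ids <- setdiff(haps$individuals, panel$individuals)
            study <- subset_individuals(masked_haps, study_ids)
            ref_haps <- subset_individuals(haps, panel$individuals)
            imp <- impute_genotypes(study, ref_haps, panel, config$imputer)

            # assemble the imputed data set: imputed dosages for study
            # individuals, truth for reference individuals, over the sites
            # the imputed set contains (array sites + reference sites)
            use_sites <- sort(union(mask$sites, panel$sites))
            dos_he <- matrix(NA_real_, L, ncol(geno$dosage),
                             dimnames = dimnames(geno$dosage))
            dos_ho <- matrix(NA_integer_, L, ncol(geno$dosage),
                             dimnames = dimnames(geno$dosage))
            dos_he[, study_ids] <- imp$dosage[, study_ids]
            dos_ho[, study_ids] <- imp$best_guess[, study_ids]
            dos_he[, panel$individuals] <- geno$dosage[, panel$individuals]
            dos_ho[, panel$individuals] <- geno$dosage[, panel$individuals]

            imp_est <- pop_estimates(dos_he, dos_ho, geno$pop, use_sites)
            imp_pw <- pairwise_estimates(dos_he, geno$pop, use_sites)
            ei <- ei + 1L
            est[[ei]] <- cbind(rep = rep_i, discovery_pop = dpop,
                                dataset = "imputed", strategy = strat_id,
                                imp_est, group = unname(groups[imp_est$pop]))
            pi_ <- pi_ + 1L
            pw[[pi_]] <- cbind(rep = rep_i, discovery_pop = dpop,
                                dataset = "imputed", strategy = strat_id,
                                imp_pw, group = pair_group(groups[imp_pw$pop1],
                                                           groups[imp_pw$pop2]))
            a <- per_animal_accuracy(geno, imp)
            ai <- ai + 1L
            acc[[ai]] <- cbind(rep = rep_i, discovery_pop = dpop,
                                strategy = strat_id, a,
                                group = unname(groups[a$pop]))
          }
        }
        list(status = "ok", seed = sim_seed)
      }, error = function(e) list(status = "error", seed = sim_seed,
                                  message = conditionMessage(e)))
      ci <- ci + 1L
      cells[[ci]] <- data.frame(rep = rep_i, discovery_pop = dpop,
                                seed = res$seed, status = res$status,
                                message = res$message %||% NA_character_,
                                stringsAsFactors = FALSE)
    }
  }

  out <- structure(list(
    estimates = do.call(rbind, est),
    pairwise = do.call(rbind, pw),
    accuracy = if (ai > 0L) do.call(rbind, acc) else NULL,
    cells = do.call(rbind, cells),
    config = config), class = "scenario_result")
  rownames(out$estimates) <- rownames(out$pairwise) <- rownames(out$cells) <- NULL
  if (!is.null(out$accuracy)) rownames(out$accuracy) <- NULL
  if (!is.null(config$output_dir)) write_scenario_result(out, config$output_dir)
  n_failed <- sum(out$cells$status != "ok")
  if (n_failed > 0) {
    warning(n_failed, " scenario cell(s) failed; see $cells for messages")
  }
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %d cells (%d failed), %d repetitions\n",
              nrow(x$cells), sum(x$cells$status != "ok"), x$config$repetitions))
  cat(sprintf("  estimates: %d rows; pairwise: %d rows; accuracy: %s rows\n",
              nrow(x$estimates), nrow(x$pairwise),
              if (is.null(x$accuracy)) "0" else nrow(x$accuracy)))
  invisible(x)
}

#' Compare biased data sets against the truth of a scenario result
#'
#' Joins a biased data set (`"ascertained"` or `"imputed"` + strategy) with
#' the `"true"` estimates of the same repetition/discovery cell and fits the
#' group-specific bias regression for the chosen statistic.
#'
#' @param result a [run_scenario()] result.
#' @param dataset `"ascertained"` or `"imputed"`.
#' @param stat `"he"`, `"ho"` (from `$estimates`) or `"d"`, `"fst"`
#'   (from `$pairwise`).
#' @param strategy strategy id (e.g. `"allPop_1"`) for `dataset = "imputed"`.
#' @param reps optional repetition subset.
#' @return a [group_regression()] `bias_fit`.
#' @export
scenario_bias_fit <- function(result, dataset = "ascertained",
                              stat = c("he", "ho", "d", "fst"),
                              strategy = NULL, reps = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  stat <- match.arg(stat)
  tab <- if (stat %in% c("he", "ho")) result$estimates else result$pairwise
  keys <- if (stat %in% c("he", "ho")) c("rep", "discovery_pop", "pop") else
    c("rep", "discovery_pop", "pop1", "pop2")
  if (!is.null(reps)) tab <- tab[tab$rep %in% reps, ]
  truth <- tab[tab$dataset == "true", ]
  biased <- tab[tab$dataset == dataset &
                  (is.null(strategy) | tab$strategy %in% strategy), ]
  if (nrow(biased) == 0L) stop("no rows for dataset ", dataset,
                               if (!is.null(strategy)) paste0(" / ", strategy))
  key_t <- do.call(paste, c(truth[keys], sep = "\x1f"))
  key_b <- do.call(paste, c(biased[keys], sep = "\x1f"))
  m <- match(key_b, key_t)
  if (anyNA(m)) stop("unmatched truth rows; inconsistent scenario tables")
  group_regression(true = truth[[stat]][m], biased = biased[[stat]],
                   groups = biased$group)
}
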