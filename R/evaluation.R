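# Bias and imputation-quality evaluation: population-group assignment,
# group-specific regression of biased on true estimates, mean
# overestimation, per-animal Pearson accuracy and leave-one-out validation.

#' Assign populations to bias groups
#'
#' Each population is labelled `discovery`, `reference` (at least one of its
#' individuals is in the imputation panel) or `application` (neither), with
#' precedence discovery > reference > application. When every population has
#' reference individuals, the reference label carries no information and
#' groups collapse to discovery/application.
#'
#' @param populations character vector of population labels to classify.
#' @param discovery_pop the discovery population label.
#' @param panel a `reference_panel` (or a character vector of reference
#'   population labels); `NULL` means no reference set.
#' @return named character vector, one group per population.
#' @export
assign_groups <- function(populations, discovery_pop, panel = NULL) {
  populations <- unique(as.character(populations))
  if (!discovery_pop %in% populations) stop("unknown discovery population: ", discovery_pop)
  ref_pops <- if (is.null(panel)) character(0) else {
    if (inherits(panel, "reference_panel")) unique(panel$pop) else unique(as.character(panel))
  }
  g <- ifelse(populations == discovery_pop, "discovery",
              ifelse(populations %in% ref_pops, "reference", "application"))
  if (all(setdiff(populations, discovery_pop) %in% ref_pops)) {
    g[g == "reference"] <- "application"
  }
  setNames(g, populations)
}

#' Group label for a pair of populations
#'
#' Unordered combination of the two member groups, e.g.
#' `"application-discovery"`.
#'
#' @param g1,g2 group labels of the two populations.
#' @return character label, symmetric in its arguments.
#' @export
pair_group <- function(g1, g2) {
  mapply(function(a, b) paste(sort(c(a, b)), collapse = "-"), g1, g2,
         USE.NAMES = FALSE)
}

#' Mean overestimation
#'
#' Mean over populations of `(biased - true) / true`. Populations with a
#' true value of 0 are excluded with a warning (relative error undefined).
#'
#' @param biased,true numeric vectors of biased and true estimates.
#' @return scalar mean relative overestimation.
#' @export
#' @examples
#' mean_overestimation(c(0.6, 0.3), c(0.5, 0.25)) # 0.2
mean_overestimation <- function(biased, true) {
  stopifnot(length(biased) == length(true))
  drop <- !is.na(true) & true == 0
  if (any(drop)) {
    warning(sum(drop), " population(s) with true value 0 excluded from mean overestimation")
  }
  keep <- !drop & is.finite(biased) & is.finite(true)
  if (!any(keep)) return(NA_real_)
  mean((biased[keep] - true[keep]) / true[keep])
}

#' Group-specific bias regression
#'
#' Regresses biased estimates on true estimates with group-specific
#' intercepts and slopes (fitted as independent per-group ordinary least
#' squares, which is algebraically identical to the single full-interaction
#' model). Unbiasedness corresponds to the identity line: slope 1,
#' intercept 0. Non-finite pairs (e.g. infinite Nei's D) are dropped with a
#' per-group count. Also reports the within-group Pearson correlation and
#' mean overestimation.
#'
#' @param true numeric vector of true (unbiased) estimates.
#' @param biased numeric vector of biased estimates.
#' @param groups group label per observation.
#' @param min_points groups with fewer points are flagged unreliable
#'   (default 3).
#' @return object of class `bias_fit`; its `groups` element is a data.frame
#'   with columns `group`, `n`, `n_dropped`, `intercept`, `slope`, `r`,
#'   `sigma2`, `mean_overestimation`, `reliable`.
#' @export
#' @examples
#' fit <- group_regression(true = c(0.1, 0.2, 0.3, 0.4),
#'                         biased = c(0.25, 0.40, 0.55, 0.70),
#'                         groups = rep("g", 4))
#' coef(fit) # intercept 0.10, slope 1.5
group_regression <- function(true, biased, groups, min_points = 3) {
  stopifnot(length(true) == length(biased), length(groups) == length(true))
  df <- data.frame(x = as.numeric(true), y = as.numeric(biased),
                   group = as.character(groups), stringsAsFactors = FALSE)
  by_group <- split(df, df$group)
  out <- Map(function(d, gname) {
    ok <- is.finite(d$x) & is.finite(d$y)
    n_dropped <- sum(!ok)
    d <- d[ok, , drop = FALSE]
    n <- nrow(d)
    res <- data.frame(group = gname, n = n,
                      n_dropped = n_dropped, intercept = NA_real_,
                      slope = NA_real_, r = NA_real_, sigma2 = NA_real_,
                      mean_overestimation = NA_real_, reliable = FALSE,
                      stringsAsFactors = FALSE)
    if (n >= 2 && length(unique(d$x)) >= 2) {
      fit <- lm(y ~ x, data = d)
      res$intercept <- unname(coef(fit)[1])
      res$slope <- unname(coef(fit)[2])
      res$sigma2 <- sum(fit$residuals^2) / max(fit$df.residual, 1)
      res$r <- if (sd(d$y) > 0) cor(d$x, d$y) else NA_real_
    }
    res$mean_overestimation <- suppressWarnings(mean_overestimation(d$y, d$x))
    res$reliable <- n >= min_points && !is.na(res$slope)
    res
  }, by_group, names(by_group))
  groups_df <- do.call(rbind, out)
  rownames(groups_df) <- NULL
  structure(list(groups = groups_df, data = df), class = "bias_fit")
}

#' @export
print.bias_fit <- function(x, digits = 3, ...) {
  cat("Group-specific bias regression (biased ~ true):\n")
  g <- x$groups
  g$intercept <- round(g$intercept, digits)
  g$slope <- round(g$slope, digits)
  g$r <- round(g$r, digits)
  g$mean_overestimation <- round(g$mean_overestimation, digits)
  print(g[, c("group", "n", "intercept", "slope", "r", "mean_overestimation")],
        row.names = FALSE)
  if (any(!x$groups$reliable)) {
    cat("note: groups flagged unreliable (< 3 points or constant x):",
        paste(g$group[!x$groups$reliable], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.bias_fit <- function(object, ...) {
  print(object, ...)
  cat(sprintf("total points: %d (dropped non-finite: %d)\n",
              sum(object$groups$n), sum(object$groups$n_dropped)))
  invisible(object$groups)
}

#' @export
coef.bias_fit <- function(object, ...) {
  m <- as.matrix(object$groups[, c("intercept", "slope")])
  rownames(m) <- object$groups$group
  m
}

#' @export
plot.bias_fit <- function(x, xlab = "true estimate", ylab = "biased estimate", ...) {
  d <- x$data[is.finite(x$data$x) & is.finite(x$data$y), ]
  grp <- factor(d$group)
  graphics::plot(d$x, d$y, col = as.integer(grp), pch = 16,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(0, 1, lty = 2)
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    if (!is.na(g$slope)) graphics::abline(g$intercept, g$slope, col = i)
  }
  graphics::legend("topleft", legend = levels(grp), col = seq_along(levels(grp)),
                   pch = 16, bty = "n")
  invisible(x)
}

#' Per-animal imputation accuracy
#'
#' Pearson correlation between an individual's true dosages and imputed
#' expected dosages across the imputed (masked) sites only — typed sites
#' would inflate the correlation trivially. Individuals with fewer than 2
#' usable sites or zero variance in either vector get `NA` with a reason.
#'
#' @param truth a [genotype_matrix] with the true genotypes.
#' @param result an [impute_genotypes()] result.
#' @param sites integer site indices to score (default: the result's
#'   imputed sites).
#' @return data.frame with columns `individual`, `pop`, `r`, `n_sites`,
#'   `reason` (`NA` when `r` is defined).
#' @export
per_animal_accuracy <- function(truth, result, sites = result$imputed_sites) {
  stopifnot(inherits(truth, "genotype_matrix"), inherits(result, "imputation_result"))
  inds <- result$individuals
  out <- data.frame(individual = inds,
                    pop = unname(result$pop[inds]),
                    r = NA_real_, n_sites = 0L, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(inds)) {
    tv <- truth$dosage[sites, inds[i]]
    iv <- result$dosage[sites, inds[i]]
    ok <- !is.na(tv) & !is.na(iv)
    out$n_sites[i] <- sum(ok)
    if (sum(ok) < 2L) {
      out$reason[i] <- "fewer than 2 imputed sites"
    } else if (sd(tv[ok]) == 0 || sd(iv[ok]) == 0) {
      out$reason[i] <- "zero variance"
    } else {
      out$r[i] <- cor(tv[ok], iv[ok])
    }
  }
  out
}

#' Leave-one-out imputation validation
#'
#' For every panel individual in turn: remove it from the panel, re-apply
#' the reference-site filter to the reduced panel, mask the individual's
#' non-array sites, impute it against the reduced panel, and score the
#' per-animal accuracy at its masked sites. The annotation records whether
#' any same-population individual remained in the reduced panel — when none
#' does, the accuracy estimate is downward-biased relative to panel members
#' with a population mate.
#'
#' @param haps the truth [haplotype_panel] of the study set (must contain
#'   all panel individuals).
#' @param panel a `reference_panel` with at least 2 individuals.
#' @param mask the array `ascertainment_mask` defining typed sites.
#' @param config an [imputer_config].
#' @param maf_threshold reference-site MAF threshold re-applied to each
#'   reduced panel (default 0.01).
#' @return data.frame with columns `individual`, `pop`, `r`, `n_sites`,
#'   `same_pop_in_panel`.
#' @export
leave_one_out <- function(haps, panel, mask, config = imputer_config(),
                          maf_threshold = 0.01) {
  stopifnot(inherits(haps, "haplotype_panel"), inherits(panel, "reference_panel"))
  if (length(panel$individuals) < 2L) stop("leave-one-out requires a panel of >= 2")
  truth <- as_genotypes(haps)
  out <- vector("list", length(panel$individuals))
  for (i in seq_along(panel$individuals)) {
    test_ind <- panel$individuals[i]
    reduced <- panel
    reduced$individuals <- panel$individuals[-i]
    reduced$pop <- panel$pop[-i]
    reduced <- filter_reference_sites(truth, reduced, maf_threshold)
    study_i <- apply_mask(subset_individuals(haps, test_ind), mask)
    ref_haps <- subset_individuals(haps, reduced$individuals)
    res <- impute_genotypes(study_i, ref_haps, reduced, config)
    acc <- per_animal_accuracy(truth, res)
    acc$same_pop_in_panel <- panel$pop[i] %in% reduced$pop
    out[[i]] <- acc[, c("individual", "pop", "r", "n_sites", "same_pop_in_panel")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
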