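# Haplotype-copying imputation. The engine is a haploid Li-Stephens HMM:
# the target haplotype is modelled as a mosaic of the reference haplotypes,
# with recombination-driven template switches and a small allele-mismatch
# probability. Posterior allele probabilities come from the forward-backward
# algorithm (compiled core in src/ls_hmm.cpp), computed per genetic-map
# window and stitched at window overlaps. Truth-phased study haplotypes are
# assumed (the simulator emits phase); phasing itself is out of scope.

#' Imputer configuration
#'
#' @param ne effective population size driving the recombination
#'   parameterisation (default 1000, a value commonly used for
#'   multi-population livestock panels).
#' @param window_cM window length in centimorgans over which the HMM is run
#'   (default 200); windows overlap by `overlap_frac` of their length and
#'   each site takes its posterior from the window whose centre is nearest.
#' @param error_rate allele-mismatch (emission error) probability
#'   (default 1e-4).
#' @param overlap_frac fractional window overlap (default 0.1).
#' @return object of class `imputer_config`.
#' @export
imputer_config <- function(ne = 1000, window_cM = 200, error_rate = 1e-4,
                           overlap_frac = 0.1) {
  stopifnot(ne > 0, window_cM > 0, error_rate > 0, error_rate < 0.5,
            overlap_frac >= 0, overlap_frac < 0.5)
  structure(list(ne = ne, window_cM = window_cM, error_rate = error_rate,
                 overlap_frac = overlap_frac),
            class = "imputer_config")
}

#' Per-interval recombination switch probabilities
#'
#' For adjacent sites at genetic distance `d` cM the probability of a
#' copy-template switch is `rho = 1 - exp(-0.04 * ne * d / K)` with `K` the
#' number of reference haplotypes (the standard Li-Stephens scaling of
#' recombination by reference size). Chromosome boundaries get `rho = 1`.
#'
#' @param map a [genetic_map] with at least 2 sites.
#' @param ne effective population size.
#' @param n_ref_haplotypes number of reference haplotypes (> 0).
#' @return numeric vector of length `nrow(map) - 1`.
#' @export
#' @examples
#' m <- genetic_map("1", c(1L, 2L), c(0, 0.01))
#' recombination_weights(m, ne = 1000, n_ref_haplotypes = 20) # 1 - exp(-0.02)
recombination_weights <- function(map, ne, n_ref_haplotypes) {
  if (n_ref_haplotypes < 1) stop("zero reference haplotypes")
  if (nrow(map) < 2L) stop("need at least 2 sites")
  d <- pmax(diff(map$cM), 0)
  rho <- 1 - exp(-0.04 * ne * d / n_ref_haplotypes)
  rho[map$chrom[-1L] != map$chrom[-nrow(map)]] <- 1
  rho
}

# Split site indices into overlapping windows along the genetic map and
# assign each site to the window whose centre is nearest (ownership).
hmm_windows <- function(cM, window_cM, overlap_frac) {
  span <- max(cM) - min(cM)
  if (span <= window_cM) {
    return(list(list(sites = seq_along(cM), own = seq_along(cM))))
  }
  step <- window_cM * (1 - overlap_frac)
  starts <- seq(min(cM), max(cM), by = step)
  starts <- starts[starts < max(cM) - 1e-12]
  wins <- lapply(starts, function(s) {
    idx <- which(cM >= s - 1e-12 & cM <= s + window_cM + 1e-12)
    list(sites = idx, centre = s + window_cM / 2)
  })
  wins <- Filter(function(w) length(w$sites) > 0, wins)
  centres <- vapply(wins, `[[`, numeric(1), "centre")
  owner <- vapply(cM, function(x) which.min(abs(centres - x)), integer(1))
  lapply(seq_along(wins), function(i) {
    list(sites = wins[[i]]$sites, own = intersect(which(owner == i), wins[[i]]$sites))
  })
}

#' Impute a single haplotype against a reference panel
#'
#' Runs the Li-Stephens forward-backward over each map window and returns
#' the posterior probability of allele 1 at every reference site. Untyped
#' (`NA`) observations emit uniformly, so a window without any typed site
#' degrades gracefully to the reference allele frequencies.
#'
#' @param observed integer vector (0/1/`NA`) of the study haplotype on the
#'   reference site grid; `NA` marks untyped/masked sites.
#' @param reference integer matrix (sites x reference haplotypes, 0/1).
#' @param map a [genetic_map] for the same sites.
#' @param config an [imputer_config].
#' @param return_states if `TRUE` (single-window maps only) also return the
#'   state posterior matrix.
#' @return numeric vector of posterior allele-1 probabilities (list with
#'   elements `allele` and `states` when `return_states = TRUE`).
#' @export
impute_haplotype <- function(observed, reference, map, config = imputer_config(),
                             return_states = FALSE) {
  reference <- as.matrix(reference)
  storage.mode(reference) <- "integer"
  L <- nrow(reference)
  stopifnot(length(observed) == L, nrow(map) == L, ncol(reference) >= 1)
  obs <- as.integer(observed)
  if (L == 1L) {
    res <- .ls_forward_backward(reference, obs, numeric(0), config$error_rate,
                                return_states)
    return(if (return_states) res else res$allele)
  }
  rho <- recombination_weights(map, config$ne, ncol(reference))
  wins <- hmm_windows(map$cM, config$window_cM, config$overlap_frac)
  if (return_states) {
    if (length(wins) > 1L) stop("state posteriors are only returned for single-window maps")
    return(.ls_forward_backward(reference, obs, rho, config$error_rate, TRUE))
  }
  ls_impute_one(obs, reference, rho, wins, config$error_rate)
}

# Windowed forward-backward with precomputed switch probabilities and
# window layout (shared across the haplotypes of one imputation run).
ls_impute_one <- function(obs, reference, rho, wins, eps) {
  if (length(wins) == 1L) {
    return(.ls_forward_backward(reference, obs, rho, eps, FALSE)$allele)
  }
  out <- rep(NA_real_, nrow(reference))
  for (w in wins) {
    idx <- w$sites
    res <- .ls_forward_backward(reference[idx, , drop = FALSE], obs[idx],
                                rho[idx[-length(idx)]], eps, FALSE)
    out[w$own] <- res$allele[match(w$own, idx)]
  }
  out
}

#' Dosage r-squared (DR2) from posterior allele probabilities
#'
#' The ratio of the between-haplotype variance of the posterior allele mean
#' to the total expected allele variance (between-haplotype variance plus
#' mean Bernoulli posterior variance), clamped to `[0, 1]`. It estimates the
#' squared correlation between imputed and true allele dose at the site and
#' equals 1 when all posteriors are certain (and both alleles occur), 0 when
#' every haplotype's posterior equals the allele frequency.
#'
#' @param p numeric vector of posterior allele-1 probabilities across
#'   haplotypes at one site (>= 2 values).
#' @return scalar DR2 in `[0, 1]`, or `NA` when the denominator is 0.
#' @export
#' @examples
#' compute_dr2(c(0.9, 0.1)) # 0.64
compute_dr2 <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 2L) stop("DR2 needs at least 2 haplotypes")
  between <- mean((p - mean(p))^2)
  within <- mean(p * (1 - p))
  denom <- between + within
  if (denom == 0) return(NA_real_)
  min(max(between / denom, 0), 1)
}

#' Impute masked study genotypes from a reference panel
#'
#' Imputes every study haplotype with [impute_haplotype()] on the panel's
#' retained reference sites, then assembles per-individual expected dosages,
#' best-guess genotypes (dosage rounded half-to-even) and per-site DR2.
#' Typed study entries pass through unchanged (cell-exact conservation);
#' masked sites absent from the reference retained set stay missing and are
#' flagged.
#'
#' @param study a [haplotype_panel] of the study individuals with masked
#'   sites set to `NA` (see [apply_mask()]).
#' @param reference a [haplotype_panel] of the reference individuals with
#'   complete data on the full site grid.
#' @param panel the [sample_reference()] panel after
#'   [filter_reference_sites()] (its `sites` define the imputation targets);
#'   may be `NULL` to use every site.
#' @param config an [imputer_config].
#' @return object of class `imputation_result`: list with `posterior`
#'   (sites x haplotypes allele probabilities), `dosage` (expected dosage,
#'   sites x individuals), `best_guess` (0/1/2/NA), `dr2` (per site, `NA`
#'   off-target), `typed` (logical sites x individuals), `imputed_sites`,
#'   `unimputable_sites`, and the study metadata.
#' @export
impute_genotypes <- function(study, reference, panel = NULL,
                             config = imputer_config()) {
  stopifnot(inherits(study, "haplotype_panel"), inherits(reference, "haplotype_panel"))
  L <- nrow(study$alleles)
  if (nrow(reference$alleles) != L) stop("study and reference must share the site grid")
  ref_sites <- if (is.null(panel)) seq_len(L) else panel$sites
  if (is.null(ref_sites)) stop("panel has no retained sites; run filter_reference_sites() first")

  ref <- reference$alleles[ref_sites, , drop = FALSE]
  storage.mode(ref) <- "integer"
  map_sub <- study$map[ref_sites, , drop = FALSE]
  class(map_sub) <- class(study$map)

  H <- ncol(study$alleles)
  posterior <- matrix(NA_real_, L, H, dimnames = dimnames(study$alleles))
  if (length(ref_sites) == 1L) {
    for (h in seq_len(H)) {
      posterior[ref_sites, h] <- impute_haplotype(study$alleles[ref_sites, h],
                                                  ref, map_sub, config)
    }
  } else {
    rho <- recombination_weights(map_sub, config$ne, ncol(ref))
    wins <- hmm_windows(map_sub$cM, config$window_cM, config$overlap_frac)
    block <- matrix(NA_real_, length(ref_sites), H)
    for (h in seq_len(H)) {
      block[, h] <- ls_impute_one(study$alleles[ref_sites, h], ref, rho, wins,
                                  config$error_rate)
    }
    posterior[ref_sites, ] <- block
  }
  # conservation: observed alleles (anywhere on the grid) override
  typed_h <- !is.na(study$alleles)
  posterior[typed_h] <- study$alleles[typed_h]

  odd <- seq(1L, H, by = 2L)
  dosage <- posterior[, odd, drop = FALSE] + posterior[, odd + 1L, drop = FALSE]
  colnames(dosage) <- study$individuals
  best <- round(dosage) # round() is IEC half-to-even
  truth_typed <- typed_h[, odd, drop = FALSE] & typed_h[, odd + 1L, drop = FALSE]
  # typed genotypes are exact integers already; enforce identity explicitly
  typed_dos <- study$alleles[, odd, drop = FALSE] + study$alleles[, odd + 1L, drop = FALSE]
  dosage[truth_typed] <- typed_dos[truth_typed]
  best[truth_typed] <- typed_dos[truth_typed]
  storage.mode(best) <- "integer"

  # DR2, vectorised over sites (equivalent to compute_dr2 per row)
  dr2 <- rep(NA_real_, L)
  P <- posterior[ref_sites, , drop = FALSE]
  m1 <- rowMeans(P)
  m2 <- rowMeans(P * P)
  between <- pmax(m2 - m1^2, 0)
  within <- pmax(m1 - m2, 0)
  denom <- between + within
  dr2[ref_sites] <- ifelse(is.na(denom) | denom == 0, NA_real_,
                           pmin(pmax(between / denom, 0), 1))

  typed_sites <- rowSums(typed_h) > 0
  structure(list(posterior = posterior, dosage = dosage,
                 best_guess = best, dr2 = dr2,
                 typed = truth_typed,
                 imputed_sites = setdiff(ref_sites, which(typed_sites)),
                 unimputable_sites = setdiff(which(!typed_sites), ref_sites),
                 individuals = study$individuals, pop = study$pop,
                 map = study$map, config = config),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf(paste0("<imputation_result> %d sites x %d individuals; ",
                     "%d imputed sites, %d unimputable; median DR2 %.3f\n"),
              nrow(x$dosage), ncol(x$dosage), length(x$imputed_sites),
              length(x$unimputable_sites),
              stats::median(x$dr2, na.rm = TRUE)))
  invisible(x)
}
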