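# Reference-panel construction: five sampling strategies plus the
# reference-side MAF filter that defines which sites imputation can output.

REF_STRATEGIES <- c("allPop", "randSamp", "randPop", "minPop", "maxPop")

#' Sample a reference panel
#'
#' Selects the individuals whose full-resolution data will serve as the
#' imputation reference, under one of five strategies:
#' \describe{
#'   \item{allPop}{`size` individuals from every population (balanced).}
#'   \item{randSamp}{`size` individuals uniformly without replacement from
#'     the whole study set.}
#'   \item{randPop}{`samples_per_pop` individuals from each of `size`
#'     uniformly chosen populations.}
#'   \item{minPop}{`samples_per_pop` individuals from each of the `size`
#'     populations *closest* to the discovery population by the supplied
#'     distance matrix (typically Nei's D).}
#'   \item{maxPop}{as minPop but the *most distant* populations.}
#' }
#' Within-population sampling is uniform without replacement. The discovery
#' population itself is eligible for selection (for minPop, distance 0 makes
#' it the first pick). Distance ties are broken by population-label order.
#'
#' @param genotypes a [genotype_matrix] (the study set).
#' @param strategy one of `"allPop"`, `"randSamp"`, `"randPop"`, `"minPop"`,
#'   `"maxPop"`.
#' @param size strategy size parameter: individuals per population (allPop),
#'   total individuals (randSamp), or number of populations (randPop,
#'   minPop, maxPop).
#' @param discovery_pop discovery population label (required for
#'   minPop/maxPop).
#' @param distances symmetric population distance matrix with dimnames
#'   (required for minPop/maxPop).
#' @param samples_per_pop individuals drawn per selected population for
#'   randPop/minPop/maxPop (default 5).
#' @param seed integer seed.
#' @return object of class `reference_panel`: list with `individuals`,
#'   `pop` (per selected individual), `strategy`, `size`, `seed`, and
#'   `sites` (`NULL` until [filter_reference_sites()] is applied).
#' @export
sample_reference <- function(genotypes, strategy, size, discovery_pop = NULL,
                             distances = NULL, samples_per_pop = 5, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  strategy <- match.arg(strategy, REF_STRATEGIES)
  stopifnot(size >= 1)
  pops <- genotypes$pop
  pop_levels <- sort(unique(unname(pops)))
  inds <- names(pops)

  draw_from_pop <- function(p, k) {
    members <- inds[pops == p]
    if (length(members) < k) {
      stop(sprintf("population %s has %d individuals; %d requested", p, length(members), k))
    }
    sort(sample(members, k))
  }

  sel <- with_seed(seed, switch(
    strategy,
    allPop = unlist(lapply(pop_levels, draw_from_pop, k = size)),
    randSamp = {
      if (size > length(inds)) stop("requested more individuals than the study set holds")
      sort(sample(inds, size))
    },
    randPop = {
      if (size > length(pop_levels)) stop("requested more populations than exist")
      chosen <- sample(pop_levels, size)
      unlist(lapply(sort(chosen), draw_from_pop, k = samples_per_pop))
    },
    minPop = ,
    maxPop = {
      if (is.null(distances)) stop(strategy, " requires a population distance matrix")
      if (is.null(discovery_pop) || !discovery_pop %in% pop_levels) {
        stop(strategy, " requires a valid discovery population")
      }
      if (size > length(pop_levels)) stop("requested more populations than exist")
      d <- distances[discovery_pop, pop_levels]
      ord <- order(if (strategy == "minPop") d else -d, pop_levels)
      chosen <- pop_levels[ord][seq_len(size)]
      unlist(lapply(chosen, draw_from_pop, k = samples_per_pop))
    }
  ))

  structure(list(individuals = unname(sel), pop = unname(pops[sel]),
                 strategy = strategy, size = size,
                 samples_per_pop = if (strategy %in% c("randPop", "minPop", "maxPop"))
                   samples_per_pop else NA_integer_,
                 discovery_pop = discovery_pop, seed = seed, sites = NULL),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %s: %d individuals from %d populations%s\n",
              x$strategy, length(x$individuals), length(unique(x$pop)),
              if (is.null(x$sites)) "" else sprintf(", %d retained sites", length(x$sites))))
  invisible(x)
}

#' Reference-side site filter
#'
#' Retains the sites with MAF strictly greater than `maf_threshold` within
#' the panel individuals. Only these sites can be output as non-missing
#' imputation targets; sites monomorphic (or too rare) within the panel are
#' invisible to the imputation step even if polymorphic globally.
#'
#' @param genotypes the full-resolution [genotype_matrix].
#' @param panel a `reference_panel`.
#' @param maf_threshold MAF threshold (strict `>`); default 0.01.
#' @return the panel with its `sites` field set (ordered integer indices).
#' @export
filter_reference_sites <- function(genotypes, panel, maf_threshold = 0.01) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(panel, "reference_panel"))
  missing_ind <- setdiff(panel$individuals, colnames(genotypes$dosage))
  if (length(missing_ind)) stop("panel individuals absent: ", paste(missing_ind, collapse = ", "))
  maf <- compute_maf(genotypes, individuals = panel$individuals)
  panel$sites <- unname(which(!is.na(maf) & maf > maf_threshold))
  panel$maf_threshold <- maf_threshold
  panel
}
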