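# Multi-population synthetic genotype generator with known truth.
#
# Differentiation follows the Balding-Nichols model: each population's
# per-site allele frequency is a Beta draw around a shared ancestral
# frequency, with variance F * p * (1 - p) controlled by the population's
# drift parameter F. Linkage disequilibrium is produced by founder-mosaic
# copying: each sampled haplotype is a mosaic of a small per-population
# founder pool, with template switches at Poisson rate `mosaic_switch_rate`
# per cM. This is not a coalescent simulation; it is the minimal generator
# that yields (a) known true frequencies, (b) tunable differentiation and
# (c) enough LD that haplotype-copying imputation is non-trivial.

#' Population model for the synthetic generator
#'
#' @param n_populations number of populations (>= 1).
#' @param drift_F per-population Balding-Nichols differentiation parameter in
#'   `[0, 1)`; a scalar is recycled, and the default spreads drift evenly on
#'   `[0.05, 0.25]` so populations span a realistic diversity range (breeds of
#'   a livestock species differ widely in heterozygosity; a between-population
#'   diversity gradient is also what makes bias regressions across
#'   populations identifiable).
#' @param ancestral_freq_range interval strictly inside (0, 1) from which
#'   ancestral allele frequencies are drawn uniformly. The default
#'   `c(0.05, 0.95)` keeps the global site-frequency spectrum dominated by
#'   common variants while drift re-creates population-private rare variants.
#' @param n_sites number of biallelic sites.
#' @param n_founder_haplotypes founder haplotypes per population; controls
#'   within-population haplotype diversity (10 mimics a small effective size
#'   typical of managed breeds).
#' @param mosaic_switch_rate expected copy-template switches per cM when
#'   sampling haplotypes as founder mosaics; 0.1 gives ~10 cM LD blocks on
#'   the default 100 cM chromosome.
#' @param map_length_cM chromosome length for the default uniform map.
#' @param seed integer master seed; `NULL` uses the current RNG stream.
#' @return an object of class `population_model`.
#' @export
#' @examples
#' m <- population_model(n_populations = 4, n_sites = 200, seed = 1)
#' f <- simulate_population_frequencies(m)
#' dim(f)
population_model <- function(n_populations = 10,
                             drift_F = seq(0.05, 0.25, length.out = n_populations),
                             ancestral_freq_range = c(0.05, 0.95),
                             n_sites = 5000,
                             n_founder_haplotypes = 10,
                             mosaic_switch_rate = 0.1,
                             map_length_cM = 100,
                             seed = NULL) {
  stopifnot(n_populations >= 1, n_sites >= 1, n_founder_haplotypes >= 1,
            mosaic_switch_rate >= 0, map_length_cM > 0)
  if (length(drift_F) == 1L) drift_F <- rep(drift_F, n_populations)
  stopifnot(length(drift_F) == n_populations, all(drift_F >= 0), all(drift_F < 1))
  r <- ancestral_freq_range
  stopifnot(length(r) == 2L, r[1] > 0, r[2] < 1, r[1] < r[2])
  pops <- sprintf("P%02d", seq_len(n_populations))
  structure(list(n_populations = as.integer(n_populations),
                 drift_F = setNames(drift_F, pops),
                 ancestral_freq_range = r,
                 n_sites = as.integer(n_sites),
                 n_founder_haplotypes = as.integer(n_founder_haplotypes),
                 mosaic_switch_rate = mosaic_switch_rate,
                 map_length_cM = map_length_cM,
                 seed = seed,
                 populations = pops),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %d populations, %d sites, drift_F in [%.3g, %.3g]\n",
              x$n_populations, x$n_sites, min(x$drift_F), max(x$drift_F)))
  invisible(x)
}

#' Simulate true per-population allele frequencies
#'
#' Ancestral frequencies are Uniform(`ancestral_freq_range`); each
#' population's frequency at a site is Balding-Nichols
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral `p`, so its mean is
#' `p` and its variance `F p (1 - p)`. `F = 0` returns the ancestral
#' frequency exactly.
#'
#' @param model a [population_model].
#' @param seed overrides `model$seed` when given.
#' @return numeric matrix, sites x populations, with the ancestral frequency
#'   vector in attribute `"ancestral"`.
#' @export
simulate_population_frequencies <- function(model, seed = model$seed) {
  stopifnot(inherits(model, "population_model"))
  with_seed(seed, {
    L <- model$n_sites
    anc <- runif(L, model$ancestral_freq_range[1], model$ancestral_freq_range[2])
    freq <- matrix(NA_real_, L, model$n_populations,
                   dimnames = list(NULL, model$populations))
    for (j in seq_len(model$n_populations)) {
      F <- model$drift_F[j]
      freq[, j] <- if (F == 0) anc else {
        rbeta(L, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
      }
    }
    attr(freq, "ancestral") <- anc
    freq
  })
}

#' Simulate phased haplotypes as founder mosaics
#'
#' Per population, `n_founder_haplotypes` founder haplotypes are drawn
#' site-wise Bernoulli from the population's true frequencies; each sampled
#' haplotype then copies founders segment-wise, switching template at Poisson
#' rate `mosaic_switch_rate` per cM (a new template is drawn uniformly, so a
#' "switch" may re-select the same founder). A switch is forced at
#' chromosome boundaries. `mosaic_switch_rate = 0` copies whole founders.
#'
#' @param freqs frequency matrix from [simulate_population_frequencies()]
#'   (rows must cover all map sites).
#' @param n_individuals_per_pop diploid individuals per population (scalar or
#'   one count per population).
#' @param map a [genetic_map]; defaults to a uniform single-chromosome map of
#'   `model$map_length_cM`.
#' @param model the [population_model] used to generate `freqs`.
#' @param seed overrides `model$seed` when given (internally offset from the
#'   frequency stage so the two stages are independent).
#' @return a [haplotype_panel] with individuals labelled `P01_i01`, ...
#' @export
simulate_haplotypes <- function(freqs, n_individuals_per_pop, map = NULL,
                                model, seed = model$seed) {
  stopifnot(inherits(model, "population_model"), nrow(freqs) == model$n_sites)
  if (is.null(map)) map <- uniform_genetic_map(model$n_sites, model$map_length_cM)
  if (nrow(map) != nrow(freqs)) stop("frequency table must cover all map sites")
  npop <- model$n_populations
  if (length(n_individuals_per_pop) == 1L) {
    n_individuals_per_pop <- rep(n_individuals_per_pop, npop)
  }
  stopifnot(length(n_individuals_per_pop) == npop, all(n_individuals_per_pop >= 1))

  L <- nrow(freqs)
  # per-interval switch probability; forced at chromosome starts
  new_chrom <- c(TRUE, map$chrom[-1L] != map$chrom[-L])
  d <- c(0, pmax(diff(map$cM), 0))
  p_switch <- 1 - exp(-model$mosaic_switch_rate * d)
  p_switch[new_chrom] <- 1
  p_switch[1L] <- 1 # first segment always draws a founder

  seed2 <- if (is.null(seed)) NULL else child_seed(seed, "haplotypes")
  with_seed(seed2, {
    K <- model$n_founder_haplotypes
    cols <- vector("list", npop)
    inds <- character(0)
    pops <- character(0)
    for (j in seq_len(npop)) {
      founders <- matrix(rbinom(L * K, 1L, freqs[, j]), L, K)
      nh <- 2L * n_individuals_per_pop[j]
      haps <- matrix(0L, L, nh)
      for (h in seq_len(nh)) {
        sw <- runif(L) < p_switch
        seg <- cumsum(sw)
        template <- sample.int(K, max(seg), replace = TRUE)[seg]
        haps[, h] <- founders[cbind(seq_len(L), template)]
      }
      cols[[j]] <- haps
      ids <- sprintf("%s_i%02d", model$populations[j], seq_len(n_individuals_per_pop[j]))
      inds <- c(inds, ids)
      pops <- c(pops, rep(model$populations[j], length(ids)))
    }
    haplotype_panel(do.call(cbind, cols), inds, pops, map)
  })
}

#' Emulate pooled sequencing of one population
#'
#' Draws `n_pool` haplotypes without replacement from the panel, then per
#' site a Poisson read depth and a Binomial alternate-read count given the
#' pool allele fraction. The frequency estimate is reads/depth; zero-depth
#' sites are missing. Sequencing error is not modelled: finite pool size and
#' finite coverage are the two noise sources relevant to pooling bias.
#'
#' @param haps a [haplotype_panel] restricted to a single population (or use
#'   `pop` to select one).
#' @param n_pool number of haplotypes in the pool (`n` of the
#'   Futschik-Schloetterer correction factor); default 20 corresponds to a
#'   pool of 10 diploids.
#' @param mean_depth mean Poisson read depth per site.
#' @param pop optional population label to restrict `haps` to.
#' @param seed integer seed.
#' @return object of class `pool_seq_estimate`: a data.frame with columns
#'   `site`, `freq`, `depth`, plus attributes `n_pool` and `pop`.
#' @export
simulate_pool_seq <- function(haps, n_pool = 20, mean_depth = 30, pop = NULL,
                              seed = NULL) {
  stopifnot(inherits(haps, "haplotype_panel"), mean_depth > 0, n_pool >= 2)
  if (!is.null(pop)) haps <- subset_individuals(haps, haps$individuals[haps$pop == pop])
  if (length(unique(haps$pop)) != 1L) {
    stop("pooled sequencing is per population; restrict the panel or pass `pop`")
  }
  n_avail <- ncol(haps$alleles)
  if (n_pool > n_avail) {
    stop(sprintf("n_pool (%d) exceeds available haplotypes (%d)", n_pool, n_avail))
  }
  with_seed(seed, {
    picked <- sample.int(n_avail, n_pool)
    pool_frac <- rowMeans(haps$alleles[, picked, drop = FALSE])
    L <- length(pool_frac)
    depth <- rpois(L, mean_depth)
    reads <- integer(L)
    reads[depth > 0] <- rbinom(sum(depth > 0), depth[depth > 0], pool_frac[depth > 0])
    freq <- ifelse(depth > 0, reads / depth, NA_real_)
    structure(data.frame(site = haps$map$id, freq = freq, depth = depth,
                         stringsAsFactors = FALSE),
              n_pool = as.integer(n_pool), pop = unique(unname(haps$pop)),
              class = c("pool_seq_estimate", "data.frame"))
  })
}
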