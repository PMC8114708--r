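# Population-genetic estimators on biallelic allele frequencies.
# All functions take the frequency of one (arbitrarily designated) allele per
# locus; every statistic is invariant to flipping the designation at any
# locus. Frequencies may come from genotypes, individual sequences, pooled
# sequencing or imputed dosages.

#' Per-population allele frequencies from a genotype matrix
#'
#' Alternate-allele frequency per site from non-missing dosages of the given
#' individuals; sites with no non-missing call are `NA`.
#'
#' @param genotypes a [genotype_matrix].
#' @param individuals individual ids (default: all); alternatively use `pop`.
#' @param pop restrict to one population label.
#' @param sites optional integer site subset.
#' @return numeric vector of frequencies (with `NA` at uncalled sites).
#' @export
allele_frequencies <- function(genotypes, individuals = NULL, pop = NULL, sites = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!is.null(pop)) {
    if (!pop %in% genotypes$pop) stop("unknown population: ", pop)
    individuals <- names(genotypes$pop)[genotypes$pop == pop]
  }
  if (is.null(individuals)) individuals <- colnames(genotypes$dosage)
  if (length(individuals) == 0L) stop("empty individual subset")
  d <- genotypes$dosage[, individuals, drop = FALSE]
  if (!is.null(sites)) d <- d[sites, , drop = FALSE]
  rowMeans(d, na.rm = TRUE) / 2
}

#' Expected heterozygosity
#'
#' Mean over loci of `2 p (1 - p)`. Loci with missing frequency are dropped.
#'
#' @param p numeric vector of per-locus allele frequencies.
#' @return scalar H_E in `[0, 0.5]`.
#' @export
#' @examples
#' expected_heterozygosity(c(0.1, 0.3)) # 0.30
expected_heterozygosity <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("expected_heterozygosity: empty locus set")
  stopifnot(all(p >= 0), all(p <= 1))
  mean(2 * p * (1 - p))
}

#' Observed heterozygosity
#'
#' Proportion of heterozygous (dosage 1) calls among all non-missing calls of
#' the population. With complete data this equals the average over loci of
#' per-locus heterozygote proportions.
#'
#' @inheritParams allele_frequencies
#' @return scalar H_O in `[0, 1]`.
#' @export
observed_heterozygosity <- function(genotypes, pop = NULL, individuals = NULL,
                                    sites = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!is.null(pop)) {
    if (!pop %in% genotypes$pop) stop("unknown population: ", pop)
    individuals <- names(genotypes$pop)[genotypes$pop == pop]
  }
  if (is.null(individuals)) individuals <- colnames(genotypes$dosage)
  d <- genotypes$dosage[, individuals, drop = FALSE]
  if (!is.null(sites)) d <- d[sites, , drop = FALSE]
  n <- sum(!is.na(d))
  if (n == 0L) stop("observed_heterozygosity: no non-missing calls")
  sum(d == 1L, na.rm = TRUE) / n
}

#' Finite-pool correction for pooled-sequencing heterozygosity
#'
#' Multiplies a pooled-sequencing H_E estimate by `n / (n - 1)` (Futschik &
#' Schloetterer), where `n` is the number of haplotypes in the pool. This
#' corrects the finite-pool-size bias of plug-in heterozygosity; residual
#' finite-depth attenuation (of order 1/depth) remains.
#'
#' @param h_e uncorrected expected heterozygosity.
#' @param n number of haplotypes in the pool (>= 2).
#' @return corrected H_E.
#' @export
#' @examples
#' pool_correct_he(0.19, 20) # 0.2
pool_correct_he <- function(h_e, n) {
  if (length(n) != 1L || !is.finite(n) || n < 2) stop("pool size n must be >= 2")
  h_e * n / (n - 1)
}

# Shared locus filter: pairwise-complete frequencies.
paired_freqs <- function(x, y) {
  if (length(x) != length(y)) stop("frequency vectors must share the locus set")
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) stop("no loci with frequencies in both populations")
  list(x = x[keep], y = y[keep])
}

#' Nei's standard genetic distance
#'
#' `D = -ln( J_xy / sqrt(J_x J_y) )` where the gene identities sum
#' `x_il * y_il` over both alleles `i` of every locus `l` (biallelic:
#' `p` and `1 - p`). Returns `+Inf` with a warning when the populations
#' share no alleles at any locus.
#'
#' @param x,y per-locus allele frequencies of the two populations (same
#'   locus set; loci missing in either are dropped).
#' @return scalar D >= 0 (possibly `Inf`).
#' @export
#' @examples
#' nei_distance(c(1, 1), c(0, 1)) # log(2)
nei_distance <- function(x, y) {
  f <- paired_freqs(x, y)
  jxy <- sum(f$x * f$y + (1 - f$x) * (1 - f$y))
  jx <- sum(f$x^2 + (1 - f$x)^2)
  jy <- sum(f$y^2 + (1 - f$y)^2)
  if (jxy == 0) {
    warning("populations share no alleles at any locus; D is infinite")
    return(Inf)
  }
  d <- -log(jxy / sqrt(jx * jy))
  # Cauchy-Schwarz guarantees d >= 0; guard rounding at identity
  if (d < 0 && d > -1e-12) d <- 0
  d
}

#' Pairwise F_ST (ratio of sums)
#'
#' Nei's G_ST form for two subpopulations:
#' `F_ST = sum_l (HT_l - HSbar_l) / sum_l HT_l`, with
#' `HT_l = 2 pbar (1 - pbar)` at the unweighted mean frequency `pbar` and
#' `HSbar_l` the mean within-population `2 p (1 - p)`. Summing numerator and
#' denominator over loci before dividing (ratio of sums) is deliberate; it
#' is not the mean of per-locus ratios.
#'
#' @inheritParams nei_distance
#' @return scalar F_ST in `[0, 1]`.
#' @export
#' @examples
#' fst_pairwise(0.2, 0.4) # 0.02/0.42
fst_pairwise <- function(x, y) {
  f <- paired_freqs(x, y)
  pbar <- (f$x + f$y) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * f$x * (1 - f$x) + 2 * f$y * (1 - f$y)) / 2
  sht <- sum(ht)
  if (sht == 0) stop("F_ST undefined: both populations identically monomorphic at every locus")
  min(max(sum(ht - hs) / sht, 0), 1)
}

#' Pairwise distance matrices across populations
#'
#' Applies [nei_distance()] (and optionally [fst_pairwise()]) to every pair
#' of columns of a frequency matrix.
#'
#' @param freqs numeric matrix, sites x populations (column names = labels).
#' @param stat `"nei"` or `"fst"`.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(freqs, stat = c("nei", "fst")) {
  stat <- match.arg(stat)
  fun <- if (stat == "nei") nei_distance else fst_pairwise
  pops <- colnames(freqs)
  n <- ncol(freqs)
  m <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      m[i, j] <- m[j, i] <- fun(freqs[, i], freqs[, j])
    }
  }
  m
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param m square matrix with population dimnames.
#' @param path output file.
#' @export
write_phylip_distances <- function(m, path) {
  stopifnot(nrow(m) == ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(formatC(rownames(m)[i], width = -10),
                     paste(formatC(m[i, ], format = "f", digits = 6), collapse = " ")), con)
  }
  invisible(path)
}
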