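# In-silico array design: discovery-population MAF filtering, masking, and
# the LD-pruning comparison arm.

#' Per-site minor allele frequency
#'
#' MAF = `min(p, 1 - p)` from non-missing dosages of the given individuals;
#' sites with no non-missing call are `NA`.
#'
#' @inheritParams allele_frequencies
#' @return numeric vector of MAF values in `[0, 0.5]` with `NA` at uncalled
#'   sites.
#' @export
#' @examples
#' # dosages (0, 1, 2) -> p = 0.5 -> MAF 0.5
compute_maf <- function(genotypes, individuals = NULL, pop = NULL) {
  p <- allele_frequencies(genotypes, individuals = individuals, pop = pop)
  pmin(p, 1 - p)
}

#' Design an in-silico SNP array by discovery-population MAF filtering
#'
#' Retains exactly the sites whose minor allele frequency within the
#' discovery population strictly exceeds `threshold` (sites at exactly the
#' threshold are excluded). Restricting an array to SNPs common in a finite
#' discovery panel is the mechanism that generates ascertainment bias.
#'
#' @param genotypes a [genotype_matrix].
#' @param discovery_pop population label used for SNP discovery.
#' @param threshold MAF threshold (strict `>`); default 0.05.
#' @return an object of class `ascertainment_mask`: list with `sites`
#'   (ordered integer indices), `site_ids`, `discovery_pop`, `threshold`.
#' @export
design_array <- function(genotypes, discovery_pop, threshold = 0.05) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!discovery_pop %in% genotypes$pop) {
    stop("unknown discovery population: ", discovery_pop)
  }
  maf <- compute_maf(genotypes, pop = discovery_pop)
  sites <- unname(which(!is.na(maf) & maf > threshold))
  structure(list(sites = sites, site_ids = genotypes$map$id[sites],
                 discovery_pop = discovery_pop, threshold = threshold),
            class = "ascertainment_mask")
}

#' @export
print.ascertainment_mask <- function(x, ...) {
  cat(sprintf("<ascertainment_mask> %d sites retained (discovery %s, MAF > %g)\n",
              length(x$sites), x$discovery_pop, x$threshold))
  invisible(x)
}

#' Apply an ascertainment mask
#'
#' Sets every site outside the mask to missing for all individuals; retained
#' sites are untouched. Site rows are kept (missingness encoding, not row
#' deletion) so masked sites remain addressable targets for imputation.
#'
#' @param x a [genotype_matrix] or [haplotype_panel].
#' @param mask an `ascertainment_mask` (or integer site indices).
#' @return object of the same class as `x` with off-mask entries `NA`.
#' @export
apply_mask <- function(x, mask) {
  sites <- if (inherits(mask, "ascertainment_mask")) mask$sites else as.integer(mask)
  n_sites <- if (inherits(x, "genotype_matrix")) nrow(x$dosage) else nrow(x$alleles)
  if (length(sites) && (min(sites) < 1L || max(sites) > n_sites)) {
    stop("mask sites outside the matrix site range")
  }
  drop <- setdiff(seq_len(n_sites), sites)
  if (inherits(x, "genotype_matrix")) {
    x$dosage[drop, ] <- NA_integer_
  } else if (inherits(x, "haplotype_panel")) {
    x$alleles[drop, ] <- NA_integer_
  } else {
    stop("apply_mask: need a genotype_matrix or haplotype_panel")
  }
  x
}

#' LD pruning by sliding-window variance inflation
#'
#' Mirrors the greedy behaviour of `plink --indep <window> <step> <vif>`:
#' a window of `window_snps` sites advances by `step_snps`; within each
#' window the site with the highest variance-inflation factor
#' (VIF = `1 / (1 - R^2)` from regressing its dosage on the other retained
#' window sites) is removed repeatedly until all VIFs are at or below
#' `vif_threshold`. Removal is global and deterministic: VIF ties are broken
#' by the lower site index. Monomorphic sites carry no LD information and
#' are never removed. Exact plink bit-compatibility is not a goal.
#'
#' @param genotypes a [genotype_matrix].
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps window step in SNPs (default 5).
#' @param vif_threshold VIF threshold (default 2).
#' @return sorted integer vector of retained site indices.
#' @export
ld_prune <- function(genotypes, window_snps = 50, step_snps = 5, vif_threshold = 2) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            window_snps > step_snps, step_snps >= 1, vif_threshold > 1)
  d <- genotypes$dosage
  L <- nrow(d)
  removed <- logical(L)
  chroms <- genotypes$map$chrom
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    starts <- seq(1L, length(idx), by = step_snps)
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, length(idx))]
      win <- win[!removed[win]]
      if (length(win) < 2L) next
      repeat {
        vif <- window_vifs(d[win, , drop = FALSE])
        worst <- max(vif)
        if (!is.finite(worst) || worst > vif_threshold) {
          kill <- win[which.max(vif)] # which.max: first (lowest index) on ties
          removed[kill] <- TRUE
          win <- win[win != kill]
          if (length(win) < 2L) break
        } else break
      }
    }
  }
  which(!removed)
}

# VIFs for all rows of a (sites x individuals) dosage block, from the
# diagonal of the inverse correlation matrix. Monomorphic rows get VIF 1;
# perfectly collinear rows get VIF Inf.
window_vifs <- function(block) {
  v <- apply(block, 1L, stats::var)
  poly <- which(v > 0)
  vif <- rep(1, nrow(block))
  if (length(poly) < 2L) return(vif)
  C <- stats::cor(t(block[poly, , drop = FALSE]))
  # perfect collinearity makes C singular: flag the involved sites directly
  off <- abs(C)
  diag(off) <- 0
  dup <- which(apply(off, 1L, max) >= 1 - 1e-10)
  if (length(dup)) {
    vif[poly[dup]] <- Inf
    return(vif)
  }
  inv <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(inv)) {
    # numerically singular without an exact duplicate pair: most correlated
    # sites are treated as infinite-VIF
    worst <- which(apply(off, 1L, max) == max(off))
    vif[poly[worst]] <- Inf
    return(vif)
  }
  vif[poly] <- pmax(diag(inv), 1)
  vif
}
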