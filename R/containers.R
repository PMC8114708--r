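# Core data containers: genetic map, phased haplotype panel, 0/1/2 genotype
# matrix. All site-indexed objects share the convention: sites in rows (in map
# order), samples in columns. Internal site indices are 0/1-based R integers;
# file formats (VCF, PLINK map) use 1-based bp positions.

#' Genetic map
#'
#' A per-site genetic map: chromosome, 1-based physical position (bp) and
#' genetic position (cM). Within a chromosome bp must be strictly increasing
#' and cM non-decreasing.
#'
#' @param chrom chromosome identifier per site (coerced to character).
#' @param bp integer physical positions (1-based).
#' @param cM numeric genetic positions in centimorgans.
#' @param id optional site identifiers; defaults to `chrom_bp`.
#' @return a `data.frame` of class `genetic_map` with columns
#'   `chrom`, `id`, `cM`, `bp` (PLINK column order).
#' @export
#' @examples
#' genetic_map(chrom = "1", bp = c(100L, 200L), cM = c(0, 0.05))
genetic_map <- function(chrom, bp, cM, id = NULL) {
  chrom <- as.character(chrom)
  n <- length(bp)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(cM) == n, n >= 1L)
  bp <- as.integer(bp)
  if (is.null(id)) id <- paste0(chrom, "_", bp)
  map <- data.frame(chrom = chrom, id = as.character(id), cM = as.numeric(cM),
                    bp = bp, stringsAsFactors = FALSE)
  validate_genetic_map(map)
  class(map) <- c("genetic_map", "data.frame")
  map
}

validate_genetic_map <- function(map, file = NULL) {
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    dbp <- diff(map$bp[i])
    if (any(dbp <= 0)) {
      at <- i[which(dbp <= 0)[1] + 1L]
      stop(sprintf("genetic map%s: bp not strictly increasing on chromosome %s at line %d",
                   if (is.null(file)) "" else paste0(" '", file, "'"), ch, at), call. = FALSE)
    }
    dcm <- diff(map$cM[i])
    if (any(dcm < 0)) {
      at <- i[which(dcm < 0)[1] + 1L]
      stop(sprintf("genetic map%s: cM decreasing on chromosome %s at line %d",
                   if (is.null(file)) "" else paste0(" '", file, "'"), ch, at), call. = FALSE)
    }
  }
  invisible(map)
}

#' Evenly spaced single-chromosome map
#'
#' Convenience constructor used by the simulator: `n_sites` sites uniformly
#' spaced over `length_cM` centimorgans with bp = 10 kb per site.
#'
#' @param n_sites number of sites.
#' @param length_cM chromosome length in cM.
#' @param chrom chromosome label.
#' @return a [genetic_map].
#' @export
uniform_genetic_map <- function(n_sites, length_cM = 100, chrom = "1") {
  stopifnot(n_sites >= 1, length_cM > 0)
  genetic_map(chrom = chrom, bp = seq_len(n_sites) * 10000L,
              cM = seq(0, length_cM, length.out = max(n_sites, 2L))[seq_len(n_sites)])
}

#' Phased haplotype panel
#'
#' Stores phased 0/1 alleles, two haplotype columns per individual (order:
#' `ind1_h1, ind1_h2, ind2_h1, ...`), individual-to-population labels and the
#' genetic map. `NA` encodes a masked/missing allele.
#'
#' @param alleles integer matrix, sites x haplotypes, values 0/1/`NA`.
#' @param individuals character vector of individual ids (half the number of
#'   haplotype columns).
#' @param pop character vector of population labels, one per individual.
#' @param map a [genetic_map] with one row per allele-matrix row.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, individuals, pop, map) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_hap <- ncol(alleles)
  if (n_hap %% 2L != 0L) stop("haplotype count must be even (two per individual)")
  if (length(individuals) != n_hap / 2L) {
    stop("need exactly one individual id per two haplotypes")
  }
  if (length(pop) != length(individuals)) stop("one population label per individual")
  if (any(!nzchar(pop)) || anyNA(pop)) stop("population labels must be non-empty")
  if (nrow(alleles) != nrow(map)) stop("map/allele row mismatch")
  ok <- alleles %in% c(0L, 1L, NA_integer_)
  if (!all(ok)) stop("alleles must be 0, 1 or NA")
  colnames(alleles) <- paste0(rep(individuals, each = 2L), c("_h1", "_h2"))
  rownames(alleles) <- map$id
  structure(list(alleles = alleles, individuals = as.character(individuals),
                 pop = setNames(as.character(pop), individuals), map = map),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d sites x %d haplotypes (%d individuals, %d populations)\n",
              nrow(x$alleles), ncol(x$alleles), length(x$individuals),
              length(unique(x$pop))))
  invisible(x)
}

#' Diploid genotype matrix
#'
#' 0/1/2-coded allele dosages, sites in rows and individuals in columns, with
#' population labels and a genetic map. `NA` encodes a missing genotype.
#'
#' @param dosage numeric/integer matrix, sites x individuals, values in
#'   {0, 1, 2, `NA`}.
#' @param pop population label per individual (named or positional).
#' @param map a [genetic_map] with one row per dosage row.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, pop, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!all(dosage %in% c(0L, 1L, 2L, NA_integer_))) stop("dosages must be 0, 1, 2 or NA")
  if (nrow(dosage) != nrow(map)) stop("map/dosage row mismatch")
  if (length(pop) != ncol(dosage)) stop("one population label per individual")
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("ind", seq_len(ncol(dosage)))
  rownames(dosage) <- map$id
  structure(list(dosage = dosage, pop = setNames(as.character(pop), colnames(dosage)),
                 map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosage))
  cat(sprintf("<genotype_matrix> %d sites x %d individuals (%d populations, %.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$pop)), 100 * miss))
  invisible(x)
}

#' Collapse a haplotype panel to genotype dosages
#'
#' Dosage is the sum of an individual's two haplotype alleles; a genotype is
#' missing if either haplotype allele is missing.
#'
#' @param haps a [haplotype_panel].
#' @return a [genotype_matrix].
#' @export
as_genotypes <- function(haps) {
  stopifnot(inherits(haps, "haplotype_panel"))
  h <- haps$alleles
  dos <- h[, seq(1L, ncol(h), by = 2L), drop = FALSE] +
    h[, seq(2L, ncol(h), by = 2L), drop = FALSE]
  colnames(dos) <- haps$individuals
  genotype_matrix(dos, pop = unname(haps$pop), map = haps$map)
}

#' Subset a haplotype panel by individual ids
#'
#' Keeps the full site grid; selects the two haplotype columns of each
#' requested individual, in the requested order.
#'
#' @param haps a [haplotype_panel].
#' @param individuals individual ids to keep.
#' @return a [haplotype_panel].
#' @export
subset_individuals <- function(haps, individuals) {
  stopifnot(inherits(haps, "haplotype_panel"))
  idx <- match(individuals, haps$individuals)
  if (anyNA(idx)) stop("unknown individuals: ", paste(individuals[is.na(idx)], collapse = ", "))
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  haplotype_panel(haps$alleles[, cols, drop = FALSE], individuals,
                  unname(haps$pop[idx]), haps$map)
}
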