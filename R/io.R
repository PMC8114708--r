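# File formats. Conventions: VCF positions are 1-based; internal site
# indices are R (1-based) row indices into the map. Synthetic sites carry
# placeholder REF/ALT alleles A/C. Haplotype panels are written phased
# ("|"), genotype matrices unphased ("/"); imputed results carry DS
# (expected dosage) per genotype and DR2 per site in INFO, mirroring the
# conventions of common imputation tools.

vcf_header <- function(samples, imputed = FALSE) {
  c("##fileformat=VCFv4.2",
    "##source=ascbias",
    if (imputed) c(
      '##INFO=<ID=DR2,Number=1,Type=Float,Description="Estimated squared correlation between imputed and true allele dose">',
      '##INFO=<ID=IMP,Number=0,Type=Flag,Description="Imputed site">',
      '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Expected alternate allele dosage">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write genotypes, haplotypes or imputation results as VCF
#'
#' @param x a [genotype_matrix] (unphased GT), [haplotype_panel] (phased GT)
#'   or [impute_genotypes()] result (phased-posterior best-guess GT plus DS
#'   and site-level DR2).
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) UseMethod("write_vcf")

#' @export
write_vcf.genotype_matrix <- function(x, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(x$dosage), ncol(x$dosage))
  ok <- !is.na(x$dosage)
  gt[ok] <- gt_codes[x$dosage[ok] + 1L]
  write_vcf_body(x$map, gt, colnames(x$dosage), path)
}

#' @export
write_vcf.haplotype_panel <- function(x, path) {
  a <- x$alleles
  h1 <- a[, seq(1L, ncol(a), by = 2L), drop = FALSE]
  h2 <- a[, seq(2L, ncol(a), by = 2L), drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(h1), ".", h1), "|", ifelse(is.na(h2), ".", h2)),
               nrow(a), ncol(a) / 2L)
  write_vcf_body(x$map, gt, x$individuals, path)
}

#' @export
write_vcf.imputation_result <- function(x, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(x$best_guess), ncol(x$best_guess))
  ok <- !is.na(x$best_guess)
  gt[ok] <- gt_codes[x$best_guess[ok] + 1L]
  ds <- ifelse(is.na(x$dosage), ".", formatC(x$dosage, format = "f", digits = 3))
  field <- matrix(paste0(gt, ":", ds), nrow(gt), ncol(gt))
  info <- ifelse(is.na(x$dr2), ".",
                 paste0("DR2=", formatC(x$dr2, format = "f", digits = 4)))
  imp <- seq_len(nrow(gt)) %in% x$imputed_sites
  info[imp] <- paste0(info[imp], ";IMP")
  write_vcf_body(x$map, field, colnames(x$best_guess), path,
                 format = "GT:DS", info = info, imputed = TRUE)
}

write_vcf_body <- function(map, field, samples, path, format = "GT",
                           info = NULL, imputed = FALSE) {
  lines <- vcf_header(samples, imputed)
  body <- paste(map$chrom, map$bp, map$id, "A", "C", ".", "PASS",
                info %||% ".", format,
                apply(field, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a VCF into a genotype matrix or haplotype panel
#'
#' Parses biallelic SNP records (via the vcfR package). Fully phased files
#' yield a [haplotype_panel], anything else a [genotype_matrix]. Genetic
#' positions default to 1 cM/Mb unless a map is supplied.
#'
#' @param path VCF file (plain or gzipped).
#' @param popfile optional 2-column TSV (individual, population) assigning
#'   population labels; unknown individuals get `"unknown"`.
#' @param map optional [genetic_map] overriding the cM positions (matched on
#'   chrom/bp).
#' @param strict if `TRUE`, a multi-allelic or non-SNP record is a hard
#'   error naming the record; otherwise such records are skipped with a
#'   message.
#' @return a [haplotype_panel] or [genotype_matrix].
#' @export
read_vcf <- function(path, popfile = NULL, map = NULL, strict = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt)
  if (any(!snp)) {
    bad <- which(!snp)[1]
    if (strict) {
      stop(sprintf("non-SNP or multi-allelic record at %s:%s (REF=%s, ALT=%s)",
                   fix[bad, "CHROM"], fix[bad, "POS"], ref[bad], alt[bad]))
    }
    message(sum(!snp), " non-SNP/multi-allelic record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  bp <- as.integer(fix[, "POS"])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", bp)[is.na(ids) | ids == "."]
  cm <- bp / 1e6
  if (!is.null(map)) {
    m <- match(paste(fix[, "CHROM"], bp), paste(map$chrom, map$bp))
    if (anyNA(m)) stop("map does not cover all VCF sites")
    cm <- map$cM[m]
  }
  gmap <- genetic_map(fix[, "CHROM"], bp, cm, id = ids)
  samples <- colnames(gt)
  pops <- rep("unknown", length(samples))
  if (!is.null(popfile)) {
    pf <- read_popfile(popfile)
    hit <- match(samples, pf$individual)
    pops[!is.na(hit)] <- pf$population[hit[!is.na(hit)]]
  }
  phased <- all(grepl("\\|", gt) | is.na(gt))
  if (phased) {
    a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
    a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
    alleles <- matrix(NA_integer_, nrow(gt), 2L * ncol(gt))
    alleles[, seq(1L, ncol(alleles), 2L)] <- a1
    alleles[, seq(2L, ncol(alleles), 2L)] <- a2
    haplotype_panel(alleles, samples, pops, gmap)
  } else {
    dos <- suppressWarnings(as.integer(substr(gt, 1L, 1L)) +
                              as.integer(substr(gt, 3L, 3L)))
    genotype_matrix(matrix(dos, nrow(gt), ncol(gt),
                           dimnames = list(NULL, samples)), pops, gmap)
  }
}

#' Read/write a PLINK-style genetic map
#'
#' Four whitespace-separated columns: chromosome, site id, genetic position
#' (cM), physical position (bp). Validation errors cite the offending line.
#'
#' @param path map file.
#' @return a [genetic_map].
#' @export
read_map <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cM", "bp"))
  if (!is.numeric(tab$cM) || !is.numeric(tab$bp)) {
    stop("map '", path, "': cM and bp columns must be numeric")
  }
  map <- data.frame(chrom = as.character(tab$chrom), id = as.character(tab$id),
                    cM = as.numeric(tab$cM), bp = as.integer(tab$bp),
                    stringsAsFactors = FALSE)
  validate_genetic_map(map, file = path)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @rdname read_map
#' @param map a [genetic_map] to write.
#' @export
write_map <- function(map, path) {
  write.table(map[, c("chrom", "id", "cM", "bp")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a 2-column population file
#'
#' Tab-separated `individual<TAB>population`, no header.
#'
#' @param path file path.
#' @return data.frame with columns `individual`, `population`.
#' @export
read_popfile <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("individual", "population"))
  if (any(!nzchar(tab$population))) {
    stop("popfile '", path, "': empty population label at line ",
         which(!nzchar(tab$population))[1])
  }
  tab
}

#' @rdname read_popfile
#' @param individuals,populations vectors to write.
#' @export
write_popfile <- function(individuals, populations, path) {
  write.table(data.frame(individuals, populations), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write one-column site-list files
#'
#' plink-style extract lists: one site id per line (used for ascertainment
#' masks and pruned/retained site sets).
#'
#' @param path file path.
#' @return character vector of site ids.
#' @export
read_site_list <- function(path) readLines(path)

#' @rdname read_site_list
#' @param ids character vector of site ids.
#' @export
write_site_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' Recognised keys mirror the [scenario_config()] and [population_model()]
#' arguments; `strategies` is a list of `{strategy, size}` mappings.
#' Missing or malformed keys raise errors naming the key.
#'
#' @param path YAML file.
#' @return a [scenario_config].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- function(key) {
    if (is.null(y[[key]])) stop("config '", path, "': missing key '", key, "'")
    y[[key]]
  }
  model_keys <- c("n_populations", "drift_F", "ancestral_freq_range", "n_sites",
                  "n_founder_haplotypes", "mosaic_switch_rate", "map_length_cM")
  margs <- y[intersect(model_keys, names(y))]
  model <- do.call(population_model, margs)
  strategies <- need("strategies")
  if (!is.list(strategies)) stop("config '", path, "': 'strategies' must be a list")
  imputer <- do.call(imputer_config, y$imputer %||% list())
  scenario_config(model = model,
                  n_individuals_per_pop = y$n_individuals_per_pop %||% 20,
                  maf_discovery = y$maf_discovery %||% 0.05,
                  maf_reference = y$maf_reference %||% 0.01,
                  strategies = strategies,
                  discovery_pops = y$discovery_pops %||% 1,
                  repetitions = y$repetitions %||% 1,
                  imputer = imputer,
                  impute = y$impute %||% TRUE,
                  seed = need("seed"),
                  output_dir = y$output_dir)
}

#' Write scenario result tables as tidy TSV
#'
#' One observation per row, keyed by repetition / discovery population /
#' data set / strategy.
#'
#' @param result a [run_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_result <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(tab, name) {
    if (!is.null(tab)) {
      write.table(tab, file.path(dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  wr(result$estimates, "estimates.tsv")
  wr(result$pairwise, "pairwise.tsv")
  wr(result$accuracy, "accuracy.tsv")
  wr(result$cells, "cells.tsv")
  invisible(dir)
}
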