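# Shared fixture builders. Everything is generated in code; no files.

toy_map <- function(n, spacing_cM = 0.05, chrom = "1") {
  genetic_map(chrom = chrom, bp = seq_len(n) * 1000L,
              cM = (seq_len(n) - 1L) * spacing_cM)
}

# Genotype matrix from an explicit dosage matrix (sites x individuals).
toy_genotypes <- function(dosage, pop = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(pop)) pop <- rep("A", ncol(dosage))
  genotype_matrix(dosage, pop, toy_map(nrow(dosage)))
}

# Haplotype panel from an explicit allele matrix (two columns per individual).
toy_haplotypes <- function(alleles, pop = NULL, map = NULL) {
  alleles <- as.matrix(alleles)
  n_ind <- ncol(alleles) / 2L
  if (is.null(pop)) pop <- rep("A", n_ind)
  if (is.null(map)) map <- toy_map(nrow(alleles))
  haplotype_panel(alleles, sprintf("i%02d", seq_len(n_ind)), pop, map)
}

# Independent oracle for the Li-Stephens posterior: exhaustive enumeration
# over all K^L copying paths. Transition j -> k has probability
# (1 - rho) [j == k] + rho / K; uniform initial state; emission 1 - eps on
# match, eps on mismatch, 1 at untyped sites.
enumerate_ls_posterior <- function(ref, obs, rho, eps) {
  L <- nrow(ref); K <- ncol(ref)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  w <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    st <- paths[i, ]
    p <- 1 / K
    for (l in seq_len(L)) {
      if (l > 1) {
        p <- p * ((1 - rho[l - 1]) * (st[l] == st[l - 1]) + rho[l - 1] / K)
      }
      if (!is.na(obs[l])) {
        p <- p * if (ref[l, st[l]] == obs[l]) 1 - eps else eps
      }
    }
    w[i] <- p
  }
  w <- w / sum(w)
  allele <- numeric(L)
  states <- matrix(0, L, K)
  for (l in seq_len(L)) {
    for (k in seq_len(K)) states[l, k] <- sum(w[paths[, l] == k])
    allele[l] <- sum(states[l, ] * ref[l, ])
  }
  list(allele = allele, states = states)
}

# Small simulated world shared by several statistical tests.
small_world <- function(seed = 401, n_pops = 5, n_sites = 600, n_ind = 12) {
  model <- population_model(n_populations = n_pops, n_sites = n_sites,
                            seed = seed)
  freqs <- simulate_population_frequencies(model)
  haps <- simulate_haplotypes(freqs, n_ind, model = model)
  list(model = model, freqs = freqs, haps = haps, geno = as_genotypes(haps))
}
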