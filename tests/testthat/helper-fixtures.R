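# shared fixtures: tiny panels, pedigrees and simulated instances,
# all generated in code under fixed seeds

rand_panel <- function(n, p, seed = 1, miss_rate = 0, maf = 0.5) {
  set.seed(seed)
  g <- matrix(sample(c(1, 0, -1), n * p, replace = TRUE,
                     prob = c(maf^2, 2 * maf * (1 - maf), (1 - maf)^2)),
              n, p)
  if (miss_rate > 0)
    g[sample(length(g), round(miss_rate * length(g)))] <- NA
  snp_panel(g,
            data.frame(name = paste0("s", seq_len(p)),
                       chrom = rep(1L, p), pos = seq_len(p)),
            paste0("i", seq_len(n)))
}

# 3 founders, a nuclear family, full sibs and an inbred full-sib offspring
ped_inbred <- function() {
  pedigree_table(id = c("A", "B", "C", "D", "E", "F"),
                 sire = c(NA, NA, NA, "A", "A", "D"),
                 dam = c(NA, NA, NA, "B", "B", "E"))
}

# random pedigree of n individuals: founders then offspring of random
# earlier parents
rand_pedigree <- function(n, n_founders = max(3, floor(n / 3)), seed = 1) {
  set.seed(seed)
  id <- paste0("p", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pr <- sample(i - 1L, 2L)
    sire[i] <- id[pr[1]]; dam[i] <- id[pr[2]]
  }
  pedigree_table(id, sire, dam)
}

# small pedigreed population with genotypes + phenotypes for EM tests
small_instance <- function(n = 12, p = 3, seed = 1, beta = NULL,
                           sigma_g2 = 0.5, sigma_e2 = 1) {
  ped <- rand_pedigree(n, seed = seed)
  A <- a_matrix(ped)
  set.seed(seed + 1000)
  X <- matrix(sample(c(1, 0, -1), n * p, replace = TRUE), n, p)
  if (is.null(beta)) beta <- rep(0, p)
  L <- t(chol(A$values + 1e-8 * diag(n)))
  y <- drop(1 + X %*% beta + sqrt(sigma_g2) * (L %*% rnorm(n)) +
              rnorm(n, 0, sqrt(sigma_e2)))
  list(y = y, X = X, A = A, ped = ped)
}

# small simulated pedigree population via the gene-dropping simulator
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(
    n_chromosomes = 2, snps_per_chromosome = 50,
    qtl_spec = data.frame(chrom = 1, snp_index = 25, effect = 0,
                          class = "major"),
    gen1_families = 10, gen1_offspring = 10,
    gen2_families = 5, gen2_offspring = 20,
    base_size = 30, historical_generations = 15, seed = seed)
  dots <- list(...)
  args <- defaults
  args[names(dots)] <- dots   # plain replacement; no recursive merging
  do.call(sim_config, args)
}
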