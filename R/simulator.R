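#' Simulation configuration
#'
#' Describes a simulated population: a genome of evenly spaced SNPs, a
#' founder pool with linkage disequilibrium built up by random-mating
#' generations (gene dropping with recombination), a two-generation
#' full-sib pedigree design, QTL positions/effects and the residual
#' variance. Defaults follow the replicated-simulation design: 6
#' chromosomes of 1 Morgan with 1,000 SNPs each, generation 1 of 50
#' full-sib families x 40 offspring and generation 2 of 20 full-sib
#' families x 100 offspring (2,000 individuals per generation), population
#' mean 1, and 43 QTL (15 major + 28 minor, see [default_qtl_spec()]).
#'
#' @param n_chromosomes number of chromosomes (default 6).
#' @param snps_per_chromosome evenly spaced SNPs per chromosome
#'   (default 1000).
#' @param chromosome_length map length per chromosome in Morgans
#'   (default 1).
#' @param qtl_spec data.frame with columns `chrom`, `snp_index` (1-based
#'   within chromosome), `effect` (trait units per allele code); default
#'   [default_qtl_spec()] rescaled to the configured SNP grid.
#' @param population_mean trait mean (default 1).
#' @param residual_variance residual variance, > 0 (default 1).
#' @param gen1_families,gen1_offspring generation-1 full-sib design
#'   (defaults 50 x 40).
#' @param gen2_families,gen2_offspring generation-2 full-sib design
#'   (defaults 20 x 100).
#' @param base_size founder-pool (historical population) size
#'   (default 100).
#' @param historical_generations random-mating generations used to build
#'   linkage disequilibrium (default 100).
#' @param founder_allele_freq initial allele frequency (default 0.5).
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 6, snps_per_chromosome = 1000,
                       chromosome_length = 1, qtl_spec = NULL,
                       population_mean = 1, residual_variance = 1,
                       gen1_families = 50, gen1_offspring = 40,
                       gen2_families = 20, gen2_offspring = 100,
                       base_size = 100, historical_generations = 100,
                       founder_allele_freq = 0.5, seed = NULL) {
  if (residual_variance <= 0) stop("residual_variance must be positive")
  if (base_size < 2 * gen1_families)
    stop("base_size must provide at least ", 2 * gen1_families,
         " founders (one sire and one dam per generation-1 family)")
  if (gen1_families < 2 * gen2_families)
    stop("generation-2 needs ", 2 * gen2_families,
         " distinct generation-1 families")
  if (is.null(qtl_spec))
    qtl_spec <- scale_qtl_spec(default_qtl_spec(), snps_per_chromosome)
  qtl_spec <- as.data.frame(qtl_spec)
  if (any(qtl_spec$chrom < 1 | qtl_spec$chrom > n_chromosomes) ||
      any(qtl_spec$snp_index < 1 |
          qtl_spec$snp_index > snps_per_chromosome))
    stop("qtl_spec refers to loci outside the configured genome")
  structure(list(
    n_chromosomes = n_chromosomes,
    snps_per_chromosome = snps_per_chromosome,
    chromosome_length = chromosome_length,
    qtl_spec = qtl_spec, population_mean = population_mean,
    residual_variance = residual_variance,
    gen1_families = gen1_families, gen1_offspring = gen1_offspring,
    gen2_families = gen2_families, gen2_offspring = gen2_offspring,
    base_size = base_size,
    historical_generations = historical_generations,
    founder_allele_freq = founder_allele_freq, seed = seed
  ), class = "sim_config")
}

#' Default QTL specification
#'
#' The package's fixed set of 43 simulated QTL: 15 major and 28 minor
#' additive effects on a 6 x 1000-SNP grid, generated once (and versioned
#' as `inst/extdata/qtl_spec_default.csv`) such that at allele frequency
#' 0.5 and residual variance 1 the major QTL jointly explain about 30% of
#' the phenotypic variance.
#'
#' @return data.frame with columns `chrom`, `snp_index`, `effect`,
#'   `class` ("major"/"minor").
#' @export
default_qtl_spec <- function() {
  path <- system.file("extdata", "qtl_spec_default.csv",
                      package = "memlgwas", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Rescale QTL indices to a different SNP grid
#'
#' Maps `snp_index` values defined on a 1000-SNP-per-chromosome grid to a
#' grid with `snps_per_chromosome` loci, preserving relative positions and
#' resolving collisions to distinct loci.
#'
#' @param qtl_spec a QTL data.frame (see [default_qtl_spec()]).
#' @param snps_per_chromosome target grid size.
#' @param from_grid source grid size (default 1000).
#' @return The rescaled QTL data.frame.
#' @export
scale_qtl_spec <- function(qtl_spec, snps_per_chromosome,
                           from_grid = 1000) {
  if (snps_per_chromosome == from_grid) return(qtl_spec)
  out <- qtl_spec
  out$snp_index <- pmax(2, pmin(snps_per_chromosome - 1,
    round(qtl_spec$snp_index / from_grid * snps_per_chromosome)))
  for (ch in unique(out$chrom)) {
    sel <- which(out$chrom == ch)
    idx <- out$snp_index[sel]
    while (anyDuplicated(idx)) {
      dup <- which(duplicated(idx))
      idx[dup] <- pmin(snps_per_chromosome - 1, idx[dup] + 2)
    }
    out$snp_index[sel] <- idx
  }
  out
}

# evenly spaced marker map positions (Morgans) on one chromosome
marker_positions <- function(L, len) (seq_len(L) - 0.5) / L * len

#' Build a founder haplotype pool with linkage disequilibrium
#'
#' Starts from a base population of `base_size` individuals whose alleles
#' are drawn independently at `founder_allele_freq`, then performs
#' `historical_generations` rounds of random mating with recombination
#' (crossover count Poisson with mean equal to the chromosome map length
#' in Morgans, breakpoints uniform: Haldane model, no interference). A
#' locus drifting to fixation is re-polymorphised by a single random
#' allele flip, which is counted.
#'
#' @param config a [sim_config()]. If `config$seed` is set the RNG is
#'   seeded here.
#' @return A `founder_pool`: list of per-chromosome 0/1 haplotype matrices
#'   (2 x base_size rows; rows 2k-1 and 2k belong to individual k),
#'   marker positions, and the re-polymorphisation count `n_flips`.
#' @export
build_founder_haplotypes <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$base_size
  L <- config$snps_per_chromosome
  len <- config$chromosome_length
  pos <- marker_positions(L, len)
  haps <- lapply(seq_len(config$n_chromosomes), function(ch)
    matrix(as.integer(stats::runif(2 * N * L) < config$founder_allele_freq),
           nrow = 2 * N, ncol = L))
  n_flips <- 0L
  repolymorphise <- function(h) {
    cs <- colSums(h)
    fixed <- which(cs == 0L | cs == nrow(h))
    for (l in fixed) {
      row <- sample.int(nrow(h), 1L)
      h[row, l] <- 1L - h[row, l]
      n_flips <<- n_flips + 1L
    }
    h
  }
  for (gen in seq_len(config$historical_generations)) {
    sires <- sample.int(N, N, replace = TRUE)
    dams <- (sires + sample.int(N - 1L, N, replace = TRUE) - 1L) %% N + 1L
    new_haps <- vector("list", length(haps))
    for (ch in seq_along(haps)) {
      pat <- make_gametes_cpp(haps[[ch]], sires, pos, len)
      mat <- make_gametes_cpp(haps[[ch]], dams, pos, len)
      h <- matrix(0L, 2 * N, L)
      h[seq(1, 2 * N, by = 2), ] <- pat
      h[seq(2, 2 * N, by = 2), ] <- mat
      new_haps[[ch]] <- repolymorphise(h)
    }
    haps <- new_haps
  }
  if (config$historical_generations == 0L)
    haps <- lapply(haps, repolymorphise)
  structure(list(haplotypes = haps, positions = pos, n_flips = n_flips,
                 n_individuals = N), class = "founder_pool")
}

#' Drop genotypes through the two-generation full-sib pedigree
#'
#' Draws generation-1 parents (one sire and one dam per family) without
#' replacement from the founder pool, produces the generation-1 full-sib
#' families, then draws generation-2 parents without replacement from
#' distinct generation-1 families and produces generation 2; offspring
#' haplotypes are formed by Mendelian gene dropping with recombination.
#'
#' @param config a [sim_config()].
#' @param pool a `founder_pool` from [build_founder_haplotypes()].
#' @return A `sim_replicate` without phenotypes: `panel` (a [snp_panel()]
#'   over all individuals, founders included), `pedigree`
#'   (a [pedigree_table()]), `generation` (0 = founder), and `true_qtl`
#'   (the QTL table with the resolved global column index `snp_col`).
#' @export
simulate_pedigree_population <- function(config, pool) {
  N <- pool$n_individuals
  L <- config$snps_per_chromosome
  len <- config$chromosome_length
  pos <- pool$positions
  nf1 <- config$gen1_families; no1 <- config$gen1_offspring
  nf2 <- config$gen2_families; no2 <- config$gen2_offspring
  if (2 * nf1 > N)
    stop("founder pool too small: need ", 2 * nf1, " parents, have ", N)

  perm <- sample.int(N, 2 * nf1)
  sire_f <- perm[seq_len(nf1)]
  dam_f <- perm[nf1 + seq_len(nf1)]

  n1 <- nf1 * no1
  sire_vec1 <- rep(sire_f, each = no1)
  dam_vec1 <- rep(dam_f, each = no1)
  g1 <- drop_generation(pool$haplotypes, sire_vec1, dam_vec1, pos, len)

  fam2 <- sample.int(nf1, 2 * nf2)   # distinct generation-1 families
  pick_in_family <- function(f) (f - 1L) * as.integer(no1) +
    sample.int(no1, 1L)
  sire_i2 <- vapply(fam2[seq_len(nf2)], pick_in_family, 1L)
  dam_i2 <- vapply(fam2[nf2 + seq_len(nf2)], pick_in_family, 1L)
  n2 <- nf2 * no2
  sire_vec2 <- rep(sire_i2, each = no2)
  dam_vec2 <- rep(dam_i2, each = no2)
  g2 <- drop_generation(g1, sire_vec2, dam_vec2, pos, len)

  f_ids <- paste0("F", seq_len(N))
  g1_ids <- paste0("G1_", seq_len(n1))
  g2_ids <- paste0("G2_", seq_len(n2))
  ped <- pedigree_table(
    id = c(f_ids, g1_ids, g2_ids),
    sire = c(rep(NA, N), f_ids[sire_vec1], g1_ids[sire_vec2]),
    dam = c(rep(NA, N), f_ids[dam_vec1], g1_ids[dam_vec2]))

  geno <- do.call(cbind, lapply(seq_along(pool$haplotypes), function(ch) {
    all_h <- rbind(pool$haplotypes[[ch]], g1[[ch]], g2[[ch]])
    odd <- seq(1, nrow(all_h), by = 2)
    all_h[odd, ] + all_h[odd + 1L, ] - 1L
  }))
  map <- data.frame(
    name = paste0("c", rep(seq_len(config$n_chromosomes), each = L),
                  "s", rep(seq_len(L), config$n_chromosomes)),
    chrom = rep(seq_len(config$n_chromosomes), each = L),
    pos = rep(seq_len(L), config$n_chromosomes))
  panel <- snp_panel(geno, map, c(f_ids, g1_ids, g2_ids))

  qtl <- config$qtl_spec
  qtl$snp_col <- (qtl$chrom - 1L) * L + qtl$snp_index
  structure(list(panel = panel, pedigree = ped,
                 generation = c(rep(0L, N), rep(1L, n1), rep(2L, n2)),
                 true_qtl = qtl, seed = config$seed),
            class = "sim_replicate")
}

# one offspring generation: paternal + maternal gametes per chromosome
drop_generation <- function(haps, sire_vec, dam_vec, pos, len) {
  n_off <- length(sire_vec)
  lapply(haps, function(h) {
    pat <- make_gametes_cpp(h, sire_vec, pos, len)
    mat <- make_gametes_cpp(h, dam_vec, pos, len)
    out <- matrix(0L, 2 * n_off, ncol(h))
    out[seq(1, 2 * n_off, by = 2), ] <- pat
    out[seq(2, 2 * n_off, by = 2), ] <- mat
    out
  })
}

#' Simulate phenotypes for a replicate
#'
#' y_i = population mean + sum_q x_iq * effect_q + e_i with
#' e_i ~ N(0, residual_variance), for every individual of the panel.
#'
#' @param replicate a `sim_replicate`.
#' @param config the [sim_config()] used to create it.
#' @return Numeric phenotype vector aligned with the panel rows.
#' @export
simulate_phenotypes <- function(replicate, config) {
  X <- replicate$panel$genotypes
  qtl <- replicate$true_qtl
  gval <- drop(X[, qtl$snp_col, drop = FALSE] %*% qtl$effect)
  config$population_mean + gval +
    stats::rnorm(nrow(X), 0, sqrt(config$residual_variance))
}

#' Simulate one full replicate
#'
#' Founder pool, pedigree population and phenotypes in one call, seeded.
#'
#' @param config a [sim_config()].
#' @return A `sim_replicate` with an additional `y` (phenotypes) element.
#' @export
simulate_replicate <- function(config) {
  pool <- build_founder_haplotypes(config)   # seeds the RNG if seed set
  rep_ <- simulate_pedigree_population(config, pool)
  rep_$y <- simulate_phenotypes(rep_, config)
  rep_
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat("sim_replicate: ", nrow(x$panel$genotypes), " individuals (",
      sum(x$generation == 0L), " founders), ",
      ncol(x$panel$genotypes), " SNPs, ", nrow(x$true_qtl), " QTL\n",
      sep = "")
  invisible(x)
}
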