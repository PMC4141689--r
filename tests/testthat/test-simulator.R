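test_that("founder pool respects the base allele frequency and determinism", {
  cfg <- small_sim_config(seed = 2, historical_generations = 0,
                          base_size = 200)
  pool <- build_founder_haplotypes(cfg)
  freqs <- colMeans(pool$haplotypes[[1]])
  # each locus frequency within the binomial 99% band around 0.5
  band <- qbinom(c(0.005, 0.995), 400, 0.5) / 400
  expect_true(all(freqs >= band[1] & freqs <= band[2]))

  cfg2 <- small_sim_config(seed = 2, historical_generations = 0,
                           base_size = 200)
  pool2 <- build_founder_haplotypes(cfg2)
  expect_identical(pool$haplotypes, pool2$haplotypes)
})

test_that("gene dropping builds LD that decays with map distance", {
  r2_mean <- function(h, j1, j2) {
    x <- h[, j1]; y <- h[, j2]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)^2
  }
  adj <- numeric(0); far <- numeric(0)
  for (seed in 1:5) {
    cfg <- small_sim_config(seed = seed, snps_per_chromosome = 100,
                            historical_generations = 30, base_size = 50)
    pool <- build_founder_haplotypes(cfg)
    h <- pool$haplotypes[[1]]
    # adjacent loci (0.01 M apart) vs loci 0.5 M apart
    adj <- c(adj, vapply(1:50, function(j) r2_mean(h, j, j + 1), 0))
    far <- c(far, vapply(1:50, function(j) r2_mean(h, j, j + 50), 0))
  }
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("the pedigree population has the configured family structure", {
  cfg <- small_sim_config(seed = 31)
  pool <- build_founder_haplotypes(cfg)
  r <- simulate_pedigree_population(cfg, pool)
  # 10 x 10 + 5 x 20 = 200 non-founders
  expect_equal(sum(r$generation > 0), 200)
  expect_equal(sum(r$generation == 0), 30)
  ped <- r$pedigree
  g1 <- grep("^G1_", ped$id)
  # full sibs share both parents: family 1 is the first 10 offspring
  fam1 <- ped$id %in% paste0("G1_", 1:10)
  expect_equal(length(unique(ped$sire[fam1])), 1)
  expect_equal(length(unique(ped$dam[fam1])), 1)
  # generation-2 parents come from distinct generation-1 families
  g2_parents <- unique(c(ped$sire[grep("^G2_", ped$id)],
                         ped$dam[grep("^G2_", ped$id)]))
  fam_of <- ceiling(as.integer(sub("G1_", "", g2_parents)) / 10)
  expect_equal(anyDuplicated(fam_of), 0)
})

test_that("offspring genotypes are Mendelian-consistent with parents", {
  cfg <- small_sim_config(seed = 44)
  r <- simulate_replicate(cfg)
  G <- r$panel$genotypes
  ped <- r$pedigree
  rows <- match(ped$id, r$panel$individual_ids)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  off <- which(!is.na(si))
  viol <- 0L
  for (i in off) {
    kid <- G[rows[i], ]; pa <- G[rows[si[i]], ]; ma <- G[rows[di[i]], ]
    # a homozygous parent must transmit its allele
    viol <- viol + sum(pa == 1 & ma == 1 & kid != 1) +
      sum(pa == -1 & ma == -1 & kid != -1) +
      sum(pa == 1 & ma == -1 & kid != 0) +
      sum(pa == -1 & ma == 1 & kid != 0) +
      sum(pa == 1 & kid == -1) + sum(pa == -1 & kid == 1) +
      sum(ma == 1 & kid == -1) + sum(ma == -1 & kid == 1)
  }
  expect_equal(viol, 0L)
})

test_that("phenotypes decompose as mean + QTL effects + residual", {
  cfg <- small_sim_config(seed = 50,
                          qtl_spec = data.frame(chrom = 1, snp_index = 25,
                                                effect = 0.8,
                                                class = "major"),
                          residual_variance = 1e-18)
  r <- simulate_replicate(cfg)
  # residual variance -> 0 with one QTL: at most 3 distinct values
  expect_lte(length(unique(round(r$y, 6))), 3)
  expect_equal(sort(unique(round(r$y, 6))),
               sort(unique(round(1 + 0.8 * r$panel$genotypes[, 25], 6))))

  # variance decomposition at larger n
  cfg2 <- small_sim_config(seed = 51, gen1_families = 20,
                           gen1_offspring = 25, gen2_families = 10,
                           gen2_offspring = 50, base_size = 60,
                           qtl_spec = data.frame(chrom = c(1, 2),
                                                 snp_index = c(20, 30),
                                                 effect = c(0.7, -0.5),
                                                 class = "major"),
                           residual_variance = 1)
  r2 <- simulate_replicate(cfg2)
  X <- r2$panel$genotypes[, r2$true_qtl$snp_col]
  gen_var <- stats::var(drop(X %*% r2$true_qtl$effect))
  expect_lt(abs(stats::var(r2$y) - (gen_var + 1)) / stats::var(r2$y), 0.1)

  # determinism
  r3 <- simulate_replicate(cfg2)
  expect_identical(r2$y, r3$y)
})

test_that("power/FPR bookkeeping follows the +-1 locus rule", {
  qtl <- data.frame(chrom = c(1, 2), snp_index = c(10, 20),
                    snp_col = c(10, 70))
  # hit at the locus, hit at +1, and one false positive
  cnt <- count_detections(c(10, 71, 40), qtl, 50)
  expect_equal(cnt$n_detected, 2)
  expect_equal(cnt$n_false_positive, 1)
  # multiple significant SNPs at one QTL count once
  cnt2 <- count_detections(c(9, 10, 11), qtl, 50)
  expect_equal(cnt2$n_detected, 1)
  expect_equal(cnt2$n_false_positive, 0)
  # aggregate-rate arithmetic: 43 QTL, 10 replicates,
  # 107 detections, 6 false positives on 5871 non-QTL loci
  expect_equal(107 / (43 * 10), 0.2488, tolerance = 1e-3)
  expect_equal(6 / (5871 * 10), 1.02e-4, tolerance = 1e-2)
})

test_that("evaluate_replicates supports mock methods and edge thresholds", {
  cfg <- small_sim_config(seed = 60,
                          qtl_spec = data.frame(chrom = 1, snp_index = 25,
                                                effect = 1, class = "major"))
  oracle_method <- function(rep_, A) rep_$true_qtl$snp_col
  nothing_method <- function(rep_, A) integer(0)
  reports <- evaluate_replicates(cfg, n_replicates = 2,
                                 methods = list(oracle = oracle_method,
                                                none = nothing_method),
                                 seed = 61)
  expect_equal(reports$oracle$power, 1)
  expect_equal(reports$oracle$fpr, 0)
  expect_equal(reports$none$power, 0)
  expect_equal(reports$none$fpr, 0)
  expect_equal(reports$oracle$non_qtl_locus_count, (100 - 3) * 2)
})

test_that("default QTL spec has the documented structure", {
  q <- default_qtl_spec()
  expect_equal(nrow(q), 43)
  expect_equal(sum(q$class == "major"), 15)
  expect_equal(sum(q$class == "minor"), 28)
  expect_true(all(q$chrom %in% 1:6))
  expect_true(all(q$snp_index >= 1 & q$snp_index <= 1000))
  # major QTL jointly explain ~30% of variance at p = 0.5, sigma_e2 = 1
  v_major <- sum(0.5 * q$effect[q$class == "major"]^2)
  v_all <- sum(0.5 * q$effect^2)
  expect_equal(v_major / (v_all + 1), 0.3, tolerance = 0.02)
  # rescaling to a smaller grid keeps loci distinct and in range
  q2 <- scale_qtl_spec(q, 150)
  expect_true(all(q2$snp_index >= 1 & q2$snp_index <= 150))
  expect_equal(anyDuplicated(paste(q2$chrom, q2$snp_index)), 0)
})

test_that("offspring allele frequencies follow parental transmission", {
  cfg <- small_sim_config(seed = 77)
  r <- simulate_replicate(cfg)
  G <- r$panel$genotypes
  ped <- r$pedigree
  rows <- match(ped$id, r$panel$individual_ids)
  g1 <- which(startsWith(ped$id, "G1_"))
  si <- match(ped$sire[g1], ped$id); di <- match(ped$dam[g1], ped$id)
  # per locus: expected transmitted allele frequency is the parental mean
  # dosage; compare the offspring allele count by a binomial chi-square
  p_exp <- (colMeans((G[rows[si], ] + 1) / 2) +
              colMeans((G[rows[di], ] + 1) / 2)) / 2
  n_all <- 2 * length(g1)
  cnt <- colSums(G[rows[g1], ] + 1)
  ok <- p_exp > 0 & p_exp < 1
  chi2 <- (cnt[ok] - n_all * p_exp[ok])^2 /
    (n_all * p_exp[ok] * (1 - p_exp[ok]))
  pvals <- pchisq(chi2, df = 1, lower.tail = FALSE)
  expect_true(all(pvals > 1e-4 / length(pvals)))
})

test_that("detection power is non-decreasing in the QTL effect size", {
  powers <- vapply(c(0.15, 0.6, 1.8), function(eff) {
    cfg <- small_sim_config(
      seed = 0, n_chromosomes = 1, snps_per_chromosome = 60,
      qtl_spec = data.frame(chrom = 1, snp_index = 30, effect = eff,
                            class = "major"))
    rep_ <- evaluate_replicates(cfg, n_replicates = 10,
                                methods = "smma", n_perm = 50,
                                alpha = 0.05, seed = round(1000 * eff))
    rep_$smma$power
  }, 0)
  expect_true(all(diff(powers) >= 0))
  expect_gt(powers[3], powers[1])
})
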