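---
title: "Multi-SNP association by EM Bayesian Lasso with a pedigree polygenic effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-SNP association by EM Bayesian Lasso with a pedigree polygenic effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlgwas)
```

## The problem

Single-marker association scans test one SNP at a time and, in populations
with strong relatedness (livestock half-sib and full-sib designs in
particular), produce broad clusters of correlated signals: dozens of SNPs
in linkage disequilibrium with one causal variant all reach significance,
and the false-positive count is high. `memlgwas` implements the
complementary strategy: fit **many SNP effects jointly** under a sparsity
prior, so that within a cluster of correlated markers one or a few
representative SNPs absorb the signal and the rest are shrunk to zero,
while a pedigree-based random effect absorbs the many tiny effects that
the explicit SNP set does not capture.

## The model

For $n$ individuals and $p$ SNPs coded $x_{ij} \in \{1, 0, -1\}$ for
genotypes AA, Aa, aa:

$$y_i = \mu + \sum_{j=1}^p x_{ij}\gamma_j + g_i + e_i, \qquad
  e \sim N(0, \sigma_e^2 I), \quad g \sim N(0, \sigma_g^2 A),$$

where $A$ is the additive (numerator) relationship matrix computed from
the pedigree by the tabular method. Each SNP effect carries its own
hierarchical double-exponential (Bayesian Lasso) prior in the
scale-mixture form

$$\gamma_j \mid \tau_j^2 \sim N(0, \tau_j^2), \qquad
  \tau_j^2 \mid \lambda_j^2 \sim \mathrm{Exp}(\text{rate} = \lambda_j^2/2),$$

so that marginally $\gamma_j \mid \lambda_j$ is double-exponential with
rate $\lambda_j$. Each $\lambda_j^2$ gets a Gamma$(a, b)$ hyperprior with
$a = b = 10^{-6}$; $\mu$ is flat and
$p(\sigma_e^2) \propto 1/\sigma_e^2$; $\sigma_g^2$ is flat.

### EM structure

The fit is a maximum-a-posteriori EM in which **two quantities are
missing data**: the polygenic vector $g$ and the per-SNP scales
$\tau_j^2$. The maximised parameters are the five blocks
$(\mu, \gamma, \lambda^2, \sigma_g^2, \sigma_e^2)$.

E-step, with $r = y - \mu 1 - X\gamma$:

* $\hat g = \sigma_g^2 A (\sigma_g^2 A + \sigma_e^2 I)^{-1} r$ with
  posterior covariance
  $V_g = \sigma_g^2 A - \sigma_g^2 A (\sigma_g^2 A + \sigma_e^2 I)^{-1}
  \sigma_g^2 A$;
* the conditional of $\tau_j^2$ is generalized inverse Gaussian with
  closed-form moments
  $E[1/\tau_j^2] = \lambda_j / |\gamma_j|$ and
  $E[\tau_j^2] = |\gamma_j|/\lambda_j + 1/\lambda_j^2$.

M-step (each block the exact conditional maximiser of the expected
complete-data log posterior):

* $\mu \leftarrow \operatorname{mean}(y - X\gamma - \hat g)$;
* $\gamma_j \leftarrow x_j^\top(y - \mu 1 - X_{-j}\gamma_{-j} - \hat g)
  \,/\, (x_j^\top x_j + \sigma_e^2 E[1/\tau_j^2])$, swept over $j$ in
  genome order;
* $\lambda_j^2 \leftarrow (1 + a)/(E[\tau_j^2]/2 + b)$;
* $\sigma_g^2 \leftarrow (\hat g^\top A^{-1}\hat g +
  \operatorname{tr}(A^{-1}V_g))/n$;
* $\sigma_e^2 \leftarrow (E\lVert y - \mu 1 - X\gamma - g\rVert^2)/(n+2)$.

Every update is validated in the test suite against an independent
numeric oracle: 1-D quadrature of the scale density, dense linear solves
for the polygenic posterior, and grid-plus-golden-section argmax of the
Q-function for each M-step block.

### A note on the $\lambda^2$ block

Two conventions exist for combining a Gamma$(a,b)$ hyperprior with the
exponential likelihood of $\tau^2$: maximising the conditional posterior
density of $\lambda^2$ gives $a/(E[\tau^2]/2+b)$, which collapses to zero
as $a \to 0$ and abolishes shrinkage at $a = 10^{-6}$; taking the
conditional posterior **mean** — equivalently, maximising with the Gamma
kernel written as $(\lambda^2)^a e^{-b\lambda^2}$ — gives
$(1+a)/(E[\tau^2]/2+b)$. This package adopts the second convention: it is
the one under which small $(a,b)$ produce the intended behaviour (null
effects driven to zero with $\lambda^2 \to (1/2 + a)/b$, i.e. a very
heavy penalty, while well-supported effects keep a moderate, data-driven
$\lambda_j$), and the one under which the degenerate choice $a=b=0$ is
visibly meaningless, since the null fixed point $(1/2)/b$ diverges. The
package's internal objective (the observed-data log posterior recorded in
`objective_trace`) uses the same kernel, so EM monotonicity holds exactly
for the implemented updates and is asserted in the tests to a $10^{-8}$
slack.

### Numerical choices

* Initialisation: $\mu = \bar y$, $\gamma = 0$, $\lambda_j^2 = 1$,
  $\sigma_g^2 = \sigma_e^2 = \operatorname{var}(y)/2$.
* Convergence: maximum absolute change of
  $(\mu, \gamma, \sigma_g^2, \sigma_e^2)$ below `tol` ($10^{-8}$ by
  default), at most `max_iter` = 10,000 iterations. An infinite `tol`
  runs a single iteration and reports `converged = FALSE`.
* Degenerate effects: $E[1/\tau_j^2]$ is capped at
  $\lambda_j/10^{-12}$ when $|\gamma_j| < 10^{-12}$; a SNP staying below
  $10^{-12}$ for 3 consecutive iterations is clamped to exactly zero and
  skipped, re-entering when its partial-residual correlation becomes the
  sweep's largest. This makes "shrunk to zero" literal in the output.
* All per-iteration work is done in the eigenbasis of $A$ (computed once
  and cached), so one EM iteration costs $O(np)$; the compiled engine and
  a pure-R reference engine implement the identical recursion and are
  compared in the tests.
* The EM is a *local* optimiser of a multimodal posterior: a SNP whose
  signal is weak relative to $\sigma_e^2$ (for example a rare variant
  whose realised variance contribution is small) can legitimately end in
  the zero mode. This is the conservative behaviour that gives the
  method its low false-positive rate.

### SNP heritability and significance

The variance contributed by SNP $j$ under Hardy-Weinberg proportions at
allele frequency $p_j$ is $2p_j(1-p_j)\gamma_j^2$, and
$h_j^2 = 2p_j(1-p_j)\gamma_j^2 / \operatorname{var}(y)$, using the sample
phenotypic variance in the denominator (the alternative — the sum of
fitted variance components — differs only by the fit's residual
discrepancy and is less transparent to report). Genome-wide significance
uses the empirical $(1-\alpha)$ quantile (type-7) of the per-permutation
maxima of $h_j^2$ over phenotype permutations (1,000 by default,
$\alpha = 0.05$). The whole phenotype vector is shuffled, which breaks
the genotype link *and* the pedigree link; the threshold is therefore an
exchangeable-null approximation, and the prescreened SNP set is held
fixed across permutations (the selection step is not repeated), both
documented limitations of the two-stage design.

## The single-marker baseline and the two-stage pipeline

`fit_null_reml()` estimates $(\sigma_g^2, \sigma_e^2)$ for
$y = \mu 1 + g + e$ by restricted maximum likelihood, profiling
analytically in the eigenbasis of $A$ and searching the variance ratio
$\delta = \sigma_e^2/\sigma_g^2$ on $\log\delta \in [\log 10^{-5},
\log 10^{5}]$. `smma_scan()` then fits each SNP by generalised least
squares with the covariance held fixed at the null estimates and reports
a two-sided Wald p-value — the standard fixed-variance approximation to
per-SNP mixed-model refits, adequate for a screen and orders of magnitude
faster. The two-stage pipeline (`run_two_stage()`) takes the `top_k`
(default 500) smallest-p SNPs into the joint MEML fit; the prescreen
exists to make 1,000-permutation thresholds affordable, and the fit is
insensitive to the exact subset size in the few-hundred to
couple-of-thousand range.

## What the simulator emulates

`sim_config()` defaults describe the package's reference simulation: 6
chromosomes of 1 Morgan carrying 1,000 evenly spaced SNPs each; a founder
pool of 100 individuals whose linkage disequilibrium is built by 100
generations of random mating with recombination (Poisson crossover count
with mean equal to the map length, uniform breakpoints, no
interference); a locus drifting to fixation is re-polymorphised by a
single random allele flip. On top of the pool sits a two-generation
full-sib design: 50 families of 40 offspring, then 20 families of 100
offspring whose parents are drawn from distinct generation-1 families —
4,000 pedigreed individuals. Phenotypes are population mean 1 plus
additive QTL effects plus $N(0, 1)$ residuals.

The 43 QTL (15 "major", 28 "minor") ship as a fixed, versioned table
(`inst/extdata/qtl_spec_default.csv`). The effect sizes were drawn once
from Gamma-distributed variance contributions with random signs,
calibrated so the major QTL jointly explain about 30% of phenotypic
variance at allele frequency 0.5 with residual variance 1; positions are
spread evenly across the six chromosomes away from the chromosome ends.
These stand in for an external workshop dataset's unpublished effect
values and are *not* regenerated at run time.

What the simulator does **not** emulate: genotyping error and
missingness, allele-frequency ascertainment of commercial SNP panels,
selection during the pedigree, non-additive (dominance/epistatic) QTL
action, and X-linked inheritance. Passing tests on simulated data
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to those real-data artefacts; QC
(`qc_filter()`) addresses the first group on real inputs.

## Power and false-positive evaluation

`evaluate_replicates()` runs, per simulated replicate, the genome-wide
SMMA scan (statistic $-\log_{10} p$) and the two-stage MEML fit
(statistic $h_j^2$), each with its own permutation threshold. A
significant SNP within one grid locus of a true QTL (same chromosome)
detects it — each QTL at most once per replicate; all other significant
SNPs are false positives, and the false-positive rate divides by the
number of non-QTL loci, each QTL masking itself and its two neighbours
(total SNPs $- 3 \times$ number of QTL). Power is non-decreasing in
effect size, the single-marker scan retains more raw power, and the
multi-SNP fit cuts the false-positive rate by well over an order of
magnitude — the qualitative pattern the method exists to deliver.

### Validation problem sizes

The test suite and `scripts/acceptance.R` exercise this protocol at the
package's chosen validation sizes: 6 chromosomes of 150 SNPs, a
two-generation design of 400 individuals over a 60-founder pool with 30
generations of LD build-up, 10 replicates, and 200 permutations per
threshold; permutation calibration uses a 200-individual null panel with
100 SNPs, 200 permutations and 100 outer replicates; the single-QTL
recovery study uses $n = 500$ with the causal SNP at allele frequency
0.5 contributing 20% of the phenotypic variance, 20 replicates. These
sizes keep the full validation in the minutes range on one core while
preserving every structural feature (LD, full-sib pedigree, two-stage
selection, permutation thresholds) of the full-size design.

The permutation and replicate studies run the EM at `tol = 1e-6` —
applied identically to the observed fit and every permuted fit, so the
compared statistics come from the same procedure. Near the null the EM's
approach to the $\sigma_g^2$ boundary is sublinear and the last two
orders of magnitude of the default tolerance cost thousands of
iterations while moving the per-SNP statistics only at rounding level;
the looser setting was checked to leave the permutation thresholds
unchanged beyond numerical dust.

## Design decisions that were genuinely open

* **Per-SNP vs shared hyperparameter** — each $\gamma_j$ has its own
  $\lambda_j^2$, matching the "independent double-exponential prior per
  effect" construction; a shared $\lambda^2$ couples unrelated SNPs and
  weakens selective shrinkage.
* **What the permutation shuffles** — the raw phenotype vector, not
  polygenic residuals; simplest exchangeable null, with the documented
  caveat that pedigree structure is broken too.
* **Reference allele** — the major allele, ties broken to the
  lexicographically smaller symbol; deterministic and consistent with
  the minor-allele-frequency convention.
* **QC order** — individual missingness, then SNP call rate, then MAF,
  then HWE, each on the then-current data; `hwe_test()` is the 1-df
  asymptotic chi-square test, appropriate at the $10^{-6}$ threshold
  with thousands of individuals.
* **Missing genotypes after QC** — per-SNP mean imputation
  ($2p_j - 1$), since the joint model assumes a complete matrix; counts
  are logged.
* **SMMA machinery** — EMMAX-style fixed-variance GLS rather than exact
  per-SNP REML refits: the scan is a screen/baseline, and refits would
  dominate run time at 40k+ SNPs.

## Worked example

```{r example, eval = FALSE}
library(memlgwas)

cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 100,
                  qtl_spec = data.frame(chrom = 1, snp_index = 50,
                                        effect = 0.7, class = "major"),
                  gen1_families = 10, gen1_offspring = 20,
                  gen2_families = 5, gen2_offspring = 40,
                  base_size = 40, historical_generations = 20, seed = 11)
r <- simulate_replicate(cfg)

run <- run_two_stage(gwas_config(
  panel = r$panel,
  phenotypes = phenotype_vector(r$y, r$panel$individual_ids),
  pedigree_table = r$pedigree,
  maf_min = 0.01, top_k = 50, n_perm = 200, seed = 1))

run$significant
plot_snp_h2(run$meml, threshold = run$thresholds$h2$threshold)
```

## Known limitations

* The EM finds a local posterior mode; weak or rare-variant signals can
  be absorbed entirely by the polygenic term (by design — this is the
  conservative trade-off).
* With $A = I$ (no pedigree) the split $\sigma_g^2$ vs $\sigma_e^2$ is
  not identifiable; the REML fit flags this, and SNP effect estimates
  remain valid because they depend only on the total covariance.
* Permutation thresholds ignore relatedness under the null (see above);
  family-wise error is calibrated in the package's tests under an
  exchangeable null.
* Dense $A$ and its eigendecomposition scale to a few thousand
  individuals (the intended design size), not to hundreds of thousands.
* Binary traits, dominance, epistasis and VCF/binary-PLINK input are out
  of scope.
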