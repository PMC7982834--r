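---
title: "Mixture-model GWAS with biological priors and cross-population selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model GWAS with biological priors and cross-population selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmmgwas)
```

## The problem this package addresses

Complex binary traits such as cruciate-ligament rupture in dogs are highly
polygenic: most associated variants have effects too small for single-marker
tests at realistic cohort sizes, and associations replicate poorly across
studies. `bmmgwas` implements a whole-genome Bayesian mixture-model
association analysis in which **all** SNP effects are estimated jointly,
each effect drawn from one of four normal components,

$$\beta_j \mid k_j \sim N(0,\; \gamma_{k_j}\,\sigma_g^2), \qquad
\gamma = (0,\; 10^{-4},\; 10^{-3},\; 10^{-2}),$$

so the model carries a point mass at zero (most SNPs do nothing) and three
effect-size tiers scaled by a common genetic-variance parameter
$\sigma_g^2$. The informed-prior extension partitions SNPs into
user-defined biological classes — here, classes built from genes
differentially expressed in ligament ("ACL"), in knee synovium ("SYN"), in
both tissues ("A&S"), and from literature candidate genes ("LIT"), with
everything else unassigned ("NA") — and gives every class its own mixing
proportions $\pi^{(c)}$ with a $\mathrm{Dirichlet}(1,1,1,1)$ prior. A class
enriched for causal variants therefore earns, from the data alone, a higher
prior probability of non-zero effects for its members; with a single class
the model collapses to the plain four-component mixture (BayesR mode,
`run_bayesr_mode()`).

The package couples this association engine with a cross-population
selection scan (XP-EHH) between case and control haplotypes, marker QC, a
genomic-relationship-matrix PCA for population structure, imputation
concordance scoring, and a synthetic-cohort generator that provides ground
truth for every stage.

## The Gibbs sampler

`run_chain()` runs a full conditional Gibbs sweep per iteration
(`gibbs_iteration()` exposes a single sweep):

1. **Fixed effects** (intercept, sex, age, weight, neuter status, and the
   top five PCs of the variance-standardized GRM) are updated one column at
   a time from their Gaussian full conditionals under a flat prior.
2. **Each SNP**: the component indicator $k_j$ is drawn with probability
   proportional to $\pi^{(c(j))}_k$ times the marginal likelihood of the
   current residual under component variance $\gamma_k \sigma_g^2$; then
   $\beta_j$ is drawn from its Gaussian full conditional ($\beta_j = 0$
   when $k_j = 0$). The residual is maintained incrementally (axpy
   updates), giving $O(nm)$ work per sweep, and is recomputed from scratch
   periodically as a conservation check (`check_every`).
3. **Mixing proportions** per class from
   $\mathrm{Dirichlet}(\alpha + \text{component counts})$.
4. **Variances** $\sigma_g^2$ (from $\sum_j \beta_j^2/\gamma_{k_j}$) and
   $\sigma_e^2$ (from the residual sum of squares) from scaled-inverse-
   $\chi^2$ conditionals with `df_prior = 4` and scales set from an initial
   heritability guess of 0.5. These priors only matter before the data
   takes over; the recovery tests verify the posterior is insensitive to
   them.

The hot loop is compiled (Rcpp) but draws all randomness from R's RNG, so
`set.seed()` makes every chain bit-reproducible. Initialization is a cold
start (all $\beta = 0$, $\pi^{(c)}$ at the prior mean, variances at the
prior scales), which makes burn-in behavior reproducible across seeds.
Summaries are streaming running means, so memory stays $O(m)$ with no
thinning. The production schedule is 200,000 iterations with 100,000
burn-in, averaged over five replicate chains (`run_replicates()`), which
also reports the between-chain correlation of SNP effects as a convergence
diagnostic.

### What the package reports as heritability

Two quantities are returned and they are not the same thing:
`sigma_g2_mean` is the posterior mean of the mixture *scale* parameter (the
per-SNP variance unit), whereas `genic_var_mean` is the posterior mean of
$\mathrm{Var}(X\beta)$, the variance actually explained by the fitted SNP
effects. The heritability estimate `h2_mean` is
$\mathrm{Var}(X\beta) / (\mathrm{Var}(X\beta) + \sigma_e^2)$ per iteration,
averaged post burn-in — the scale parameter alone would not be
interpretable as heritability because it is not multiplied by the number of
non-zero SNPs.

### Binary response

Case/control status is fit directly as a 0/1 Gaussian response, matching
the common practice for this model family and keeping effect sizes on the
scale of reported per-SNP effects. Note that an observed-scale analysis of
a binary trait attenuates heritability relative to the liability scale by
Robertson's factor $z^2/(p(1-p))$; the package's parameter-recovery tests
therefore use the continuous liability (which the generator returns) when
checking that $h^2$ is recovered, and the binary status everywhere the
real analysis would use it.

### Zero spike versus the smallest component at desk scale

The smallest effect component has variance $10^{-4}\sigma_g^2$; for a
single SNP the marginal-likelihood ratio between it and the zero spike is
$1 + O((n\,10^{-4}\sigma_g^2/\sigma_e^2)^2)$ — indistinguishable at any
realistic $n$. What separates them in a full-size analysis is the
*collective* penalty: with hundreds of thousands of SNPs, parking a
quarter of them in the $10^{-4}$ component adds non-trivial junk variance
to the fit and the likelihood pushes the class proportions back onto the
spike. At desk-scale marker counts (thousands of SNPs) that pressure is
weak, so the posterior zero-component occupancy of null SNPs is governed
mostly by the Dirichlet posterior rather than pinned near 1. Tests of the
null model therefore check what actually holds at this scale — effects
shrink to near zero, the strong components stay rare, and estimated
heritability is near zero — rather than demanding full spike occupancy.

## The synthetic cohort generator

`simulate_cohort()` produces the study conditions every validation runs
under:

* **Haplotypes** (`simulate_haplotypes()`): founder-mosaic block copying.
  Chromosomes are divided into 20 kb blocks (matching the average
  haplotype-block length reported for the breed that motivated the
  pipeline, ~19 kb); within a block each haplotype copies one of 8 founder
  haplotypes, switching founders between blocks with probability 0.1.
  This produces strong within-block r², decaying EHH with distance, and a
  realistic small-founder breed structure without the cost of a coalescent
  simulator. The ancestral allele is defined as the founder-major allele
  and recorded in the panel, so selection scans never need external
  ancestral inference. Target MAFs are drawn from (0.05, 0.5).
* **Phenotypes** (`simulate_phenotypes()`): liability threshold model.
  SNP components are drawn per class from the configured 4-vectors
  (defaults give ~0.8% of unannotated SNPs a non-zero effect, mirroring
  the fraction reported in the motivating analysis, with tenfold
  enrichment in annotated classes); the liability is
  $Z\beta + \text{covariates} + e$ with $\sigma_e^2$ scaled to realize the
  configured $h^2$ (default 0.3, in the range reported for canine
  cruciate-ligament rupture), and the case threshold is the empirical
  quantile realizing the configured prevalence (default 0.4, the case
  fraction of the motivating cohort, 156/397). Covariates are sex and
  neuter status (Bernoulli), age and weight (Gaussian), each contributing
  0.1 liability SD by default — enough confounding to make fixed-effect
  correction testable without dominating the signal.
* **Sweep** (`inject_sweep()`): one donor case haplotype is copied into
  case haplotypes over the configured span until it reaches the configured
  frequency among case haplotypes, leaving controls untouched — the
  over-represented long haplotype that XP-EHH is designed to detect.
* **Defaults** are ~400 samples and 10k SNPs over 5 chromosomes; tests and
  benchmarks state their own sizes explicitly (e.g. n = 1000, m = 5000 for
  parameter recovery; 20 replicates of n = 200, m = 2000 for sweep
  localization).

What the generator does *not* emulate: coalescent-exact genealogies,
recombination hotspots, genotyping error beyond uniform missingness, the X
chromosome, or linkage between covariates and genotype. Passing tests
demonstrate correctness of the machinery under block-LD polygenic
architecture, not performance on any particular real cohort.

## Quality control and population structure

`apply_qc()` applies the standard marker filters sequentially — MAF < 0.01,
call rate < 90%, Hardy-Weinberg exact-test p < 1e-7, then any remaining
SNP with missing genotypes (the sampler tolerates none) — reporting
per-filter removal counts. The HWE test is the two-sided exact test on the
conditional distribution of heterozygote counts (the PLINK convention; a
χ² approximation is unreliable at p thresholds as extreme as 1e-7), and
MAF uses non-missing calls only since the call-rate filter runs
separately. `compute_grm()` standardizes genotypes by observed frequencies
($(x - 2\hat p)/\sqrt{2\hat p \hat q}$) and `top_pcs()` returns
eigenvectors scaled by the root eigenvalue; PCs are computed after QC.
`imputation_concordance()` scores per-chromosome accuracy as the fraction
of complete diploid genotypes that match the truth at shared sites.

Coordinates are 1-based inclusive internally; BED annotation is read and
written 0-based half-open.

## Prior classes

`build_gene_classes()` maps gene symbols to classes: both DEG lists →
"A&S", one list → "ACL"/"SYN", literature → "LIT". A gene in both a DEG
list and the literature list follows the DEG branch (precedence
A&S > ACL > SYN > LIT): replicated expression evidence carries less
uncertainty than a citation. `assign_snps()` assigns a SNP to a classed
gene whose body ± 25 kb contains it (both flank boundaries inclusive; the
flank default reflects the average haplotype-block scale of the data the
pipeline was designed around, and is a parameter). Overlaps resolve by the
same precedence, then by distance. Symbols match case-insensitively;
unmatched symbols are logged, not fatal. Which genes belong on the
literature list is a user decision — the lists are plain text inputs, never
hard-coded.

## Selection scan

`ehh()` computes extended haplotype homozygosity by outward group
splitting: carriers of the core allele start in one group, groups split at
each marker, and EHH is the probability two random carriers remain in the
same group — by construction EHH starts at 1 and never increases outward.
`integrate_ehh()` integrates the curve trapezoidally over physical
distance where it stays at or above the floor (default 0.05, the
convention of the established EHH packages; genetic-map distance is out of
scope). For the site-level statistic, the ancestral- and derived-allele
curves are combined with pair-count weights
$w_a = \binom{n_a}{2} / (\binom{n_a}{2} + \binom{n_d}{2})$ — the combined
curve is then exactly the probability that two random haplotypes sharing
the core allele are identical, alleles with fewer than two carriers
contribute no pairs, and the curve still starts at 1.

`xpehh_scan()` forms $\ln(iES_{\text{cases}}/iES_{\text{controls}})$ per
SNP, standardizes genome-wide to mean 0 and SD 1 (unbinned — the reported
statistic/p-value pairs this convention was validated against are
consistent with unbinned standardization), and converts to two-sided
Gaussian tail p-values on the log scale (`neglog10_p_two_sided()`, exact
to |z| ≈ 40). Tiers are candidate at p ≤ 1e-5 and genome-wide at p ≤ 1e-8,
boundaries inclusive. `calc_haplen()` reports the per-allele span over
which EHH stays above the floor, and `overlap_report()` flags selection
hits whose span union contains a top-50 GWAS SNP. Sites where either
population has zero or undefined iES are reported missing, never zero.

Phasing is an input contract: the scan consumes phased haplotypes (the
generator produces them phased; real data would arrive phased from
standard tools).

## Numerical and design choices

* Component-indicator sampling works on log weights with max-subtraction;
  variance draws guard against non-finite values.
* The residual is the single source of truth for the likelihood; the
  from-scratch conservation check bounds drift at 1e-8 in the tests.
* Top-effect tables break |effect| ties by chromosome, then position.
* Monomorphic and half-called records are rejected at I/O with counts;
  zero-variance SNPs abort GRM/model construction with advice to run QC.
* PLINK `.ped`/`.map` carries no allele orientation, so dosages orient to
  the minor allele unless the caller supplies `alt`; VCF round trips are
  exact.
* Problem sizes in tests (n ≤ 1000, m ≤ 5000, ≤ 20k iterations; 10–20
  seed replicates for comparative claims) were chosen as the smallest
  scales at which each property is statistically decisive.

## Known limitations

* The observed-scale binary fit is not a threshold/probit model; reported
  effects are on the standardized-genotype 0/1-response scale.
* Per-SNP effect magnitudes are not comparable across datasets without
  undoing the genotype standardization ($\beta_{\text{dosage}} =
  \beta / \sqrt{2\hat p \hat q}$).
* The generator's block-mosaic LD has no recombination-rate variation, so
  EHH decay is more homogeneous than in real data.
* Genomic prediction / polygenic risk scores, within-population iHS, and
  phasing are out of scope.
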