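test_that("haplotype simulation is reproducible and degenerates correctly", {
  cfg <- sim_config(n_samples = 30, n_snps = 300, n_chroms = 2, seed = 4)
  p1 <- simulate_haplotypes(cfg)
  p2 <- simulate_haplotypes(cfg)
  expect_identical(p1$hap, p2$hap)
  expect_identical(p1$variants, p2$variants)

  # single founder, no recombination: every haplotype is the founder
  cfg1 <- sim_config(n_samples = 20, n_snps = 100, n_chroms = 1,
                     n_founders = 1, recomb_between_blocks = 0, seed = 2)
  p <- simulate_haplotypes(cfg1)
  expect_true(all(p$hap == rep(p$hap[1, ], each = nrow(p$hap))))
})

test_that("allele frequencies land in the configured MAF range", {
  cfg <- sim_config(n_samples = 200, n_snps = 2000, n_chroms = 2, seed = 9)
  p <- simulate_haplotypes(cfg)
  freq <- colMeans(p$hap)
  maf <- pmin(freq, 1 - freq)
  expect_gt(mean(maf >= cfg$maf_range[1] & maf <= cfg$maf_range[2]), 0.95)
})

test_that("LD is stronger within blocks than between blocks", {
  cfg <- sim_config(n_samples = 250, n_snps = 1000, n_chroms = 1,
                    block_len_kb = 20, seed = 21)
  p <- simulate_haplotypes(cfg)
  block <- (p$variants$bp - 1L) %/% (cfg$block_len_kb * 1000)
  set.seed(1)
  js <- sample(ncol(p$hap) - 30L, 250)
  r2_within <- r2_between <- numeric(0)
  for (j in js) {
    same <- which(block == block[j] & seq_along(block) > j)
    diff_b <- which(block == block[j] + 2L)
    if (length(same)) {
      k <- same[1]
      r2_within <- c(r2_within, cor(p$hap[, j], p$hap[, k])^2)
    }
    if (length(diff_b)) {
      k <- diff_b[1]
      r2_between <- c(r2_between, cor(p$hap[, j], p$hap[, k])^2)
    }
  }
  expect_gt(mean(r2_within, na.rm = TRUE), mean(r2_between, na.rm = TRUE))
})

test_that("null configuration yields zero effects and no genotype-phenotype link", {
  em <- default_effect_mixture(); em[, ] <- 0; em[, 1] <- 1
  cfg <- sim_config(n_samples = 300, n_snps = 400, n_chroms = 1,
                    effect_mixture = em, h2 = 0, seed = 5)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$effect == 0))
  expect_true(all(co$truth$component == 0L))
  # case status carries no genetic signal: max point-biserial correlation
  # is at chance level for 400 SNPs
  r <- abs(cor(co$genotypes$dosage, co$covariates$case))
  expect_lt(max(r), 4.5 / sqrt(cfg$n_samples))
})

test_that("a forced strong-component SNP is the strongest marginal association", {
  em <- default_effect_mixture(); em[, ] <- 0; em[, 1] <- 1
  cfg <- sim_config(n_samples = 2000, n_snps = 400, n_chroms = 1,
                    effect_mixture = em, h2 = 0.5,
                    covariate_effects = c(sex = 0, neuter = 0, age = 0,
                                          weight = 0),
                    planted_qtl = list(n = 1, component = 3, effect = 0.1),
                    seed = 31)
  co <- simulate_cohort(cfg)
  r <- abs(cor(co$genotypes$dosage, co$covariates$case))
  expect_equal(which.max(r), co$truth$planted)
})

test_that("liability regression on the true genetic value recovers h2", {
  cfg <- sim_config(n_samples = 2000, n_snps = 2000, n_chroms = 2,
                    h2 = 0.5,
                    covariate_effects = c(sex = 0, neuter = 0, age = 0,
                                          weight = 0), seed = 13)
  co <- simulate_cohort(cfg)
  r2 <- summary(lm(co$truth$liability ~ co$truth$genetic_value))$r.squared
  expect_equal(r2, 0.5, tolerance = 0.1)  # 0.5 +/- 0.05 absolute
  expect_lt(abs(r2 - 0.5), 0.05)
  # realized case fraction tracks configured prevalence
  expect_lt(abs(mean(co$covariates$case) - cfg$prevalence), 0.05)
})

test_that("component frequencies match configured probabilities (chi-square GOF)", {
  em <- default_effect_mixture()
  cfg <- sim_config(n_samples = 40, n_snps = 50000, n_chroms = 5,
                    class_fractions = c(ACL = 0, SYN = 0, `A&S` = 0,
                                        LIT = 0),
                    effect_mixture = em, seed = 17)
  co <- simulate_cohort(cfg)
  obs <- table(factor(co$truth$component, levels = 0:3))
  gof <- suppressWarnings(
    chisq.test(obs, p = em["NA", ]))
  expect_gt(gof$p.value, 0.01)
})

test_that("sweep injection respects frequency targets and bounds", {
  cfg <- sim_config(n_samples = 60, n_snps = 600, n_chroms = 1, seed = 3,
                    sweep = list(chrom = 1, pos_bp = 300000,
                                 case_freq = 1.0, span_kb = 100))
  co <- simulate_cohort(cfg)
  cases <- co$covariates$sample[co$covariates$case == 1]
  cpan <- subset_panel(co$panel, cases)
  sites <- which(abs(cpan$variants$bp - 300000) <= 50000)
  # fixation: every case haplotype identical over the span -> EHH = 1
  core <- sites[which.min(abs(cpan$variants$bp[sites] - 300000))]
  seg <- cpan$hap[, sites, drop = FALSE]
  expect_true(all(seg == rep(seg[1, ], each = nrow(seg))))
  al <- if (cpan$hap[1, core] == 0) "ancestral" else "derived"
  curve <- ehh(cpan, core, al, floor = 0)
  inspan <- abs(curve$pos - 300000) <= 50000
  expect_true(all(curve$ehh[inspan] == 1))

  # no-op when the target frequency is already reached
  pan2 <- co$panel
  cfg2 <- cfg; cfg2$sweep$case_freq <- 0
  expect_identical(inject_sweep(pan2, cases, cfg2)$hap, pan2$hap)

  # out-of-bounds span names the chromosome length
  cfg3 <- cfg; cfg3$sweep$pos_bp <- 10e6
  expect_error(inject_sweep(co$panel, cases, cfg3), "length")
})
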