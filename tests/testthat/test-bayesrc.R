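test_that("model data is centered, scaled, and validated", {
  set.seed(2)
  # planted allele frequency 0.25: scaling must be 1/sqrt(2 * 0.25 * 0.75)
  X <- cbind(c(rep(2L, 1), rep(1L, 2), rep(0L, 5)),
             rbinom(8, 2, 0.5))
  g <- make_genotypes(X)
  cov <- data.frame(sample = g$samples, case = c(1, 0, 1, 0, 1, 0, 1, 0))
  md <- build_model_data(g, cov)
  expect_lt(max(abs(colMeans(md$X))), 1e-10)
  expect_equal(md$X[1, 1], (2 - 2 * 0.25) / sqrt(2 * 0.25 * 0.75))

  cov_bad <- cov; cov_bad$case <- 1
  expect_error(build_model_data(g, cov_bad), "no variance")
  cov_na <- cov; cov_na$sample[1] <- "other"
  expect_error(build_model_data(g, cov_na), "S001")
})

test_that("chains are deterministic given a seed", {
  cfg <- sim_config(n_samples = 50, n_snps = 200, n_chroms = 1, seed = 3)
  co <- simulate_cohort(cfg)
  md <- build_model_data(co$genotypes, co$covariates)
  a <- run_chain(md, n_iter = 300, burn_in = 100, seed = 42)
  b <- run_chain(md, n_iter = 300, burn_in = 100, seed = 42)
  expect_identical(a$effect, b$effect)
  expect_identical(a$occupancy, b$occupancy)
  expect_identical(a$h2_mean, b$h2_mean)
})

test_that("zero-SNP model reduces to Bayesian regression with the GLS mean", {
  set.seed(8)
  n <- 80
  W <- cbind(1, rnorm(n), rnorm(n))
  theta_true <- c(0.5, -1, 0.3)
  y <- as.vector(W %*% theta_true + rnorm(n, 0, 0.5))
  md <- micro_model_data(y, matrix(numeric(0), n, 0))
  md$W <- W
  ps <- run_chain(md, n_iter = 6000, burn_in = 1000, seed = 1)
  gls <- solve(crossprod(W), crossprod(W, y))
  expect_equal(unname(ps$theta_mean), as.vector(gls), tolerance = 0.02)
})

test_that("single-SNP component probabilities match the quadrature oracle", {
  set.seed(21)
  n <- 40
  x <- as.vector(scale(rbinom(n, 2, 0.3)))
  sgg <- 1; sge <- 0.6
  y <- x * 0.12 + rnorm(n, 0, sqrt(sge))
  spec <- mixture_spec()
  md <- micro_model_data(y, matrix(x, ncol = 1))
  ps <- run_chain(md, spec, n_iter = 60000, burn_in = 10000, seed = 5,
                  sigma_g2_fixed = sgg, sigma_e2_fixed = sge,
                  store_samples = TRUE)
  ml <- vapply(spec$gamma, function(g)
    component_marginal_lik(y, x, g * sgg, sge), numeric(1))
  oracle <- ml / sum(ml)   # uniform Dirichlet: P(k) proportional to ML_k
  expect_equal(as.vector(ps$occupancy), oracle, tolerance = 0.02)
})

test_that("stationary effect distribution matches the conjugate posterior (KS)", {
  set.seed(9)
  n <- 2
  x <- c(1, -1)
  sgg <- 1; sge <- 0.5
  y <- c(0.8, -0.1)
  spec <- mixture_spec()
  md <- micro_model_data(y, matrix(x, ncol = 1))
  # pin the indicator to the largest component: beta's full conditional is
  # then a fixed Gaussian
  ps <- run_chain(md, spec, n_iter = 12000, burn_in = 2000, seed = 3,
                  sigma_g2_fixed = sgg, sigma_e2_fixed = sge,
                  fix_pi = TRUE, pi_init = matrix(c(0, 0, 0, 1), 1),
                  store_samples = TRUE)
  v <- spec$gamma[4] * sgg
  lhs <- sum(x^2) / sge + 1 / v
  mu <- (sum(x * y) / sge) / lhs
  draws <- ps$beta_samples[, 1]
  ks <- ks.test(draws, "pnorm", mean = mu, sd = sqrt(1 / lhs))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero spike is conserved: nonzero draws equal non-zero occupancy", {
  cfg <- sim_config(n_samples = 40, n_snps = 60, n_chroms = 1, seed = 6)
  co <- simulate_cohort(cfg)
  md <- build_model_data(co$genotypes, co$covariates)
  ps <- run_chain(md, n_iter = 500, burn_in = 100, seed = 2,
                  store_samples = TRUE, check_every = 1)
  frac_nonzero <- colMeans(ps$beta_samples != 0)
  occ_nonzero <- rowSums(ps$occupancy[, 2:4])
  expect_equal(frac_nonzero, occ_nonzero)
  # component-0 iterations have beta exactly 0
  expect_true(all((ps$beta_samples == 0) == (ps$k_samples == 0)))
  # incremental residual equals the from-scratch residual at every sweep
  expect_lt(ps$max_resid_err, 1e-8)
})

test_that("a class with no SNPs reproduces the Dirichlet prior mean", {
  set.seed(4)
  n <- 30
  X <- scale(matrix(rbinom(n * 5, 2, 0.4), n, 5))
  y <- rnorm(n)
  md <- micro_model_data(y, X, class_index = rep(1L, 5),
                         class_levels = c("used", "empty"))
  ps <- run_chain(md, n_iter = 6000, burn_in = 1000, seed = 7)
  expect_equal(unname(ps$pi_mean["empty", ]), rep(0.25, 4),
               tolerance = 0.01)
})

test_that("a single Gibbs sweep returns a valid, advanced chain state", {
  cfg <- sim_config(n_samples = 30, n_snps = 50, n_chroms = 1, seed = 7)
  co <- simulate_cohort(cfg)
  md <- build_model_data(co$genotypes, co$covariates)
  spec <- mixture_spec()
  set.seed(1)
  st <- init_chain_state(md, spec)
  st2 <- gibbs_iteration(st, md, spec)
  expect_length(st2$beta, ncol(md$X))
  expect_true(all(st2$pi >= 0))
  expect_equal(rowSums(st2$pi), rep(1, nrow(st2$pi)))
  expect_true(all((st2$beta == 0) == (st2$k == 0)))
  expect_true(st2$sigma_g2 > 0 && st2$sigma_e2 > 0)
  # residual bookkeeping holds after the sweep
  r_direct <- md$y - as.vector(md$W %*% st2$theta) -
    as.vector(md$X %*% st2$beta)
  expect_equal(as.vector(st2$residual), r_direct, tolerance = 1e-10)
})

test_that("replicate averaging equals the single chain when n_chains = 1", {
  cfg <- sim_config(n_samples = 40, n_snps = 100, n_chroms = 1, seed = 5)
  co <- simulate_cohort(cfg)
  md <- build_model_data(co$genotypes, co$covariates)
  one <- run_chain(md, n_iter = 400, burn_in = 200, seed = 11)
  rep1 <- run_replicates(md, n_chains = 1, n_iter = 400, burn_in = 200,
                         seed = 11)
  expect_identical(rep1$effect, one$effect)
  expect_identical(rep1$h2_mean, one$h2_mean)
})

test_that("all-NA class labels reproduce the single-class (BayesR) run", {
  cfg <- sim_config(n_samples = 40, n_snps = 100, n_chroms = 1, seed = 5)
  co <- simulate_cohort(cfg)
  res <- assign_snps(co$genotypes, co$annotation, build_gene_classes())
  md_na <- build_model_data(co$genotypes, co$covariates,
                            class_assignment = res)
  br <- run_bayesr_mode(co$genotypes, co$covariates, n_chains = 2,
                        n_iter = 400, burn_in = 200, seed = 9)
  rc <- run_replicates(md_na, n_chains = 2, n_iter = 400, burn_in = 200,
                       seed = 9)
  expect_identical(rc$effect, br$effect)
  expect_identical(unname(rc$comp_counts), unname(br$comp_counts))
})
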