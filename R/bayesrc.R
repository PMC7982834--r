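#' Mixture specification for the Bayesian mixture-model sampler
#'
#' Four normal components for SNP effects with relative variances
#' `gamma * sigma_g2`: a zero spike and three effect distributions
#' `N(0, 1e-4 sigma_g2)`, `N(0, 1e-3 sigma_g2)`, `N(0, 1e-2 sigma_g2)`.
#' The per-class mixing proportions carry a mostly uninformative
#' `Dirichlet(1,1,1,1)` prior so biological class information influences
#' the fit only when the data support it.
#'
#' @param gamma Component relative variances, non-decreasing, first 0.
#' @param alpha Dirichlet prior, strictly positive.
#' @param df_prior Degrees of freedom of the scaled-inverse-chi-square
#'   priors on both variance components.
#' @param h2_init Initial heritability guess used only to set the prior
#'   scales (the conditionals are data-dominated after burn-in).
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(gamma = c(0, 1e-4, 1e-3, 1e-2),
                         alpha = c(1, 1, 1, 1),
                         df_prior = 4, h2_init = 0.5) {
  if (gamma[1] != 0) stop("first mixture component must have zero variance")
  if (any(diff(gamma) < 0)) stop("gamma must be non-decreasing")
  if (any(alpha <= 0)) stop("alpha must be strictly positive")
  if (length(alpha) != length(gamma))
    stop("alpha and gamma must have equal length")
  structure(list(gamma = gamma, alpha = alpha, df_prior = df_prior,
                 h2_init = h2_init), class = "mixture_spec")
}

#' Assemble model data for the mixture-model sampler
#'
#' SNP columns are centered by twice the observed allele frequency and
#' scaled to unit Hardy-Weinberg variance (`sqrt(2 p q)`), so the mixture
#' variances are fractions of the genetic variance as specified.
#' Covariates (sex, age, weight, neuter status) are standardized and an
#' intercept plus any principal-component scores are appended to the
#' fixed-effect design.
#'
#' @param genotypes A QC'd [genotype_matrix()] (no missing calls).
#' @param covariates Data frame with `sample`, the response column, and any
#'   covariates named in `covariate_cols`.
#' @param pcs Optional n x k matrix of PC scores (rows in `covariates`
#'   sample order or named).
#' @param class_assignment Optional `prior_class_assignment` from
#'   [assign_snps()]; omitted, all SNPs share a single class (BayesR).
#' @param response Name of the 0/1 response column (default "case").
#' @param covariate_cols Covariate columns to include as fixed effects.
#' @return Object of class `model_data`: response `y`, fixed design `W`,
#'   standardized SNP design `X`, integer `class_index`, `class_levels`,
#'   `variants`, `class_labels`, `samples`.
#' @export
build_model_data <- function(genotypes, covariates, pcs = NULL,
                             class_assignment = NULL, response = "case",
                             covariate_cols = c("sex", "age", "weight",
                                                "neuter")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  idx <- match(genotypes$samples, covariates$sample)
  if (anyNA(idx))
    stop("covariates missing for sample(s): ",
         paste(genotypes$samples[is.na(idx)], collapse = ", "))
  cov <- covariates[idx, , drop = FALSE]
  y <- as.numeric(cov[[response]])
  if (anyNA(y)) stop("missing response for sample(s): ",
                     paste(cov$sample[is.na(y)], collapse = ", "))
  if (var(y) == 0) stop("response has no variance (all-case or all-control)")

  covariate_cols <- intersect(covariate_cols, names(cov))
  W <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  for (cc in covariate_cols) {
    v <- as.numeric(cov[[cc]])
    if (anyNA(v)) stop("missing covariate '", cc, "' for sample(s): ",
                       paste(cov$sample[is.na(v)], collapse = ", "))
    if (sd(v) > 0) v <- as.vector(scale(v))
    W <- cbind(W, setNames(data.frame(v), cc)[[1]])
    colnames(W)[ncol(W)] <- cc
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (!is.null(rownames(pcs))) pcs <- pcs[genotypes$samples, , drop = FALSE]
    W <- cbind(W, pcs)
  }

  X <- genotypes$dosage
  if (anyNA(X)) stop("missing genotypes; run apply_qc() first")
  p <- colMeans(X) / 2
  s <- sqrt(2 * p * (1 - p))
  obs_var <- colMeans(X^2) - colMeans(X)^2
  if (any(s == 0 | obs_var == 0))
    stop("zero-variance SNP present; run apply_qc() first")
  X <- scale(X, center = 2 * p, scale = s)
  attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL

  if (is.null(class_assignment)) {
    class_labels <- rep("all", ncol(X))
  } else {
    cls <- class_assignment$assignment
    stopifnot(nrow(cls) == ncol(X))
    class_labels <- cls$class
  }
  class_levels <- unique(class_labels)
  class_index <- match(class_labels, class_levels)

  structure(list(y = y, W = W, X = X, class_index = class_index,
                 class_levels = class_levels, class_labels = class_labels,
                 variants = genotypes$variants,
                 samples = genotypes$samples),
            class = "model_data")
}

#' Cold-start chain state
#'
#' All SNP effects at zero (zero component), mixing proportions at the
#' normalized Dirichlet prior mean, variances at the prior scales.
#'
#' @param data A [build_model_data()] object.
#' @param spec A [mixture_spec()].
#' @return A `chain_state` list (`beta`, `k`, `pi`, `theta`, `sigma_g2`,
#'   `sigma_e2`).
#' @export
init_chain_state <- function(data, spec) {
  C <- length(data$class_levels)
  K <- length(spec$gamma)
  vy <- var(data$y)
  list(beta = numeric(ncol(data$X)), k = integer(ncol(data$X)),
       pi = matrix(spec$alpha / sum(spec$alpha), C, K, byrow = TRUE),
       theta = numeric(ncol(data$W)),
       sigma_g2 = spec$h2_init * vy,
       sigma_e2 = (1 - spec$h2_init) * vy)
}

run_chain_internal <- function(data, spec, n_iter, burn_in, state,
                               fix_pi = FALSE, sigma_g2_fixed = NULL,
                               sigma_e2_fixed = NULL, store_samples = FALSE,
                               check_every = 1000L) {
  vy <- var(data$y)
  .bayesrc_chain_cpp(
    data$X, data$W, data$y, data$class_index - 1L,
    length(data$class_levels), spec$gamma, spec$alpha,
    as.integer(n_iter), as.integer(burn_in),
    state$pi, fix_pi,
    if (is.null(sigma_g2_fixed)) state$sigma_g2 else sigma_g2_fixed,
    if (is.null(sigma_e2_fixed)) state$sigma_e2 else sigma_e2_fixed,
    !is.null(sigma_g2_fixed), !is.null(sigma_e2_fixed),
    spec$df_prior, spec$h2_init * vy, (1 - spec$h2_init) * vy,
    state$beta, as.integer(state$k), state$theta,
    store_samples, as.integer(check_every))
}

#' One full Gibbs sweep
#'
#' Updates, in order: fixed effects from their Gaussian full conditionals;
#' each SNP's component indicator (probability proportional to the class
#' mixing proportion times the marginal likelihood under that component
#' variance) and effect from its Gaussian full conditional, with
#' incremental residual maintenance; per-class mixing proportions from
#' `Dirichlet(alpha + counts)`; both variance components from their
#' scaled-inverse-chi-square conditionals.
#'
#' @param state A chain state from [init_chain_state()] or a previous call.
#' @param data A [build_model_data()] object.
#' @param spec A [mixture_spec()].
#' @param ... Passed to the sampler core (e.g. `sigma_g2_fixed`,
#'   `sigma_e2_fixed`, `fix_pi`).
#' @return The updated chain state.
#' @export
gibbs_iteration <- function(state, data, spec, ...) {
  res <- run_chain_internal(data, spec, n_iter = 1L, burn_in = 0L,
                            state = state, check_every = 1L, ...)
  st <- res$state
  st
}

#' Run one MCMC chain and summarize the posterior
#'
#' @param data A [build_model_data()] object.
#' @param spec A [mixture_spec()].
#' @param n_iter Total iterations (default 200000).
#' @param burn_in Burn-in iterations discarded from all summaries
#'   (default 100000).
#' @param seed Integer seed (R RNG; chains are bit-reproducible).
#' @param store_samples Keep post-burn-in draws of `beta` and the component
#'   indicators (memory O(iterations x SNPs); small problems only).
#' @param check_every Recompute the residual from scratch every this many
#'   iterations as a conservation diagnostic (0 disables).
#' @param pi_init Optional n_class x 4 matrix of starting mixing
#'   proportions (combined with `fix_pi = TRUE`, pins them).
#' @param ... Further sampler options (`fix_pi`, `sigma_g2_fixed`,
#'   `sigma_e2_fixed`).
#' @return Object of class `posterior_summary`: per-SNP posterior-mean
#'   effects and component-occupancy probabilities, per-class mixing
#'   proportion means, average per-component SNP counts, fixed-effect
#'   means, variance-component means, genic variance and heritability
#'   estimate, plus diagnostics.
#' @export
run_chain <- function(data, spec = mixture_spec(), n_iter = 200000,
                      burn_in = 100000, seed = 1, store_samples = FALSE,
                      check_every = 1000L, pi_init = NULL, ...) {
  stopifnot(burn_in < n_iter)
  set.seed(seed)
  state <- init_chain_state(data, spec)
  if (!is.null(pi_init)) state$pi <- pi_init
  res <- run_chain_internal(data, spec, n_iter, burn_in, state,
                            store_samples = store_samples,
                            check_every = check_every, ...)
  summarize_chain(res, data, spec, n_iter, burn_in, seed)
}

summarize_chain <- function(res, data, spec, n_iter, burn_in, seed) {
  occ <- res$occupancy
  colnames(occ) <- paste0("comp", seq_len(ncol(occ)) - 1L)
  pi_mean <- res$pi_mean
  dimnames(pi_mean) <- list(data$class_levels,
                            paste0("comp", seq_len(ncol(pi_mean)) - 1L))
  comp_counts <- res$comp_counts
  dimnames(comp_counts) <- dimnames(pi_mean)
  out <- list(effect = as.vector(res$beta_mean), occupancy = occ,
              pi_mean = pi_mean, comp_counts = comp_counts,
              theta_mean = setNames(as.vector(res$theta_mean),
                                    colnames(data$W)),
              sigma_g2_mean = res$sigma_g2_mean,
              sigma_e2_mean = res$sigma_e2_mean,
              genic_var_mean = res$genic_var_mean,
              h2_mean = res$h2_mean,
              max_resid_err = res$max_resid_err,
              n_kept = res$n_kept,
              variants = data$variants, class_labels = data$class_labels,
              n_iter = n_iter, burn_in = burn_in, seed = seed)
  if (!is.null(res$beta_samples)) {
    out$beta_samples <- res$beta_samples
    out$k_samples <- res$k_samples
  }
  structure(out, class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Bayesian mixture-model posterior summary\n")
  cat(sprintf("  %d SNPs, %d kept iterations (burn-in %d of %d)\n",
              length(x$effect), x$n_kept, x$burn_in, x$n_iter))
  cat(sprintf("  mean SNPs per component: %s\n",
              paste(round(colSums(x$comp_counts), 1), collapse = " / ")))
  cat(sprintf("  genic variance %.4f, sigma_e2 %.4f, h2 estimate %.3f\n",
              x$genic_var_mean, x$sigma_e2_mean, x$h2_mean))
  invisible(x)
}

#' Average posterior summaries across replicate chains
#'
#' Repeats the analysis with different seeds and averages per-SNP effects
#' and occupancies across chains; per-chain summaries are retained and the
#' between-chain Pearson correlation of per-SNP effects reported as a
#' convergence diagnostic.
#'
#' @inheritParams run_chain
#' @param n_chains Number of replicate chains (default 5).
#' @return A `posterior_summary` whose effects are across-chain averages,
#'   with `chains` (per-chain summaries) and `chain_cor` (correlation
#'   matrix of per-SNP effects) attached.
#' @export
run_replicates <- function(data, spec = mixture_spec(), n_chains = 5,
                           n_iter = 200000, burn_in = 100000, seed = 1,
                           ...) {
  stopifnot(n_chains >= 1)
  chains <- lapply(seq_len(n_chains), function(i)
    run_chain(data, spec, n_iter = n_iter, burn_in = burn_in,
              seed = seed + i - 1L, ...))
  avg <- chains[[1L]]
  if (n_chains > 1) {
    avg$effect <- Reduce(`+`, lapply(chains, `[[`, "effect")) / n_chains
    avg$occupancy <- Reduce(`+`, lapply(chains, `[[`, "occupancy")) / n_chains
    avg$pi_mean <- Reduce(`+`, lapply(chains, `[[`, "pi_mean")) / n_chains
    avg$comp_counts <- Reduce(`+`, lapply(chains, `[[`, "comp_counts")) /
      n_chains
    avg$theta_mean <- Reduce(`+`, lapply(chains, `[[`, "theta_mean")) /
      n_chains
    for (f in c("sigma_g2_mean", "sigma_e2_mean", "genic_var_mean",
                "h2_mean"))
      avg[[f]] <- mean(vapply(chains, `[[`, numeric(1), f))
  }
  B <- vapply(chains, `[[`, numeric(length(avg$effect)), "effect")
  avg$chain_cor <- if (n_chains > 1) cor(B) else matrix(1, 1, 1)
  avg$chains <- chains
  avg$n_chains <- n_chains
  avg
}

#' Single-class (BayesR) analysis
#'
#' Identical machinery with every SNP in one class — the informed-prior
#' model collapses to the plain four-component mixture model.
#'
#' @inheritParams run_replicates
#' @param genotypes,covariates,pcs As in [build_model_data()].
#' @param ... Passed to [run_replicates()].
#' @return A `posterior_summary`.
#' @export
run_bayesr_mode <- function(genotypes, covariates, pcs = NULL,
                            spec = mixture_spec(), ...) {
  data <- build_model_data(genotypes, covariates, pcs = pcs,
                           class_assignment = NULL)
  run_replicates(data, spec, ...)
}

#' Posterior effects as a ranked data frame
#'
#' @param summary A `posterior_summary`.
#' @return Data frame (id, chrom, bp, class, effect, occupancy columns)
#'   sorted by |effect| descending, ties by chromosome then position.
#' @export
effects_table <- function(summary) {
  d <- data.frame(id = summary$variants$id, chrom = summary$variants$chrom,
                  bp = summary$variants$bp, class = summary$class_labels,
                  effect = summary$effect, stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(summary$occupancy))
  d[order(-abs(d$effect), d$chrom, d$bp), , drop = FALSE]
}
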