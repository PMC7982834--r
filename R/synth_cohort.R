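#' Simulate phased haplotypes with block linkage disequilibrium
#'
#' Generates `2 * n_samples` phased haplotypes by founder-mosaic copying:
#' each chromosome is divided into blocks of `block_len_kb`; within a block
#' every haplotype is a verbatim copy of one of `n_founders` founder
#' haplotypes, and at each block boundary a haplotype switches to a random
#' founder with probability `recomb_between_blocks`. This produces high
#' within-block r2, decaying haplotype homozygosity with distance, and a
#' small founder-set structure comparable to a breed with extensive LD.
#'
#' The ancestral allele at every site is the founder-major allele (recorded
#' in the variant table), so downstream selection scans need no external
#' ancestral-state inference.
#'
#' @param config A [sim_config()].
#' @return A [haplotype_panel()].
#' @export
simulate_haplotypes <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_hap <- 2L * config$n_samples
  per_chrom <- rep(config$n_snps %/% config$n_chroms, config$n_chroms)
  per_chrom[config$n_chroms] <- per_chrom[config$n_chroms] +
    config$n_snps %% config$n_chroms
  block_bp <- config$block_len_kb * 1000

  hap <- matrix(0L, n_hap, config$n_snps)
  chrom <- integer(config$n_snps); bp <- integer(config$n_snps)
  off <- 0L
  for (ch in seq_len(config$n_chroms)) {
    m <- per_chrom[ch]
    pos <- cumsum(sample(800:1200, m, replace = TRUE))
    fall <- founder_alleles(config$n_founders, m, config$maf_range)
    block <- (pos - 1L) %/% block_bp + 1L
    ublock <- sort(unique(block))
    nb <- length(ublock)
    # founder path per haplotype across blocks
    path <- matrix(0L, n_hap, nb)
    path[, 1L] <- sample.int(config$n_founders, n_hap, replace = TRUE)
    if (nb > 1L) {
      sw <- matrix(runif(n_hap * (nb - 1L)) < config$recomb_between_blocks,
                   n_hap, nb - 1L)
      for (b in 2:nb) {
        path[, b] <- path[, b - 1L]
        idx <- sw[, b - 1L]
        if (any(idx))
          path[idx, b] <- sample.int(config$n_founders, sum(idx),
                                     replace = TRUE)
      }
    }
    for (b in seq_len(nb)) {
      sites <- which(block == ublock[b])
      hap[, off + sites] <- fall[path[, b], sites, drop = FALSE]
    }
    chrom[off + seq_len(m)] <- ch
    bp[off + seq_len(m)] <- pos
    off <- off + m
  }
  variants <- data.frame(
    id = paste0("chr", chrom, ":", bp), chrom = chrom, bp = bp,
    ref = "A", alt = "C", ancestral = "ref", stringsAsFactors = FALSE)
  haplotype_panel(hap, variants, sprintf("S%04d", seq_len(config$n_samples)))
}

# founder haplotype alleles: per site, a target frequency drawn from
# maf_range determines how many founders (1 .. floor(F/2)) carry the
# alternate allele; the founder-major allele is therefore always ref.
founder_alleles <- function(n_founders, m, maf_range) {
  fall <- matrix(0L, n_founders, m)
  if (n_founders == 1L) return(fall)
  kmin <- max(1L, ceiling(n_founders * maf_range[1]))
  kmax <- max(kmin, floor(n_founders / 2))
  p <- runif(m, maf_range[1], maf_range[2])
  k <- pmin(pmax(round(n_founders * p), kmin), kmax)
  for (j in seq_len(m))
    fall[sample.int(n_founders, k[j]), j] <- 1L
  fall
}

#' Simulate liability-threshold phenotypes and covariates for a panel
#'
#' Collapses the panel to dosages, lays out synthetic gene annotation with
#' per-class differential-expression / literature gene lists, draws each
#' SNP's mixture component from its class-specific 4-vector of component
#' probabilities (component variances `c(0, 1e-4, 1e-3, 1e-2) * sigma_g2` on
#' the standardized-genotype scale), and builds the liability
#' `l = Z beta + covariate terms + e` with the residual variance scaled so
#' the realized genic variance explains `h2` of `Z beta + e`. Case status is
#' liability above the empirical `1 - prevalence` quantile, so the realized
#' case fraction matches the configuration.
#'
#' @param panel A [haplotype_panel()] from [simulate_haplotypes()].
#' @param config The same [sim_config()].
#' @return A list with elements `genotypes` ([genotype_matrix()]),
#'   `covariates` (data frame: sample, sex, neuter, age, weight, case),
#'   `truth` (list: per-SNP `effect`, `component` (0..3), `class`,
#'   per-sample `liability`, `genetic_value`, `threshold`, `sigma_e2`),
#'   `annotation` (gene interval data frame) and `gene_lists`
#'   (ACL/SYN/LIT symbol vectors).
#' @export
simulate_phenotypes <- function(panel, config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  geno <- panel_to_genotypes(panel)
  X <- geno$dosage
  n <- nrow(X); m <- ncol(X)

  ann <- layout_annotation(geno$variants, config)
  snp_class <- ann$snp_class

  # mixture component and effect per SNP
  gam <- c(0, 1e-4, 1e-3, 1e-2)
  comp <- integer(m)
  for (cl in prior_class_levels()) {
    idx <- which(snp_class == cl)
    if (!length(idx)) next
    comp[idx] <- sample(0:3, length(idx), replace = TRUE,
                        prob = config$effect_mixture[cl, ])
  }
  planted <- integer(0)
  if (!is.null(config$planted_qtl)) {
    pq <- config$planted_qtl
    planted <- sample.int(m, pq$n)
    comp[planted] <- pq$component
  }
  beta <- numeric(m)
  nz <- comp > 0L
  beta[nz] <- rnorm(sum(nz), 0, sqrt(gam[comp[nz] + 1L] * config$sigma_g2))
  if (length(planted) && !is.null(config$planted_qtl$effect))
    beta[planted] <- sample(c(-1, 1), length(planted), replace = TRUE) *
      config$planted_qtl$effect

  p_hat <- colMeans(X) / 2
  sdx <- sqrt(2 * p_hat * (1 - p_hat))
  sdx[sdx == 0] <- 1
  g <- as.vector(scale(X, center = 2 * p_hat, scale = sdx) %*% beta)

  sex    <- rbinom(n, 1, 0.5)
  neuter <- rbinom(n, 1, 0.78)
  age    <- pmax(rnorm(n, 8, 3), 0.5)
  weight <- pmax(rnorm(n, 35, 6), 10)
  covs <- cbind(sex = sex, neuter = neuter, age = age, weight = weight)
  ce <- config$covariate_effects
  cov_term <- as.vector(scale(covs) %*% ce[colnames(covs)])

  var_g <- var(g)
  h2 <- config$h2
  if (h2 > 0 && var_g == 0) {
    warning("all true effects are zero; falling back to h2 = 0")
    h2 <- 0
  }
  sigma_e2 <- if (h2 > 0) var_g * (1 - h2) / h2 else 1
  liability <- g + cov_term + rnorm(n, 0, sqrt(sigma_e2))

  n_case <- round(n * config$prevalence)
  threshold <- sort(liability, decreasing = TRUE)[max(n_case, 1L)]
  case <- as.integer(liability >= threshold)

  covariates <- data.frame(sample = geno$samples, sex = sex, neuter = neuter,
                           age = age, weight = weight, case = case,
                           stringsAsFactors = FALSE)
  truth <- list(effect = beta, component = comp, class = snp_class,
                liability = liability, genetic_value = g,
                threshold = threshold, sigma_e2 = sigma_e2,
                planted = planted)
  list(genotypes = geno, covariates = covariates, truth = truth,
       annotation = ann$annotation, gene_lists = ann$gene_lists)
}

# contiguous runs of gene_size_snps SNPs become synthetic genes; per class,
# enough non-overlapping genes are placed to hit the configured SNP
# fraction, and gene symbols are distributed to the DEG / literature lists
# that define that class (A&S genes appear in both DEG lists).
layout_annotation <- function(variants, config) {
  m <- nrow(variants)
  gs <- max(2L, min(config$gene_size_snps, m %/% 4L))
  snp_class <- rep("NA", m)
  used <- logical(m)
  ann <- list(); lists <- list(ACL = character(), SYN = character(),
                               LIT = character())
  gi <- 0L
  for (cl in c("A&S", "ACL", "SYN", "LIT")) {
    target <- round((config$class_fractions[[cl]] %||% 0) * m)
    placed <- 0L
    guard <- 0L
    while (placed < target && guard < 50L * max(target, 1L)) {
      guard <- guard + 1L
      start <- sample.int(m - gs + 1L, 1L)
      idx <- start:(start + gs - 1L)
      if (any(used[idx])) next
      if (length(unique(variants$chrom[idx])) != 1L) next
      used[idx] <- TRUE
      snp_class[idx] <- cl
      gi <- gi + 1L
      sym <- sprintf("GENE%04d", gi)
      ann[[length(ann) + 1L]] <- data.frame(
        gene = sym, chrom = variants$chrom[start],
        start = variants$bp[start], end = variants$bp[idx[gs]],
        stringsAsFactors = FALSE)
      if (cl == "A&S") { lists$ACL <- c(lists$ACL, sym)
                         lists$SYN <- c(lists$SYN, sym) }
      if (cl == "ACL") lists$ACL <- c(lists$ACL, sym)
      if (cl == "SYN") lists$SYN <- c(lists$SYN, sym)
      if (cl == "LIT") lists$LIT <- c(lists$LIT, sym)
      placed <- placed + gs
    }
  }
  annotation <- if (length(ann)) do.call(rbind, ann) else
    data.frame(gene = character(), chrom = integer(), start = integer(),
               end = integer(), stringsAsFactors = FALSE)
  list(snp_class = snp_class, annotation = annotation, gene_lists = lists)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Engineer a partial selective sweep into case haplotypes
#'
#' Within the configured span, one donor case haplotype is copied into
#' randomly chosen case haplotypes until the donor haplotype reaches the
#' configured frequency among case haplotypes. Control haplotypes are left
#' untouched, creating the over-represented long haplotype in one
#' population that a cross-population EHH scan is designed to detect.
#'
#' @param panel A [haplotype_panel()] containing all samples.
#' @param case_ids Sample ids of cases.
#' @param config A [sim_config()] with a non-NULL `sweep`.
#' @return The modified [haplotype_panel()].
#' @export
inject_sweep <- function(panel, case_ids, config) {
  stopifnot(inherits(panel, "haplotype_panel"))
  sw <- config$sweep
  if (is.null(sw)) stop("config$sweep is not set")
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  v <- panel$variants
  on_chrom <- v$chrom == sw$chrom
  if (!any(on_chrom)) stop("no such chromosome: ", sw$chrom)
  chrom_len <- max(v$bp[on_chrom])
  half <- sw$span_kb * 1000 / 2
  if (sw$pos_bp - half < 0 || sw$pos_bp + half > chrom_len + 1000)
    stop(sprintf("sweep span [%d, %d] lies outside chromosome %s (length %d bp)",
                 as.integer(sw$pos_bp - half), as.integer(sw$pos_bp + half),
                 as.character(sw$chrom), chrom_len))
  sites <- which(on_chrom & abs(v$bp - sw$pos_bp) <= half)
  if (length(sites) < 10L)
    stop("sweep span contains fewer than 10 SNPs")

  keep <- match(case_ids, panel$samples)
  if (anyNA(keep)) stop("unknown case sample id(s)")
  case_rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  H <- panel$hap
  donor <- case_rows[1L]
  donor_hap <- H[donor, sites]
  same <- which(colSums(abs(t(H[case_rows, sites, drop = FALSE]) -
                              donor_hap)) == 0L)
  target_n <- ceiling(sw$case_freq * length(case_rows))
  need <- target_n - length(same)
  if (need > 0L) {
    pool <- setdiff(seq_along(case_rows), same)
    pick <- sample(pool, min(need, length(pool)))
    H[case_rows[pick], sites] <- rep(donor_hap, each = length(pick))
  }
  panel$hap <- H
  panel
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: haplotypes, phenotypes/covariates/annotation, and
#' (if configured) the case sweep, with genotypes recomputed from the
#' post-sweep panel so genotypes and haplotypes stay consistent.
#'
#' @param config A [sim_config()].
#' @return List: `panel`, `genotypes`, `covariates`, `truth`, `annotation`,
#'   `gene_lists`, `config`.
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_haplotypes(config)
  ph <- simulate_phenotypes(panel, config)
  if (!is.null(config$sweep)) {
    cases <- ph$covariates$sample[ph$covariates$case == 1L]
    panel <- inject_sweep(panel, cases, config)
    ph$genotypes <- panel_to_genotypes(panel)
  }
  c(list(panel = panel), ph, list(config = config))
}
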