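#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test on the conditional distribution of the heterozygote
#' count given the allele counts: the p-value is the total probability of
#' all heterozygote counts no more likely than the one observed (the
#' convention used by PLINK's `--hwe`). Monomorphic counts give p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, sum >= 1).
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0L) return(1)
  d <- hwe_het_distribution(n, rare)
  obs <- d$prob[match(n_Aa, d$het)]
  sum(d$prob[d$prob <= obs * (1 + 1e-12)])
}

# conditional distribution of the heterozygote count given n individuals
# and `rare` copies of the rarer allele, from the log-factorial closed form
hwe_het_distribution <- function(n, rare) {
  het <- seq(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  hom_r <- (rare - het) %/% 2L
  hom_c <- n - het - hom_r
  logp <- lfactorial(n) - lfactorial(hom_r) - lfactorial(het) -
    lfactorial(hom_c) + het * log(2) +
    lfactorial(rare) + lfactorial(2L * n - rare) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  list(het = het, prob = p / sum(p))
}

#' Apply marker quality-control filters
#'
#' Filters are applied sequentially in the order minor allele frequency,
#' genotyping call rate, Hardy-Weinberg exact test, then removal of any SNP
#' with remaining missing genotypes (the mixture-model sampler tolerates no
#' missing data). MAF and genotype counts use non-missing calls only.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min Remove SNPs with MAF below this value.
#' @param callrate_min Remove SNPs with call rate below this value.
#' @param hwe_alpha Remove SNPs with exact HWE p-value below this value.
#' @param drop_any_missing Remove SNPs with any missing genotype.
#' @return List with the filtered [genotype_matrix()] (`genotypes`) and a
#'   `qc_report` (`report`) of per-filter removal counts and per-SNP
#'   statistics.
#' @export
apply_qc <- function(g, maf_min = 0.01, callrate_min = 0.90,
                     hwe_alpha = 1e-7, drop_any_missing = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (ncol(g$dosage) == 0L) stop("empty genotype matrix")
  for (thr in c(maf_min, callrate_min))
    if (thr < 0 || thr > 1) stop("thresholds must lie in [0, 1]")
  if (hwe_alpha < 0 || hwe_alpha > 1) stop("thresholds must lie in [0, 1]")
  X <- g$dosage
  n <- nrow(X)

  callrate <- colMeans(!is.na(X))
  p_alt <- colMeans(X, na.rm = TRUE) / 2
  p_alt[is.nan(p_alt)] <- 0
  maf <- pmin(p_alt, 1 - p_alt)
  hwe_p <- vapply(seq_len(ncol(X)), function(j) {
    d <- X[, j]
    hwe_exact_test(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                   sum(d == 2L, na.rm = TRUE))
  }, numeric(1))

  keep <- rep(TRUE, ncol(X))
  removed <- c(maf = 0L, callrate = 0L, hwe = 0L, missing = 0L)
  drop1 <- keep & maf < maf_min
  removed["maf"] <- sum(drop1); keep <- keep & !drop1
  drop2 <- keep & callrate < callrate_min
  removed["callrate"] <- sum(drop2); keep <- keep & !drop2
  drop3 <- keep & hwe_p < hwe_alpha
  removed["hwe"] <- sum(drop3); keep <- keep & !drop3
  if (drop_any_missing) {
    drop4 <- keep & colSums(is.na(X)) > 0L
    removed["missing"] <- sum(drop4); keep <- keep & !drop4
  }
  out <- genotype_matrix(X[, keep, drop = FALSE],
                         g$variants[keep, , drop = FALSE], g$samples)
  report <- structure(list(
    n_input = ncol(X), n_output = sum(keep), removed = removed,
    thresholds = c(maf_min = maf_min, callrate_min = callrate_min,
                   hwe_alpha = hwe_alpha,
                   drop_any_missing = as.numeric(drop_any_missing)),
    snp_stats = data.frame(id = g$variants$id, maf = maf,
                           callrate = callrate, hwe_p = hwe_p,
                           kept = keep, stringsAsFactors = FALSE)),
    class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC:", x$n_input, "SNPs in,", x$n_output, "SNPs out\n")
  cat(sprintf("  removed by MAF < %g:        %d\n",
              x$thresholds["maf_min"], x$removed["maf"]))
  cat(sprintf("  removed by call rate < %g:  %d\n",
              x$thresholds["callrate_min"], x$removed["callrate"]))
  cat(sprintf("  removed by HWE p < %g:      %d\n",
              x$thresholds["hwe_alpha"], x$removed["hwe"]))
  cat(sprintf("  removed with missing calls: %d\n", x$removed["missing"]))
  invisible(x)
}

#' Per-chromosome imputation concordance
#'
#' Accuracy per chromosome is the number of genotypes imputed correctly
#' divided by the number of genotypes compared; a genotype is correct only
#' when the complete diploid call matches the truth. Comparison is
#' restricted to shared (chrom, bp) sites and to genotypes that are
#' non-missing in the truth set.
#'
#' @param imputed,truth [genotype_matrix()] objects on the same samples.
#' @return Data frame with columns `chrom`, `n_compared`, `n_correct`,
#'   `accuracy`.
#' @export
imputation_concordance <- function(imputed, truth) {
  stopifnot(inherits(imputed, "genotype_matrix"),
            inherits(truth, "genotype_matrix"))
  if (!identical(sort(imputed$samples), sort(truth$samples)))
    stop("imputed and truth matrices must cover the same samples")
  key_i <- paste(imputed$variants$chrom, imputed$variants$bp)
  key_t <- paste(truth$variants$chrom, truth$variants$bp)
  shared <- intersect(key_i, key_t)
  if (!length(shared)) stop("no shared variants between imputed and truth")
  ii <- match(shared, key_i); it <- match(shared, key_t)
  si <- match(truth$samples, imputed$samples)
  A <- imputed$dosage[si, ii, drop = FALSE]
  B <- truth$dosage[, it, drop = FALSE]
  chrom <- truth$variants$chrom[it]
  res <- lapply(unique(chrom), function(ch) {
    cols <- chrom == ch
    a <- A[, cols, drop = FALSE]; b <- B[, cols, drop = FALSE]
    cmp <- !is.na(b)
    correct <- cmp & !is.na(a) & a == b
    data.frame(chrom = ch, n_compared = sum(cmp), n_correct = sum(correct),
               accuracy = sum(correct) / sum(cmp))
  })
  do.call(rbind, res)
}
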