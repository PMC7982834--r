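#' Variance-standardized genomic relationship matrix
#'
#' Each SNP column is centered by twice its observed allele frequency and
#' scaled to unit variance under Hardy-Weinberg (`sqrt(2 p q)`), and the
#' GRM is `Z Z' / m` (VanRaden's second method). With this standardization
#' the expected diagonal is 1, so `trace(GRM)/n` is close to 1 for an
#' outbred sample.
#'
#' @param g A [genotype_matrix()] with no missing genotypes (run
#'   [apply_qc()] first).
#' @return List of class `grm`: `K` (n x n symmetric matrix),
#'   `allele_freq`, `n_snps`.
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  X <- g$dosage
  if (anyNA(X)) stop("missing genotypes present; run apply_qc() first")
  p <- colMeans(X) / 2
  s <- sqrt(2 * p * (1 - p))
  obs_var <- colMeans(X^2) - colMeans(X)^2
  if (any(s == 0 | obs_var == 0))
    stop("zero-variance SNP present; run apply_qc() first")
  Z <- scale(X, center = 2 * p, scale = s)
  K <- tcrossprod(Z) / ncol(X)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(g$samples, g$samples)
  structure(list(K = K, allele_freq = p, n_snps = ncol(X)), class = "grm")
}

#' Top principal components of a GRM
#'
#' Eigen decomposition of the relationship matrix; the returned scores are
#' eigenvectors scaled by the square root of their eigenvalue, ordered by
#' descending eigenvalue — the usual population-structure covariates.
#'
#' @param grm A `grm` from [compute_grm()].
#' @param k Number of components.
#' @return n x k matrix of PC scores.
#' @export
top_pcs <- function(grm, k = 5) {
  stopifnot(inherits(grm, "grm"))
  e <- eigen(grm$K, symmetric = TRUE)
  k <- min(k, ncol(e$vectors))
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(scores) <- rownames(grm$K)
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}
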