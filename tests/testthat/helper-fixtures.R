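# fixture builders and independent oracles shared across test files

# haplotype panel from an explicit 0/1 matrix (rows = haplotypes)
make_panel <- function(mat, pos = NULL, chrom = 1L, ancestral = "ref") {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  m <- ncol(mat)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  v <- data.frame(id = paste0("chr", chrom, ":", pos), chrom = chrom,
                  bp = as.integer(pos), ref = "A", alt = "C",
                  ancestral = ancestral, stringsAsFactors = FALSE)
  haplotype_panel(mat, v, sprintf("S%03d", seq_len(nrow(mat) / 2)))
}

# genotype matrix from an explicit dosage matrix
make_genotypes <- function(dos, pos = NULL, chrom = 1L) {
  dos <- as.matrix(dos)
  storage.mode(dos) <- "integer"
  m <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  v <- data.frame(id = paste0("snp", seq_len(m)), chrom = chrom,
                  bp = as.integer(pos), ref = "A", alt = "C",
                  stringsAsFactors = FALSE)
  genotype_matrix(dos, v, sprintf("S%03d", seq_len(nrow(dos))))
}

# O(n^2) pairwise EHH oracle: probability that two distinct carrier
# haplotypes are identical over the whole interval between core and site
ehh_pairwise_oracle <- function(H, core, carriers, site) {
  lo <- min(core, site); hi <- max(core, site)
  seg <- H[carriers, lo:hi, drop = FALSE]
  nc <- length(carriers)
  same <- 0L
  for (i in seq_len(nc - 1L))
    for (j in (i + 1L):nc)
      if (all(seg[i, ] == seg[j, ])) same <- same + 1L
  same / (nc * (nc - 1L) / 2)
}

# heterozygote-count distribution under HWE by the upward recurrence
# P(h + 2) = P(h) * 4 * hom_rare * hom_common / ((h + 2) * (h + 1)),
# an independent construction of the conditional distribution
hwe_recurrence_dist <- function(n, rare) {
  h0 <- rare %% 2L
  hs <- seq(h0, min(rare, 2L * n - rare), by = 2L)
  p <- numeric(length(hs))
  p[1] <- 1
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1L]
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    p[i] <- p[i - 1L] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  list(het = hs, prob = p / sum(p))
}

hwe_oracle_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)
  if (rare == 0L) return(1)
  d <- hwe_recurrence_dist(n, rare)
  obs <- d$prob[match(n_Aa, d$het)]
  sum(d$prob[d$prob <= obs * (1 + 1e-12)])
}

# marginal likelihood of y under one mixture component by 1-D quadrature
component_marginal_lik <- function(y, x, v, sigma_e2) {
  if (v == 0)
    return(prod(dnorm(y, 0, sqrt(sigma_e2))))
  f <- function(b) vapply(b, function(bb)
    prod(dnorm(y - x * bb, 0, sqrt(sigma_e2))) * dnorm(bb, 0, sqrt(v)),
    numeric(1))
  integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

# bare-bones model_data for sampler micro-tests (no intercept, one class)
micro_model_data <- function(y, X, class_index = NULL,
                             class_levels = "all") {
  X <- as.matrix(X)
  structure(list(y = y, W = matrix(numeric(0), length(y), 0),
                 X = X,
                 class_index = class_index %||% rep(1L, ncol(X)),
                 class_levels = class_levels,
                 class_labels = rep(class_levels[1], ncol(X)),
                 variants = data.frame(
                   id = paste0("s", seq_len(ncol(X)), recycle0 = TRUE),
                   chrom = rep(1L, ncol(X)), bp = seq_len(ncol(X)),
                   ref = rep("A", ncol(X)), alt = rep("C", ncol(X)),
                   stringsAsFactors = FALSE),
                 samples = paste0("I", seq_along(y))),
            class = "model_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
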