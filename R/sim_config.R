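#' Simulation configuration for a synthetic case-control cohort
#'
#' Collects every knob of the synthetic cohort generator: cohort and marker
#' panel dimensions, the block-LD haplotype model, the per-class mixture of
#' SNP effects on the liability scale, covariate effects, and an optional
#' engineered partial sweep in cases.
#'
#' The effect-size model mirrors the four-component mixture used by the
#' association engine: a zero spike plus three normal components with
#' variances `c(1e-4, 1e-3, 1e-2) * sigma_g2`. `effect_mixture` gives, per
#' prior class, the probability that a SNP falls in each component, so
#' enriching a class simply shifts mass out of the zero spike for that class.
#'
#' @param n_samples Number of diploid individuals.
#' @param n_snps Total SNPs across all chromosomes (remainder of an uneven
#'   split goes to the last chromosome).
#' @param n_chroms Number of chromosomes.
#' @param block_len_kb Haplotype block length in kb; within a block every
#'   haplotype is a copy of one of `n_founders` founder haplotypes.
#' @param n_founders Founder haplotypes per block.
#' @param recomb_between_blocks Probability that a haplotype switches founder
#'   at a block boundary (mosaic copying).
#' @param maf_range Length-2 numeric, target minor-allele-frequency range in
#'   (0, 0.5].
#' @param class_fractions Named fractions of SNPs belonging to each
#'   biological prior class ("ACL", "SYN", "A&S", "LIT"); the remainder is
#'   unannotated ("NA").
#' @param effect_mixture 5 x 4 matrix of per-class component probabilities
#'   (rows "ACL","SYN","A&S","LIT","NA"; each row sums to 1).
#' @param sigma_g2 Additive-genetic variance scale (liability units).
#' @param h2 Narrow-sense heritability of liability in (0, 1), or 0 for a
#'   pure-noise phenotype.
#' @param prevalence Case fraction of the cohort (liability threshold is set
#'   to realize it).
#' @param covariate_effects Named effects (liability units per SD) for
#'   "sex", "neuter", "age", "weight".
#' @param gene_size_snps SNPs per synthetic gene used to lay out annotation.
#' @param sweep `NULL`, or `list(chrom=, pos_bp=, case_freq=, span_kb=)`
#'   describing a partial sweep engineered into case haplotypes.
#' @param planted_qtl `NULL`, or `list(n=, component=, effect=)` forcing
#'   `n` randomly chosen SNPs into the given mixture component; `effect`
#'   (optional) fixes the |effect| instead of drawing it, for recovery
#'   benchmarks with a known strongest locus.
#' @param seed Integer seed; every generator function sets it when non-NULL.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 400,
                       n_snps = 10000,
                       n_chroms = 5,
                       block_len_kb = 20,
                       n_founders = 8,
                       recomb_between_blocks = 0.1,
                       maf_range = c(0.05, 0.5),
                       class_fractions = c(ACL = 0.0059, SYN = 0.0177,
                                           `A&S` = 0.0016, LIT = 0.0024),
                       effect_mixture = default_effect_mixture(),
                       sigma_g2 = 1,
                       h2 = 0.3,
                       prevalence = 0.4,
                       covariate_effects = c(sex = 0.1, neuter = 0.1,
                                             age = 0.1, weight = 0.1),
                       gene_size_snps = 25,
                       sweep = NULL,
                       planted_qtl = NULL,
                       seed = NULL) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_chroms = as.integer(n_chroms), block_len_kb = block_len_kb,
              n_founders = as.integer(n_founders),
              recomb_between_blocks = recomb_between_blocks,
              maf_range = maf_range, class_fractions = class_fractions,
              effect_mixture = effect_mixture, sigma_g2 = sigma_g2, h2 = h2,
              prevalence = prevalence, covariate_effects = covariate_effects,
              gene_size_snps = as.integer(gene_size_snps),
              sweep = sweep, planted_qtl = planted_qtl, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default per-class mixture-component probabilities
#'
#' Unannotated SNPs get a polygenic background with roughly 0.8% of SNPs
#' outside the zero spike; annotated classes are enriched tenfold for
#' non-zero effects, emulating the situation the informed prior is built for.
#'
#' @return 5 x 4 numeric matrix, rows ACL/SYN/A&S/LIT/NA, rows sum to 1.
#' @export
default_effect_mixture <- function() {
  bg  <- c(0.9916, 0.0075, 0.0008, 1e-04)
  enr <- c(0.916, 0.075, 0.008, 0.001)
  m <- rbind(ACL = enr, SYN = enr, `A&S` = enr, LIT = enr, `NA` = bg)
  colnames(m) <- paste0("comp", 0:3)
  m
}

prior_class_levels <- function() c("ACL", "SYN", "A&S", "LIT", "NA")

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples >= 2, cfg$n_snps >= cfg$n_chroms, cfg$n_chroms >= 1,
            cfg$n_founders >= 1, cfg$block_len_kb > 0,
            cfg$recomb_between_blocks >= 0, cfg$recomb_between_blocks <= 1)
  if (!(cfg$h2 >= 0 && cfg$h2 < 1))
    stop("h2 must lie in [0, 1)")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  em <- cfg$effect_mixture
  if (!is.matrix(em) || ncol(em) != 4 ||
      !setequal(rownames(em), prior_class_levels()))
    stop("effect_mixture must be a 5 x 4 matrix with rows ",
         paste(prior_class_levels(), collapse = ", "))
  if (any(abs(rowSums(em) - 1) > 1e-12))
    stop("each effect_mixture row must sum to 1")
  if (any(em < 0)) stop("effect_mixture probabilities must be non-negative")
  if (sum(cfg$class_fractions) >= 1)
    stop("class_fractions must sum to less than 1")
  if (!is.null(cfg$sweep)) {
    need <- c("chrom", "pos_bp", "case_freq", "span_kb")
    if (!all(need %in% names(cfg$sweep)))
      stop("sweep must provide ", paste(need, collapse = ", "))
    if (cfg$sweep$case_freq < 0 || cfg$sweep$case_freq > 1)
      stop("sweep case_freq must lie in [0, 1]")
  }
  invisible(cfg)
}
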