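#' Construct a phased haplotype panel
#'
#' A haplotype panel holds a binary matrix of phased haplotypes (two rows per
#' diploid sample, consecutive) together with variant metadata including the
#' ancestral-allele orientation used by the selection-scan functions.
#'
#' @param hap Integer matrix (2n x m) of 0/1 alternate-allele indicators;
#'   rows are haplotypes, columns are variants.
#' @param variants Data frame with columns `id`, `chrom`, `bp`, `ref`, `alt`,
#'   `ancestral` (one of "ref"/"alt"), positions strictly increasing within
#'   chromosome.
#' @param samples Character vector of sample ids (length n).
#' @return Object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(hap, variants, samples) {
  stopifnot(is.matrix(hap), nrow(hap) == 2L * length(samples),
            ncol(hap) == nrow(variants))
  stopifnot(all(c("id", "chrom", "bp", "ref", "alt", "ancestral") %in%
                  names(variants)))
  if (any(!hap %in% c(0L, 1L))) stop("haplotype matrix must be 0/1")
  for (ch in unique(variants$chrom)) {
    bp <- variants$bp[variants$chrom == ch]
    if (any(diff(bp) <= 0))
      stop("variant positions must be strictly increasing within chromosome")
  }
  rownames(hap) <- paste0(rep(samples, each = 2L), "_", 1:2)
  colnames(hap) <- variants$id
  structure(list(hap = hap, variants = variants, samples = samples),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$samples), "samples (",
      nrow(x$hap), "haplotypes ) x", nrow(x$variants), "variants on",
      length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Construct a genotype matrix
#'
#' Diploid dosages (0/1/2 copies of the alternate allele, `NA` for missing
#' calls) with variant metadata, the central container consumed by QC, GRM
#' and association functions.
#'
#' @param dosage Integer matrix (n samples x m variants), values in
#'   0/1/2/NA.
#' @param variants Data frame with columns `id`, `chrom`, `bp`, `ref`,
#'   `alt`.
#' @param samples Character vector of sample ids.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  stopifnot(is.matrix(dosage), nrow(dosage) == length(samples),
            ncol(dosage) == nrow(variants))
  stopifnot(all(c("id", "chrom", "bp", "ref", "alt") %in% names(variants)))
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  for (ch in unique(variants$chrom)) {
    bp <- variants$bp[variants$chrom == ch]
    if (any(diff(bp) <= 0))
      stop("variant positions must be strictly increasing within chromosome")
  }
  rownames(dosage) <- samples
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosage))
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants;", nmiss, "missing call(s)\n")
  invisible(x)
}

#' Collapse a haplotype panel to diploid dosages
#'
#' @param panel A [haplotype_panel()].
#' @return A [genotype_matrix()] of alternate-allele dosages (haplotype
#'   sums), no missing values.
#' @export
panel_to_genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- length(panel$samples)
  dos <- panel$hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    panel$hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(dos, panel$variants, panel$samples)
}

#' Split a haplotype panel by sample ids
#'
#' @param panel A [haplotype_panel()].
#' @param ids Sample ids to keep.
#' @return A [haplotype_panel()] restricted to `ids`.
#' @export
subset_panel <- function(panel, ids) {
  stopifnot(inherits(panel, "haplotype_panel"))
  keep <- match(ids, panel$samples)
  if (anyNA(keep)) stop("unknown sample id(s): ",
                        paste(ids[is.na(keep)], collapse = ", "))
  rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  haplotype_panel(panel$hap[rows, , drop = FALSE], panel$variants, ids)
}
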