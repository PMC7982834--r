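#' Extended haplotype homozygosity curve around a core SNP
#'
#' EHH at distance x from the core is the probability that two distinct
#' haplotypes carrying the chosen core allele are identical over the whole
#' interval between the core and x: `sum_h C(n_h,2) / C(n_c,2)` over the
#' distinct extended haplotypes h among the n_c carriers. The curve starts
#' at 1 at the core and is non-increasing outward; extension stops at the
#' chromosome end or when EHH falls below `floor` (that value is kept so
#' threshold crossings are visible).
#'
#' @param panel A [haplotype_panel()].
#' @param core Variant id or column index of the core SNP.
#' @param allele "ancestral" or "derived" (orientation from the panel's
#'   variant metadata).
#' @param floor Stop extending once EHH drops below this value (0 extends
#'   to the chromosome ends).
#' @return Object of class `ehh_curve`: data frame with `id`, `pos`,
#'   `offset` (bp, signed) and `ehh`; `NULL`-like with attribute
#'   `defined = FALSE` when fewer than 2 carriers exist.
#' @export
ehh <- function(panel, core, allele = c("ancestral", "derived"),
                floor = 0) {
  stopifnot(inherits(panel, "haplotype_panel"))
  allele <- match.arg(allele)
  j <- if (is.character(core)) match(core, panel$variants$id) else core
  if (is.na(j) || j < 1 || j > ncol(panel$hap)) stop("unknown core SNP")
  ch <- panel$variants$chrom[j]
  sites <- which(panel$variants$chrom == ch)
  H <- panel$hap[, sites, drop = FALSE]
  core_local <- match(j, sites)
  anc_dose <- ifelse(panel$variants$ancestral[j] == "ref", 0L, 1L)
  want <- if (allele == "ancestral") anc_dose else 1L - anc_dose
  carriers <- which(H[, core_local] == want)
  res <- .ehh_curve_cpp(H, core_local - 1L, carriers - 1L, floor)
  if (!res$defined) {
    out <- data.frame(id = character(), pos = integer(),
                      offset = integer(), ehh = numeric())
    attr(out, "defined") <- FALSE
    class(out) <- c("ehh_curve", class(out))
    return(out)
  }
  idx <- sites[res$site + 1L]
  out <- data.frame(id = panel$variants$id[idx],
                    pos = panel$variants$bp[idx],
                    offset = panel$variants$bp[idx] - panel$variants$bp[j],
                    ehh = res$ehh, stringsAsFactors = FALSE)
  attr(out, "defined") <- TRUE
  attr(out, "core_id") <- panel$variants$id[j]
  attr(out, "allele") <- allele
  class(out) <- c("ehh_curve", class(out))
  out
}

#' Integrate an EHH curve over physical distance
#'
#' Trapezoidal integral of the curve over both directions, restricted to
#' the region where EHH stays at or above `floor`; the result is in
#' bp x EHH units (iES). A curve with no flanking markers integrates to 0.
#'
#' @param curve An `ehh_curve` from [ehh()].
#' @param floor Integration floor (default 0.05).
#' @return The integrated EHH (numeric scalar), `NA` if the curve is
#'   undefined.
#' @export
integrate_ehh <- function(curve, floor = 0.05) {
  if (!isTRUE(attr(curve, "defined"))) return(NA_real_)
  total <- 0
  for (side in c(-1, 1)) {
    seg <- curve[sign(curve$offset) %in% c(0, side), , drop = FALSE]
    seg <- seg[order(abs(seg$offset)), , drop = FALSE]
    if (nrow(seg) < 2) next
    keep <- cumsum(seg$ehh < floor) == 0
    seg <- seg[keep, , drop = FALSE]
    if (nrow(seg) < 2) next
    total <- total + sum(diff(abs(seg$offset)) *
                           (head(seg$ehh, -1) + seg$ehh[-1]) / 2)
  }
  total
}

#' Cross-population XP-EHH scan
#'
#' For every SNP, the site-level integrated EHH (iES) is computed in each
#' population by combining the ancestral- and derived-allele EHH curves
#' with pair-count weights and integrating where the combined curve stays
#' at or above `floor`. The raw statistic `ln(iES_cases / iES_controls)`
#' is standardized genome-wide to mean 0 and SD 1, and the two-sided
#' standard-normal tail of the standardized value gives the p-value.
#'
#' @param cases,controls [haplotype_panel()] objects on the same variant
#'   grid.
#' @param floor EHH integration floor (default 0.05).
#' @param candidate,genomewide Significance thresholds on the p-value
#'   (boundary inclusive).
#' @return Data frame of class `xpehh_result`: id, chrom, bp, iES_cases,
#'   iES_controls, raw ln-ratio, standardized `xpehh`, `neglog10p`, tier
#'   ("none"/"candidate"/"genomewide").
#' @export
xpehh_scan <- function(cases, controls, floor = 0.05,
                       candidate = 1e-5, genomewide = 1e-8) {
  stopifnot(inherits(cases, "haplotype_panel"),
            inherits(controls, "haplotype_panel"))
  if (!identical(cases$variants$id, controls$variants$id))
    stop("case and control panels must share the same variant grid")
  v <- cases$variants
  ies_a <- ies_b <- numeric(nrow(v))
  for (ch in unique(v$chrom)) {
    sites <- which(v$chrom == ch)
    pos <- as.numeric(v$bp[sites])
    ies_a[sites] <- .ies_scan_cpp(cases$hap[, sites, drop = FALSE], pos,
                                  floor)
    ies_b[sites] <- .ies_scan_cpp(controls$hap[, sites, drop = FALSE], pos,
                                  floor)
  }
  raw <- rep(NA_real_, nrow(v))
  ok <- !is.na(ies_a) & !is.na(ies_b) & ies_a > 0 & ies_b > 0
  if (any(!ok))
    message(sum(!ok), " site(s) with undefined or zero iES skipped")
  raw[ok] <- log(ies_a[ok] / ies_b[ok])
  z <- rep(NA_real_, nrow(v))
  z[ok] <- (raw[ok] - mean(raw[ok])) / sd(raw[ok])
  nlp <- rep(NA_real_, nrow(v))
  nlp[ok] <- neglog10_p_two_sided(z[ok])
  out <- data.frame(id = v$id, chrom = v$chrom, bp = v$bp,
                    iES_cases = ies_a, iES_controls = ies_b, raw = raw,
                    xpehh = z, neglog10p = nlp, stringsAsFactors = FALSE)
  out <- classify_hits(out, candidate = candidate, genomewide = genomewide,
                       sort = FALSE)
  class(out) <- c("xpehh_result", class(out))
  out
}

#' Minus log10 of the two-sided Gaussian tail probability
#'
#' Computed on the log scale (`pnorm(..., log.p = TRUE)`), so there is no
#' underflow for |z| up to several tens.
#'
#' @param z Standardized statistic(s).
#' @return `-log10(2 * P(Z > |z|))`, vectorized.
#' @export
neglog10_p_two_sided <- function(z) {
  -(log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)) / log(10)
}

#' Tier selection-scan results by significance
#'
#' Candidate hits have p <= `candidate`, genome-wide hits p <=
#' `genomewide` (both boundaries inclusive).
#'
#' @param results Data frame with a `neglog10p` column.
#' @param candidate,genomewide p-value thresholds.
#' @param sort Sort by `neglog10p` descending (default).
#' @return `results` with a `tier` column.
#' @export
classify_hits <- function(results, candidate = 1e-5, genomewide = 1e-8,
                          sort = TRUE) {
  nlp <- results$neglog10p
  tier <- rep("none", length(nlp))
  tier[!is.na(nlp) & nlp >= -log10(candidate)] <- "candidate"
  tier[!is.na(nlp) & nlp >= -log10(genomewide)] <- "genomewide"
  results$tier <- tier
  if (sort) results <- results[order(-results$neglog10p), , drop = FALSE]
  results
}

#' Extent of the extended haplotype around a core SNP
#'
#' The span is the outermost marker position in each direction at which
#' the allele-specific EHH is still at or above `threshold` (the same
#' floor used for integration by default).
#'
#' @param panel A [haplotype_panel()].
#' @param core Variant id or index.
#' @param allele "ancestral" or "derived".
#' @param threshold EHH threshold defining the span edges.
#' @return Named numeric `c(start, end)` in bp (containing the core), or
#'   `c(NA, NA)` if the curve is undefined.
#' @export
calc_haplen <- function(panel, core, allele = c("ancestral", "derived"),
                        threshold = 0.05) {
  allele <- match.arg(allele)
  curve <- ehh(panel, core, allele, floor = threshold)
  if (!isTRUE(attr(curve, "defined")) || nrow(curve) == 0)
    return(c(start = NA_real_, end = NA_real_))
  # extension already stops at the first sub-threshold marker per side and
  # EHH is monotone outward, so the span is the range of markers above it
  ok <- curve$ehh >= threshold
  c(start = min(curve$pos[ok]), end = max(curve$pos[ok]))
}
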