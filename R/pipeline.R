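#' Per-allele haplotype spans for selection-scan hits
#'
#' For each hit, [calc_haplen()] is evaluated for the ancestral and
#' derived allele in both populations.
#'
#' @param cases,controls [haplotype_panel()] objects.
#' @param hits Character vector of core variant ids.
#' @param threshold EHH threshold defining span edges.
#' @return Data frame: id, population, allele, start, end.
#' @export
haplotype_spans <- function(cases, controls, hits, threshold = 0.05) {
  rows <- list()
  for (id in hits)
    for (popname in c("cases", "controls"))
      for (al in c("ancestral", "derived")) {
        pan <- if (popname == "cases") cases else controls
        sp <- calc_haplen(pan, id, al, threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, population = popname, allele = al,
          start = sp[["start"]], end = sp[["end"]],
          stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}

#' Overlap of selection signatures with top GWAS effects
#'
#' For each selection hit the union of its case/control, ancestral/derived
#' haplotype spans is taken; the hit is flagged "Yes" when any of the top
#' `top_n` GWAS SNPs (ranked by |posterior mean effect|) on the same
#' chromosome falls inside that union.
#'
#' @param gwas A `posterior_summary` (or an [effects_table()] data frame).
#' @param sel An `xpehh_result` (only rows with tier != "none" are used).
#' @param spans Output of [haplotype_spans()] for the hit ids.
#' @param top_n Number of top GWAS SNPs considered (default 50).
#' @return Data frame: hit id, chrom, bp, xpehh, neglog10p, tier, span
#'   union start/end, gwas_overlap ("Yes"/"No").
#' @export
overlap_report <- function(gwas, sel, spans, top_n = 50) {
  eff <- if (inherits(gwas, "posterior_summary")) effects_table(gwas) else
    gwas
  top <- eff[seq_len(min(top_n, nrow(eff))), , drop = FALSE]
  hits <- sel[sel$tier != "none", , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(id = character(), chrom = character(), bp = integer(),
                      xpehh = numeric(), neglog10p = numeric(),
                      tier = character(), span_start = numeric(),
                      span_end = numeric(), gwas_overlap = character(),
                      stringsAsFactors = FALSE))
  res <- lapply(seq_len(nrow(hits)), function(i) {
    sp <- spans[spans$id == hits$id[i] & !is.na(spans$start), , drop = FALSE]
    lo <- if (nrow(sp)) min(sp$start) else hits$bp[i]
    hi <- if (nrow(sp)) max(sp$end) else hits$bp[i]
    inside <- top$chrom == hits$chrom[i] & top$bp >= lo & top$bp <= hi
    data.frame(id = hits$id[i], chrom = hits$chrom[i], bp = hits$bp[i],
               xpehh = hits$xpehh[i], neglog10p = hits$neglog10p[i],
               tier = hits$tier[i], span_start = lo, span_end = hi,
               gwas_overlap = if (any(inside)) "Yes" else "No",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(-out$neglog10p), , drop = FALSE]
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate (or reuse) a cohort, apply marker QC, compute the GRM and its
#' top principal components, assign biological prior classes, run the
#' replicate-averaged mixture-model association analysis, scan for
#' cross-population selection signatures between case and control
#' haplotypes, and report the overlap between the two analyses.
#'
#' @param config A [sim_config()] (its `seed` drives every stage).
#' @param cohort Optional pre-simulated cohort (from [simulate_cohort()]);
#'   by default one is simulated from `config`.
#' @param n_iter,burn_in,n_chains MCMC schedule (scaled down from the
#'   production 200k/100k/5 defaults for interactive use).
#' @param n_pcs Number of GRM principal components used as fixed effects.
#' @param flank_bp Gene flank for prior-class assignment.
#' @param use_priors Run with biological classes (BayesRC); `FALSE` uses a
#'   single class (BayesR).
#' @param run_selscan Run the XP-EHH scan stage.
#' @param top_n Top-effect count used in reports.
#' @param out_dir Optional directory; when given, cohort files and result
#'   tables are written there and digests recorded in the manifest.
#' @return List: `cohort`, `qc`, `pcs`, `priors`, `gwas`, `selscan`,
#'   `spans`, `overlap`, `top_effects`, `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL,
                         n_iter = 5000, burn_in = 2500, n_chains = 2,
                         n_pcs = 5, flank_bp = 25000, use_priors = TRUE,
                         run_selscan = TRUE, top_n = 50, out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  qc <- apply_qc(cohort$genotypes)
  grm <- compute_grm(qc$genotypes)
  pcs <- top_pcs(grm, k = n_pcs)

  priors <- NULL
  if (use_priors) {
    classes <- build_gene_classes(cohort$gene_lists$ACL,
                                  cohort$gene_lists$SYN,
                                  cohort$gene_lists$LIT)
    priors <- assign_snps(qc$genotypes, cohort$annotation, classes,
                          flank_bp = flank_bp)
  }
  data <- build_model_data(qc$genotypes, cohort$covariates, pcs = pcs,
                           class_assignment = priors)
  seed <- config$seed %||% 1L
  gwas <- run_replicates(data, mixture_spec(), n_chains = n_chains,
                         n_iter = n_iter, burn_in = burn_in, seed = seed)
  top_eff <- effects_table(gwas)[seq_len(min(top_n, length(gwas$effect))), ]

  sel <- spans <- overlap <- NULL
  if (run_selscan) {
    case_ids <- cohort$covariates$sample[cohort$covariates$case == 1L]
    ctrl_ids <- setdiff(cohort$covariates$sample, case_ids)
    cases <- subset_panel(cohort$panel, case_ids)
    controls <- subset_panel(cohort$panel, ctrl_ids)
    sel <- xpehh_scan(cases, controls)
    hit_ids <- sel$id[sel$tier != "none"]
    spans <- if (length(hit_ids))
      haplotype_spans(cases, controls, hit_ids) else
        data.frame(id = character(), population = character(),
                   allele = character(), start = numeric(),
                   end = numeric(), stringsAsFactors = FALSE)
    overlap <- overlap_report(gwas, sel, spans, top_n = top_n)
  }

  manifest <- list(
    config = config, seed = seed,
    stage_counts = c(
      snps_in = ncol(cohort$genotypes$dosage),
      snps_post_qc = ncol(qc$genotypes$dosage),
      samples = length(cohort$genotypes$samples),
      cases = sum(cohort$covariates$case),
      selscan_hits = if (is.null(sel)) NA_integer_ else
        sum(sel$tier != "none")))

  if (!is.null(out_dir)) {
    paths <- write_cohort(out_dir, cohort)
    write.table(top_eff, file.path(out_dir, "top_effects.tsv"),
                quote = FALSE, sep = "\t", row.names = FALSE)
    if (!is.null(sel))
      write.table(sel, file.path(out_dir, "xpehh.tsv"), quote = FALSE,
                  sep = "\t", row.names = FALSE)
    if (!is.null(overlap))
      write.table(overlap, file.path(out_dir, "overlap.tsv"), quote = FALSE,
                  sep = "\t", row.names = FALSE)
    files <- c(paths, file.path(out_dir, "top_effects.tsv"))
    manifest$digests <- tools::md5sum(files[file.exists(files)])
  }

  list(cohort = cohort, qc = qc, pcs = pcs, priors = priors, gwas = gwas,
       selscan = sel, spans = spans, overlap = overlap,
       top_effects = top_eff, manifest = manifest)
}
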