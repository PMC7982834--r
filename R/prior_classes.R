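#' Build the gene-to-class map from DEG and literature gene lists
#'
#' Genes differentially expressed in both tissues become class "A&S", genes
#' in only one list become "ACL" or "SYN", and literature candidate genes
#' become "LIT". A gene present in both a DEG list and the literature list
#' follows the DEG branch (precedence A&S > ACL > SYN > LIT): replicated
#' expression evidence carries less uncertainty than a literature citation.
#' Symbols are matched case-insensitively.
#'
#' @param deg_acl,deg_syn,lit Character vectors of gene symbols.
#' @return Named character vector mapping upper-cased gene symbol to class.
#' @export
build_gene_classes <- function(deg_acl = character(),
                               deg_syn = character(),
                               lit = character()) {
  a <- unique(toupper(trimws(deg_acl)))
  s <- unique(toupper(trimws(deg_syn)))
  l <- unique(toupper(trimws(lit)))
  a <- a[nzchar(a)]; s <- s[nzchar(s)]; l <- l[nzchar(l)]
  out <- c(setNames(rep("A&S", length(intersect(a, s))), intersect(a, s)),
           setNames(rep("ACL", length(setdiff(a, s))), setdiff(a, s)),
           setNames(rep("SYN", length(setdiff(s, a))), setdiff(s, a)))
  l_only <- setdiff(l, names(out))
  out <- c(out, setNames(rep("LIT", length(l_only)), l_only))
  if (is.null(names(out))) names(out) <- character(0)
  out
}

class_precedence <- function() c("A&S" = 1, ACL = 2, SYN = 3, LIT = 4)

#' Assign every SNP to one biological prior class
#'
#' A SNP takes the class of any classed gene whose body, widened by
#' `flank_bp` on both sides (boundaries inclusive), contains it; SNPs
#' covered by no classed gene are "NA". When genes of different classes
#' cover one SNP, precedence is A&S > ACL > SYN > LIT; ties within a class
#' go to the nearest gene.
#'
#' @param g A [genotype_matrix()] (or its `variants` data frame).
#' @param annotation Gene intervals: data frame with `gene`, `chrom`,
#'   `start`, `end` in 1-based inclusive coordinates.
#' @param classes Named gene-to-class map from [build_gene_classes()].
#' @param flank_bp Flank width in bp (default 25 kb).
#' @return List of class `prior_class_assignment`: `assignment` (data frame
#'   snp id, chrom, bp, class, gene, distance) and `counts` (named vector
#'   over ACL/SYN/A&S/LIT/NA).
#' @export
assign_snps <- function(g, annotation, classes, flank_bp = 25000) {
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  variants <- if (inherits(g, "genotype_matrix")) g$variants else g
  ann <- annotation
  ann$class <- unname(classes[toupper(ann$gene)])
  unmatched <- is.na(ann$class)
  if (any(unmatched) && any(!is.na(classes)))
    message(sum(unmatched), " annotated gene(s) not present in any class list")
  ann <- ann[!unmatched, , drop = FALSE]

  m <- nrow(variants)
  cls <- rep("NA", m); gene <- rep(NA_character_, m)
  dist <- rep(NA_integer_, m)
  prec <- class_precedence()
  best_prec <- rep(Inf, m); best_dist <- rep(Inf, m)
  for (i in seq_len(nrow(ann))) {
    hit <- which(variants$chrom == ann$chrom[i] &
                   variants$bp >= ann$start[i] - flank_bp &
                   variants$bp <= ann$end[i] + flank_bp)
    if (!length(hit)) next
    d <- pmax(0L, pmax(ann$start[i] - variants$bp[hit],
                       variants$bp[hit] - ann$end[i]))
    pr <- prec[[ann$class[i]]]
    better <- pr < best_prec[hit] |
      (pr == best_prec[hit] & d < best_dist[hit])
    hb <- hit[better]
    cls[hb] <- ann$class[i]; gene[hb] <- ann$gene[i]
    dist[hb] <- d[better]
    best_prec[hb] <- pr; best_dist[hb] <- d[better]
  }
  assignment <- data.frame(id = variants$id, chrom = variants$chrom,
                           bp = variants$bp, class = cls, gene = gene,
                           distance = dist, stringsAsFactors = FALSE)
  counts <- table(factor(cls, levels = prior_class_levels()))
  structure(list(assignment = assignment,
                 counts = setNames(as.integer(counts), names(counts))),
            class = "prior_class_assignment")
}

#' @export
print.prior_class_assignment <- function(x, ...) {
  cat("SNPs assigned to biological prior classes:\n")
  print(x$counts)
  invisible(x)
}

#' Rank SNP effects and assign them to genes
#'
#' Orders SNPs by the absolute value of the (averaged) posterior effect —
#' ties broken by chromosome then position — and reports, for the top `n`,
#' the nearest gene whose boundary lies within `flank_bp`, with distance 0
#' for SNPs inside the gene body.
#'
#' @param effects Data frame with columns `id`, `chrom`, `bp`, `effect`
#'   (and optionally `class`).
#' @param annotation Gene intervals as in [assign_snps()] (need not be
#'   classed; all genes are eligible).
#' @param flank_bp Maximum distance for gene assignment.
#' @param n Number of top effects to report.
#' @return Data frame: id, chrom, bp, class (if supplied), effect, gene,
#'   distance — ordered by |effect| descending.
#' @export
effects_to_genes <- function(effects, annotation, flank_bp = 25000, n = 50) {
  ord <- order(-abs(effects$effect), effects$chrom, effects$bp)
  top <- effects[ord[seq_len(min(n, nrow(effects)))], , drop = FALSE]
  gene <- rep(NA_character_, nrow(top))
  dist <- rep(NA_integer_, nrow(top))
  for (i in seq_len(nrow(top))) {
    cand <- which(annotation$chrom == top$chrom[i] &
                    top$bp[i] >= annotation$start - flank_bp &
                    top$bp[i] <= annotation$end + flank_bp)
    if (!length(cand)) next
    d <- pmax(0L, pmax(annotation$start[cand] - top$bp[i],
                       top$bp[i] - annotation$end[cand]))
    j <- cand[which.min(d)]
    gene[i] <- annotation$gene[j]
    dist[i] <- min(d)
  }
  top$gene <- gene
  top$distance <- dist
  rownames(top) <- NULL
  top
}
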