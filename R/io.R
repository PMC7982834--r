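#' Read genotypes from VCF or PLINK text files
#'
#' VCF parsing goes through \pkg{vcfR}; dosage is the count of alternate
#' alleles, phased and unphased separators are treated alike, and `.`
#' anywhere in a call yields a missing dosage. Half calls and
#' non-biallelic records are dropped with a message giving the count.
#' PLINK text input expects the `.ped`/`.map` pair; because `.map` carries
#' no allele columns, the alternate allele is the minor allele (ties broken
#' alphabetically) unless `alt` supplies the orientation explicitly.
#'
#' @param path Path to a `.vcf` file or to either member of a
#'   `.ped`/`.map` pair.
#' @param format "vcf" or "plink".
#' @param alt Optional character vector of alternate alleles, one per
#'   variant, to orient PLINK dosages deterministically.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink"), alt = NULL) {
  format <- match.arg(format)
  if (format == "vcf") read_genotypes_vcf(path) else
    read_genotypes_plink(path, alt = alt)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) gt <- matrix(character(), nrow(fix), 0)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    message(sum(multi), " non-biallelic record(s) dropped")
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  half <- (a1 == ".") != (a2 == ".")
  if (any(half, na.rm = TRUE))
    message(sum(half, na.rm = TRUE), " half call(s) set to missing")
  dos <- suppressWarnings(as.integer(a1)) + suppressWarnings(as.integer(a2))
  dos <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt))
  keep <- !multi
  dos <- t(dos[keep, , drop = FALSE])
  variants <- data.frame(
    id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                paste0("chr", fix$CHROM[keep], ":", fix$POS[keep]),
                fix$ID[keep]),
    chrom = type_chrom(fix$CHROM[keep]), bp = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep], stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, colnames(gt))
}

type_chrom <- function(x) {
  x <- sub("^chr", "", x)
  if (all(grepl("^[0-9]+$", x))) as.integer(x) else x
}

read_genotypes_plink <- function(path, alt = NULL) {
  stem <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(stem, ".ped"); map_path <- paste0(stem, ".map")
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  names(map) <- c("chrom", "id", "cm", "bp")[seq_len(ncol(map))]
  lines <- readLines(ped_path)
  m <- nrow(map)
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- 6L + 2L * m
  samples <- character(length(toks))
  dos <- matrix(NA_integer_, length(toks), m)
  a_alt <- character(m)
  allele_mat <- matrix("0", 2L * length(toks), m)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) != nfield)
      stop(sprintf("malformed .ped line %d: expected %d fields, found %d",
                   i, nfield, length(tk)))
    samples[i] <- tk[2L]
    al <- tk[-(1:6)]
    allele_mat[2L * i - 1L, ] <- al[seq(1L, 2L * m, 2L)]
    allele_mat[2L * i, ]      <- al[seq(2L, 2L * m, 2L)]
  }
  ref <- character(m)
  for (j in seq_len(m)) {
    al <- allele_mat[, j]
    obs <- al[al != "0"]
    u <- sort(unique(obs))
    if (length(u) > 2L)
      stop("more than two alleles at variant ", map$id[j])
    if (is.null(alt)) {
      if (length(u) == 1L) { aj <- u[1L]; rj <- u[1L] }
      else {
        cnt <- table(factor(obs, levels = u))
        aj <- if (cnt[1L] == cnt[2L]) u[2L] else names(which.min(cnt))
        rj <- setdiff(u, aj)[1L]
      }
    } else {
      aj <- alt[j]
      rj <- if (length(setdiff(u, aj))) setdiff(u, aj)[1L] else aj
    }
    a_alt[j] <- aj; ref[j] <- rj
    h1 <- al[seq(1L, length(al), 2L)]; h2 <- al[seq(2L, length(al), 2L)]
    d <- (h1 == aj) + (h2 == aj)
    d[h1 == "0" | h2 == "0"] <- NA_integer_
    dos[, j] <- as.integer(d)
  }
  variants <- data.frame(id = map$id, chrom = type_chrom(as.character(map$chrom)),
                         bp = as.integer(map$bp), ref = ref, alt = a_alt,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, samples)
}

#' Write genotypes to VCF or PLINK text files
#'
#' @param g A [genotype_matrix()] (VCF output requires phase-free dosage
#'   only and writes unphased `0/1`-style calls).
#' @param path Output path (`.vcf`, or the `.ped`/`.map` stem for PLINK).
#' @param format "vcf" or "plink".
#' @return Invisibly, the path(s) written.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "plink")) {
  format <- match.arg(format)
  if (format == "vcf") {
    gt_str <- matrix("./.", nrow(g$dosage), ncol(g$dosage))
    gt_str[!is.na(g$dosage) & g$dosage == 0L] <- "0/0"
    gt_str[!is.na(g$dosage) & g$dosage == 1L] <- "0/1"
    gt_str[!is.na(g$dosage) & g$dosage == 2L] <- "1/1"
    write_vcf_body(path, g$variants, gt_str, g$samples, phased = FALSE)
    return(invisible(path))
  }
  stem <- sub("\\.(ped|map)$", "", path)
  map <- data.frame(g$variants$chrom, g$variants$id, 0, g$variants$bp)
  write.table(map, paste0(stem, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  n <- length(g$samples); m <- nrow(g$variants)
  al <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    d <- g$dosage[, j]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, g$variants$alt[j],
                                       g$variants$ref[j]))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, g$variants$alt[j],
                                       g$variants$ref[j]))
    al[, 2L * j - 1L] <- a1; al[, 2L * j] <- a2
  }
  ped <- cbind("FAM", g$samples, "0", "0", "0", "-9", al)
  write.table(ped, paste0(stem, ".ped"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(stem, ".ped"), paste0(stem, ".map")))
}

write_vcf_body <- function(path, variants, gt_cols, samples, phased) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  for (ch in unique(variants$chrom))
    writeLines(sprintf("##contig=<ID=%s>", ch), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  aa <- if ("ancestral" %in% names(variants))
    ifelse(variants$ancestral == "ref", variants$ref, variants$alt) else
      variants$ref
  body <- paste(variants$chrom, variants$bp, variants$id, variants$ref,
                variants$alt, ".", "PASS", paste0("AA=", aa), "GT",
                apply(gt_cols, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write a phased haplotype panel as VCF 4.2
#'
#' Genotypes use the `|` phase separator; the ancestral allele is recorded
#' in the `AA` INFO key so [read_haplotypes()] round-trips orientation.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output `.vcf` path.
#' @return Invisibly, `path`.
#' @export
write_haplotypes <- function(panel, path) {
  n <- length(panel$samples)
  h1 <- panel$hap[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- panel$hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(h1, "|", h2), n, ncol(panel$hap))
  write_vcf_body(path, panel$variants, gt, panel$samples, phased = TRUE)
}

#' Read a phased haplotype panel from VCF
#'
#' All genotypes must be phased (`|` separator) and complete; ancestral
#' orientation is taken from the `AA` INFO key when present, defaulting to
#' the reference allele.
#'
#' @param path Path to a phased `.vcf`.
#' @return A [haplotype_panel()].
#' @export
read_haplotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("\\|", gt)))
    stop("unphased genotype(s) found; haplotype input must be phased")
  m <- nrow(gt); n <- ncol(gt)
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), m, n)
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), m, n)
  hap <- matrix(0L, 2L * n, m)
  hap[seq(1L, 2L * n, 2L), ] <- t(a1)
  hap[seq(2L, 2L * n, 2L), ] <- t(a2)
  info <- fix$INFO
  aa <- sub(".*AA=([^;]+).*", "\\1", info)
  ancestral <- ifelse(grepl("AA=", info) & aa == fix$ALT, "alt", "ref")
  variants <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0("chr", fix$CHROM, ":", fix$POS), fix$ID),
    chrom = type_chrom(fix$CHROM), bp = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, ancestral = ancestral,
    stringsAsFactors = FALSE)
  haplotype_panel(hap, variants, colnames(gt))
}

#' Read a sample covariate table
#'
#' Tab-separated with a header; must contain a `sample` column.
#'
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_covariates <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"sample" %in% names(d)) stop("covariate table needs a 'sample' column")
  d
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open on disk; intervals are converted to the 1-based
#' inclusive coordinates used internally.
#'
#' @param path Path to a BED3+name file.
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("BED annotation needs chrom, start, end, name")
  data.frame(gene = d[[4L]], chrom = type_chrom(as.character(d[[1L]])),
             start = as.integer(d[[2L]]) + 1L, end = as.integer(d[[3L]]),
             stringsAsFactors = FALSE)
}

#' Write gene intervals as BED (0-based half-open)
#'
#' @param annotation Data frame with `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_bed <- function(annotation, path) {
  bed <- data.frame(annotation$chrom, annotation$start - 1L, annotation$end,
                    annotation$gene)
  write.table(bed, path, quote = FALSE, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' @param path Path to the list.
#' @return Character vector of symbols (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Write a full synthetic cohort to disk
#'
#' Produces the file set every downstream stage reads: phased VCF, PLINK
#' `.ped`/`.map` text genotypes, covariate TSV, BED gene annotation and the
#' three gene-list files.
#'
#' @param dir Output directory (created if needed).
#' @param cohort A list as returned by [simulate_cohort()].
#' @return Invisibly, a named character vector of written paths.
#' @export
write_cohort <- function(dir, cohort) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "cohort.ped"),
    map = file.path(dir, "cohort.map"),
    covariates = file.path(dir, "covariates.tsv"),
    bed = file.path(dir, "genes.bed"),
    deg_acl = file.path(dir, "deg_acl.txt"),
    deg_syn = file.path(dir, "deg_syn.txt"),
    lit = file.path(dir, "lit_genes.txt"))
  write_haplotypes(cohort$panel, paths[["vcf"]])
  write_genotypes(cohort$genotypes, paths[["ped"]], format = "plink")
  write.table(cohort$covariates, paths[["covariates"]], quote = FALSE,
              sep = "\t", row.names = FALSE)
  write_gene_bed(cohort$annotation, paths[["bed"]])
  writeLines(cohort$gene_lists$ACL, paths[["deg_acl"]])
  writeLines(cohort$gene_lists$SYN, paths[["deg_syn"]])
  writeLines(cohort$gene_lists$LIT, paths[["lit"]])
  invisible(paths)
}
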