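test_that("gene class map follows the DEG/literature precedence rules", {
  cl <- build_gene_classes(deg_acl = c("g1", "g2", "g5"),
                           deg_syn = c("g2", "g3"),
                           lit = c("g4", "g5", "g2"))
  expect_equal(unname(cl[c("G1", "G2", "G3", "G4", "G5")]),
               c("ACL", "A&S", "SYN", "LIT", "ACL"))
  expect_equal(build_gene_classes(), setNames(character(0), character(0)))
  # deterministic: same inputs, same map
  expect_identical(cl, build_gene_classes(c("g1", "g2", "g5"),
                                          c("g2", "g3"),
                                          c("g4", "g5", "g2")))
})

test_that("SNP class assignment respects the inclusive 25 kb flank", {
  v <- data.frame(id = c("a", "b", "c", "d"), chrom = 1L,
                  bp = c(74999L, 75000L, 110000L, 145001L),
                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  ann <- data.frame(gene = "g1", chrom = 1L, start = 100000L,
                    end = 120000L, stringsAsFactors = FALSE)
  cl <- c(G1 = "ACL")
  res <- assign_snps(v, ann, cl, flank_bp = 25000)
  expect_equal(res$assignment$class, c("NA", "ACL", "ACL", "NA"))
  expect_equal(res$assignment$distance, c(NA, 25000L, 0L, NA))
  expect_error(assign_snps(v, ann, cl, flank_bp = -1), ">= 0")
})

test_that("overlap precedence and counts match a planted fixture", {
  v <- data.frame(id = paste0("s", 1:6), chrom = 1L,
                  bp = c(1000L, 2000L, 3000L, 4000L, 5000L, 9000L),
                  ref = "A", alt = "C", stringsAsFactors = FALSE)
  ann <- data.frame(gene = c("gl", "ga", "gb"), chrom = 1L,
                    start = c(500L, 1500L, 4800L),
                    end = c(3500L, 2500L, 5200L), stringsAsFactors = FALSE)
  cl <- c(GL = "LIT", GA = "A&S", GB = "SYN")
  res <- assign_snps(v, ann, cl, flank_bp = 0)
  # A&S outranks LIT wherever both cover a SNP
  expect_equal(res$assignment$class,
               c("LIT", "A&S", "LIT", "NA", "SYN", "NA"))
  expect_equal(unname(res$counts),
               c(0L, 1L, 1L, 2L, 2L))  # ACL SYN A&S LIT NA
  # partition: every SNP has exactly one class and counts sum to total
  expect_equal(sum(res$counts), nrow(v))
})

test_that("widening the flank never demotes a SNP to NA", {
  cfg <- sim_config(n_samples = 20, n_snps = 800, n_chroms = 2, seed = 14)
  co <- simulate_cohort(cfg)
  cl <- build_gene_classes(co$gene_lists$ACL, co$gene_lists$SYN,
                           co$gene_lists$LIT)
  a1 <- assign_snps(co$genotypes, co$annotation, cl, flank_bp = 5000)
  a2 <- assign_snps(co$genotypes, co$annotation, cl, flank_bp = 50000)
  was_classed <- a1$assignment$class != "NA"
  expect_true(all(a2$assignment$class[was_classed] != "NA"))
})

test_that("effect ranking orders by |effect| and reports gene distances", {
  eff <- data.frame(id = c("x", "y", "z"), chrom = c(1L, 1L, 1L),
                    bp = c(53865770L, 100L, 500L),
                    effect = c(0.006, -0.004, 0.005),
                    stringsAsFactors = FALSE)
  ann <- data.frame(gene = "FN1", chrom = 1L, start = 53874914L,
                    end = 53999999L, stringsAsFactors = FALSE)
  top <- effects_to_genes(eff, ann, flank_bp = 25000, n = 3)
  expect_equal(top$effect, c(0.006, 0.005, -0.004))
  # 9,144 bp from the gene edge
  expect_equal(top$distance[top$id == "x"], 9144L)
  # a SNP inside the gene body reports distance 0
  eff2 <- data.frame(id = "w", chrom = 1L, bp = 53900000L, effect = 0.01)
  expect_equal(effects_to_genes(eff2, ann)$distance, 0L)
})

test_that("empty gene lists leave all SNPs unassigned (single-class model)", {
  cfg <- sim_config(n_samples = 20, n_snps = 300, n_chroms = 1, seed = 2)
  co <- simulate_cohort(cfg)
  res <- assign_snps(co$genotypes, co$annotation, build_gene_classes())
  expect_true(all(res$assignment$class == "NA"))
  md <- build_model_data(co$genotypes, co$covariates,
                         class_assignment = res)
  expect_equal(length(md$class_levels), 1L)
})
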