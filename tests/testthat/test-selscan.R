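test_that("EHH is 1 for identical carriers and splits by the homozygosity formula", {
  # 6 haplotypes; the 4 carriers of allele 1 at the core stay identical
  # for two markers then split into two pairs
  H <- rbind(c(0, 0, 1, 1, 1), c(0, 0, 1, 1, 1),
             c(0, 1, 1, 1, 0), c(0, 1, 1, 1, 0),
             c(1, 0, 0, 0, 0), c(1, 1, 0, 1, 1))
  p <- make_panel(H)
  curve <- ehh(p, core = 3, allele = "derived", floor = 0)
  expect_equal(curve$ehh[curve$offset == 0], 1)
  expect_equal(curve$ehh[curve$offset == 1000], 1)    # all carriers share
  expect_equal(curve$ehh[curve$offset == 2000], 1 / 3)  # two pairs: 2/C(4,2)
  expect_equal(curve$ehh[curve$offset == -1000], 1 / 3)
  # fewer than 2 carriers: undefined, not zero
  H1 <- H; H1[, 3] <- c(1, 0, 0, 0, 0, 0)
  und <- ehh(make_panel(H1), core = 3, allele = "derived")
  expect_false(attr(und, "defined"))
})

test_that("EHH equals the O(n^2) pairwise oracle on random panels", {
  set.seed(77)
  for (rep in 1:5) {
    nh <- sample(c(12, 30, 50), 1)
    m <- 40
    H <- matrix(rbinom(nh * m, 1, runif(m, 0.2, 0.8)), nh, m, byrow = TRUE)
    core <- sample(5:(m - 5), 1)
    for (al in c(0L, 1L)) {
      carriers <- which(H[, core] == al)
      if (length(carriers) < 2) next
      p <- make_panel(H)
      curve <- ehh(p, core, if (al == 0L) "ancestral" else "derived",
                   floor = 0)
      for (row in seq_len(nrow(curve))) {
        site <- match(curve$id[row], p$variants$id)
        expect_equal(curve$ehh[row],
                     ehh_pairwise_oracle(H, core, carriers, site))
      }
      # monotone non-increasing away from the core in both directions
      for (side in c(-1, 1)) {
        seg <- curve[sign(curve$offset) %in% c(0, side), ]
        seg <- seg[order(abs(seg$offset)), ]
        expect_true(all(diff(seg$ehh) <= 1e-12))
      }
    }
  }
})

test_that("EHH integration handles rectangles, points, and matches quadrature", {
  # constant EHH = 1 over +/- 10 markers spaced 1 kb -> iES = 2L
  H <- matrix(rep(c(0, 1), each = 10), 20, 21)
  p <- make_panel(H)
  curve <- ehh(p, core = 11, allele = "derived", floor = 0)
  expect_equal(integrate_ehh(curve), 2 * 10000)
  # single-point curve integrates to zero
  single <- curve[curve$offset == 0, ]
  attr(single, "defined") <- TRUE
  expect_equal(integrate_ehh(single), 0)
  # independent quadrature of the piecewise-linear curve
  set.seed(3)
  Hr <- matrix(rbinom(40 * 61, 1, 0.5), 40, 61)
  Hr[, 31] <- rep(c(0, 1), each = 20)
  pr <- make_panel(Hr)
  cv <- ehh(pr, core = 31, allele = "derived", floor = 0)
  # sum of per-side adaptive quadratures equals the trapezoidal iES
  quad_total <- 0
  for (side in c(-1, 1)) {
    seg <- cv[sign(cv$offset) %in% c(0, side), ]
    seg <- seg[order(abs(seg$offset)), ]
    seg <- seg[cumsum(seg$ehh < 0.05) == 0, ]
    if (nrow(seg) < 2) next
    seg <- seg[order(seg$pos), ]
    f <- approxfun(seg$pos, seg$ehh)
    quad_total <- quad_total +
      integrate(f, min(seg$pos), max(seg$pos), subdivisions = 2000)$value
  }
  expect_equal(integrate_ehh(cv), quad_total, tolerance = 0.01)
})

test_that("XP-EHH is antisymmetric and standardized genome-wide", {
  cfg <- sim_config(n_samples = 60, n_snps = 500, n_chroms = 1, seed = 10)
  pan <- simulate_haplotypes(cfg)
  a <- subset_panel(pan, pan$samples[1:30])
  b <- subset_panel(pan, pan$samples[31:60])
  # identical panels: raw ln-ratio is exactly zero everywhere
  same <- suppressMessages(xpehh_scan(a, a))
  expect_true(all(same$raw[!is.na(same$raw)] == 0))
  ab <- suppressMessages(xpehh_scan(a, b))
  ba <- suppressMessages(xpehh_scan(b, a))
  ok <- !is.na(ab$raw)
  expect_equal(ab$raw[ok], -ba$raw[ok])
  expect_lt(abs(mean(ab$xpehh, na.rm = TRUE)), 1e-6)
  expect_equal(sd(ab$xpehh, na.rm = TRUE), 1, tolerance = 1e-6)
})

test_that("two-sided log-scale p-values are exact and underflow-safe", {
  expect_equal(neglog10_p_two_sided(0), 0)
  expect_equal(neglog10_p_two_sided(1.959964), 1.30103, tolerance = 1e-5)
  expect_equal(neglog10_p_two_sided(-1.959964),
               neglog10_p_two_sided(1.959964))
  expect_true(is.finite(neglog10_p_two_sided(40)))
  expect_gt(neglog10_p_two_sided(40), 300)
})

test_that("hit tiers respect inclusive thresholds", {
  res <- data.frame(neglog10p = c(5.0, 4.999, 8.541, 9.2, NA))
  out <- classify_hits(res, sort = FALSE)
  expect_equal(out$tier,
               c("candidate", "none", "genomewide", "genomewide", "none"))
})

test_that("haplotype spans track the EHH threshold crossing", {
  # EHH = 1 across the window for the derived carriers
  H <- matrix(rep(c(0, 1), each = 8), 16, 11)
  p <- make_panel(H)
  sp <- calc_haplen(p, core = 6, allele = "derived", threshold = 0.05)
  expect_equal(unname(sp), c(1000, 11000))
  # engineered crossing: carriers split completely at known markers
  H2 <- matrix(0L, 8, 7)
  H2[, 4] <- 1L                      # all 8 carry the derived core
  H2[, 5] <- c(0, 1, 0, 1, 0, 1, 0, 1)   # split into groups of 4: EHH 3/7
  H2[, 6] <- c(0, 0, 1, 1, 0, 0, 1, 1)   # groups of 2: EHH 1/7 -> above 0.1
  H2[, 7] <- c(0, 1, 0, 1, 1, 0, 1, 0)   # singletons: EHH 0 < 0.1
  H2[, 3] <- c(0, 1, 0, 1, 0, 1, 0, 1)
  H2[, 2] <- 1:0                     # recycled split
  p2 <- make_panel(H2)
  sp2 <- calc_haplen(p2, core = 4, allele = "derived", threshold = 0.1)
  expect_equal(unname(sp2[2]), 6000)  # last marker with EHH >= 0.1
})
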