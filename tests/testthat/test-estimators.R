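toy_map <- function(n = 10, chrom = 1L, spacing = 1e6) {
  marker_map(data.frame(name = paste0("m", seq_len(n)), chrom = chrom,
                        pos_bp = spacing * seq_len(n)))
}

seg_df <- function(chrom, start, end, kind = "ROH") {
  data.frame(individual = "x", chrom = chrom, start_bp = start, end_bp = end,
             n_snps = 5L, kind = kind, stringsAsFactors = FALSE)
}

test_that("F_ROH and F_HRR are coverage fractions of the scope span", {
  map <- marker_map(data.frame(name = paste0("m", 1:20), chrom = rep(1:2, each = 10),
                               pos_bp = rep(1e6 * 1:10, 2)))
  # scope span per chromosome: 9e6 + 1
  empty <- seg_df(1, 1, 2)[0, ]
  expect_equal(f_roh(empty, map, "genome"), 0)
  expect_equal(f_hrr(empty, map, "genome"), 1)
  full <- seg_df(1, 1e6, 1e7)
  expect_equal(f_roh(full, map, 1), 1)
  expect_equal(f_hrr(full, map, 1), 0)
  # two disjoint 1 Mb segments on one chromosome
  two <- rbind(seg_df(1, 1e6, 2e6 - 1), seg_df(1, 5e6, 6e6 - 1))
  expect_equal(f_roh(two, map, 1), 2e6 / (9e6 + 1))
  # genome-wide value is the length-weighted combination of per-chromosome values
  expect_equal(f_roh(two, map, "genome"),
               f_roh(two, map, 1) * (9e6 + 1) / (2 * (9e6 + 1)))
  # overlapping segments are not double-counted
  ov <- rbind(seg_df(1, 1e6, 3e6), seg_df(1, 2e6, 4e6))
  expect_equal(f_roh(ov, map, 1), (3e6 + 1) / (9e6 + 1))
})

test_that("F_LH matches its closed form on the worked four-locus cases", {
  map <- toy_map(4)
  bp <- structure(list(member_ids = "b", p0 = rep(0.5, 4),
                       monomorphic = rep(FALSE, 4)), class = "base_population")
  # p0 = 0.5 everywhere: E = sum(1 - 0.5) = 2
  expect_equal(f_lh(c(0L, 2L, 1L, 1L), bp, map), 0)      # F_NEJ = 0.5
  expect_equal(f_lh(c(0L, 2L, 0L, 2L), bp, map), 1)      # fully homozygous
  expect_equal(f_lh(c(0L, 2L, 2L, 1L), bp, map), 0.5)    # F_NEJ = 0.75
  # missing loci drop from both S and F_NEJ
  expect_equal(f_lh(c(0L, 2L, 2L, NA), bp, map),
               (3 * 1 - 1.5) / (3 - 1.5))
  # all loci monomorphic in BP -> undefined
  bp_mono <- structure(list(member_ids = "b", p0 = rep(1, 4),
                            monomorphic = rep(TRUE, 4)), class = "base_population")
  expect_true(is.na(f_lh(c(0L, 2L, 2L, 2L), bp_mono, map)))
})

test_that("F_LH is invariant to allele relabeling", {
  set.seed(5)
  map <- toy_map(50)
  p <- runif(50, 0.1, 0.9)
  bp <- structure(list(member_ids = "b", p0 = p, monomorphic = rep(FALSE, 50)),
                  class = "base_population")
  bp_flip <- structure(list(member_ids = "b", p0 = 1 - p,
                            monomorphic = rep(FALSE, 50)),
                       class = "base_population")
  g <- sample(0:2, 50, replace = TRUE)
  expect_equal(f_lh(g, bp, map), f_lh(2L - g, bp_flip, map))
})

test_that("F_YAN matches the per-SNP identities of the uniting-gametes form", {
  map <- toy_map(1)
  mk_bp <- function(p) structure(list(member_ids = "b", p0 = p,
                                      monomorphic = p <= 0 | p >= 1),
                                 class = "base_population")
  expect_equal(f_yan(1L, mk_bp(0.5), map), -1)
  expect_equal(f_yan(2L, mk_bp(0.5), map), +1)
  expect_equal(f_yan(0L, mk_bp(0.25), map), 1 / 3)
  # rare-allele homozygote out-weighs common-allele homozygote
  expect_gt(f_yan(0L, mk_bp(0.9), map), f_yan(2L, mk_bp(0.9), map))
})

test_that("genome-wide LH/YAN equal the SNP-count-weighted combination of per-chromosome values", {
  set.seed(8)
  n1 <- 30; n2 <- 20
  map <- marker_map(data.frame(name = paste0("m", 1:(n1 + n2)),
                               chrom = rep(1:2, c(n1, n2)),
                               pos_bp = c(1e5 * 1:n1, 1e5 * 1:n2)))
  p <- runif(n1 + n2, 0.05, 0.95)
  bp <- structure(list(member_ids = "b", p0 = p,
                       monomorphic = rep(FALSE, n1 + n2)),
                  class = "base_population")
  g <- sample(0:2, n1 + n2, replace = TRUE)
  y1 <- f_yan(g, bp, map, 1); y2 <- f_yan(g, bp, map, 2)
  expect_equal(f_yan(g, bp, map, "genome"), (n1 * y1 + n2 * y2) / (n1 + n2),
               tolerance = 1e-9)
  l1 <- f_lh(g, bp, map, 1); l2 <- f_lh(g, bp, map, 2)
  # LH combines via its numerator/denominator sums, recompute longhand
  E1 <- sum(1 - 2 * p[1:n1] * (1 - p[1:n1]))
  E2 <- sum(1 - 2 * p[(n1 + 1):(n1 + n2)] * (1 - p[(n1 + 1):(n1 + n2)]))
  num <- l1 * (n1 - E1) + l2 * (n2 - E2)
  expect_equal(f_lh(g, bp, map, "genome"), num / ((n1 - E1) + (n2 - E2)),
               tolerance = 1e-9)
})

test_that("base_population counts alleles and flags monomorphic SNPs", {
  geno <- rbind(b1 = c(0L, 2L, 1L, NA), b2 = c(0L, 2L, 1L, 2L))
  colnames(geno) <- paste0("m", 1:4)
  bp <- base_population(geno, c("b1", "b2"))
  expect_equal(unname(bp$p0), c(0, 1, 0.5, 1))
  expect_equal(unname(bp$monomorphic), c(TRUE, TRUE, FALSE, TRUE))
  expect_error(base_population(geno, "nope"), "not genotyped")
})

test_that("regression on t matches the closed-form OLS oracle", {
  set.seed(21)
  t <- runif(40, 0, 4)
  y <- 0.02 + 0.05 * t + rnorm(40, 0, 0.02)
  fit <- regress_on_t(y, t)
  oracle <- oracle_ols(y, t)
  expect_equal(fit$b, oracle$b, tolerance = 1e-10)
  expect_equal(fit$p_value, oracle$p_value, tolerance = 1e-10)
  expect_equal(fit$R2, oracle$R2, tolerance = 1e-10)
  # exact linear and constant cases (lm warns about the perfect fit)
  exact <- suppressWarnings(regress_on_t(1 + 2 * t, t))
  expect_equal(exact$R2, 1)
  expect_equal(exact$b, 2)
  expect_equal(suppressWarnings(regress_on_t(rep(0.3, 40), t))$b, 0)
  expect_true(is.na(regress_on_t(y, rep(1, 40))$b))
})
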