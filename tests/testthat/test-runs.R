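make_map <- function(pos, chrom = 1L) {
  marker_map(data.frame(name = paste0("s", seq_along(pos)), chrom = chrom,
                        pos_bp = pos))
}

test_that("a clean homozygous stretch is one ROH; an over-budget gap splits and kills it", {
  pos <- round(seq(1e6, 3e6, length.out = 25))
  map <- make_map(pos)
  g <- rep(0L, 25)
  runs <- detect_runs(g, map, kind = "ROH")
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_snps, 25L)
  expect_equal(runs$end_bp - runs$start_bp + 1, 2e6 + 1)

  # 1.5 Mb hole in the middle: two 12/13-SNP stretches, below min_snps = 20
  pos2 <- c(seq(1e6, 2e6, length.out = 13), seq(3.5e6, 4.5e6, length.out = 12))
  g2 <- rep(2L, 25)
  expect_equal(nrow(detect_runs(g2, make_map(round(pos2)), kind = "ROH")), 0L)
})

test_that("segmentation with interspersed heterozygotes equals the exhaustive-window oracle", {
  set.seed(42)
  pos <- sort(sample(1:6e6, 60))
  map <- make_map(pos)
  g <- sample(c(0L, 2L), 60, replace = TRUE)
  g[sort(sample(60, 6))] <- 1L          # six hets under a five-het budget
  params <- run_params("ROH")
  expect_equal(detect_runs(g, map, params, "ROH"),
               oracle_runs(g, map, params, "ROH"))
})

test_that("detect_runs equals the exhaustive-window oracle on random vectors, both kinds", {
  for (seed in 1:120) {
    case <- random_genotype_case(seed)
    for (kind in c("ROH", "HRR")) {
      params <- run_params(kind)
      expect_equal(detect_runs(case$geno, case$map, params, kind),
                   oracle_runs(case$geno, case$map, params, kind),
                   info = sprintf("seed=%d kind=%s", seed, kind))
    }
  }
})

test_that("runs are invariant to allele relabeling and never exceed the map span", {
  for (seed in 1:20) {
    case <- random_genotype_case(seed + 500)
    flipped <- 2L - case$geno
    for (kind in c("ROH", "HRR")) {
      expect_equal(detect_runs(case$geno, case$map, kind = kind),
                   detect_runs(flipped, case$map, kind = kind))
    }
    runs <- detect_runs(case$geno, case$map, run_params("ROH", min_snps = 6L),
                        kind = "ROH")
    if (nrow(runs)) {
      span <- autosome_lengths(case$map)
      per_chr <- tapply(runs$end_bp - runs$start_bp + 1, runs$chrom, sum)
      # union coverage bounded by span (individual maximal windows overlap at
      # most pairwise, so the union per chromosome is what f_roh measures)
      for (ch in names(per_chr)) {
        seg <- runs[runs$chrom == as.integer(ch), ]
        cov <- autozyg:::.union_length(seg$start_bp, seg$end_bp)
        expect_lte(cov, span[[ch]])
      }
    }
  }
})

test_that("run boundaries always sit on supporting SNPs within budget", {
  for (seed in c(3, 17, 31)) {
    case <- random_genotype_case(seed)
    for (kind in c("ROH", "HRR")) {
      runs <- detect_runs(case$geno, case$map,
                          run_params(kind, min_snps = 6L), kind = kind)
      for (r in seq_len(nrow(runs))) {
        ix <- which(case$map$chrom == runs$chrom[r] &
                      case$map$pos_bp >= runs$start_bp[r] &
                      case$map$pos_bp <= runs$end_bp[r])
        g <- case$geno[ix]
        ends <- g[c(1, length(g))]
        if (kind == "ROH") {
          expect_true(all(!is.na(ends) & ends != 1L))
          expect_lte(sum(g == 1L, na.rm = TRUE), 5L)
        } else {
          expect_true(all(!is.na(ends) & ends == 1L))
          expect_lte(sum(g != 1L, na.rm = TRUE), 5L)
        }
        expect_lte(sum(is.na(g)), 5L)
      }
    }
  }
})

test_that("merge_regions unions overlapping segments and counts distinct individuals", {
  seg <- data.frame(
    individual = c("a", "b", "c", "c", "d"),
    chrom = c(1L, 1L, 1L, 2L, 2L),
    start_bp = c(100, 100, 150, 500, 900),
    end_bp = c(200, 200, 300, 700, 1000),
    n_snps = 5L, kind = "ROH", stringsAsFactors = FALSE)
  reg <- merge_regions(seg)
  expect_equal(nrow(reg), 3L)
  expect_equal(reg$n_individuals[reg$chrom == 1], 3L)
  expect_equal(reg$start_bp[reg$chrom == 1], 100)
  expect_equal(reg$end_bp[reg$chrom == 1], 300)
  expect_equal(reg$n_individuals[reg$chrom == 2], c(1L, 1L))

  # staircase of pairwise-overlapping segments collapses to one region
  stair <- data.frame(individual = c("a", "b", "c"), chrom = 1L,
                      start_bp = c(1, 50, 90), end_bp = c(60, 100, 140),
                      n_snps = 3L, kind = "ROH", stringsAsFactors = FALSE)
  reg2 <- merge_regions(stair)
  expect_equal(reg2[, c("start_bp", "end_bp", "n_individuals")],
               data.frame(start_bp = 1, end_bp = 140, n_individuals = 3L))
})

test_that("merge_regions agrees with IRanges::reduce on random segment sets", {
  skip_if_not_installed("IRanges")
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    start <- sample(1:5000, n, replace = TRUE)
    seg <- data.frame(individual = sample(letters[1:5], n, replace = TRUE),
                      chrom = sample(1:2, n, replace = TRUE),
                      start_bp = start, end_bp = start + sample(1:500, n, TRUE),
                      n_snps = 2L, kind = "HRR", stringsAsFactors = FALSE)
    mine <- merge_regions(seg)
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, ]
      red <- IRanges::reduce(IRanges::IRanges(s$start_bp, s$end_bp))
      m <- mine[mine$chrom == ch, ]
      expect_equal(m$start_bp, IRanges::start(red))
      expect_equal(m$end_bp, IRanges::end(red))
    }
  }
})

test_that("Mendelian filter removes exactly the SNPs with impossible trios", {
  ped <- pedigree_table(data.frame(id = c("S", "D", "O"),
                                   sire = c(NA, NA, "S"),
                                   dam = c(NA, NA, "D"), genotyped = TRUE))
  #          snp1 snp2 snp3 snp4 snp5
  geno <- rbind(
    S = c(0L, 0L, 2L, 2L, 1L),
    D = c(0L, 2L, 2L, 0L, 1L),
    O = c(2L, 1L, 1L, 1L, 0L))   # snp1: 0x0 -> 2 bad; snp3: 2x2 -> 1 bad
  colnames(geno) <- paste0("snp", 1:5)
  res <- mendelian_filter(geno, ped)
  expect_setequal(res$report$removed_snps, c("snp1", "snp3"))
  expect_equal(colnames(res$geno), c("snp2", "snp4", "snp5"))
  expect_equal(res$report$per_trio$n_errors, 2L)

  # no trios: pass-through with warning
  lone <- geno["S", , drop = FALSE]
  expect_warning(res2 <- mendelian_filter(lone, ped), "no resolvable trios")
  expect_identical(res2$geno, lone)
})
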