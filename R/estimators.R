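#' Declare the base population and its allele frequencies
#'
#' The base population (BP) anchors the frequency-based estimators: `p0` is
#' the per-SNP reference-allele frequency obtained by allele counting over
#' the BP members (missing genotypes excluded per SNP), and SNPs fixed in
#' the BP (`p0` 0 or 1, or entirely missing) are flagged: the Yang
#' denominator `2 p0 (1 - p0)` is singular there, so such SNPs are excluded
#' from [f_lh()] and [f_yan()] while still participating in run detection.
#'
#' @param geno integer matrix, individuals x SNPs, rownames = ids.
#' @param member_ids ids of the BP members (must be genotyped rows).
#' @return List of class `base_population`: `member_ids`, `p0`,
#'   `monomorphic` (logical per SNP).
#' @export
base_population <- function(geno, member_ids) {
  member_ids <- as.character(member_ids)
  if (!all(member_ids %in% rownames(geno))) {
    stop("BP member(s) not genotyped: ",
         paste(setdiff(member_ids, rownames(geno)), collapse = ", "))
  }
  sub <- geno[member_ids, , drop = FALSE]
  p0 <- colMeans(sub, na.rm = TRUE) / 2
  mono <- is.nan(p0) | p0 <= 0 | p0 >= 1
  structure(list(member_ids = member_ids, p0 = p0, monomorphic = mono),
            class = "base_population")
}

.scope_sel <- function(map, scope) {
  if (identical(scope, "genome")) rep(TRUE, nrow(map)) else map$chrom == as.integer(scope)
}

.scope_length <- function(map, scope, l_auto = NULL) {
  la <- if (is.null(l_auto)) autosome_lengths(map) else l_auto
  if (identical(scope, "genome")) sum(la) else unname(la[as.character(scope)])
}

# total length of the union of [start, end] intervals (single chromosome
# handled per group by the callers)
.union_length <- function(start, end) {
  if (!length(start)) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0
  cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce) ce <- max(ce, end[i]) else { tot <- tot + ce - cs + 1; cs <- start[i]; ce <- end[i] }
  }
  tot + ce - cs + 1
}

#' Genomic inbreeding from ROH coverage
#'
#' `F_ROH = sum(L_ROH) / L_AUTO`: the fraction of the autosomal genome
#' covered by the individual's runs of homozygosity. Coverage is the union
#' of the segments, and `L_AUTO` defaults to the marker-map span
#' ([autosome_lengths()]) so that complete coverage yields exactly 1.
#'
#' @param segments one individual's ROH segments ([detect_runs()] output).
#' @param map a [marker_map()].
#' @param scope `"genome"` or a chromosome label.
#' @param l_auto optional named per-chromosome length override (e.g.
#'   assembly lengths).
#' @return Proportion in `[0, 1]`; `NA` for an empty scope.
#' @export
f_roh <- function(segments, map, scope = "genome", l_auto = NULL) {
  L <- .scope_length(map, scope, l_auto)
  if (is.na(L) || L <= 0) return(NA_real_)
  seg <- segments[if (identical(scope, "genome")) TRUE else segments$chrom == as.integer(scope), , drop = FALSE]
  cov <- sum(vapply(split(seg, seg$chrom),
                    function(s) .union_length(s$start_bp, s$end_bp), numeric(1)))
  cov / L
}

#' Genomic inbreeding from HRR coverage
#'
#' `F_HRR = 1 - sum(L_HRR) / L_AUTO`: one minus the fraction of the genome
#' covered by heterozygosity-rich regions.
#'
#' @inheritParams f_roh
#' @param segments one individual's HRR segments.
#' @return Value in `[0, 1]`; `NA` for an empty scope.
#' @export
f_hrr <- function(segments, map, scope = "genome", l_auto = NULL) {
  L <- .scope_length(map, scope, l_auto)
  if (is.na(L) || L <= 0) return(NA_real_)
  seg <- segments[if (identical(scope, "genome")) TRUE else segments$chrom == as.integer(scope), , drop = FALSE]
  cov <- sum(vapply(split(seg, seg$chrom),
                    function(s) .union_length(s$start_bp, s$end_bp), numeric(1)))
  1 - cov / L
}

#' Li-Horvitz homozygosity relative to the base population
#'
#' Deviation of the observed frequency of homozygous loci from the
#' Hardy-Weinberg expectation in the BP:
#' `F_LH = (S * F_NEJ - E) / (S - E)` with
#' `E = sum_k (1 - 2 p0_k (1 - p0_k))`, `S` the number of usable loci in
#' scope and `F_NEJ` the proportion of those loci that are homozygous.
#' Loci missing in the individual or monomorphic in the BP are removed from
#' both `S` and the sums.
#'
#' @param geno one individual's genotype vector (0/1/2/NA) aligned to `map`.
#' @param bp a [base_population()].
#' @param map a [marker_map()].
#' @param scope `"genome"` or a chromosome label.
#' @param include_monomorphic_bp keep BP-monomorphic SNPs in `S`/`F_NEJ`
#'   (they still contribute `1` to `E`'s homozygosity expectation); default
#'   `FALSE` (polymorphic-only).
#' @return Value in `[-1, 1]`; `NA` when no usable locus remains.
#' @export
f_lh <- function(geno, bp, map, scope = "genome", include_monomorphic_bp = FALSE) {
  sel <- .scope_sel(map, scope) & !is.na(geno)
  if (!include_monomorphic_bp) sel <- sel & !bp$monomorphic
  if (!any(sel)) return(NA_real_)
  x <- geno[sel]
  p <- bp$p0[sel]
  S <- length(x)
  E <- sum(1 - 2 * p * (1 - p))
  if (S - E <= 0) return(NA_real_)
  F_nej <- mean(x != 1L)
  (S * F_nej - E) / (S - E)
}

#' Yang homozygosity (correlation between uniting gametes)
#'
#' Diagonal of the Yang et al. genomic relationship matrix with BP allele
#' frequencies: the mean over usable loci of
#' `(x^2 - (1 + 2 p0) x + 2 p0^2) / (2 p0 (1 - p0))`. Homozygotes for the
#' rarer allele weigh more than homozygotes for the common allele. Loci
#' missing in the individual or monomorphic in the BP are excluded.
#'
#' @inheritParams f_lh
#' @return Numeric value (unbounded in principle, near `[-1, 1]` in
#'   practice); `NA` when no usable locus remains.
#' @export
f_yan <- function(geno, bp, map, scope = "genome") {
  sel <- .scope_sel(map, scope) & !is.na(geno) & !bp$monomorphic
  if (!any(sel)) return(NA_real_)
  x <- geno[sel]
  p <- bp$p0[sel]
  mean((x^2 - (1 + 2 * p) * x + 2 * p^2) / (2 * p * (1 - p)))
}

#' Per-individual homozygosity table, genome-wide and per autosome
#'
#' Computes the four raw estimators for every genotyped individual at every
#' scope (genome plus each autosome): `F_ROH` and `F_HRR` from the detected
#' run segments, `F_LH` and `F_YAN` from the genotypes and BP frequencies.
#'
#' @param geno integer matrix, individuals x SNPs, rownames = ids.
#' @param map a [marker_map()].
#' @param roh,hrr segment tables from [detect_runs_all()].
#' @param bp a [base_population()].
#' @param l_auto optional per-chromosome length override.
#' @return Long data frame of class `homozygosity_table`: `id`,
#'   `estimator` (`ROH`/`HRR`/`LH`/`YAN`), `scope` (`"genome"` or the
#'   chromosome label), `value`.
#' @export
homozygosity_table <- function(geno, map, roh, hrr, bp, l_auto = NULL) {
  ids <- rownames(geno)
  scopes <- c("genome", as.character(sort(unique(map$chrom))))
  roh_by <- split(roh, factor(roh$individual, levels = ids))
  hrr_by <- split(hrr, factor(hrr$individual, levels = ids))
  empty <- roh[0, , drop = FALSE]
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    g <- geno[id, ]
    rs <- roh_by[[id]]; if (is.null(rs)) rs <- empty
    hs <- hrr_by[[id]]; if (is.null(hs)) hs <- empty
    vals <- lapply(scopes, function(sc) c(
      ROH = f_roh(rs, map, sc, l_auto),
      HRR = f_hrr(hs, map, sc, l_auto),
      LH = f_lh(g, bp, map, sc),
      YAN = f_yan(g, bp, map, sc)))
    rows[[i]] <- data.frame(
      id = id,
      estimator = rep(c("ROH", "HRR", "LH", "YAN"), times = length(scopes)),
      scope = rep(scopes, each = 4L),
      value = unlist(vals, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("homozygosity_table", "data.frame")
  out
}

#' Regress an estimator on pedigree depth
#'
#' Ordinary least-squares regression of per-individual homozygosity values
#' on equivalent discrete generations `t`, with the two-sided test of the
#' slope; used to screen for trends of homozygosity with pedigree depth.
#'
#' @param values numeric vector of per-individual estimator values.
#' @param t matching vector of equivalent discrete generations.
#' @return List `b` (slope), `p_value`, `R2`, `n`.
#' @export
regress_on_t <- function(values, t) {
  ok <- !is.na(values) & !is.na(t)
  if (sum(ok) < 3) stop("need at least 3 individuals with defined values")
  if (stats::var(t[ok]) == 0) {
    return(list(b = NA_real_, p_value = NA_real_, R2 = NA_real_, n = sum(ok)))
  }
  fit <- stats::lm(values[ok] ~ t[ok])
  sm <- summary(fit)
  list(b = unname(stats::coef(fit)[2]),
       p_value = sm$coefficients[2, 4],
       R2 = sm$r.squared,
       n = sum(ok))
}
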