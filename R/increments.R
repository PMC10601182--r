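#' Individual increase in homozygosity
#'
#' `dtF_i = 1 - (1 - F_i)^(1/t)`: the per-generation rate at which an
#' individual's (BP-adjusted or jackknifed) homozygosity accumulated over
#' its whole pedigree depth. Note the exponent is `1/t`, not `1/(t-1)` as
#' in the genealogical [delta_F_individual()]: the genomic estimate already
#' deviates from the base population in the first generation, so the full
#' depth is the natural time scale, and for equal `F` the genomic rate is
#' smaller than the genealogical one. Negative adjusted values pass through
#' (yielding negative rates).
#'
#' @param F adjusted homozygosity value(s), `< 1`.
#' @param t equivalent discrete generations, `> 0`.
#' @return Numeric vector; `NA` where `t <= 0` or `F >= 1`.
#' @export
delta_t_homozygosity <- function(F, t) {
  out <- 1 - (1 - F)^(1 / t)
  out[t <= 0 | F >= 1 | is.na(F) | is.na(t)] <- NA_real_
  out
}

#' Increase in pairwise homozygosity
#'
#' `dpF_ijk = (F_i - mean(F_j, F_k)) / (1 - mean(F_j, F_k))`: the
#' offspring's homozygosity excess over its parents' mean, rescaled by the
#' heterozygosity the parents had left. The parents act as the reference
#' population from which the offspring is differentiated.
#'
#' @param F_off offspring value(s).
#' @param F_sire,F_dam parental values of the same estimator and basis.
#' @return Numeric vector; `NA` where a parental value is missing or the
#'   parental mean is `>= 1`.
#' @export
delta_p_homozygosity <- function(F_off, F_sire, F_dam) {
  pm <- 0.5 * (F_sire + F_dam)
  out <- (F_off - pm) / (1 - pm)
  out[is.na(F_off) | is.na(pm) | pm >= 1] <- NA_real_
  out
}

#' Increments of homozygosity for every individual
#'
#' Builds the per-individual increase table from an [adjust_pipeline()]
#' result: for each estimator and each basis (`bp_adjusted`, `jackknifed`),
#' the individual increase `dtF` (needs `t > 0`) and the pairwise increase
#' `dpF` (needs both parents' values on the same basis; individuals with a
#' non-genotyped parent get `NA` and are excluded from cohort means).
#'
#' @param adjusted an [adjust_pipeline()] result (or any data frame with
#'   `id`, `estimator`, `bp_adjusted`, `jackknifed`).
#' @param ped a [pedigree_table()].
#' @param stats optional precomputed [genealogy_stats()].
#' @return Data frame `id`, `estimator`, `basis`, `F`, `dtF`, `dpF`.
#' @export
increment_table <- function(adjusted, ped, stats = NULL) {
  if (is.null(stats)) stats <- genealogy_stats(ped)
  tmap <- stats::setNames(stats$t, stats$id)
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)

  rows <- lapply(c("bp_adjusted", "jackknifed"), function(basis) {
    val <- stats::setNames(adjusted[[basis]],
                           paste(adjusted$id, adjusted$estimator))
    F_off <- adjusted[[basis]]
    F_s <- unname(val[paste(sire[adjusted$id], adjusted$estimator)])
    F_d <- unname(val[paste(dam[adjusted$id], adjusted$estimator)])
    data.frame(
      id = adjusted$id, estimator = adjusted$estimator, basis = basis,
      F = F_off,
      dtF = delta_t_homozygosity(F_off, unname(tmap[adjusted$id])),
      dpF = delta_p_homozygosity(F_off, F_s, F_d),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic effective population size for a cohort
#'
#' `Ne = 1 / (2 * mean increment)` over the cohort members with a defined
#' increment of the requested kind. A non-positive mean yields `Inf`
#' (no measurable loss of heterozygosity) rather than a negative size.
#'
#' @param increments an [increment_table()] result.
#' @param cohort a cohort (list with `member_ids`) or id vector.
#' @param estimator one of `"ROH"`, `"HRR"`, `"LH"`, `"YAN"`.
#' @param basis `"bp_adjusted"` or `"jackknifed"`.
#' @param approach `"individual"` (uses `dtF`) or `"pairwise"` (uses `dpF`).
#' @return List `Ne`, `mean_increment`, `n` (members used).
#' @export
ne_genomic <- function(increments, cohort, estimator,
                       basis = c("bp_adjusted", "jackknifed"),
                       approach = c("individual", "pairwise")) {
  basis <- match.arg(basis)
  approach <- match.arg(approach)
  members <- if (is.list(cohort)) cohort$member_ids else as.character(cohort)
  col <- if (approach == "individual") "dtF" else "dpF"
  sel <- increments$id %in% members &
    increments$estimator == estimator & increments$basis == basis
  v <- increments[[col]][sel]
  v <- v[!is.na(v)]
  if (!length(v)) return(list(Ne = NA_real_, mean_increment = NA_real_, n = 0L))
  m <- mean(v)
  Ne <- if (m <= 0) Inf else 1 / (2 * m)
  list(Ne = Ne, mean_increment = m, n = length(v))
}

#' Root-mean-squared error of genomic Ne against a genealogical reference
#'
#' `RMSE = sqrt(sum((Ne_ref - Ne_est)^2) / n)` over paired per-cohort
#' estimates; all members must be defined.
#'
#' @param ne_genomic numeric vector of genomic Ne estimates (one per
#'   cohort).
#' @param ne_reference matching genealogical reference values.
#' @return Non-negative scalar.
#' @export
rmse_vs_reference <- function(ne_genomic, ne_reference) {
  if (length(ne_genomic) != length(ne_reference)) stop("vectors must be paired")
  if (anyNA(ne_genomic) || anyNA(ne_reference) ||
      any(!is.finite(ne_genomic)) || any(!is.finite(ne_reference))) {
    stop("undefined Ne in RMSE input")
  }
  sqrt(mean((ne_reference - ne_genomic)^2))
}

#' Cohort-level Ne report and RMSE summary
#'
#' Assembles, for a list of cohorts, the genealogical `Ne_Fi`/`Ne_Cij` and
#' every genomic Ne (4 estimators x 2 bases x 2 approaches), plus the RMSE
#' of each genomic series against each genealogical reference across the
#' cohorts.
#'
#' @param increments an [increment_table()] result.
#' @param ped a [pedigree_table()].
#' @param cohorts list of cohorts (see [define_cohorts()]).
#' @param stats optional precomputed [genealogy_stats()].
#' @param A optional precomputed [relationship_matrix()].
#' @return List with `ne` (long data frame: cohort, n, mean_t, method,
#'   estimator, basis, approach, Ne) and `rmse` (data frame: estimator,
#'   approach, basis, reference, rmse). RMSE rows are only emitted when all
#'   cohorts have finite estimates.
#' @export
ne_report <- function(increments, ped, cohorts, stats = NULL, A = NULL) {
  if (is.null(stats)) stats <- genealogy_stats(ped)
  if (is.null(A)) A <- relationship_matrix(ped)
  ests <- unique(increments$estimator)
  rows <- list()
  for (co in cohorts) {
    gen <- ne_genealogical(ped, co, stats = stats, A = A)
    rows[[length(rows) + 1L]] <- data.frame(
      cohort = co$label, n = co$n, mean_t = co$mean_t,
      method = c("Ne_Fi", "Ne_Cij"), estimator = NA_character_,
      basis = NA_character_, approach = NA_character_,
      Ne = c(gen$Ne_Fi, gen$Ne_Cij), stringsAsFactors = FALSE)
    for (e in ests) for (b in c("bp_adjusted", "jackknifed")) {
      for (ap in c("individual", "pairwise")) {
        g <- ne_genomic(increments, co, e, b, ap)
        rows[[length(rows) + 1L]] <- data.frame(
          cohort = co$label, n = co$n, mean_t = co$mean_t,
          method = "genomic", estimator = e, basis = b, approach = ap,
          Ne = g$Ne, stringsAsFactors = FALSE)
      }
    }
  }
  ne <- do.call(rbind, rows)
  rownames(ne) <- NULL

  rmse <- list()
  for (ref in c("Ne_Fi", "Ne_Cij")) {
    ref_v <- ne$Ne[ne$method == ref]
    for (e in ests) for (b in c("bp_adjusted", "jackknifed")) {
      for (ap in c("individual", "pairwise")) {
        est_v <- ne$Ne[ne$method == "genomic" & ne$estimator == e &
                         ne$basis == b & ne$approach == ap]
        if (length(est_v) == length(ref_v) &&
            all(is.finite(est_v)) && all(is.finite(ref_v))) {
          rmse[[length(rmse) + 1L]] <- data.frame(
            estimator = e, approach = ap, basis = b, reference = ref,
            rmse = rmse_vs_reference(est_v, ref_v), stringsAsFactors = FALSE)
        }
      }
    }
  }
  rmse <- if (length(rmse)) do.call(rbind, rmse) else
    data.frame(estimator = character(0), approach = character(0),
               basis = character(0), reference = character(0),
               rmse = numeric(0))
  rownames(rmse) <- NULL
  list(ne = ne, rmse = rmse)
}
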