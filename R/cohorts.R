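#' Define reference subpopulations (cohorts)
#'
#' Three schemes are supported, mirroring how small-population studies slice
#' a pedigree into reference subpopulations:
#' \describe{
#'   \item{`year`}{one cohort per birth year, after applying `merge_years`
#'     (e.g. `c("2010" = "2009")` folds the 2010-born tail into the 2009
#'     cohort). Labels are `C<year>`.}
#'   \item{`complete_generations`}{one cohort per value of the fully traced
#'     generations `G`; labels are `CG<G>`.}
#'   \item{`t_threshold`}{a single cohort of all individuals with
#'     `t >= t_threshold` (default 2), labelled `t-subset`.}
#' }
#'
#' @param ped a [pedigree_table()].
#' @param scheme one of `"year"`, `"complete_generations"`, `"t_threshold"`.
#' @param merge_years named character vector mapping a source year to the
#'   year whose cohort absorbs it (year scheme only).
#' @param t_threshold minimum `t` for the `t_threshold` scheme.
#' @param genotyped_only restrict membership to genotyped individuals
#'   (default `TRUE`; cohorts are usually defined over the typed sample).
#' @param stats optional precomputed [genealogy_stats()] output.
#' @return List of cohorts, each a list with `label`, `member_ids`, `n`,
#'   `mean_t`. Empty result triggers a warning.
#' @export
define_cohorts <- function(ped,
                           scheme = c("year", "complete_generations", "t_threshold"),
                           merge_years = NULL,
                           t_threshold = 2,
                           genotyped_only = TRUE,
                           stats = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(stats)) stats <- genealogy_stats(ped)
  keep <- if (genotyped_only) ped$genotyped else rep(TRUE, nrow(ped))
  ids <- ped$id[keep]
  st <- stats[match(ids, stats$id), , drop = FALSE]

  groups <- switch(scheme,
    year = {
      yr <- as.character(ped$birth_year[keep])
      if (!is.null(merge_years)) {
        hit <- yr %in% names(merge_years)
        yr[hit] <- unname(merge_years[yr[hit]])
      }
      ok <- !is.na(yr) & yr != "NA"
      split(ids[ok], paste0("C", yr[ok]))
    },
    complete_generations = split(ids, paste0("CG", st$G)),
    t_threshold = {
      sub <- ids[!is.na(st$t) & st$t >= t_threshold]
      if (length(sub)) stats::setNames(list(sub), "t-subset") else list()
    }
  )
  groups <- groups[lengths(groups) > 0]
  if (!length(groups)) {
    warning("no individuals match cohort scheme '", scheme, "'")
    return(list())
  }
  tmap <- stats::setNames(stats$t, stats$id)
  out <- lapply(names(groups), function(lab) {
    m <- groups[[lab]]
    list(label = lab, member_ids = m, n = length(m),
         mean_t = mean(tmap[m], na.rm = TRUE))
  })
  names(out) <- names(groups)
  out[order(names(out))]
}

#' Genealogical effective population size for a cohort
#'
#' Two realized-rate estimators: `Ne_Fi = 1 / (2 * mean dF_i)` over the
#' cohort members with a defined individual increase in inbreeding, and
#' `Ne_Cij = 1 / (2 * mean dC_ij)` over all unordered within-cohort pairs
#' (self-pairs excluded) with a defined increase in pairwise coancestry.
#' A non-positive mean rate yields `Inf` (diversity not being lost), never a
#' negative size.
#'
#' @param ped a [pedigree_table()].
#' @param cohort one element of [define_cohorts()] output (or a character
#'   vector of member ids).
#' @param stats optional precomputed [genealogy_stats()].
#' @param A optional precomputed [relationship_matrix()].
#' @return List with `Ne_Fi`, `Ne_Cij`, `n_dF` and `n_pairs` used.
#' @export
ne_genealogical <- function(ped, cohort, stats = NULL, A = NULL) {
  members <- if (is.list(cohort)) cohort$member_ids else as.character(cohort)
  if (!length(members)) stop("empty cohort")
  if (is.null(stats)) stats <- genealogy_stats(ped)
  st <- stats[match(members, stats$id), , drop = FALSE]

  dF <- st$dF[!is.na(st$dF)]
  Ne_Fi <- if (!length(dF)) NA_real_ else {
    m <- mean(dF)
    if (m <= 0) Inf else 1 / (2 * m)
  }

  Ne_Cij <- NA_real_
  n_pairs <- 0L
  if (length(members) >= 2) {
    if (is.null(A)) A <- relationship_matrix(ped)
    cmb <- utils::combn(members, 2)
    C <- A[cbind(cmb[1, ], cmb[2, ])] / 2
    tv <- stats::setNames(st$t, st$id)
    dC <- delta_C_pairwise(C, tv[cmb[1, ]], tv[cmb[2, ]])
    dC <- dC[!is.na(dC)]
    n_pairs <- length(dC)
    if (n_pairs) {
      m <- mean(dC)
      Ne_Cij <- if (m <= 0) Inf else 1 / (2 * m)
    }
  }
  list(Ne_Fi = Ne_Fi, Ne_Cij = Ne_Cij, n_dF = length(dF), n_pairs = n_pairs)
}
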