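#' Adjust a homozygosity estimate for the base population
#'
#' `F_ia = (F_i - F_BP) / (1 - F_BP)`: re-expresses an individual's
#' homozygosity relative to the mean homozygosity of the base population,
#' so a BP-average individual scores 0 and a fully homozygous one scores 1.
#' Negative values (less homozygous than the BP mean) are legitimate and
#' retained.
#'
#' @param F_i raw estimate(s).
#' @param F_BP mean of the same estimator over the BP members (`< 1`).
#' @return Adjusted value(s); `NA` where `F_BP >= 1`.
#' @export
bp_adjust <- function(F_i, F_BP) {
  out <- (F_i - F_BP) / (1 - F_BP)
  out[F_BP >= 1] <- NA_real_
  out
}

#' Delete-one jackknife over autosomes
#'
#' Quenouille/Tukey pseudo-value jackknife of a per-individual estimator
#' from its per-autosome values: with `theta_all` the (optionally weighted)
#' mean over the n autosomes and `theta_(-c)` the mean leaving autosome c
#' out, the pseudo-values are `n * theta_all - (n - 1) * theta_(-c)`; the
#' estimate is their mean and the standard error comes from their variance.
#' Undefined per-chromosome values are dropped (with a warning), reducing n.
#'
#' @param values per-chromosome values (typically 18 autosomes).
#' @param weights optional positive per-chromosome weights (SNP counts or
#'   lengths); equal weights by default, under which the estimate reduces
#'   to the plain mean.
#' @return List `estimate`, `se`, `n`.
#' @export
jackknife_autosomes <- function(values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(weights) == length(values), all(weights > 0 | is.na(values)))
  ok <- !is.na(values)
  if (any(!ok)) {
    warning(sum(!ok), " undefined chromosome value(s) dropped from jackknife")
    values <- values[ok]; weights <- weights[ok]
  }
  n <- length(values)
  if (n < 2) stop("need at least 2 defined chromosome values")
  theta_all <- sum(weights * values) / sum(weights)
  loo <- vapply(seq_len(n), function(c) {
    sum(weights[-c] * values[-c]) / sum(weights[-c])
  }, numeric(1))
  pseudo <- n * theta_all - (n - 1) * loo
  est <- mean(pseudo)
  se <- sqrt(stats::var(pseudo) / n)
  list(estimate = est, se = se, n = n)
}

#' Base-population adjustment and jackknife for all individuals
#'
#' Applies the two consecutive adjustment steps to a raw
#' [homozygosity_table()]: (1) genome-wide BP adjustment with the
#' genome-wide BP mean per estimator, giving the `bp_adjusted` column;
#' (2) per-autosome BP adjustment with each autosome's own BP mean, then a
#' delete-one jackknife of the per-autosome adjusted values, giving the
#' `jackknifed` value and its standard error. BP members with an undefined
#' value for an estimator/scope are dropped from that BP mean with a
#' warning.
#'
#' @param raw a [homozygosity_table()].
#' @param bp a [base_population()] (its `member_ids` define the BP means).
#' @param weights optional named per-chromosome jackknife weights.
#' @return Data frame of class `adjusted_table`: `id`, `estimator`,
#'   `bp_adjusted`, `jackknifed`, `jackknife_se`. The per-autosome
#'   BP-adjusted values are attached as attribute `"per_chrom"`.
#' @export
adjust_pipeline <- function(raw, bp, weights = NULL) {
  stopifnot(inherits(raw, "homozygosity_table") || is.data.frame(raw))
  members <- bp$member_ids
  is_bp <- raw$id %in% members
  if (!any(is_bp)) stop("no BP member present in the raw table")

  key <- interaction(raw$estimator, raw$scope, drop = TRUE)
  bp_rows <- raw[is_bp, ]
  if (anyNA(bp_rows$value)) {
    warning("BP member value(s) undefined for some estimator/scope; dropped from BP mean")
  }
  bp_mean <- tapply(bp_rows$value, interaction(bp_rows$estimator, bp_rows$scope, drop = TRUE),
                    mean, na.rm = TRUE)
  adj <- bp_adjust(raw$value, as.numeric(bp_mean[as.character(key)]))

  per_chrom <- data.frame(id = raw$id, estimator = raw$estimator,
                          scope = raw$scope, adjusted = adj,
                          stringsAsFactors = FALSE)
  gw <- per_chrom[per_chrom$scope == "genome", ]
  pc <- per_chrom[per_chrom$scope != "genome", ]

  ids <- unique(raw$id)
  ests <- unique(raw$estimator)
  rows <- list()
  for (id in ids) {
    for (e in ests) {
      v <- pc$adjusted[pc$id == id & pc$estimator == e]
      ch <- pc$scope[pc$id == id & pc$estimator == e]
      w <- if (is.null(weights)) NULL else unname(weights[ch])
      jk <- if (sum(!is.na(v)) >= 2) {
        suppressWarnings(jackknife_autosomes(v, w))
      } else {
        list(estimate = NA_real_, se = NA_real_, n = sum(!is.na(v)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, estimator = e,
        bp_adjusted = gw$adjusted[gw$id == id & gw$estimator == e],
        jackknifed = jk$estimate, jackknife_se = jk$se,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_chrom") <- pc
  class(out) <- c("adjusted_table", "data.frame")
  out
}
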