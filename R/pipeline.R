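#' Full genotype-level analysis pipeline
#'
#' Orchestrates the whole assessment on a pedigree plus genotype matrix:
#' Mendelian-error SNP filtering, ROH and HRR detection, the four raw
#' homozygosity estimators (genome-wide and per autosome), base-population
#' adjustment and jackknifing over autosomes, individual and pairwise
#' increases in homozygosity, cohort definitions, and genealogical plus
#' genomic effective population sizes with RMSE against the genealogical
#' references.
#'
#' @param ped a [pedigree_table()]; `is_bp` flags define the base
#'   population.
#' @param geno individuals x SNPs integer matrix (0/1/2/NA).
#' @param map a [marker_map()].
#' @param roh_params,hrr_params [run_params()] overrides.
#' @param cohort_labels which cohorts enter the Ne/RMSE comparison;
#'   intersected with the cohorts actually found. `NULL` keeps all.
#' @param merge_years year-merging map for the year cohorts.
#' @param mendel_filter apply [mendelian_filter()] first (default `TRUE`).
#' @param l_auto optional per-chromosome length override for the coverage
#'   estimators.
#' @return List with elements `ped`, `stats` (genealogy), `geno`, `map`,
#'   `mendel_report`, `roh`, `hrr`, `roh_regions`, `hrr_regions`, `bp`,
#'   `raw`, `adjusted`, `increments`, `cohorts`, `ne`, `rmse`.
#' @export
autozyg_analysis <- function(ped, geno, map,
                             roh_params = run_params("ROH"),
                             hrr_params = run_params("HRR"),
                             cohort_labels = NULL,
                             merge_years = NULL,
                             mendel_filter = TRUE,
                             l_auto = NULL) {
  stopifnot(inherits(ped, "pedigree_table"), is.matrix(geno),
            inherits(map, "marker_map"))
  mendel_report <- NULL
  if (mendel_filter) {
    mf <- mendelian_filter(geno, ped, map)
    geno <- mf$geno; map <- mf$map; mendel_report <- mf$report
  }
  stats <- genealogy_stats(ped)

  roh <- detect_runs_all(geno, map, roh_params, "ROH")
  hrr <- detect_runs_all(geno, map, hrr_params, "HRR")

  bp_ids <- ped$id[ped$is_bp & ped$id %in% rownames(geno)]
  if (!length(bp_ids)) stop("no genotyped base-population member (is_bp flag)")
  bp <- base_population(geno, bp_ids)

  raw <- homozygosity_table(geno, map, roh, hrr, bp, l_auto = l_auto)
  adjusted <- adjust_pipeline(raw, bp)
  increments <- increment_table(adjusted, ped, stats = stats)

  cohorts <- c(define_cohorts(ped, "year", merge_years = merge_years, stats = stats),
               define_cohorts(ped, "complete_generations", stats = stats))
  if (!is.null(cohort_labels)) cohorts <- cohorts[names(cohorts) %in% cohort_labels]
  A <- relationship_matrix(ped)
  rep <- if (length(cohorts)) {
    ne_report(increments, ped, cohorts, stats = stats, A = A)
  } else {
    list(ne = NULL, rmse = NULL)
  }
  list(ped = ped, stats = stats, geno = geno, map = map,
       mendel_report = mendel_report,
       roh = roh, hrr = hrr,
       roh_regions = merge_regions(roh), hrr_regions = merge_regions(hrr),
       bp = bp, raw = raw, adjusted = adjusted, increments = increments,
       cohorts = cohorts, ne = rep$ne, rmse = rep$rmse)
}

.read_sheet <- function(x) {
  if (is.data.frame(x)) return(x)
  if (!file.exists(x)) stop("file not found: ", x)
  ext <- tolower(tools::file_ext(x))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package")
    }
    as.data.frame(readxl::read_excel(x))
  } else if (ext == "csv") {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(x, stringsAsFactors = FALSE, comment.char = "#")
  }
}

#' Replay deposited per-individual tables through the downstream stages
#'
#' Runs the adjustment, increment, cohort and Ne/RMSE stages directly on
#' per-individual values (pedigree columns plus raw genome-wide and,
#' optionally, per-autosome estimator values), bypassing the genotype-level
#' stages. This is how deposited supplementary tables are re-analysed, and
#' how any external per-individual homozygosity table can be pushed through
#' the pipeline. Column names are taken from `column_map` rather than
#' guessed.
#'
#' @param s1 raw table (data frame or a CSV/TSV/XLSX path): pedigree
#'   columns and the four raw genome-wide estimator columns; per-autosome
#'   columns named `<estimator column>_chr<k>` are used when present
#'   (enabling the jackknife stage).
#' @param s2,s4 optional tables carrying deposited BP-adjusted (`s2`) and
#'   jackknifed (`s4`) genome-wide values; when supplied they replace the
#'   recomputed ones.
#' @param column_map named list mapping the internal names `id`, `sire`,
#'   `dam`, `birth_year`, `genotyped`, `is_bp`, `ROH`, `HRR`, `LH`, `YAN`
#'   to the table's column names; defaults assume those exact names.
#' @param cohort_labels cohorts entering the Ne/RMSE block (default the
#'   five study-style cohorts, intersected with what the pedigree yields).
#' @param merge_years year-merging map (default folds 2010 into 2009).
#' @return List with `ped`, `stats`, `raw`, `adjusted`, `increments`,
#'   `cohorts`, `ne`, `rmse` and `summary` (per-estimator means of raw,
#'   BP-adjusted, jackknifed values and their increments, plus genealogical
#'   means).
#' @export
replay_supplementary <- function(s1, s2 = NULL, s4 = NULL,
                                 column_map = list(),
                                 cohort_labels = c("C2007", "C2008", "C2009", "CG2", "CG3"),
                                 merge_years = c("2010" = "2009")) {
  cm <- utils::modifyList(
    list(id = "id", sire = "sire", dam = "dam", birth_year = "birth_year",
         genotyped = "genotyped", is_bp = "is_bp",
         ROH = "F_ROH", HRR = "F_HRR", LH = "F_LH", YAN = "F_YAN"),
    column_map)
  s1 <- .read_sheet(s1)
  need <- unlist(cm[c("id", "sire", "dam", "ROH", "HRR", "LH", "YAN")])
  miss <- setdiff(need, names(s1))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))

  peddf <- data.frame(id = s1[[cm$id]], sire = s1[[cm$sire]], dam = s1[[cm$dam]],
                      stringsAsFactors = FALSE)
  for (f in c("birth_year", "genotyped", "is_bp")) {
    if (cm[[f]] %in% names(s1)) peddf[[f]] <- s1[[cm[[f]]]]
  }
  if (is.null(peddf$genotyped)) peddf$genotyped <- TRUE
  ped <- pedigree_table(peddf)
  stats <- genealogy_stats(ped)

  ests <- c("ROH", "HRR", "LH", "YAN")
  long <- list()
  for (e in ests) {
    col <- cm[[e]]
    long[[length(long) + 1L]] <- data.frame(
      id = s1[[cm$id]], estimator = e, scope = "genome",
      value = as.numeric(s1[[col]]), stringsAsFactors = FALSE)
    chrcols <- grep(paste0("^", col, "_chr[0-9]+$"), names(s1), value = TRUE)
    for (cc in chrcols) {
      long[[length(long) + 1L]] <- data.frame(
        id = s1[[cm$id]], estimator = e,
        scope = sub(paste0("^", col, "_chr"), "", cc),
        value = as.numeric(s1[[cc]]), stringsAsFactors = FALSE)
    }
  }
  raw <- do.call(rbind, long)
  class(raw) <- c("homozygosity_table", "data.frame")

  bp_ids <- ped$id[ped$is_bp]
  if (!length(bp_ids)) stop("replay requires is_bp flags to define the BP")
  bp <- structure(list(member_ids = bp_ids), class = "base_population")
  has_chrom <- any(raw$scope != "genome")
  adjusted <- adjust_pipeline(raw, bp)
  if (!has_chrom) adjusted$jackknifed <- NA_real_

  override <- function(adjusted, sheet, basis) {
    sheet <- .read_sheet(sheet)
    for (e in ests) {
      col <- cm[[e]]
      if (!col %in% names(sheet)) stop("override sheet lacks column ", col)
      v <- stats::setNames(as.numeric(sheet[[col]]), as.character(sheet[[cm$id]]))
      sel <- adjusted$estimator == e
      adjusted[[basis]][sel] <- unname(v[adjusted$id[sel]])
    }
    adjusted
  }
  if (!is.null(s2)) adjusted <- override(adjusted, s2, "bp_adjusted")
  if (!is.null(s4)) adjusted <- override(adjusted, s4, "jackknifed")

  increments <- increment_table(adjusted, ped, stats = stats)
  cohorts <- c(define_cohorts(ped, "year", merge_years = merge_years, stats = stats),
               define_cohorts(ped, "complete_generations", stats = stats))
  if (!is.null(cohort_labels)) cohorts <- cohorts[names(cohorts) %in% cohort_labels]
  rep <- if (length(cohorts)) {
    ne_report(increments, ped, cohorts, stats = stats)
  } else {
    list(ne = NULL, rmse = NULL)
  }

  gstats <- stats[ped$genotyped[match(stats$id, ped$id)], ]
  summary <- list(
    n_genotyped = nrow(gstats),
    mean_F = mean(gstats$F), sd_F = stats::sd(gstats$F),
    mean_t = mean(gstats$t), sd_t = stats::sd(gstats$t),
    mean_dF = mean(gstats$dF, na.rm = TRUE),
    n_noninbred = sum(gstats$F == 0),
    raw_means = tapply(raw$value[raw$scope == "genome"],
                       raw$estimator[raw$scope == "genome"], mean, na.rm = TRUE),
    n_negative_raw = tapply(raw$value[raw$scope == "genome"] < 0,
                            raw$estimator[raw$scope == "genome"], sum, na.rm = TRUE),
    bp_adjusted_means = tapply(adjusted$bp_adjusted, adjusted$estimator, mean, na.rm = TRUE),
    jackknifed_means = tapply(adjusted$jackknifed, adjusted$estimator, mean, na.rm = TRUE),
    dtF_means = tapply(increments$dtF[increments$basis == "bp_adjusted"],
                       increments$estimator[increments$basis == "bp_adjusted"],
                       mean, na.rm = TRUE),
    dpF_means = tapply(increments$dpF[increments$basis == "bp_adjusted"],
                       increments$estimator[increments$basis == "bp_adjusted"],
                       mean, na.rm = TRUE)
  )
  list(ped = ped, stats = stats, raw = raw, adjusted = adjusted,
       increments = increments, cohorts = cohorts,
       ne = rep$ne, rmse = rep$rmse, summary = summary)
}
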