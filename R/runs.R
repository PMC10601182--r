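#' Construct a marker map
#'
#' @param df data frame with columns `name`, `chrom`, `pos_bp` and
#'   optionally `is_monomorphic_bp`. Chromosomes must be autosomal integer
#'   labels; positions must be strictly increasing within a chromosome.
#' @return A `marker_map` data frame sorted by `(chrom, pos_bp)`.
#' @export
marker_map <- function(df) {
  stopifnot(is.data.frame(df), all(c("name", "chrom", "pos_bp") %in% names(df)))
  map <- data.frame(
    name = as.character(df$name),
    chrom = as.integer(df$chrom),
    pos_bp = as.numeric(df$pos_bp),
    stringsAsFactors = FALSE
  )
  map$is_monomorphic_bp <- if ("is_monomorphic_bp" %in% names(df)) {
    as.logical(df$is_monomorphic_bp)
  } else {
    NA
  }
  if (anyNA(map$chrom) || any(map$chrom < 1)) stop("chromosome labels must be positive integers")
  if (any(is.na(map$pos_bp) | map$pos_bp < 1)) stop("positions must be positive")
  if (anyDuplicated(map$name)) stop("duplicate SNP names")
  map <- map[order(map$chrom, map$pos_bp), , drop = FALSE]
  rownames(map) <- NULL
  dup <- unlist(tapply(map$pos_bp, map$chrom, function(p) duplicated(p)))
  if (any(dup)) stop("positions must be strictly increasing within chromosome")
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Autosome spans from a marker map
#'
#' The per-autosome genome length used as the denominator of the coverage
#' estimators: span of the mapped SNPs, `last pos - first pos + 1`, per
#' chromosome. An explicit assembly-length override can be supplied to the
#' estimator functions instead.
#'
#' @param map a [marker_map()].
#' @return Named numeric vector (names = chromosome labels).
#' @export
autosome_lengths <- function(map) {
  sp <- tapply(map$pos_bp, map$chrom, function(p) max(p) - min(p) + 1)
  stats::setNames(as.numeric(sp), names(sp))
}

#' Run-detection parameters
#'
#' Defaults follow consecutive-runs detection on a high-density porcine
#' array: ROH requires at least 20 SNPs per run with at most 5 heterozygous
#' and 5 missing calls, minimum length 1 kb, and at most 1 Mb between
#' consecutive SNPs; HRR uses the same budgets with a 10-SNP minimum (HRR
#' are short and sparse, so the binding constraint is the number of
#' homozygous calls allowed inside the run).
#'
#' @param kind `"ROH"` or `"HRR"`.
#' @param min_snps,max_opposite,max_missing,min_length_bp,max_gap_bp
#'   overrides of the per-kind defaults.
#' @return List of class `run_params`.
#' @export
run_params <- function(kind = c("ROH", "HRR"),
                       min_snps = NULL, max_opposite = 5L, max_missing = 5L,
                       min_length_bp = 1000, max_gap_bp = 1e6) {
  kind <- match.arg(kind)
  if (is.null(min_snps)) min_snps <- if (kind == "ROH") 20L else 10L
  p <- list(kind = kind, min_snps = as.integer(min_snps),
            max_opposite = as.integer(max_opposite),
            max_missing = as.integer(max_missing),
            min_length_bp = as.numeric(min_length_bp),
            max_gap_bp = as.numeric(max_gap_bp))
  if (any(unlist(p[-1]) < 0) || p$min_snps < 1 || p$min_length_bp < 1 || p$max_gap_bp < 1) {
    stop("run parameters must be positive")
  }
  if (p$max_opposite >= p$min_snps) stop("max_opposite must be < min_snps")
  class(p) <- "run_params"
  p
}

# state encoding relative to the run kind: 0 = supporting the run state,
# 1 = opposite state, 2 = missing
.run_state <- function(g, kind) {
  if (!all(g %in% c(0L, 1L, 2L) | is.na(g))) {
    stop("unknown genotype code; expected 0/1/2/NA")
  }
  st <- integer(length(g))
  if (kind == "ROH") st[!is.na(g) & g == 1L] <- 1L else st[!is.na(g) & g != 1L] <- 1L
  st[is.na(g)] <- 2L
  st
}

# All maximal conforming windows inside one gap-block.
# A window is conforming iff it starts and ends on a supporting SNP and its
# opposite-state / missing counts stay within budget; maximality is against
# containment by another conforming window.
.maximal_windows <- function(state, max_opposite, max_missing) {
  n <- length(state)
  mpos <- which(state == 0L)
  if (!length(mpos)) return(NULL)
  # candidate left ends: supporting SNP at block start or right after a
  # non-supporting SNP (any other left end extends leftward)
  cand <- mpos[mpos == 1L | state[pmax(mpos - 1L, 1L)] != 0L]
  co <- cumsum(state == 1L)
  cm <- cumsum(state == 2L)
  co0 <- c(0, co)[cand]          # counts strictly before each candidate
  cm0 <- c(0, cm)[cand]
  e <- pmin(findInterval(co0 + max_opposite, co),
            findInterval(cm0 + max_missing, cm))
  lastm <- cummax(seq_len(n) * (state == 0L))
  r <- lastm[e]
  keep <- !duplicated(r)         # r is non-decreasing in the left end
  cbind(l = cand[keep], r = r[keep])
}

#' Detect ROH or HRR runs in one individual
#'
#' Consecutive-runs detection: scanning each chromosome, a run is a stretch
#' of SNPs that starts and ends on a SNP supporting the run state
#' (homozygous for ROH, heterozygous for HRR), contains at most
#' `max_opposite` opposite-state and `max_missing` missing calls, and never
#' jumps more than `max_gap_bp` between consecutive SNPs (a larger gap
#' closes the run). All maximal such stretches are reported, then filtered
#' on `min_snps` and `min_length_bp`. Two maximal runs may overlap when the
#' opposite-state budget binds on both sides; coverage-based estimators
#' ([f_roh()], [f_hrr()]) therefore measure the union of an individual's
#' runs.
#'
#' @param geno integer vector of reference-allele counts (0/1/2, `NA` =
#'   missing) aligned with `map`.
#' @param map a [marker_map()].
#' @param params a [run_params()]; defaults to `run_params(kind)`.
#' @param kind `"ROH"` or `"HRR"`.
#' @return Data frame `chrom`, `start_bp`, `end_bp`, `n_snps`, `kind`.
#'   Coordinates are the bp positions of the first and last SNP of the run,
#'   1-based inclusive; `n_snps` counts every SNP inside the span.
#' @export
detect_runs <- function(geno, map, params = NULL, kind = c("ROH", "HRR")) {
  kind <- match.arg(kind)
  if (is.null(params)) params <- run_params(kind)
  stopifnot(inherits(params, "run_params"), params$kind == kind)
  if (length(geno) != nrow(map)) stop("genotype vector does not match map")
  if (is.unsorted(order(map$chrom, map$pos_bp))) stop("marker map must be sorted")
  state_all <- .run_state(as.integer(geno), kind)

  out <- vector("list", 0)
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    pos <- map$pos_bp[sel]
    state <- state_all[sel]
    block <- cumsum(c(0, diff(pos) > params$max_gap_bp))
    for (b in unique(block)) {
      bi <- which(block == b)
      w <- .maximal_windows(state[bi], params$max_opposite, params$max_missing)
      if (is.null(w)) next
      l <- bi[w[, "l"]]; r <- bi[w[, "r"]]
      n_snps <- r - l + 1L
      len <- pos[r] - pos[l] + 1
      ok <- n_snps >= params$min_snps & len >= params$min_length_bp
      if (any(ok)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start_bp = pos[l][ok], end_bp = pos[r][ok],
          n_snps = n_snps[ok], kind = kind, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect runs for every individual of a genotype matrix
#'
#' @param geno integer matrix, individuals x SNPs (0/1/2/NA), rownames = ids.
#' @param map a [marker_map()].
#' @param params a [run_params()] (defaults per kind).
#' @param kind `"ROH"` or `"HRR"`.
#' @return Data frame `individual`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `kind`.
#' @export
detect_runs_all <- function(geno, map, params = NULL, kind = c("ROH", "HRR")) {
  kind <- match.arg(kind)
  if (is.null(params)) params <- run_params(kind)
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  res <- lapply(rownames(geno), function(id) {
    seg <- detect_runs(geno[id, ], map, params, kind)
    if (nrow(seg)) cbind(individual = id, seg, stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(individual = character(0), chrom = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), kind = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Merge run segments across individuals into population regions
#'
#' Sweep-line union of overlapping (or bookended) segments of one kind
#' across individuals, reporting per merged region how many distinct
#' individuals contributed a segment.
#'
#' @param segments output of [detect_runs_all()] (a single `kind`).
#' @return Data frame `chrom`, `start_bp`, `end_bp`, `n_individuals`.
#' @export
merge_regions <- function(segments) {
  if (length(unique(segments$kind)) > 1) stop("segments must be of a single kind")
  if (!nrow(segments)) {
    return(data.frame(chrom = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_individuals = integer(0)))
  }
  segments <- segments[order(segments$chrom, segments$start_bp, segments$end_bp), ]
  out <- list()
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    cur_start <- s$start_bp[1]; cur_end <- s$end_bp[1]
    members <- s$individual[1]
    flush <- function(start, end, members) {
      data.frame(chrom = ch, start_bp = start, end_bp = end,
                 n_individuals = length(unique(members)))
    }
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start_bp[i] <= cur_end + 1) {   # overlap or bookended
        cur_end <- max(cur_end, s$end_bp[i])
        members <- c(members, s$individual[i])
      } else {
        out[[length(out) + 1L]] <- flush(cur_start, cur_end, members)
        cur_start <- s$start_bp[i]; cur_end <- s$end_bp[i]
        members <- s$individual[i]
      }
    }
    out[[length(out) + 1L]] <- flush(cur_start, cur_end, members)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove SNPs with Mendelian inconsistencies
#'
#' For every resolvable trio (genotyped offspring with both parents
#' genotyped), a SNP is inconsistent when the offspring's reference-allele
#' count is impossible given the parents (e.g. parents 0/0 with offspring 1
#' or 2, an offspring 2 under a parent 0, opposite homozygous parents with a
#' homozygous offspring). Any SNP with at least one trio inconsistency is
#' removed entirely; no other genotype filtering is applied.
#'
#' @param geno integer matrix, individuals x SNPs, rownames = ids.
#' @param ped a [pedigree_table()].
#' @param map optional [marker_map()]; if given, it is subset in step and
#'   returned alongside.
#' @return List with `geno` (filtered matrix), `map` (filtered map or
#'   `NULL`) and `report` (`removed_snps`, `per_snp_errors`, `per_trio`).
#' @export
mendelian_filter <- function(geno, ped, map = NULL) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  ids <- rownames(geno)
  trio <- ped[ped$id %in% ids &
                !is.na(ped$sire) & ped$sire %in% ids &
                !is.na(ped$dam) & ped$dam %in% ids, c("id", "sire", "dam")]
  if (!nrow(trio)) {
    warning("no resolvable trios; genotypes passed through unfiltered")
    rep0 <- list(removed_snps = character(0),
                 per_snp_errors = integer(0),
                 per_trio = data.frame(offspring = character(0),
                                       sire = character(0),
                                       dam = character(0),
                                       n_errors = integer(0)))
    return(list(geno = geno, map = map, report = rep0))
  }
  nsnp <- ncol(geno)
  err_snp <- integer(nsnp)
  err_trio <- integer(nrow(trio))
  for (k in seq_len(nrow(trio))) {
    O <- geno[trio$id[k], ]; S <- geno[trio$sire[k], ]; D <- geno[trio$dam[k], ]
    bad <- (.eq(S, 0L) & .eq(D, 0L) & !.eq(O, 0L) & !is.na(O)) |
           (.eq(S, 2L) & .eq(D, 2L) & !.eq(O, 2L) & !is.na(O)) |
           (((.eq(S, 0L) & .eq(D, 2L)) | (.eq(S, 2L) & .eq(D, 0L))) & !.eq(O, 1L) & !is.na(O)) |
           ((.eq(S, 0L) | .eq(D, 0L)) & .eq(O, 2L)) |
           ((.eq(S, 2L) | .eq(D, 2L)) & .eq(O, 0L))
    err_snp <- err_snp + bad
    err_trio[k] <- sum(bad)
  }
  drop <- err_snp > 0L
  snp_names <- colnames(geno)
  if (is.null(snp_names)) snp_names <- as.character(seq_len(nsnp))
  report <- list(
    removed_snps = snp_names[drop],
    per_snp_errors = stats::setNames(err_snp[drop], snp_names[drop]),
    per_trio = data.frame(offspring = trio$id, sire = trio$sire,
                          dam = trio$dam, n_errors = err_trio,
                          stringsAsFactors = FALSE)
  )
  geno <- geno[, !drop, drop = FALSE]
  if (!is.null(map)) {
    map <- map[!drop, , drop = FALSE]
    rownames(map) <- NULL
    class(map) <- c("marker_map", "data.frame")
  }
  list(geno = geno, map = map, report = report)
}

.eq <- function(x, v) !is.na(x) & x == v
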