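#' Construct a validated pedigree table
#'
#' A `pedigree_table` is a data frame with one row per individual and the
#' columns `id`, `sire`, `dam`, `birth_year`, `sex`, `family_id`,
#' `litter_id`, `genotyped` and `is_bp`. Unknown parents are stored as `NA`.
#' On construction the pedigree is checked for duplicate ids, unresolved
#' parent references, parent-offspring cycles and birth years earlier than a
#' parent's, and rows are re-ordered topologically (parents before
#' offspring), which every downstream recursion relies on.
#'
#' @param df data frame holding at least `id`, `sire` and `dam`. Missing
#'   metadata columns are filled with `NA`/`FALSE`. `"0"`, `""` and `NA` in
#'   `sire`/`dam` all denote an unknown parent.
#' @return A `pedigree_table` (data frame subclass), topologically sorted.
#' @export
pedigree_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree must have columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  ped <- data.frame(
    id   = as.character(df$id),
    sire = .norm_parent(df$sire),
    dam  = .norm_parent(df$dam),
    stringsAsFactors = FALSE
  )
  ped$birth_year <- if ("birth_year" %in% names(df)) suppressWarnings(as.integer(df$birth_year)) else NA_integer_
  ped$sex        <- if ("sex" %in% names(df)) as.character(df$sex) else NA_character_
  ped$family_id  <- if ("family_id" %in% names(df)) as.character(df$family_id) else NA_character_
  ped$litter_id  <- if ("litter_id" %in% names(df)) as.character(df$litter_id) else NA_character_
  ped$genotyped  <- if ("genotyped" %in% names(df)) .as_flag(df$genotyped) else FALSE
  ped$is_bp      <- if ("is_bp" %in% names(df)) .as_flag(df$is_bp) else FALSE

  if (anyDuplicated(ped$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  for (col in c("sire", "dam")) {
    bad <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$id)
    if (any(bad)) {
      stop("unresolved ", col, " reference(s): ",
           paste(unique(ped[[col]][bad]), collapse = ", "))
    }
  }
  ord <- .topo_order(ped)          # errors on cycles
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL

  yr <- ped$birth_year
  names(yr) <- ped$id
  for (p in c("sire", "dam")) {
    has <- !is.na(ped[[p]]) & !is.na(yr[ped[[p]]]) & !is.na(ped$birth_year)
    bad <- has & ped$birth_year < yr[ped[[p]]]
    if (any(bad)) {
      warning("birth_year earlier than ", p, "'s for: ",
              paste(ped$id[bad], collapse = ", "))
    }
  }
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

.norm_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("0", "", "NA", ".")] <- NA_character_
  x
}

.as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(as.character(x))
  x %in% c("1", "true", "t", "yes", "y")
}

# Kahn topological sort; on a cycle, report one offending id chain.
.topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), NA_integer_, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  NA_integer_, idx[ped$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    chain <- .find_cycle(left[1], si, di, ped$id, left)
    stop("pedigree cycle detected: ", paste(chain, collapse = " -> "))
  }
  out
}

# Every node left over by Kahn's algorithm has at least one leftover parent;
# walking leftover parents from any such node must revisit a node = a cycle.
.find_cycle <- function(start, si, di, ids, leftover) {
  seen <- integer(0)
  v <- start
  repeat {
    if (v %in% seen) {
      i0 <- match(v, seen)
      return(ids[c(seen[i0:length(seen)], v)])
    }
    seen <- c(seen, v)
    parents <- c(si[v], di[v])
    parents <- parents[!is.na(parents) & parents %in% leftover]
    v <- parents[1]
  }
}

#' Read a pedigree CSV
#'
#' Expects the columns `id,sire,dam,birth_year,sex,family_id,litter_id,
#' genotyped,is_bp` (extra columns are ignored, missing metadata columns are
#' tolerated). `"0"` or an empty field marks an unknown parent.
#'
#' @param path path to a CSV file.
#' @return A [pedigree_table()].
#' @export
load_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  pedigree_table(df)
}

#' Founder indicator
#'
#' Founders are individuals with both parents unknown.
#' @param ped a [pedigree_table()].
#' @return Named logical vector over individuals.
#' @export
is_founder <- function(ped) {
  stats::setNames(is.na(ped$sire) & is.na(ped$dam), ped$id)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes each individual's inbreeding coefficient F (probability that its
#' two alleles at a locus are identical by descent) by tracing, per
#' individual, the contributions of all its ancestors with the
#' within-subject accumulation algorithm of Meuwissen and Luo. Unknown
#' parents are treated as unrelated non-inbred base individuals.
#'
#' @param ped a [pedigree_table()].
#' @return Named numeric vector of F in `[0, 1]`, in pedigree order.
#' @export
inbreeding_meuwissen_luo <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  0L, idx[ped$dam])
  f <- numeric(n)
  # F of an unknown parent enters D as -1 so that founders get D = 1.
  fpar <- function(p) if (p == 0L) -1 else f[p]
  for (i in seq_len(n)) {
    if (si[i] == 0L && di[i] == 0L) { f[i] <- 0; next }
    an <- numeric(i)                 # ancestor path coefficients
    an[i] <- 1
    aii <- 0
    for (j in rev(seq_len(i))) {
      if (an[j] == 0) next
      a <- an[j]
      if (si[j] > 0L) an[si[j]] <- an[si[j]] + a / 2
      if (di[j] > 0L) an[di[j]] <- an[di[j]] + a / 2
      dj <- 0.5 - 0.25 * (fpar(si[j]) + fpar(di[j]))
      aii <- aii + a * a * dj
    }
    f[i] <- aii - 1
  }
  stats::setNames(f, ped$id)
}

#' Pedigree depth: fully traced and equivalent discrete generations
#'
#' `t` (equivalent discrete generations) is the sum of `(1/2)^n` over all
#' known ancestors, `n` generations back; it satisfies the recursion
#' `t_i = sum over known parents of 0.5 * (1 + t_parent)`. `G` (fully traced
#' generations) is the deepest generation at which *all* `2^G` ancestors are
#' known: 0 for an individual with any unknown parent, otherwise
#' `1 + min(G_sire, G_dam)`.
#'
#' @param ped a [pedigree_table()].
#' @return Data frame with columns `id`, `G` (integer), `t` (numeric).
#' @export
equivalent_generations <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  0L, idx[ped$dam])
  t <- numeric(n)
  G <- integer(n)
  for (i in seq_len(n)) {
    ti <- 0
    if (si[i] > 0L) ti <- ti + 0.5 * (1 + t[si[i]])
    if (di[i] > 0L) ti <- ti + 0.5 * (1 + t[di[i]])
    t[i] <- ti
    G[i] <- if (si[i] > 0L && di[i] > 0L) 1L + min(G[si[i]], G[di[i]]) else 0L
  }
  data.frame(id = ped$id, G = G, t = t, stringsAsFactors = FALSE)
}

#' Individual increase in inbreeding
#'
#' The per-generation rate at which an individual accumulated inbreeding
#' over its realized pedigree: `1 - (1 - F)^(1/(t - 1))`. The exponent is
#' singular at `t = 1`, so the rate is undefined (`NA`) for individuals with
#' `t <= 1`; such individuals are excluded from cohort means downstream.
#'
#' @param F inbreeding coefficient(s) in `[0, 1)`.
#' @param t equivalent discrete generations.
#' @return Numeric vector; `NA` where `t <= 1` or `F >= 1`.
#' @export
delta_F_individual <- function(F, t) {
  out <- 1 - (1 - F)^(1 / (t - 1))
  out[t <= 1 | F >= 1 | is.na(F) | is.na(t)] <- NA_real_
  out
}

#' Additive relationship matrix (tabular method)
#'
#' Recursive tabular construction of the numerator relationship matrix A
#' over the whole pedigree; coancestry (kinship) is `A / 2`.
#'
#' @param ped a [pedigree_table()].
#' @return `n x n` matrix with dimnames set to the ids, pedigree order.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam),  0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Pairwise coancestry coefficients
#'
#' Coancestry (kinship) `C_ij` is the probability that random alleles drawn
#' from individuals i and j are identical by descent; it equals half the
#' additive relationship. Self-coancestry is `(1 + F_i) / 2`.
#'
#' @param ped a [pedigree_table()].
#' @param pairs two-column matrix or data frame of id pairs; `NULL` for all
#'   unordered pairs (excluding self-pairs).
#' @return Data frame with columns `i`, `j`, `C`.
#' @export
coancestry <- function(ped, pairs = NULL) {
  A <- relationship_matrix(ped)
  if (is.null(pairs)) {
    cmb <- utils::combn(ped$id, 2)
    pairs <- data.frame(i = cmb[1, ], j = cmb[2, ], stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("i", "j")
    pairs$i <- as.character(pairs$i)
    pairs$j <- as.character(pairs$j)
    miss <- setdiff(c(pairs$i, pairs$j), ped$id)
    if (length(miss)) stop("unknown id(s) in pairs: ", paste(miss, collapse = ", "))
  }
  pairs$C <- A[cbind(pairs$i, pairs$j)] / 2
  pairs
}

#' Increase in pairwise coancestry
#'
#' `1 - (1 - C)^(2 / (t_i + t_j))`: the per-generation rate at which the
#' coancestry of a pair accumulated, using the mean pedigree depth of the
#' two members as the time scale.
#'
#' @param C coancestry coefficient(s) in `[0, 1)`.
#' @param ti,tj equivalent discrete generations of the two individuals.
#' @return Numeric vector; `NA` where `ti + tj == 0` or `C >= 1`.
#' @export
delta_C_pairwise <- function(C, ti, tj) {
  tm <- (ti + tj) / 2
  out <- 1 - (1 - C)^(1 / tm)
  out[tm <= 0 | C >= 1 | is.na(C) | is.na(tm)] <- NA_real_
  out
}

#' Per-individual genealogical statistics
#'
#' Convenience wrapper combining [inbreeding_meuwissen_luo()],
#' [equivalent_generations()] and [delta_F_individual()].
#'
#' @param ped a [pedigree_table()].
#' @return Data frame `id`, `F`, `G`, `t`, `dF` (NA where undefined).
#' @export
genealogy_stats <- function(ped) {
  eg <- equivalent_generations(ped)
  F <- inbreeding_meuwissen_luo(ped)
  data.frame(
    id = eg$id, F = unname(F[eg$id]), G = eg$G, t = eg$t,
    dF = delta_F_individual(unname(F[eg$id]), eg$t),
    stringsAsFactors = FALSE
  )
}
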