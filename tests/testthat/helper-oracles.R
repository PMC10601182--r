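# Independent oracles used by the test suite. These re-derive expected
# values by different routes than the package implementation (memoized
# recursion instead of the within-subject algorithm; brute-force window
# enumeration instead of the two-sided cumulative construction; closed-form
# normal equations instead of lm).

# --- recursive tabular kinship oracle ---------------------------------------
# phi(i,i) = (1 + 0.5*phi(s,d))/2 ; phi(i,j) = (phi(s,j) + phi(d,j))/2 for
# i younger than j, with phi = 0 against an unknown parent.
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    key <- paste(min(i, j), max(i, j))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else {
      a <- max(i, j); b <- min(i, j)   # rows are topologically sorted
      0.5 * (phi(si[a], b) + phi(di[a], b))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) K[i, j] <- K[j, i] <- phi(i, j)
  K
}

oracle_inbreeding <- function(ped) {
  K <- oracle_kinship(ped)
  stats::setNames(2 * diag(K) - 1, ped$id)
}

# --- Monte-Carlo gene-dropping kinship (single unlinked locus) --------------
oracle_kinship_mc <- function(ped, i, j, nrep = 20000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  hits <- 0
  for (r in seq_len(nrep)) {
    a1 <- integer(n); a2 <- integer(n)
    lab <- 0L
    for (k in seq_len(n)) {
      a1[k] <- if (si[k] > 0L) {
        if (stats::runif(1) < 0.5) a1[si[k]] else a2[si[k]]
      } else { lab <- lab + 1L; lab }
      a2[k] <- if (di[k] > 0L) {
        if (stats::runif(1) < 0.5) a1[di[k]] else a2[di[k]]
      } else { lab <- lab + 1L; lab }
    }
    ii <- idx[i]; jj <- idx[j]
    pick_i <- if (stats::runif(1) < 0.5) a1[ii] else a2[ii]
    pick_j <- if (stats::runif(1) < 0.5) a1[jj] else a2[jj]
    hits <- hits + (pick_i == pick_j)
  }
  hits / nrep
}

# --- brute-force maximal-window run oracle ----------------------------------
# Enumerates every conforming window (both ends supporting the run state,
# opposite/missing within budget, all internal gaps <= max_gap), filters to
# windows not strictly contained in another conforming window, then applies
# the min_snps / min_length emission thresholds.
oracle_runs <- function(geno, map, params, kind) {
  supp <- if (kind == "ROH") !is.na(geno) & geno != 1L else !is.na(geno) & geno == 1L
  opp <- if (kind == "ROH") !is.na(geno) & geno == 1L else !is.na(geno) & geno != 1L
  mis <- is.na(geno)
  out <- list()
  for (ch in unique(map$chrom)) {
    ix <- which(map$chrom == ch)
    pos <- map$pos_bp[ix]
    n <- length(ix)
    wins <- list()
    for (l in seq_len(n)) {
      if (!supp[ix[l]]) next
      seg <- l:n
      o <- cumsum(opp[ix[seg]])
      m <- cumsum(mis[ix[seg]])
      gmax <- cummax(c(0, diff(pos[seg])))
      ok <- supp[ix[seg]] & o <= params$max_opposite &
        m <= params$max_missing & gmax <= params$max_gap_bp
      rs <- seg[ok]
      if (length(rs)) wins[[length(wins) + 1L]] <- cbind(l = l, r = rs)
    }
    if (!length(wins)) next
    w <- do.call(rbind, wins)
    w <- w[order(w[, "l"], -w[, "r"]), , drop = FALSE]
    maximal <- w[, "r"] > cummax(c(-1L, w[-nrow(w), "r"]))
    w <- w[maximal, , drop = FALSE]
    n_snps <- w[, "r"] - w[, "l"] + 1L
    len <- pos[w[, "r"]] - pos[w[, "l"]] + 1
    keep <- n_snps >= params$min_snps & len >= params$min_length_bp
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = pos[w[keep, "l"]], end_bp = pos[w[keep, "r"]],
        n_snps = n_snps[keep], kind = kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- closed-form OLS oracle --------------------------------------------------
oracle_ols <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  tval <- b / sqrt(s2 / sxx)
  list(b = b,
       p_value = 2 * stats::pt(-abs(tval), df = n - 2),
       R2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}
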