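#' Configuration for the gene-dropping simulator
#'
#' Defaults emulate a recently recovered, highly endangered pig population:
#' six founders, four discrete generations of managed matings (an early
#' phase of full-sib matings followed by a strict policy avoiding close
#' relatives), large full-sib families, 18 autosomes typed at array-like
#' density with a substantial monomorphic fraction. Litter sizes are
#' `1 + NegBin(mu = litter_mean - 1, size = litter_dispersion)`; litter
#' counts per generation default to `c(12, 20, 30, 33)` which with the
#' default litter mean yields on the order of 95 litters and 530 offspring.
#'
#' @param n_founders number of founders (even; half of each sex).
#' @param n_generations number of discrete generations (1-4 typical).
#' @param mating_policy `"full_sib_burst"` (default: founder pairs, then
#'   full-sib matings in generation 2, then avoidance), `"avoid_close_relatives"`
#'   (never mate pairs with coancestry >= 0.125) or `"random"`.
#' @param n_litters_per_generation litters per generation (recycled).
#' @param litter_mean,litter_dispersion litter-size distribution.
#' @param n_autosomes,snps_per_autosome marker panel dimensions.
#' @param chrom_length_morgans,chrom_length_bp per-autosome genetic and
#'   physical lengths (recycled).
#' @param founder_maf_beta shape parameters of the symmetric Beta from
#'   which founder reference-allele frequencies are drawn.
#' @param monomorphic_fraction fraction of SNPs forced monomorphic in the
#'   founders (array-like site-frequency spectrum).
#' @param missing_rate per-genotype missing probability.
#' @param seed integer seed; mandatory, all randomness derives from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_founders = 6L,
                       n_generations = 4L,
                       mating_policy = c("full_sib_burst", "avoid_close_relatives", "random"),
                       n_litters_per_generation = c(12L, 20L, 30L, 33L),
                       litter_mean = 5.6,
                       litter_dispersion = 2,
                       n_autosomes = 18L,
                       snps_per_autosome = 400L,
                       chrom_length_morgans = 1,
                       chrom_length_bp = 1e8,
                       founder_maf_beta = c(0.8, 0.8),
                       monomorphic_fraction = 0.3,
                       missing_rate = 0.01,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  cfg <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    mating_policy = match.arg(mating_policy),
    n_litters_per_generation = rep_len(as.integer(n_litters_per_generation), n_generations),
    litter_mean = litter_mean,
    litter_dispersion = litter_dispersion,
    n_autosomes = as.integer(n_autosomes),
    snps_per_autosome = as.integer(snps_per_autosome),
    chrom_length_morgans = rep_len(chrom_length_morgans, n_autosomes),
    chrom_length_bp = rep_len(chrom_length_bp, n_autosomes),
    founder_maf_beta = founder_maf_beta,
    monomorphic_fraction = monomorphic_fraction,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_founders >= 2, cfg$n_founders %% 2 == 0,
            cfg$n_generations >= 1,
            cfg$monomorphic_fraction >= 0, cfg$monomorphic_fraction < 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$litter_mean >= 1)
  class(cfg) <- "sim_config"
  cfg
}

.litter_size <- function(cfg) {
  1L + stats::rnbinom(1L, size = cfg$litter_dispersion, mu = cfg$litter_mean - 1)
}

#' Simulate a pedigree under a mating policy
#'
#' Builds a discrete-generation pedigree from the configured founders.
#' Candidate parents for generation g are all individuals born earlier
#' (founders keep breeding, emulating deliberately prolonged reproductive
#' careers). Policies:
#' * `full_sib_burst` - generation 1 mates the founder pairs, generation 2
#'   mates full sibs from the generation-1 litters (producing F = 0.25
#'   offspring), later generations switch to avoidance of close relatives;
#' * `avoid_close_relatives` - litters only from pairs with pedigree
#'   coancestry < 0.125 (warns and falls back to the least-related pair if
#'   none exists);
#' * `random` - any male x female pair.
#'
#' The matings actually used, with the pair's coancestry at mating time,
#' are attached as attribute `"matings"` for auditing.
#'
#' @param cfg a [sim_config()].
#' @return A [pedigree_table()]; all individuals are marked genotyped and
#'   the founders form the base population (`is_bp`).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nf <- cfg$n_founders
  ped <- data.frame(
    id = paste0("F", seq_len(nf)),
    sire = NA_character_, dam = NA_character_,
    birth_year = 2000L,
    sex = rep(c("M", "F"), length.out = nf),
    family_id = NA_character_, litter_id = NA_character_,
    generation = 0L,
    genotyped = TRUE, is_bp = TRUE,
    stringsAsFactors = FALSE
  )
  matings <- list()

  kin <- function(df) {
    A <- relationship_matrix(pedigree_table(df))
    A / 2
  }

  eligible_pairs <- function(df, K, policy, gen) {
    males <- df$id[df$sex == "M" & df$generation < gen]
    females <- df$id[df$sex == "F" & df$generation < gen]
    pairs <- expand.grid(sire = males, dam = females,
                         stringsAsFactors = FALSE)
    pairs$C <- K[cbind(pairs$sire, pairs$dam)]
    if (policy == "avoid_close_relatives") {
      ok <- pairs[pairs$C < 0.125, , drop = FALSE]
      if (!nrow(ok)) {
        warning("no pair with coancestry < 0.125; falling back to least-related pair")
        ok <- pairs[which.min(pairs$C), , drop = FALSE]
      }
      ok
    } else {
      pairs
    }
  }

  for (g in seq_len(cfg$n_generations)) {
    n_litters <- cfg$n_litters_per_generation[g]
    K <- kin(ped)
    policy <- cfg$mating_policy
    chosen <- NULL
    if (policy == "full_sib_burst" && g == 1L) {
      fpairs <- data.frame(sire = ped$id[ped$sex == "M" & ped$generation == 0L],
                           dam = ped$id[ped$sex == "F" & ped$generation == 0L],
                           stringsAsFactors = FALSE)
      chosen <- fpairs[rep_len(seq_len(nrow(fpairs)), n_litters), , drop = FALSE]
    } else if (policy == "full_sib_burst" && g == 2L) {
      sib_pairs <- do.call(rbind, lapply(split(ped[ped$generation == 1L, ],
                                               ped$litter_id[ped$generation == 1L]),
        function(l) {
          m <- l$id[l$sex == "M"]; f <- l$id[l$sex == "F"]
          if (length(m) && length(f)) {
            data.frame(sire = sample(m, 1), dam = sample(f, 1),
                       stringsAsFactors = FALSE)
          } else NULL
        }))
      if (is.null(sib_pairs) || !nrow(sib_pairs)) {
        chosen <- eligible_pairs(ped, K, "avoid_close_relatives", g)
        chosen <- chosen[sample.int(nrow(chosen), n_litters, replace = TRUE), 1:2]
      } else {
        chosen <- sib_pairs[rep_len(seq_len(nrow(sib_pairs)), n_litters), , drop = FALSE]
      }
    } else {
      eff <- if (policy == "full_sib_burst") "avoid_close_relatives" else policy
      pool <- eligible_pairs(ped, K, eff, g)
      chosen <- pool[sample.int(nrow(pool), n_litters, replace = TRUE), c("sire", "dam"), drop = FALSE]
    }
    for (li in seq_len(nrow(chosen))) {
      s <- chosen$sire[li]; d <- chosen$dam[li]
      size <- .litter_size(cfg)
      litter_id <- sprintf("L%d_%d", g, li)
      kid_ids <- sprintf("G%d_%d_%d", g, li, seq_len(size))
      ped <- rbind(ped, data.frame(
        id = kid_ids, sire = s, dam = d,
        birth_year = 2000L + g,
        sex = sample(c("M", "F"), size, replace = TRUE),
        family_id = paste(s, d, sep = "x"), litter_id = litter_id,
        generation = g, genotyped = TRUE, is_bp = FALSE,
        stringsAsFactors = FALSE))
      matings[[length(matings) + 1L]] <- data.frame(
        generation = g, sire = s, dam = d, C = K[s, d],
        stringsAsFactors = FALSE)
    }
  }
  out <- pedigree_table(ped)
  attr(out, "generation") <- stats::setNames(ped$generation, ped$id)[out$id]
  attr(out, "matings") <- do.call(rbind, matings)
  out
}

#' Drop founder alleles down a pedigree
#'
#' Gene dropping with recombination: founder reference-allele frequencies
#' are drawn from the configured Beta (a configured fraction forced
#' monomorphic), each founder receives two labelled haplotypes, and every
#' non-founder gamete is formed by a meiosis with a Poisson number of
#' crossovers (Haldane map, no interference) placed uniformly along the
#' chromosome. Because founder-haplotype labels travel with the alleles,
#' each individual's realized identity-by-descent fraction (share of SNPs
#' at which both labels coincide) is recorded exactly, genome-wide and per
#' autosome - the recovery target for every downstream estimator.
#'
#' @param ped a [pedigree_table()] (e.g. from [simulate_pedigree()]).
#' @param cfg the [sim_config()] used (provides panel and map parameters;
#'   the gene-dropping stream is seeded from `cfg$seed` independently of
#'   the pedigree stream).
#' @return List with `geno` (individuals x SNPs integer matrix, NA =
#'   missing), `map` (a [marker_map()]; `is_monomorphic_bp` flags SNPs
#'   fixed in the founders), `truth` (data frame: `id`, `ibd_genome`,
#'   one `ibd_chr<k>` column per autosome) and `founder_freq` (`p` used).
#' @export
drop_genes <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree_table"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 777L)
  nchr <- cfg$n_autosomes
  nper <- cfg$snps_per_autosome
  nsnp <- nchr * nper
  chrom <- rep(seq_len(nchr), each = nper)
  pos <- unlist(lapply(seq_len(nchr), function(c) {
    sort(sample.int(cfg$chrom_length_bp[c], nper))
  }))
  p <- stats::rbeta(nsnp, cfg$founder_maf_beta[1], cfg$founder_maf_beta[2])
  fix <- stats::runif(nsnp) < cfg$monomorphic_fraction
  p[fix] <- stats::rbinom(sum(fix), 1L, 0.5)

  founders <- ped$id[is_founder(ped)]
  nf <- length(founders)
  nh <- 2L * nf
  H <- matrix(stats::rbinom(nh * nsnp, 1L, rep(p, each = nh)), nrow = nh)
  map <- marker_map(data.frame(
    name = sprintf("SNP_%d_%d", chrom, unlist(lapply(seq_len(nchr), function(c) seq_len(nper)))),
    chrom = chrom, pos_bp = pos,
    is_monomorphic_bp = apply(H, 2, function(col) length(unique(col)) == 1L)))
  # marker_map re-sorts by (chrom, pos); our construction is already sorted

  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  pat <- matrix(0L, n, nsnp)
  mat <- matrix(0L, n, nsnp)
  chr_idx <- split(seq_len(nsnp), chrom)

  meiosis <- function(h1, h2) {
    gam <- integer(nsnp)
    for (c in seq_len(nchr)) {
      ix <- chr_idx[[c]]
      nx <- stats::rpois(1L, cfg$chrom_length_morgans[c])
      xpos <- sort(stats::runif(nx, 0, cfg$chrom_length_bp[c]))
      phase <- stats::rbinom(1L, 1L, 0.5)
      take1 <- (findInterval(pos[ix], xpos) + phase) %% 2L == 0L
      gam[ix] <- ifelse(take1, h1[ix], h2[ix])
    }
    gam
  }

  fi <- match(founders, ped$id)
  for (k in seq_along(fi)) {
    pat[fi[k], ] <- 2L * k - 1L
    mat[fi[k], ] <- 2L * k
  }
  # haplotypes of unknown single parents: unique label, alleles drawn once
  # from the founder frequencies so descendants inherit them consistently
  extraH <- list()
  for (i in seq_len(n)) {
    if (si[i] > 0L) pat[i, ] <- meiosis(pat[si[i], ], mat[si[i], ])
    if (di[i] > 0L) mat[i, ] <- meiosis(pat[di[i], ], mat[di[i], ])
    if (xor(si[i] > 0L, di[i] > 0L)) {
      lab <- nh + i
      extraH[[as.character(lab)]] <- stats::rbinom(nsnp, 1L, p)
      if (si[i] > 0L) mat[i, ] <- lab else pat[i, ] <- lab
    }
  }

  allele <- function(labrow) {
    out <- integer(nsnp)
    known <- labrow <= nh
    out[known] <- H[cbind(labrow[known], which(known))]
    if (any(!known)) {
      for (lab in unique(labrow[!known])) {
        s <- !known & labrow == lab
        out[s] <- extraH[[as.character(lab)]][s]
      }
    }
    out
  }
  geno <- matrix(NA_integer_, n, nsnp, dimnames = list(ped$id, map$name))
  gt <- ped$genotyped
  for (i in seq_len(n)) {
    g <- allele(pat[i, ]) + allele(mat[i, ])
    if (cfg$missing_rate > 0) {
      g[stats::runif(nsnp) < cfg$missing_rate] <- NA_integer_
    }
    geno[i, ] <- g
  }

  ibd <- pat == mat
  truth <- data.frame(id = ped$id,
                      ibd_genome = rowMeans(ibd),
                      stringsAsFactors = FALSE)
  for (c in seq_len(nchr)) {
    truth[[sprintf("ibd_chr%d", c)]] <- rowMeans(ibd[, chr_idx[[c]], drop = FALSE])
  }
  list(geno = geno[gt, , drop = FALSE], map = map, truth = truth,
       founder_freq = p)
}
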