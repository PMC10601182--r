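# Programmatic fixtures shared across test files.

# Random valid pedigree: each individual is a founder or has two distinct
# earlier parents (sexless; the tabular method does not need sexes).
random_pedigree <- function(n, p_founder = 0.3, seed = 1) {
  set.seed(seed)
  id <- paste0("I", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) > p_founder) {
      par <- sample(i - 1L, 2L)
      sire[i] <- id[par[1]]; dam[i] <- id[par[2]]
    }
  }
  pedigree_table(data.frame(id = id, sire = sire, dam = dam,
                            genotyped = TRUE, stringsAsFactors = FALSE))
}

# Random genotype vector + map with realistic state mixes and gap structure.
random_genotype_case <- function(seed) {
  set.seed(seed)
  n <- sample(30:200, 1)
  nchr <- sample(1:3, 1)
  chrom <- sort(sample(nchr, n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(ix) {
    # exponential gaps, occasionally exceeding the 1 Mb budget
    cumsum(ceiling(stats::rexp(length(ix), rate = 1 / 3e5)) + 1)
  }))
  p_het <- stats::runif(1, 0.02, 0.5)
  p_mis <- stats::runif(1, 0, 0.1)
  g <- sample(c(0L, 2L), n, replace = TRUE)
  g[stats::runif(n) < p_het] <- 1L
  g[stats::runif(n) < p_mis] <- NA_integer_
  map <- marker_map(data.frame(name = paste0("s", seq_len(n)),
                               chrom = chrom, pos_bp = pos))
  list(geno = g, map = map)
}

# Three-generation design used for parameter recovery: founder pairs,
# their full-sib children, and offspring of full-sib matings (F = 0.25).
fullsib_recovery_pedigree <- function(n_founder_pairs = 30, n_offspring = 17) {
  nf <- 2L * n_founder_pairs
  ids <- paste0("F", seq_len(nf))
  base <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                     family_id = NA_character_, stringsAsFactors = FALSE)
  rows <- list(base)
  for (k in seq_len(n_founder_pairs)) {
    kids <- sprintf("S%d_%d", k, 1:2)
    rows[[length(rows) + 1L]] <- data.frame(
      id = kids, sire = ids[2 * k - 1], dam = ids[2 * k],
      family_id = paste0("fam", k), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("O%d_%d", k, seq_len(n_offspring)),
      sire = kids[1], dam = kids[2],
      family_id = paste0("fam", k), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$genotyped <- TRUE
  df$is_bp <- is.na(df$sire)
  pedigree_table(df)
}

# Small S1-shaped replay sheet built from a simulated dataset (synthetic
# stand-in for a deposited per-individual table).
synthetic_s1_sheet <- function(seed = 11) {
  cfg <- sim_config(seed = seed, snps_per_autosome = 120,
                    n_litters_per_generation = c(4, 6, 8, 8),
                    litter_mean = 4, n_autosomes = 6)
  ped <- simulate_pedigree(cfg)
  sim <- drop_genes(ped, cfg)
  bp <- base_population(sim$geno, ped$id[ped$is_bp])
  roh <- detect_runs_all(sim$geno, sim$map, kind = "ROH")
  hrr <- detect_runs_all(sim$geno, sim$map, kind = "HRR")
  raw <- homozygosity_table(sim$geno, sim$map, roh, hrr, bp)
  wide <- ped[, c("id", "sire", "dam", "birth_year", "genotyped", "is_bp")]
  for (e in c("ROH", "HRR", "LH", "YAN")) {
    col <- paste0("F_", e)
    gv <- raw[raw$estimator == e & raw$scope == "genome", ]
    wide[[col]] <- gv$value[match(wide$id, gv$id)]
    for (ch in sort(unique(sim$map$chrom))) {
      cv <- raw[raw$estimator == e & raw$scope == as.character(ch), ]
      wide[[sprintf("%s_chr%d", col, ch)]] <- cv$value[match(wide$id, cv$id)]
    }
  }
  list(sheet = wide, ped = ped, raw = raw, sim = sim, bp = bp)
}
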