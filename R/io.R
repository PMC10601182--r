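#' Read PLINK-style PED/MAP genotypes
#'
#' Parses a whitespace-delimited `.ped` (six leading columns, then two
#' allele columns per SNP; `0` = missing allele) and its `.map` (chromosome,
#' SNP name, genetic position, bp position). Genotypes are recoded to
#' counts of a deterministically chosen reference allele - the
#' lexicographically smaller of the two allele labels observed at the SNP -
#' so repeated imports of the same data always produce the same coding.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @return List with `geno` (individuals x SNPs integer matrix, `NA` =
#'   missing), `map` (a [marker_map()]) and `recode` (data frame `name`,
#'   `ref`, `alt` documenting the allele coding).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               col.names = c("chrom", "name", "cm", "pos_bp"),
                               stringsAsFactors = FALSE)
  pedl <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
  nsnp <- nrow(map_raw)
  if (ncol(pedl) != 6 + 2 * nsnp) {
    stop("ragged PED: expected ", 6 + 2 * nsnp, " columns, found ", ncol(pedl))
  }
  ids <- pedl[[2]]
  a1 <- as.matrix(pedl[, 6 + 2 * seq_len(nsnp) - 1, drop = FALSE])
  a2 <- as.matrix(pedl[, 6 + 2 * seq_len(nsnp), drop = FALSE])
  geno <- matrix(NA_integer_, nrow(pedl), nsnp,
                 dimnames = list(ids, map_raw$name))
  ref <- alt <- character(nsnp)
  for (k in seq_len(nsnp)) {
    al <- c(a1[, k], a2[, k])
    obs <- sort(unique(al[al != "0"]))
    if (length(obs) > 2) stop("triallelic SNP: ", map_raw$name[k])
    ref[k] <- if (length(obs)) obs[1] else NA_character_
    alt[k] <- if (length(obs) == 2) obs[2] else NA_character_
    miss <- a1[, k] == "0" | a2[, k] == "0"
    g <- (a1[, k] == ref[k]) + (a2[, k] == ref[k])
    g[miss] <- NA_integer_
    geno[, k] <- as.integer(g)
  }
  map <- marker_map(map_raw[, c("name", "chrom", "pos_bp")])
  geno <- geno[, match(map$name, colnames(geno)), drop = FALSE]
  list(geno = geno, map = map,
       recode = data.frame(name = map$name,
                           ref = ref[match(map$name, map_raw$name)],
                           alt = alt[match(map$name, map_raw$name)],
                           stringsAsFactors = FALSE))
}

#' Write genotypes as PLINK-style PED/MAP
#'
#' Inverse of [read_ped_map()]: reference-allele counts become `A`/`B`
#' allele pairs (`A` = reference, i.e. the lexicographically smaller
#' label), missing genotypes become `0 0`.
#'
#' @param geno individuals x SNPs integer matrix.
#' @param map a [marker_map()].
#' @param ped_path,map_path output paths.
#' @param ped optional [pedigree_table()] for the family/parent columns.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(geno, map, ped_path, map_path, ped = NULL) {
  ids <- rownames(geno)
  sire <- dam <- rep("0", length(ids))
  sexc <- rep("0", length(ids))
  if (!is.null(ped)) {
    m <- match(ids, ped$id)
    sire <- ifelse(is.na(ped$sire[m]), "0", ped$sire[m])
    dam <- ifelse(is.na(ped$dam[m]), "0", ped$dam[m])
    sexc <- ifelse(is.na(ped$sex[m]), "0", ifelse(ped$sex[m] == "M", "1", "2"))
  }
  n <- nrow(geno); nsnp <- ncol(geno)
  al <- matrix("0", n, 2 * nsnp)
  for (k in seq_len(nsnp)) {
    g <- geno[, k]
    al[, 2 * k - 1] <- ifelse(is.na(g), "0", ifelse(g >= 1, "A", "B"))
    al[, 2 * k] <- ifelse(is.na(g), "0", ifelse(g == 2, "A", "B"))
  }
  out <- cbind("FAM1", ids, sire, dam, sexc, "-9", al)
  utils::write.table(out, ped_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(map$chrom, map$name, 0, map$pos_bp),
                     map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(ped_path, map_path))
}

#' Write merged regions as BED
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention; the score column carries the number of
#' contributing individuals.
#'
#' @param regions a [merge_regions()] result.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start_bp - 1, scientific = FALSE, trim = TRUE),
                    end = format(regions$end_bp, scientific = FALSE, trim = TRUE),
                    name = sprintf("region_%d", seq_len(nrow(regions))),
                    score = regions$n_individuals)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a TSV report with a manifest header
#'
#' All tabular outputs share this writer: a `#` comment line carrying the
#' package version and the digest of the run manifest, then a header row
#' and tab-separated values.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param manifest optional manifest list (see [run_manifest()]).
#' @return Invisibly, the path.
#' @export
write_report_tsv <- function(df, path, manifest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  digest <- if (is.null(manifest)) "none" else manifest$digest
  writeLines(sprintf("# autozyg %s manifest=%s",
                     as.character(utils::packageVersion("autozyg")), digest), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a run manifest
#'
#' Records what a run saw: the configuration snapshot, md5 digests of the
#' input files, package version, seed and timestamp. Identical manifests
#' (ignoring the timestamp) imply identical outputs.
#'
#' @param config list of configuration values.
#' @param inputs character vector of input file paths.
#' @param seed integer seed of the run.
#' @return List of class `run_manifest` with a `digest` field.
#' @export
run_manifest <- function(config = list(), inputs = character(0), seed = NA_integer_) {
  files <- inputs[file.exists(inputs)]
  m <- list(
    version = as.character(utils::packageVersion("autozyg")),
    seed = seed,
    config = config,
    input_digests = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  m$digest <- substr(.manifest_digest(m[c("version", "seed", "config", "input_digests")]), 1, 12)
  class(m) <- "run_manifest"
  m
}

.manifest_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path (conventionally `manifest.json` in the output
#'   directory; one manifest per output directory).
#' @return Invisibly, the path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
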