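## File interchange conventions: VCF and all TSV tables use 1-based
## positions; BED probe annotation is 0-based half-open. Conversions happen
## at these boundaries only. Genotype values always count copies of allele1
## (written as the VCF ALT allele).

#' Write a genotype matrix as VCF
#'
#' Minimal VCF 4.2 with GT fields: one biallelic record per SNP, REF =
#' allele2, ALT = allele1, genotype = number of ALT copies, missing as
#' `./.`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, path) {
  G <- genotypes$geno; map <- genotypes$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=slepipe",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(map$chrom[j], map$pos[j], map$snp_id[j],
                       map$allele2[j], map$allele1[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from VCF or genotype TSV
#'
#' VCF: biallelic records only; multi-allelic sites are rejected and
#' counted (attribute `n_multiallelic_rejected`); genotype = ALT dose;
#' mixed-ploidy GT entries are an error naming the record. TSV: the dialect
#' written by [write_genotype_tsv()] (samples as rows, SNPs as columns,
#' values 0/1/2/NA) with its sidecar map file.
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`.
#' @param map_path for TSV input, the SNP map file (default
#'   `<path>.map.tsv`).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"), map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path, map_path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    message(sprintf("rejected %d multi-allelic site(s)", n_multi))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic records in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ok <- grepl("^([01][/|][01]|\\.[/|]\\.)$", gt) | is.na(gt)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed or mixed-ploidy GT '%s' at record %s",
                 gt[!ok][1], fix$ID[bad[1]]), call. = FALSE)
  }
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  dose[gt %in% c("0/0", "0|0")] <- 0L
  dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dose[gt %in% c("1/1", "1|1")] <- 2L
  G <- t(dose)
  map <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS),
                    allele1 = fix$ALT, allele2 = fix$REF,
                    stringsAsFactors = FALSE)
  colnames(G) <- map$snp_id
  out <- structure(list(
    geno = G, map = map,
    samples = data.frame(sample_id = rownames(G), status = NA_integer_,
                         stage = NA_character_, stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
  attr(out, "n_multiallelic_rejected") <- n_multi
  out
}

#' Write a genotype matrix as TSV (plus sidecar SNP map)
#'
#' Dialect: samples as rows, SNPs as columns, values in {0, 1, 2, NA}
#' counting copies of allele1; first column `sample_id`. The SNP map
#' (`snp_id`, `chrom`, `pos` 1-based, `allele1`, `allele2`) goes to
#' `<path>.map.tsv`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes$geno),
                   genotypes$geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genotypes$map[, c("snp_id", "chrom", "pos", "allele1", "allele2")],
                     paste0(path, ".map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_genotypes_tsv <- function(path, map_path = NULL) {
  map_path <- map_path %||% paste0(path, ".map.tsv")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  bad <- !is.na(G) & !(G %in% 0:2)
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed genotype value at row %d, column %d", j[1] + 1L, j[2] + 1L),
         call. = FALSE)
  }
  rownames(G) <- df$sample_id
  structure(list(
    geno = G, map = map,
    samples = data.frame(sample_id = df$sample_id, status = NA_integer_,
                         stage = NA_character_, stringsAsFactors = FALSE)
  ), class = "genotype_matrix")
}

#' Write / read phenotype TSV
#'
#' Columns `sample_id`, `status` (1 = control, 2 = case), `stage`.
#' @param samples samples data frame.
#' @param path file path.
#' @return the path / the data frame.
#' @export
write_phenotypes <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read probe annotation as BED (0-based half-open)
#'
#' Columns: chrom, start, end, probe_id, score (0), gene_label.
#' @param probes probe annotation data frame.
#' @param path file path.
#' @return the path / the annotation data frame.
#' @export
write_probe_bed <- function(probes, path) {
  bed <- data.frame(probes$chrom, probes$start, probes$end, probes$probe_id,
                    0L, probes$gene_label)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_bed
#' @export
read_probe_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(probe_id = bed[[4]], chrom = bed[[1]], start = bed[[2]],
             end = bed[[3]], gene_label = bed[[6]], stringsAsFactors = FALSE)
}

#' Write / read an expression matrix TSV (probe x sample)
#'
#' @param expr probes x samples matrix.
#' @param path file path.
#' @return the path / the matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  m
}

#' Load the packaged table of previously reported SLE susceptibility loci
#'
#' Twenty-six loci with their published association P-values, eQTL-positivity
#' flags, and the population (European or Asian studies) each was first
#' identified in. The file checksum is verified before parsing.
#'
#' @return data frame of 26 known-locus records.
#' @export
load_known_loci <- function() {
  path <- system.file("extdata", "known_sle_loci.tsv", package = "slepipe")
  md5_path <- system.file("extdata", "known_sle_loci.md5", package = "slepipe")
  if (path == "" || md5_path == "")
    stop("packaged known-loci fixture not found", call. = FALSE)
  expected <- readLines(md5_path, warn = FALSE)[1]
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, expected))
    stop(sprintf("known-loci fixture checksum mismatch (%s != %s)",
                 actual, expected), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  df$discovered_in <- ifelse(df$discovered_caucasian, "caucasian", "asian")
  df
}

#' Load the packaged genome-wide significant GWAS loci table
#'
#' Six loci reaching genome-wide significance in the emulated study's first
#' stage, with published allele frequencies, sample sizes, odds ratios and
#' P-values — the worked-example input for [allelic_odds_ratio()].
#'
#' @return data frame of 6 records.
#' @export
load_gwas_top_loci <- function() {
  path <- system.file("extdata", "gwas_top_loci.tsv", package = "slepipe")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

#' Load the packaged staged results for the discovery SNP
#'
#' Published per-stage allele frequencies, sample sizes and statistics for
#' the discovered locus (GWAS, two replications, combined) — the
#' worked-example input for [mantel_haenszel()].
#'
#' @return data frame of 4 stage records.
#' @export
load_combined_study <- function() {
  path <- system.file("extdata", "combined_study_rs340630.tsv",
                      package = "slepipe")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

## Canonical hash of an R object (numbers rounded to 12 significant digits so
## the hash is stable across platforms' printf quirks).
canonical_hash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) return(lapply(v, canon))
    if (is.double(v)) return(signif(v, 12))
    v
  }
  digest::digest(canon(x), algo = "sha256")
}

#' Write a machine-readable run report with manifest
#'
#' Each stage output (a data frame) is written as TSV with a header comment
#' naming the producing module and the configuration hash. The manifest
#' records the configuration hash, seed, per-stage row counts and a hash of
#' all stage outputs, enabling byte-exact re-run verification. Missing
#' stages are noted, not invented.
#'
#' @param stages named list of data frames (a `NULL` entry = stage missing).
#' @param dir output directory (created if needed).
#' @param config the run configuration (hashed into the manifest).
#' @param seed master seed of the run.
#' @return the manifest, invisibly (list with `config_hash`,
#'   `manifest_hash`, `counts`, `missing_stages`).
#' @export
write_report <- function(stages, dir, config, seed) {
  if (length(stages) == 0L || all(vapply(stages, is.null, logical(1))))
    stop("at least one stage output required", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- canonical_hash(config)
  counts <- integer(0); missing <- character(0)
  for (nm in names(stages)) {
    if (is.null(stages[[nm]])) { missing <- c(missing, nm); next }
    f <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(f, "w")
    writeLines(sprintf("# module: %s\tconfig_hash: %s", nm, cfg_hash), con)
    suppressWarnings(utils::write.table(stages[[nm]], con, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    close(con)
    counts[nm] <- nrow(stages[[nm]])
  }
  manifest <- list(config_hash = cfg_hash, seed = seed, counts = as.list(counts),
                   missing_stages = missing,
                   manifest_hash = canonical_hash(
                     list(cfg_hash, seed, counts,
                          stages[!vapply(stages, is.null, logical(1))])))
  mf <- file.path(dir, "manifest.tsv")
  mdf <- data.frame(key = c("config_hash", "seed", "manifest_hash",
                            paste0("rows_", names(counts)),
                            if (length(missing)) paste0("missing_", missing)),
                    value = c(manifest$config_hash, seed, manifest$manifest_hash,
                              unname(counts),
                              if (length(missing)) rep("stage not run", length(missing))),
                    stringsAsFactors = FALSE)
  utils::write.table(mdf, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
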