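# Readers and writers for the formats the pipeline touches: intensity TSV
# (LRR or summed X+Y dialect), probe manifest TSV, CNVR BED, phenotype TSV,
# SNP dosages (TSV or VCF), and YAML pipeline configuration.  All tabular
# outputs are TSV with a header line, "NA" for missing.

AUTOSOMES <- paste0("chr", 1:22)

norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Read a probe intensity matrix
#'
#' TSV with the sample id in the first column and one probe per remaining
#' column; missing values encoded `NA`.  The `"XY"` dialect (summed allele
#' intensities) is median-centred per probe on read so both dialects share a
#' location convention.
#'
#' @param path TSV file.
#' @param dialect `"LRR"` (read as-is) or `"XY"` (median-centred per probe).
#' @return numeric samples x probes matrix with a `"dialect"` attribute.
#' @export
read_intensities <- function(path, dialect = c("LRR", "XY")) {
  dialect <- match.arg(dialect)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (anyDuplicated(names(d)[-1]))
    stop("duplicate probe columns: ",
         paste(unique(names(d)[-1][duplicated(names(d)[-1])]), collapse = ", "))
  for (j in seq_along(d)[-1]) {
    bad <- !is.na(d[[j]]) & is.na(suppressWarnings(as.numeric(d[[j]])))
    if (any(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   which(bad)[1], names(d)[j]))
  }
  X <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(d[[1]])
  if (dialect == "XY")
    X <- sweep(X, 2, apply(X, 2, stats::median, na.rm = TRUE))
  attr(X, "dialect") <- dialect
  X
}

#' Write a probe intensity matrix
#'
#' @param x samples x probes matrix.
#' @param path output TSV.
#' @export
write_intensities <- function(x, path) {
  d <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CNVR catalogue (BED)
#'
#' BED convention: 0-based half-open `[start, end)`, columns
#' chrom / start / end / name.  `one_based = TRUE` accepts a 1-based
#' inclusive catalogue and converts on read (`start - 1`).  Non-autosomal
#' rows are dropped with a message; rows with `start >= end` are an error.
#'
#' @param path BED-like file (no header, tab-separated).
#' @param one_based input coordinates are 1-based inclusive.
#' @return data.frame `chrom, start, end, cnvr_id`, sorted by chrom and
#'   start, autosomes only; attribute `"n_dropped"` counts non-autosomal
#'   rows.
#' @export
read_regions <- function(path, one_based = FALSE) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "cnvr_id"),
                         colClasses = c("character", "integer", "integer",
                                        "character"))
  if (one_based) d$start <- d$start - 1L
  if (any(d$start >= d$end))
    stop("malformed region (start >= end): ",
         d$cnvr_id[which(d$start >= d$end)[1]])
  d$chrom <- norm_chrom(d$chrom)
  auto <- d$chrom %in% AUTOSOMES
  if (any(!auto))
    message(sum(!auto), " non-autosomal region(s) dropped")
  d <- d[auto, , drop = FALSE]
  d <- d[order(match(d$chrom, AUTOSOMES), d$start), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "n_dropped") <- sum(!auto)
  d
}

#' Write a CNVR catalogue as BED
#' @param regions data.frame `chrom, start, end, cnvr_id`.
#' @param path output file.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "cnvr_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a probe manifest TSV (`probe_id, chrom, pos`)
#' @param path TSV with header.
#' @return data.frame with normalized chromosome names.
#' @export
read_probes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(d)))
  d$chrom <- norm_chrom(d$chrom)
  d
}

#' Read a phenotype/covariate table TSV
#' @param path TSV with header; must contain `sample_id`.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot("sample_id" %in% names(d))
  d$sample_id <- as.character(d$sample_id)
  d
}

#' Read SNP dosages from TSV or VCF
#'
#' TSV layout: columns `snp_id, chrom, pos, effect_allele, other_allele`
#' then one dosage column per sample.  VCF (via the `vcfR` package): the
#' `DS` FORMAT field is used when present, otherwise dosages are counted
#' from `GT` (number of ALT alleles); the effect allele is ALT.
#'
#' @param path TSV or VCF file (`.vcf` / `.vcf.gz` detected by extension).
#' @return list with `info` (data.frame `snp_id, chrom, pos, effect_allele,
#'   other_allele`) and `dosage` (SNPs x samples numeric matrix in `[0, 2]`).
#' @export
read_snp_dosages <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) return(read_snp_dosages_vcf(path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  stopifnot(all(meta_cols %in% names(d)))
  info <- d[, meta_cols]
  info$chrom <- norm_chrom(info$chrom)
  dosage <- as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE])
  storage.mode(dosage) <- "double"
  rownames(dosage) <- info$snp_id
  check_dosage_range(dosage)
  list(info = info, dosage = dosage)
}

read_snp_dosages_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-variant VCF
  info <- data.frame(snp_id = fix[, "ID"], chrom = norm_chrom(fix[, "CHROM"]),
                     pos = as.integer(fix[, "POS"]),
                     effect_allele = fix[, "ALT"], other_allele = fix[, "REF"],
                     stringsAsFactors = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- t(as.matrix(gt))
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  if (is.null(dim(ds))) ds <- t(as.matrix(ds))
  dosage <- matrix(as.numeric(ds), nrow = nrow(ds), dimnames =
                     list(info$snp_id, colnames(ds)))
  check_dosage_range(dosage)
  list(info = info, dosage = dosage)
}

check_dosage_range <- function(dosage, tol = 1e-6) {
  if (any(dosage < -tol | dosage > 2 + tol, na.rm = TRUE))
    stop("dosage outside [0, 2]")
  invisible(TRUE)
}

#' Flip a SNP dosage to the other allele
#'
#' `dosage -> 2 - dosage` with effect/other alleles swapped; any squared
#' correlation with another vector is invariant under the flip.
#'
#' @param dosage numeric dosage vector or matrix in `[0, 2]`.
#' @return flipped dosage with `effect_allele`/`other_allele` attributes
#'   swapped when present.
#' @export
allele_flip <- function(dosage) {
  out <- 2 - dosage
  ea <- attr(dosage, "effect_allele"); oa <- attr(dosage, "other_allele")
  attr(out, "effect_allele") <- oa
  attr(out, "other_allele") <- ea
  out
}

#' Read external summary statistics TSV
#'
#' Columns: `snp_id, effect_allele, other_allele, beta, se, p, n`.
#' @param path TSV with header.
#' @return data.frame.
#' @export
read_summary_stats <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("snp_id", "effect_allele", "other_allele", "beta", "se",
                  "p", "n") %in% names(d)))
  d
}

#' Write a result table as TSV with a provenance header
#'
#' Header comment lines carry the package version and the seed; missing
#' values are written `NA`.
#'
#' @param d data.frame.
#' @param path output TSV.
#' @param seed seed recorded in the header (optional).
#' @export
write_result_tsv <- function(d, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cnvgwas %s | seed=%s | %s",
                     as.character(utils::packageVersion("cnvgwas")),
                     seed, format(Sys.time(), "%Y-%m-%d")), con)
  utils::write.table(format_floats(d), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# 6 significant digits; P-values below 1e-4 in scientific notation
format_floats <- function(d) {
  for (j in seq_along(d)) {
    if (!is.numeric(d[[j]])) next
    x <- d[[j]]
    d[[j]] <- ifelse(is.na(x), NA,
                     ifelse(abs(x) < 1e-4 & x != 0,
                            formatC(x, format = "e", digits = 3),
                            formatC(signif(x, 6), format = "g", digits = 6)))
  }
  d
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields mirror [run_pipeline()]'s arguments
#'   (cohort input paths, reference cohort, thresholds, seed, out_dir).
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(noise_threshold = 0.30, pc_sd = 6, alpha = 0.05,
                   suggestive_p = 0.001, tag_r2 = 0.7, bonferroni_alpha = 0.05,
                   seed = 1)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = "pipeline_config")
}
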