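#' Construct a genotype panel
#'
#' A genotype panel holds the imputed expected-dosage matrix for one centre
#' together with per-SNP metadata: identifier, chromosome, 1-based
#' position, effect allele, other allele, and imputation info score.
#'
#' @param snps `data.frame` with columns `snp`, `chr`, `pos`, `a1` (effect
#'   allele), `a2` (other allele), `info` (imputation quality in `[0, 1]`).
#' @param dosage Numeric matrix of expected effect-allele dosages in
#'   `[0, 2]`, samples in rows, SNPs in columns; column names must match
#'   `snps$snp`, row names are sample ids.
#' @param centre_id Centre/study identifier.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(snps, dosage, centre_id = "centre1") {
  need <- c("snp", "chr", "pos", "a1", "a2", "info")
  miss <- setdiff(need, names(snps))
  if (length(miss))
    stop("snp metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(snps$snp))
    stop("duplicated SNP identifiers within panel")
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(snps))
    stop("dosage matrix has ", ncol(dosage), " columns but ", nrow(snps),
         " SNPs in metadata")
  if (ncol(dosage) > 0L) {
    if (is.null(colnames(dosage))) colnames(dosage) <- snps$snp
    if (!identical(colnames(dosage), as.character(snps$snp)))
      stop("dosage column names do not match SNP metadata order")
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 2)
      stop("dosages must lie within [0, 2]")
  }
  structure(list(snps = as.data.frame(snps), dosage = dosage,
                 centre_id = centre_id),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel `%s`: %d samples x %d SNPs\n",
              x$centre_id, nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Effect-allele frequencies of a panel
#'
#' @param panel A [genotype_panel()].
#' @return Named vector `colMeans(dosage) / 2`.
#' @export
panel_eaf <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  colMeans(panel$dosage, na.rm = TRUE) / 2
}

#' Imputation-quality and allele-frequency QC filter
#'
#' Discards SNPs with poor imputation quality (`info < min_info`) or low
#' minor-allele frequency (`MAF < min_maf`). The boundary is kept: a SNP
#' with `info` exactly 0.3 or MAF exactly 0.01 is retained. Counts removed
#' per criterion are attached as attribute `qc_counts` and reported via
#' `message()`.
#'
#' @param panel A [genotype_panel()].
#' @param min_info Minimum imputation info score, default 0.3.
#' @param min_maf Minimum minor-allele frequency, default 0.01.
#' @param verbose Emit a per-criterion message? Default `TRUE`.
#' @return The filtered `genotype_panel` (possibly with zero SNPs, with a
#'   warning).
#' @export
qc_filter <- function(panel, min_info = 0.3, min_maf = 0.01, verbose = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  eaf <- panel_eaf(panel)
  maf <- pmin(eaf, 1 - eaf)
  bad_info <- panel$snps$info < min_info
  bad_maf <- maf < min_maf
  keep <- !(bad_info | bad_maf)
  if (verbose)
    message(sprintf(
      "qc_filter [%s]: %d SNPs in, %d removed (info<%g: %d, MAF<%g: %d), %d retained",
      panel$centre_id, length(keep), sum(!keep), min_info, sum(bad_info),
      min_maf, sum(bad_maf), sum(keep)))
  if (!any(keep)) warning("no SNPs survive QC in panel ", panel$centre_id)
  out <- genotype_panel(panel$snps[keep, , drop = FALSE],
                        panel$dosage[, keep, drop = FALSE],
                        centre_id = panel$centre_id)
  attr(out, "qc_counts") <- c(n_in = length(keep), n_info = sum(bad_info),
                              n_maf = sum(bad_maf), n_out = sum(keep))
  out
}

#' Read a dosage panel from TSV
#'
#' Dialect B of the dosage interface: rows are SNPs; the first six columns
#' are `snp`, `chr`, `pos`, `a1`, `a2`, `info`, followed by one dosage
#' column per sample. Missing dosages are mean-imputed per SNP (the
#' expected-dosage convention).
#'
#' @param path TSV file path (header required).
#' @param centre_id Centre identifier recorded on the panel.
#' @return A [genotype_panel()].
#' @export
read_dosage_tsv <- function(path, centre_id = basename(path)) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("snp", "chr", "pos", "a1", "a2", "info")
  if (!all(need %in% names(tab)[1:6]))
    stop("dosage TSV must start with columns snp, chr, pos, a1, a2, info: ",
         path)
  snps <- tab[, need]
  dos <- t(as.matrix(tab[, -(1:6), drop = FALSE]))
  colnames(dos) <- snps$snp
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    na <- which(is.na(dos), arr.ind = TRUE)
    dos[na] <- mu[na[, 2L]]
  }
  genotype_panel(snps, dos, centre_id = centre_id)
}

#' Write a dosage panel to TSV
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @param digits Decimal places for dosages (default 3).
#' @return Invisibly, `path`.
#' @export
write_dosage_tsv <- function(panel, path, digits = 3) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- round(t(panel$dosage), digits)
  out <- cbind(panel$snps[, c("snp", "chr", "pos", "a1", "a2", "info")],
               as.data.frame(dos))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a dosage panel from VCF
#'
#' Dialect A of the dosage interface: a VCF whose genotype FORMAT contains
#' an expected-dosage field (default `DS`) and whose INFO column carries
#' the imputation-quality key (default `INFO`). Sites without the quality
#' key get info score `NA` and should be filtered with [qc_filter()].
#'
#' @param path VCF file path (plain or gzipped).
#' @param centre_id Centre identifier.
#' @param dosage_field FORMAT key holding the expected dosage, default
#'   `"DS"`.
#' @param info_key INFO key holding imputation quality, default `"INFO"`.
#' @return A [genotype_panel()].
#' @export
read_dosage_vcf <- function(path, centre_id = basename(path),
                            dosage_field = "DS", info_key = "INFO") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info <- vcfR::extract.info(v, element = info_key, as.numeric = TRUE)
  if (is.null(info)) info <- rep(NA_real_, nrow(fix))
  ds <- vcfR::extract.gt(v, element = dosage_field, as.numeric = TRUE)
  if (is.null(ds)) stop("VCF has no `", dosage_field, "` genotype field: ", path)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  snps <- data.frame(snp = ids, chr = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     a1 = fix[, "ALT"], a2 = fix[, "REF"],
                     info = as.numeric(info))
  dos <- t(ds)
  colnames(dos) <- snps$snp
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    na <- which(is.na(dos), arr.ind = TRUE)
    dos[na] <- mu[na[, 2L]]
  }
  genotype_panel(snps, dos, centre_id = centre_id)
}

#' Write a dosage panel as a VCF with DS genotypes
#'
#' Emits a minimal VCF 4.2 file: one line per SNP with the imputation
#' quality in the INFO column and per-sample expected dosages in a `DS`
#' FORMAT field (GT is emitted as `./.` since only dosages are stored).
#'
#' @inheritParams write_dosage_tsv
#' @param info_key INFO key used for the imputation quality, default
#'   `"INFO"`.
#' @return Invisibly, `path`.
#' @export
write_dosage_vcf <- function(panel, path, digits = 3, info_key = "INFO") {
  stopifnot(inherits(panel, "genotype_panel"))
  s <- panel$snps
  samples <- rownames(panel$dosage)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(panel$dosage)))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=onsetGWAS",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation info score\">",
            info_key),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  ds <- format(round(t(panel$dosage), digits), trim = TRUE, scientific = FALSE)
  gt <- matrix(paste0("./.:", ds), nrow = nrow(ds))
  body <- paste(
    s$chr, s$pos, s$snp, s$a2, s$a1, ".", "PASS",
    sprintf("%s=%s", info_key, format(s$info, trim = TRUE, scientific = FALSE)),
    "GT:DS",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
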