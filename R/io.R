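#' Write genotypes as a dosage TSV
#'
#' Plain tab-separated table: `sample`, `phenotype` (1 = case, 0 = control),
#' then one 0/1/2 dosage column per site (`site_1`, ...).
#'
#' @param genotypes A [genotype_data()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_genotypes()]
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_data"))
  readr::write_tsv(as_tibble(genotypes), path)
  invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a small VCFv4.2 file with one pseudo-contig (`chr1`), 1-based
#' positions, biallelic A/T records and a GT field. The ALT allele encodes
#' the minor allele (dosage counts ALT copies). Phenotype is carried in the
#' sample names (`case_1..., control_1...`), since VCF itself has no
#' phenotype field; [read_genotypes()] recovers it from those prefixes.
#'
#' @inheritParams write_dosage_tsv
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_data"))
  d <- genotypes$dosages
  ph <- genotypes$phenotype
  samples <- ifelse(ph == 1L, "case", "control")
  samples <- paste0(samples, stats::ave(ph, ph, FUN = seq_along))
  gt <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c("chr1", j, paste0("site_", j), "A", "T", ".", ".", ".", "GT",
            gt[d[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

.parse_gt <- function(gt_field, where) {
  gt <- sub(":.*$", "", gt_field)
  alleles <- strsplit(gt, "[/|]")
  bad <- lengths(alleles) != 2L | vapply(alleles, function(a) any(!a %in% c("0", "1")), logical(1))
  if (any(bad)) {
    abort(paste0("Missing or non-biallelic genotype call at ", where[which(bad)[1]], "."))
  }
  vapply(alleles, function(a) sum(a == "1"), numeric(1))
}

#' Read a genotype matrix with phenotype labels
#'
#' Reads either the dosage TSV written by [write_dosage_tsv()] (columns
#' `sample`, `phenotype`, `site_*` with values 0/1/2) or a biallelic VCF.
#' For VCF, GT fields (phased or unphased) are converted to ALT-allele
#' dosage, and any site whose pooled ALT frequency exceeds 0.5 is flipped so
#' that dosage counts the minor allele (ties kept oriented to ALT);
#' phenotype comes from `case`/`control` sample-name prefixes. Multi-allelic
#' records, missing genotypes, out-of-range dosages and missing phenotypes
#' are rejected with the offending record identified — no imputation is
#' attempted.
#'
#' @param path Input file path.
#' @param format `"dosage_tsv"` or `"vcf"`.
#' @return A [genotype_data()] object.
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    if (!"phenotype" %in% names(tab)) {
      abort("Dosage TSV must contain a `phenotype` column (1 = case, 0 = control).")
    }
    if (anyNA(tab$phenotype) || !all(tab$phenotype %in% c(0, 1))) {
      bad <- which(is.na(tab$phenotype) | !tab$phenotype %in% c(0, 1))[1]
      abort(paste0("Invalid phenotype for sample row ", bad, "."))
    }
    site_cols <- setdiff(names(tab), c("sample", "phenotype"))
    if (length(site_cols) == 0) abort("No dosage columns found.")
    d <- as.matrix(tab[site_cols])
    bad <- which(!(d %in% c(0, 1, 2)) | is.na(d))
    if (length(bad)) {
      ij <- arrayInd(bad[1], dim(d))
      abort(paste0(
        "Invalid dosage value `", d[bad[1]], "` for sample row ", ij[1],
        ", column `", site_cols[ij[2]], "`: dosages must be 0, 1 or 2."
      ))
    }
    return(genotype_data(d, tab$phenotype))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt)
  if (any(multi)) {
    abort(paste0(
      "Multi-allelic record at ", vcfR::getCHROM(vcf)[multi][1], ":",
      vcfR::getPOS(vcf)[multi][1], "; only biallelic sites are supported."
    ))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  ph <- dplyr::case_when(
    grepl("^case", samples, ignore.case = TRUE) ~ 1L,
    grepl("^control", samples, ignore.case = TRUE) ~ 0L,
    TRUE ~ NA_integer_
  )
  if (anyNA(ph)) {
    abort(paste0(
      "Cannot infer phenotype for sample `", samples[which(is.na(ph))[1]],
      "`: VCF sample names must start with `case` or `control`."
    ))
  }
  m <- nrow(gt)
  d <- matrix(0L, length(samples), m)
  pos <- vcfR::getPOS(vcf)
  for (i in seq_len(m)) {
    d[, i] <- .parse_gt(gt[i, ], paste0("record chr", ":", pos[i], " sample ", samples))
  }
  # orient to the minor allele from the pooled sample; ties stay on ALT
  flip <- colMeans(d) / 2 > 0.5
  d[, flip] <- 2L - d[, flip]
  genotype_data(d, ph)
}
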