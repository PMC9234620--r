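#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.x, GT field) into a [geno_matrix()]. Only biallelic SNP
#' records are accepted; dosage is coded against the VCF REF allele
#' (0 = hom REF). Missing calls (`./.` or `.`) become `NA`. Sample
#' metadata (population, cohort year) can be joined from a sidecar TSV,
#' since VCF does not encode them natively.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param sample_table optional path to a TSV with columns
#'   `sample_id`, `population`, `cohort_year`.
#' @return a `geno_matrix`.
#' @export
read_vcf <- function(path, sample_table = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multiallelic record(s) not supported: ",
         paste(utils::head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 3),
               collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  # tolerate phased separators; count ALT alleles
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    bad <- !is.na(x) & !x %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
    if (any(bad)) stop("unparseable GT value(s): ",
                       paste(utils::head(unique(x[bad]), 3), collapse = ", "))
    out
  }
  dosage <- t(apply(gt, 1, code))            # loci x samples -> transpose
  dosage <- t(matrix(dosage, nrow = nrow(fix)))
  loci <- data.frame(chrom = fix$CHROM,
                     pos_bp = as.integer(fix$POS),
                     snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, ":", fix$POS), fix$ID),
                     ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  if (!is.null(sample_table)) samples <- join_sample_meta(samples, sample_table)
  geno_matrix(dosage, loci, samples)
}

join_sample_meta <- function(samples, sample_table) {
  meta <- utils::read.table(sample_table, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(meta))
  idx <- match(samples$sample_id, meta$sample_id)
  if (anyNA(idx))
    warning("no metadata for sample(s): ",
            paste(samples$sample_id[is.na(idx)], collapse = ", "))
  samples$population <- meta$population[idx]
  samples$cohort_year <- as.integer(meta$cohort_year[idx])
  samples
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF v4.2 with the GT field only, suitable for interchange and
#' round-tripping with [read_vcf()].
#'
#' @param g a `geno_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  loci <- g$loci
  ref <- if ("ref" %in% names(loci)) loci$ref else rep("A", nrow(loci))
  alt <- if ("alt" %in% names(loci)) loci$alt else rep("G", nrow(loci))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- g$dosage
  body <- vapply(seq_len(ncol(d)), function(j) {
    gts <- ifelse(is.na(d[, j]), "./.", gt_code[as.character(d[, j])])
    paste(c(loci$chrom[j], loci$pos_bp[j], loci$snp_id[j], ref[j], alt[j],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples$sample_id), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the sample-metadata sidecar TSV
#'
#' @param g a `geno_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(g, path) {
  utils::write.table(g$samples[, c("sample_id", "population", "cohort_year")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
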