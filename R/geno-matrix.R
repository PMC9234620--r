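#' Construct a genotype matrix
#'
#' The in-memory genotype model shared by every estimator in the package:
#' a samples x loci matrix of diploid allele dosages (0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, `NA` = missing),
#' with a locus map and per-sample metadata. Loci are re-sorted on
#' construction so that chromosomes form contiguous blocks and positions
#' increase strictly within each chromosome; sorted maps are a precondition
#' for ROH calling and LD pruning.
#'
#' @param dosage integer matrix, samples in rows, loci in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param loci data.frame with columns `chrom`, `pos_bp` (1-based), and
#'   optionally `snp_id`, `ref`, `alt`.
#' @param samples data.frame with column `sample_id` (unique) and optionally
#'   `population`, `cohort_year`.
#' @return An object of class `geno_matrix`: a list with elements `dosage`,
#'   `loci`, `samples`.
#' @export
geno_matrix <- function(dosage, loci, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos_bp") %in% names(loci)),
            "sample_id" %in% names(samples))
  if (nrow(dosage) != nrow(samples))
    stop("dosage rows (", nrow(dosage), ") != samples (", nrow(samples), ")")
  if (ncol(dosage) != nrow(loci))
    stop("dosage columns (", ncol(dosage), ") != loci (", nrow(loci), ")")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (any(loci$pos_bp < 1L)) stop("pos_bp must be >= 1")
  if (!"snp_id" %in% names(loci))
    loci$snp_id <- paste0(loci$chrom, ":", loci$pos_bp)
  if (!"population" %in% names(samples)) samples$population <- NA_character_
  if (!"cohort_year" %in% names(samples)) samples$cohort_year <- NA_integer_

  ord <- order(chrom_rank(loci$chrom), loci$pos_bp)
  if (is.unsorted(ord) && any(ord != seq_along(ord))) {
    warning("loci not sorted by (chrom, pos_bp); sorting")
  }
  loci <- loci[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  dup <- duplicated(paste(loci$chrom, loci$pos_bp))
  if (any(dup))
    stop("duplicate locus positions: ",
         paste(utils::head(loci$snp_id[dup], 3), collapse = ", "))
  rownames(loci) <- NULL
  rownames(samples) <- NULL
  dimnames(dosage) <- list(samples$sample_id, loci$snp_id)
  structure(list(dosage = dosage, loci = loci, samples = samples),
            class = "geno_matrix")
}

# order chromosomes numerically when every label parses as a number,
# lexicographically otherwise; keeps "2" before "10"
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  if (!anyNA(num)) num else match(chrom, sort(unique(as.character(chrom))))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage), "loci on",
      length(unique(x$loci$chrom)), "chromosomes\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  if (!all(is.na(x$samples$population))) {
    tab <- table(x$samples$population, x$samples$cohort_year, useNA = "ifany")
    print(tab)
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Number of samples / loci
#' @param g a `geno_matrix`
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_loci <- function(g) ncol(g$dosage)

#' Subset a genotype matrix
#'
#' @param g a `geno_matrix`.
#' @param samples sample selector: logical/integer index, or character
#'   vector of `sample_id`s. `NULL` keeps all.
#' @param loci locus selector: logical/integer index. `NULL` keeps all.
#' @return a `geno_matrix`.
#' @export
subset_geno <- function(g, samples = NULL, loci = NULL) {
  si <- resolve_samples(g, samples)
  li <- if (is.null(loci)) seq_len(n_loci(g)) else seq_len(n_loci(g))[loci]
  geno_matrix(g$dosage[si, li, drop = FALSE],
              g$loci[li, , drop = FALSE],
              g$samples[si, , drop = FALSE])
}

resolve_samples <- function(g, samples) {
  if (is.null(samples)) return(seq_len(n_samples(g)))
  if (is.character(samples)) {
    idx <- match(samples, g$samples$sample_id)
    if (anyNA(idx))
      stop("unknown sample ids: ",
           paste(samples[is.na(idx)], collapse = ", "))
    return(idx)
  }
  seq_len(n_samples(g))[samples]
}

#' Select samples belonging to a population cohort
#'
#' @param g a `geno_matrix`.
#' @param population population label, or `NULL` for any.
#' @param cohort_year sampling year, or `NULL` for any.
#' @return integer indices into the sample dimension.
#' @export
cohort_index <- function(g, population = NULL, cohort_year = NULL) {
  keep <- rep(TRUE, n_samples(g))
  if (!is.null(population)) keep <- keep & g$samples$population %in% population
  if (!is.null(cohort_year)) keep <- keep & g$samples$cohort_year %in% cohort_year
  which(keep)
}

#' Per-locus reference-allele frequencies
#'
#' Frequency of the reference allele computed from dosages with pairwise
#' deletion of missing calls: `p = (2 n_homref + n_het) / (2 n_nonmissing)`.
#' Feeds the F^III estimator, IBD expectations, HMM emissions, F_ST and
#' allele-frequency-change diagnostics.
#'
#' @param g a `geno_matrix`.
#' @param subset optional sample selector (see [subset_geno()]).
#' @return numeric vector of length `n_loci(g)`; `NaN` where a locus has no
#'   non-missing call in the subset.
#' @export
allele_frequencies <- function(g, subset = NULL) {
  si <- resolve_samples(g, subset)
  if (length(si) == 0L) stop("empty sample subset")
  d <- g$dosage[si, , drop = FALSE]
  n_called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  p <- 1 - alt / (2 * n_called)   # NaN when n_called == 0
  unname(p)
}

#' Swap reference and alternate allele coding at selected loci
#'
#' Dosages map `x -> 2 - x`; ref/alt labels swap. Used by the
#' allele-order-covariance property tests: every downstream statistic in the
#' package is invariant under this relabelling.
#'
#' @param g a `geno_matrix`.
#' @param loci logical or integer locus selector; default all.
#' @return a `geno_matrix` with flipped coding.
#' @export
swap_alleles <- function(g, loci = NULL) {
  li <- if (is.null(loci)) seq_len(n_loci(g)) else seq_len(n_loci(g))[loci]
  d <- g$dosage
  d[, li] <- 2L - d[, li]
  out <- g
  out$dosage <- d
  if (all(c("ref", "alt") %in% names(out$loci))) {
    tmp <- out$loci$ref[li]
    out$loci$ref[li] <- out$loci$alt[li]
    out$loci$alt[li] <- tmp
  }
  out
}
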