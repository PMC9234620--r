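#' Identity-by-state counts for one pair
#'
#' Over loci called in both individuals: IBS2 when dosages are equal, IBS0
#' when they are opposite homozygotes, IBS1 otherwise.
#'
#' @param x,y dosage vectors of equal length.
#' @return named integer vector `(n_ibs0, n_ibs1, n_ibs2)`.
#' @export
ibs_counts <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no loci called in both individuals")
  x <- x[ok]; y <- y[ok]
  n2 <- sum(x == y)
  n0 <- sum(abs(x - y) == 2L)
  c(n_ibs0 = n0, n_ibs1 = length(x) - n0 - n2, n_ibs2 = n2)
}

# expected per-locus IBS-state probabilities conditional on IBD state
# under HWE, as functions of the reference frequency p (PLINK --genome
# method of moments, without the finite-sample bias corrections)
ibd_expectations <- function(p) {
  q <- 1 - p
  list(e0_i0 = 2 * p^2 * q^2,
       e1_i0 = 4 * p^3 * q + 4 * p * q^3,
       e2_i0 = p^4 + q^4 + 4 * p^2 * q^2,
       e1_i1 = 2 * p^2 * q + 2 * p * q^2,   # = 2pq
       e2_i1 = 1 - (2 * p^2 * q + 2 * p * q^2))
}

#' Method-of-moments pairwise IBD estimate
#'
#' PLINK `--genome`-style estimator: observed genome-wide IBS0/1/2 counts
#' are equated to their expectations under HWE given allele frequencies,
#' solved sequentially for the probabilities Z0, Z1, Z2 that a random locus
#' shares 0, 1 or 2 alleles identical by descent. Negative solutions are
#' truncated to zero and the triple renormalized;
#' `PI_HAT = Z2 + Z1/2`. Loci fixed in the frequency reference or missing
#' in either individual are excluded.
#'
#' @param x,y dosage vectors.
#' @param freqs per-locus reference-allele frequencies.
#' @param min_loci minimum usable shared loci (default 500).
#' @return named numeric vector `(z0, z1, z2, pi_hat, n_loci)`.
#' @export
estimate_ibd <- function(x, y, freqs, min_loci = 500L) {
  stopifnot(length(x) == length(y), length(freqs) == length(x))
  ok <- !is.na(x) & !is.na(y) & is.finite(freqs) & freqs > 0 & freqs < 1
  if (sum(ok) < min_loci)
    stop("only ", sum(ok), " usable shared loci (need ", min_loci, ")")
  x <- x[ok]; y <- y[ok]; p <- freqs[ok]
  nl <- length(x)
  ibs2 <- x == y
  ibs0 <- abs(x - y) == 2L
  n0 <- sum(ibs0); n2 <- sum(ibs2); n1 <- nl - n0 - n2
  e <- ibd_expectations(p)
  z0 <- n0 / sum(e$e0_i0)
  z1 <- (n1 - z0 * sum(e$e1_i0)) / sum(e$e1_i1)
  z2 <- (n2 - z0 * sum(e$e2_i0) - z1 * sum(e$e2_i1)) / nl
  z <- pmax(c(z0, z1, z2), 0)
  z <- z / sum(z)
  c(z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = z[3] + z[2] / 2, n_loci = nl)
}

#' Pairwise IBD estimates for a set of pairs
#'
#' @param g a `geno_matrix`.
#' @param pairs two-column matrix/data.frame of sample ids (or indices);
#'   `NULL` means all unordered pairs in `g`.
#' @param freqs per-locus frequencies; defaults to pooled sample
#'   frequencies of `g`.
#' @param min_loci passed to [estimate_ibd()].
#' @return data.frame: `id_a`, `id_b` (canonically ordered `id_a < id_b`),
#'   `z0`, `z1`, `z2`, `pi_hat`, `n_loci`, `class`.
#' @export
ibd_pairs <- function(g, pairs = NULL, freqs = NULL, min_loci = 500L) {
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  ids <- g$samples$sample_id
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2))
  }
  pairs <- as.matrix(pairs)
  if (is.numeric(pairs)) pairs <- matrix(ids[pairs], ncol = 2)
  swap <- pairs[, 1] > pairs[, 2]
  pairs[swap, ] <- pairs[swap, 2:1]
  ia <- match(pairs[, 1], ids); ib <- match(pairs[, 2], ids)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id in pairs")
  est <- t(vapply(seq_len(nrow(pairs)), function(k)
    estimate_ibd(g$dosage[ia[k], ], g$dosage[ib[k], ], freqs, min_loci),
    numeric(5)))
  out <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                    est, stringsAsFactors = FALSE)
  out$class <- classify_pair(out$pi_hat)
  out
}

#' Relationship class from PI_HAT
#'
#' Pedigree-calibrated bins, lower-bound inclusive: `HIGH` (PI_HAT >= 0.40;
#' parent-offspring and full siblings), `MODERATE` ([0.18, 0.40); half
#' sibling, avuncular, grandparent-grandchild), `COUSIN` ([0.09, 0.18);
#' first cousins — 0.09 is the lower end of PI_HAT observed for known
#' first cousins), `UNRELATED` (< 0.09).
#'
#' @param pi_hat numeric vector of PI_HAT values.
#' @return character vector of class labels.
#' @export
classify_pair <- function(pi_hat) {
  ifelse(pi_hat >= 0.40, "HIGH",
         ifelse(pi_hat >= 0.18, "MODERATE",
                ifelse(pi_hat >= 0.09, "COUSIN", "UNRELATED")))
}

#' Within- or between-group relatedness summary
#'
#' Within mode: all unordered pairs inside one group. Between mode: the
#' full bipartite set of one member from each group (all possible draws of
#' one bird from each subpopulation).
#'
#' @param g a `geno_matrix`.
#' @param group_a,group_b lists with elements `population` and
#'   `cohort_year` selecting each group (`group_b` ignored in within mode).
#' @param mode `"within"` or `"between"`.
#' @param freqs,min_loci passed to [ibd_pairs()].
#' @return a list: `estimates` (per-pair data.frame), `mean_pi_hat`,
#'   `n_pairs`, `prop_related` (PI_HAT >= 0.09), `class_proportions`.
#' @export
group_relatedness <- function(g, group_a, group_b = NULL,
                              mode = c("within", "between"),
                              freqs = NULL, min_loci = 500L) {
  mode <- match.arg(mode)
  ia <- cohort_index(g, group_a$population, group_a$cohort_year)
  if (mode == "within") {
    if (length(ia) < 2) stop("within-group mode needs >= 2 samples")
    pairs <- t(utils::combn(g$samples$sample_id[ia], 2))
  } else {
    ib <- cohort_index(g, group_b$population, group_b$cohort_year)
    if (length(intersect(ia, ib))) stop("groups overlap")
    pairs <- as.matrix(expand.grid(a = g$samples$sample_id[ia],
                                   b = g$samples$sample_id[ib],
                                   stringsAsFactors = FALSE))
  }
  est <- ibd_pairs(g, pairs, freqs, min_loci)
  cls <- factor(est$class, levels = c("HIGH", "MODERATE", "COUSIN",
                                      "UNRELATED"))
  list(estimates = est,
       mean_pi_hat = mean(est$pi_hat),
       se_pi_hat = stats::sd(est$pi_hat) / sqrt(nrow(est)),
       n_pairs = nrow(est),
       prop_related = mean(est$pi_hat >= 0.09),
       class_proportions = prop.table(table(cls)))
}
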