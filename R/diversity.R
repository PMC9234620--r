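#' Per-individual site-based heterozygosity
#'
#' Fraction of an individual's genotyped loci that are heterozygous.
#' This is array heterozygosity at known SNP sites, not per-nucleotide
#' genome heterozygosity.
#'
#' @param g a `geno_matrix`.
#' @return data.frame with `sample_id`, `het_obs`, `n_loci_used`; `het_obs`
#'   is `NaN` for an individual with no called genotypes.
#' @export
site_heterozygosity <- function(g) {
  if (n_loci(g) == 0L) stop("empty panel")
  d <- g$dosage
  n_called <- rowSums(!is.na(d))
  n_het <- rowSums(d == 1L, na.rm = TRUE)
  data.frame(sample_id = g$samples$sample_id,
             het_obs = n_het / n_called,
             n_loci_used = n_called,
             stringsAsFactors = FALSE)
}

#' Moment-based inbreeding coefficient F^III
#'
#' The third of the moment estimators popularised by GCTA/PLINK (`--ibc`
#' Fhat3): for individual i with dosage x at a locus with reference-allele
#' frequency p,
#' \deqn{f_i = mean_j [x^2 - (1+2p)x + 2p^2] / (2p(1-p))}
#' over loci where p is in (0,1) and x is called. Negative values indicate
#' heterozygosity in excess of Hardy-Weinberg expectation. The per-locus
#' term is symmetric under allele relabelling (x -> 2-x, p -> 1-p).
#'
#' @param g a `geno_matrix`.
#' @param freqs per-locus reference-allele frequencies; defaults to the
#'   pooled frequencies of all samples in `g`.
#' @return data.frame with `sample_id`, `f3`, `n_loci_used`.
#' @export
fhat3 <- function(g, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  stopifnot(length(freqs) == n_loci(g))
  usable <- is.finite(freqs) & freqs > 0 & freqs < 1
  d <- g$dosage[, usable, drop = FALSE]
  # dosage counts the alternate allele, so the formula takes the
  # alternate-allele frequency; the term is symmetric under the joint
  # swap (x -> 2-x, p -> 1-p), which makes f3 allele-order invariant
  p <- 1 - freqs[usable]
  denom <- 2 * p * (1 - p)
  t0 <- (0 - (1 + 2 * p) * 0 + 2 * p^2) / denom    # x = 0
  t1 <- (1 - (1 + 2 * p) * 1 + 2 * p^2) / denom    # x = 1 (identically -1)
  t2 <- (4 - (1 + 2 * p) * 2 + 2 * p^2) / denom    # x = 2
  n <- nrow(d)
  f3 <- numeric(n); used <- integer(n)
  for (i in seq_len(n)) {
    x <- d[i, ]
    ok <- !is.na(x)
    used[i] <- sum(ok)
    terms <- ifelse(x[ok] == 0L, t0[ok], ifelse(x[ok] == 1L, t1[ok], t2[ok]))
    f3[i] <- if (used[i]) mean(terms) else NaN
  }
  data.frame(sample_id = g$samples$sample_id, f3 = f3, n_loci_used = used,
             stringsAsFactors = FALSE)
}

#' Marker-covered genome length
#'
#' Denominator for F_ROH on a sparse array: the sum over chromosomes of
#' (last marker position - first marker position). With sparse panels this
#' is preferred over assembly length, which would deflate F_ROH
#' non-comparably.
#'
#' @param g a `geno_matrix`.
#' @return total covered length in bp.
#' @export
covered_genome_bp <- function(g) {
  sum(tapply(g$loci$pos_bp, g$loci$chrom,
             function(x) max(x) - min(x)))
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Fraction of the marker-covered autosome lying inside called runs of
#' homozygosity, per individual.
#'
#' @param segments a data.frame of ROH segments (as returned by the
#'   callers) for any set of individuals.
#' @param covered_bp covered genome length in bp ([covered_genome_bp()]).
#' @param sample_ids individuals to report (so that individuals with no
#'   segments get F_ROH = 0); defaults to those present in `segments`.
#' @return data.frame with `sample_id`, `f_roh`.
#' @export
f_roh <- function(segments, covered_bp, sample_ids = NULL) {
  stopifnot(covered_bp > 0)
  if (nrow(segments)) {
    sp <- split(segments, list(segments$sample_id, segments$chrom),
                drop = TRUE)
    for (s in sp) {
      if (nrow(s) < 2) next
      o <- order(s$start_bp)
      if (any(s$start_bp[o][-1] < s$end_bp[o][-nrow(s)]))
        stop("overlapping ROH segments for ", s$sample_id[1],
             " on chromosome ", s$chrom[1])
    }
  }
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  tot <- tapply(segments$length_bp, segments$sample_id, sum)
  val <- as.numeric(tot[match(sample_ids, names(tot))])
  val[is.na(val)] <- 0
  data.frame(sample_id = sample_ids, f_roh = val / covered_bp,
             stringsAsFactors = FALSE)
}

#' Allele-frequency change between two cohorts of one population
#'
#' Per-locus change p(year2) - p(year1) within a population, with the
#' across-locus sample variance — the drift signal compared between the
#' stable and declining subpopulations.
#'
#' @param g a `geno_matrix`.
#' @param population population label.
#' @param year1,year2 cohort years.
#' @return a list of class `pop_delta_p`: `population`, `delta_p` (per-locus
#'   vector, `NA` where a cohort is untyped), `var_delta_p`,
#'   `n_loci_excluded`.
#' @export
delta_p <- function(g, population, year1, year2) {
  i1 <- cohort_index(g, population, year1)
  i2 <- cohort_index(g, population, year2)
  if (!length(i1) || !length(i2))
    stop("empty cohort for ", population, " in ", year1, " or ", year2)
  p1 <- allele_frequencies(g, i1)
  p2 <- allele_frequencies(g, i2)
  dp <- p2 - p1
  excl <- !is.finite(dp)
  dp[excl] <- NA_real_
  structure(list(population = population,
                 delta_p = dp,
                 var_delta_p = stats::var(dp, na.rm = TRUE),
                 n_loci_excluded = sum(excl)),
            class = "pop_delta_p")
}

#' Weir-Cockerham F_ST between two populations
#'
#' Multi-locus ratio-of-averages theta (Weir & Cockerham 1984) over all
#' loci polymorphic in the pooled pair of populations, from genotype
#' counts (two populations, diploid, biallelic). A Hudson-style estimator
#' is available as a cross-check.
#'
#' @param g a `geno_matrix`.
#' @param pop_a,pop_b population labels (all cohort years pooled unless
#'   `year` given).
#' @param year optional cohort year restriction.
#' @param method `"wc"` (Weir-Cockerham, default) or `"hudson"`.
#' @return F_ST estimate (scalar); `NaN` if the panel is monomorphic.
#' @export
fst_weir_cockerham <- function(g, pop_a, pop_b, year = NULL,
                               method = c("wc", "hudson")) {
  method <- match.arg(method)
  ia <- cohort_index(g, pop_a, year)
  ib <- cohort_index(g, pop_b, year)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 samples per population")
  da <- g$dosage[ia, , drop = FALSE]
  db <- g$dosage[ib, , drop = FALSE]
  na <- colSums(!is.na(da)); nb <- colSums(!is.na(db))
  pa <- 1 - colSums(da, na.rm = TRUE) / (2 * na)
  pb <- 1 - colSums(db, na.rm = TRUE) / (2 * nb)
  ha <- colMeans(da == 1L, na.rm = TRUE)    # observed het fractions
  hb <- colMeans(db == 1L, na.rm = TRUE)
  ok <- na >= 2 & nb >= 2 & is.finite(pa) & is.finite(pb)
  pool <- (2 * na * pa + 2 * nb * pb) / (2 * (na + nb))
  poly <- ok & pool > 0 & pool < 1
  if (!any(poly)) return(NaN)
  na <- na[poly]; nb <- nb[poly]; pa <- pa[poly]; pb <- pb[poly]
  ha <- ha[poly]; hb <- hb[poly]
  if (method == "hudson") {
    # Hudson/Bhatia ratio of averages: num = (pa-pb)^2 - pa(1-pa)/(na2-1)
    #   - pb(1-pb)/(nb2-1); den = pa(1-pb) + pb(1-pa), with allele counts
    na2 <- 2 * na; nb2 <- 2 * nb
    num <- (pa - pb)^2 - pa * (1 - pa) / (na2 - 1) - pb * (1 - pb) / (nb2 - 1)
    den <- pa * (1 - pb) + pb * (1 - pa)
    return(sum(num) / sum(den))
  }
  r <- 2
  n_bar <- (na + nb) / r
  nc <- (r * n_bar - (na^2 + nb^2) / (r * n_bar)) / (r - 1)
  p_bar <- (na * pa + nb * pb) / (r * n_bar)
  s2 <- (na * (pa - p_bar)^2 + nb * (pb - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (na * ha + nb * hb) / (r * n_bar)
  a <- n_bar / nc *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  sum(a) / sum(a + b + cc)
}
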