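#' QC configuration
#'
#' Thresholds for the marker/individual quality-control pipeline:
#' SNP call rate, individual call rate, Hardy-Weinberg screening,
#' sex-chromosome exclusion, and PLINK-style `--indep-pairwise`
#' LD pruning.
#'
#' @param min_snp_call_rate minimum fraction of non-missing calls per SNP.
#' @param min_ind_call_rate minimum fraction of non-missing calls per
#'   individual (applied after the SNP filter).
#' @param hwe_alpha exact-test p-value threshold below which a SNP is
#'   dropped.
#' @param ld_window_snps,ld_step_snps,ld_r2_max greedy windowed LD-pruning
#'   parameters (window size in SNPs, step in SNPs, maximum pairwise r^2).
#' @param exclude_chroms chromosome labels removed before pruning
#'   (e.g. `"Z"`).
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(min_snp_call_rate = 0.95, min_ind_call_rate = 0.95,
                      hwe_alpha = 1e-6, ld_window_snps = 50L,
                      ld_step_snps = 5L, ld_r2_max = 0.2,
                      exclude_chroms = "Z") {
  stopifnot(min_snp_call_rate > 0, min_snp_call_rate <= 1,
            min_ind_call_rate > 0, min_ind_call_rate <= 1,
            ld_step_snps <= ld_window_snps,
            ld_r2_max >= 0, ld_r2_max <= 1)
  structure(list(min_snp_call_rate = min_snp_call_rate,
                 min_ind_call_rate = min_ind_call_rate,
                 hwe_alpha = hwe_alpha,
                 ld_window_snps = as.integer(ld_window_snps),
                 ld_step_snps = as.integer(ld_step_snps),
                 ld_r2_max = ld_r2_max,
                 exclude_chroms = exclude_chroms),
            class = "qc_config")
}

#' Filter loci and samples on call rate
#'
#' Within each round, loci below the SNP call-rate threshold are removed
#' first, then samples below the individual call-rate threshold
#' (recomputed on the surviving loci). Because removing a sample can push
#' a borderline locus back under its threshold, rounds repeat until
#' nothing more is removed, so the filter is a fixpoint: re-running it on
#' its own output is a no-op. Drop order is recorded in the report.
#'
#' @param g a `geno_matrix`.
#' @param cfg a [qc_config()].
#' @return a list: `g` (filtered matrix), `dropped_loci` (snp ids, in drop
#'   order), `dropped_samples` (sample ids, in drop order).
#' @export
filter_call_rate <- function(g, cfg = qc_config()) {
  dropped_loci <- character(0)
  dropped_samples <- character(0)
  repeat {
    snp_cr <- colMeans(!is.na(g$dosage))
    keep_l <- snp_cr >= cfg$min_snp_call_rate
    if (!any(keep_l)) stop("empty panel: all loci fail the call-rate filter")
    dropped_loci <- c(dropped_loci, g$loci$snp_id[!keep_l])
    g <- subset_geno(g, loci = keep_l)
    ind_cr <- rowMeans(!is.na(g$dosage))
    keep_s <- ind_cr >= cfg$min_ind_call_rate
    if (!any(keep_s))
      stop("empty panel: all samples fail the call-rate filter")
    dropped_samples <- c(dropped_samples, g$samples$sample_id[!keep_s])
    g <- subset_geno(g, samples = keep_s)
    if (all(keep_l) && all(keep_s)) break
  }
  list(g = g, dropped_loci = dropped_loci,
       dropped_samples = dropped_samples)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test on genotype counts at one biallelic
#' locus: given the observed allele counts, the p-value sums the
#' probabilities of all heterozygote counts (same parity) whose conditional
#' probability does not exceed that of the observed count. Computed by the
#' standard recurrence on the heterozygote-count distribution; monomorphic
#' loci return 1 by convention.
#'
#' @param n_het,n_homref,n_homalt genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_pvalue <- function(n_het, n_homref, n_homalt) {
  stopifnot(n_het >= 0, n_homref >= 0, n_homalt >= 0)
  n <- n_het + n_homref + n_homalt
  if (n < 1) stop("no genotypes")
  n_a <- 2 * min(n_homref, n_homalt) + n_het     # rarer-allele count
  if (n_a == 0) return(1.0)
  # heterozygote counts share the parity of the rarer-allele count
  hets <- seq(n_a %% 2, n_a, by = 2)
  probs <- numeric(length(hets))
  # recurrence on P(het = h | n, n_a):
  # P(h+2)/P(h) = 4 * n_rr(h) * n_cc(h) / ((h+2)*(h+1))
  # with n_rr = (n_a - h)/2 rare homs, n_cc = (n - h - n_rr) common homs
  probs[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    n_rr <- (n_a - h) / 2
    n_cc <- n - h - n_rr
    probs[k] <- probs[k - 1] * 4 * n_rr * n_cc / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  p <- sum(probs[probs <= probs[obs] * (1 + 1e-12)])
  min(p, 1.0)
}

#' Per-locus HWE screen
#'
#' @param g a `geno_matrix`.
#' @param subset optional sample selector over which genotype counts are
#'   taken (default: all samples pooled).
#' @return numeric vector of exact p-values (`NA` for untyped loci).
#' @export
hwe_scan <- function(g, subset = NULL) {
  si <- resolve_samples(g, subset)
  d <- g$dosage[si, , drop = FALSE]
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_pvalue(sum(x == 1L), sum(x == 0L), sum(x == 2L))
  }, numeric(1))
}

#' Greedy windowed LD pruning
#'
#' PLINK `--indep-pairwise`-style pruning on dosage correlation: within
#' each window of `ld_window_snps` kept SNPs, while any kept pair has
#' squared correlation above `ld_r2_max`, the member of the worst offending
#' pair with the lower minor-allele frequency is removed (ties: the later
#' locus); the window then advances by `ld_step_snps` SNPs. r^2 uses
#' pairwise deletion of missing calls; monomorphic loci (undefined r) are
#' never tested and always kept.
#'
#' @param g a `geno_matrix` (loci sorted; enforced by the class).
#' @param cfg a [qc_config()].
#' @return integer vector of kept locus indices (into `g$loci`).
#' @export
ld_prune <- function(g, cfg = qc_config()) {
  keep <- rep(TRUE, n_loci(g))
  # MAF from integer allele counts so the value is bit-identical under
  # ref/alt relabelling (pruning must be allele-order covariant)
  n_called <- colSums(!is.na(g$dosage))
  alt <- colSums(g$dosage, na.rm = TRUE)
  maf <- pmin(alt, 2 * n_called - alt) / (2 * n_called)
  d <- g$dosage
  for (chrom in unique(g$loci$chrom)) {
    idx <- which(g$loci$chrom == chrom)
    repeat {   # sweep the chromosome until a full pass removes nothing,
               # so pruning is a fixpoint and the pipeline is idempotent
      removed_this_sweep <- FALSE
      start <- 1L
      repeat {
      win_pool <- idx[keep[idx]]
      if (start > length(win_pool)) break
      win <- win_pool[seq(start, min(start + cfg$ld_window_snps - 1L,
                                     length(win_pool)))]
      if (length(win) >= 2L) {
        repeat {
          wk <- win[keep[win]]
          if (length(wk) < 2L) break
          r2 <- pairwise_r2_int(d[, wk, drop = FALSE])
          diag(r2) <- 0
          mx <- max(r2)
          if (mx <= cfg$ld_r2_max) break
          hit <- which(r2 == mx, arr.ind = TRUE)[1, ]
          a <- wk[hit[1]]; b <- wk[hit[2]]
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else max(a, b)              # tie: remove the later locus
          keep[drop] <- FALSE
          removed_this_sweep <- TRUE
        }
      }
        if (start + cfg$ld_window_snps - 1L >= length(win_pool)) break
        start <- start + cfg$ld_step_snps
      }
      if (!removed_this_sweep) break
    }
  }
  which(keep)
}

# squared dosage correlation between all column pairs with pairwise
# deletion, computed from integer cross-products; exact, and invariant to
# allele relabelling (x -> 2-x flips the sign of the covariance only).
# undefined correlations (monomorphic pairs) come back as 0: never tested.
pairwise_r2_int <- function(dw) {
  m <- !is.na(dw)
  storage.mode(m) <- "double"
  dw[is.na(dw)] <- 0L
  storage.mode(dw) <- "double"
  d2 <- dw * dw
  n <- crossprod(m)
  sx <- crossprod(dw, m)          # sum of x over loci called in both
  sxy <- crossprod(dw)
  sxx <- crossprod(d2, m)
  cov_num <- n * sxy - sx * t(sx)
  var_x <- n * sxx - sx * sx
  den <- var_x * t(var_x)
  r2 <- ifelse(den > 0, cov_num * cov_num / den, 0)
  r2
}

#' Run the full QC pipeline
#'
#' Fixed stage order: SNP call rate, individual call rate, HWE screen,
#' chromosome exclusion, LD pruning. Returns both the analysis panels the
#' downstream modules use: the unpruned post-QC panel (for ROH calling,
#' where LD pruning would bias detection) and the LD-pruned panel (for
#' heterozygosity, inbreeding and IBD).
#'
#' @param g a `geno_matrix`.
#' @param cfg a [qc_config()].
#' @return a list: `panel_roh` (unpruned), `panel_pruned`, and `report`
#'   (a list of per-stage drop records).
#' @export
run_qc <- function(g, cfg = qc_config()) {
  cr <- filter_call_rate(g, cfg)
  g1 <- cr$g
  hwe_p <- hwe_scan(g1)
  keep_hwe <- is.na(hwe_p) | hwe_p >= cfg$hwe_alpha
  dropped_hwe <- g1$loci$snp_id[!keep_hwe]
  g2 <- subset_geno(g1, loci = keep_hwe)
  keep_chr <- !g2$loci$chrom %in% cfg$exclude_chroms
  dropped_chr <- g2$loci$snp_id[!keep_chr]
  g3 <- subset_geno(g2, loci = keep_chr)
  kept_idx <- ld_prune(g3, cfg)
  dropped_ld <- g3$loci$snp_id[-kept_idx]
  g4 <- subset_geno(g3, loci = kept_idx)
  list(panel_roh = g3, panel_pruned = g4,
       report = list(dropped_loci_call_rate = cr$dropped_loci,
                     dropped_samples_call_rate = cr$dropped_samples,
                     dropped_loci_hwe = dropped_hwe,
                     dropped_loci_chrom = dropped_chr,
                     dropped_loci_ld = dropped_ld,
                     n_panel_roh = n_loci(g3),
                     n_panel_pruned = n_loci(g4)))
}
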