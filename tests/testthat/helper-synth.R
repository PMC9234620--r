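# shared fixture builders; everything is generated in code at test time

# tiny genotype matrix from a dosage matrix (loci on one chromosome
# unless chrom given), positions 100 kb apart
toy_geno <- function(dosage, chrom = NULL, pos = NULL, pops = NULL,
                     years = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- ave(seq_len(m), chrom, FUN = seq_along) * 1e5
  n <- nrow(dosage)
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                        stringsAsFactors = FALSE)
  if (!is.null(pops)) samples$population <- pops
  if (!is.null(years)) samples$cohort_year <- years
  geno_matrix(dosage,
              data.frame(chrom = chrom, pos_bp = pos,
                         ref = "A", alt = "G", stringsAsFactors = FALSE),
              samples)
}

# HWE genotypes for n individuals at the given reference frequencies
hwe_geno <- function(n, freqs, seed, pops = NULL, years = NULL) {
  set.seed(seed)
  d <- matrix(stats::rbinom(n * length(freqs), 2L,
                            rep(1 - freqs, each = n)), nrow = n)
  toy_geno(d, pops = pops, years = years)
}

# small genome map reused across files (memoized; deterministic)
.fixture_cache <- new.env(parent = emptyenv())
small_gmap <- function() {
  if (is.null(.fixture_cache$gmap))
    .fixture_cache$gmap <- genome_map(n_chrom = 12, genome_bp = 4e8,
                                      spacing_bp = 85500, seed = 101)
  .fixture_cache$gmap
}

# outbred cohort with planted tracts on the small map (shared between
# ROH tests); returns list(g, truth, calls_window)
planted_fixture <- function() {
  if (!is.null(.fixture_cache$planted)) return(.fixture_cache$planted)
  gmap <- small_gmap()
  wf <- wf_simulate(wf_config(nrow(gmap$markers), 2, 1000, 1000, 0,
                              init_freqs = founder_freq_uniform()),
                    seed = 102)
  g <- make_two_deme_cohorts(wf, gmap, 15, 15, seed = 103)
  set.seed(104)
  spec <- do.call(rbind, lapply(1:30, function(i) {
    ch <- sample(1:6, 1)
    L <- runif(1, 1.5e6, 20e6)
    st <- runif(1, 1, gmap$chrom$length_bp[ch] - L)
    data.frame(sample_id = g$samples$sample_id[i],
               chrom = as.character(ch), start_bp = st, end_bp = st + L,
               stringsAsFactors = FALSE)
  }))
  pl <- plant_roh(g, spec, seed = 105)
  .fixture_cache$planted <- list(g = pl$g, truth = pl$truth,
                                 calls_window = call_roh_windows(pl$g))
  .fixture_cache$planted
}

# conditional exact HWE distribution by the log-factorial closed form —
# an independent route from the package's recurrence
hwe_enumeration_pvalue <- function(n_het, n_homref, n_homalt) {
  n <- n_het + n_homref + n_homalt
  na <- 2 * min(n_homref, n_homalt) + n_het
  if (na == 0) return(1.0)
  hets <- seq(na %% 2, na, by = 2)
  logp <- vapply(hets, function(h) {
    nrr <- (na - h) / 2
    ncc <- n - h - nrr
    lfactorial(n) - lfactorial(h) - lfactorial(nrr) - lfactorial(ncc) +
      h * log(2) + lfactorial(na) + lfactorial(2 * n - na) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

# exhaustive Wilcoxon rank-sum: distribution of W over all assignments
wilcoxon_enumeration <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  ranks <- rank(pool)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  list(W = w_obs, p = min(1, p))
}
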