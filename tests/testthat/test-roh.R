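# a single-chromosome fixture: het-rich flanks around a homozygous tract
tract_chrom <- function(n_flank = 100, n_tract = 300, tract_mb = 2.0,
                        het_seed = 61, mid_het = 0) {
  set.seed(het_seed)
  flank1 <- rbinom(n_flank, 2, 0.5)
  flank2 <- rbinom(n_flank, 2, 0.5)
  tract <- rep(ifelse(runif(n_tract) < 0.5, 0L, 2L))
  if (mid_het > 0) tract[round(n_tract / 2) + seq_len(mid_het)] <- 1L
  x <- as.integer(c(flank1, tract, flank2))
  pos <- c(seq(1e5, by = 9e4, length.out = n_flank),
           seq(1e7, by = tract_mb * 1e6 / n_tract, length.out = n_tract),
           seq(1e7 + tract_mb * 1e6 + 6e5, by = 9e4,   # gap > max_gap_kb:
               length.out = n_flank))                  # tract stands alone
  toy_geno(matrix(x, 1), pos = round(pos))
}

test_that("an ideal homozygous tract yields exactly one covering segment", {
  g <- tract_chrom()
  segs <- call_roh_windows(g)
  expect_equal(nrow(segs), 1)
  # boundary SNPs whose windows all straddle the het flank are trimmed;
  # allow a few marker spacings of slack at each end
  spacing <- 2e6 / 300
  expect_lte(segs$start_bp, 1e7 + 3 * spacing)
  expect_gte(segs$end_bp, 1e7 + 2e6 - 3 * spacing)
})

test_that("one heterozygote mid-tract is tolerated at window_het_max = 1", {
  g <- tract_chrom(mid_het = 1)
  segs <- call_roh_windows(g)
  expect_equal(nrow(segs), 1)
  expect_gte(segs$length_bp, 1.9e6)
})

test_that("tracts below the minimum length are not reported", {
  g <- tract_chrom(tract_mb = 0.8)
  segs <- call_roh_windows(g)
  expect_equal(nrow(segs), 0)
})

test_that("reported segments never violate their config thresholds", {
  px <- planted_fixture()
  cfg <- roh_window_config()
  segs <- px$calls_window
  expect_true(all(segs$n_snps >= cfg$min_snps))
  expect_true(all(segs$length_bp >= cfg$min_length_kb * 1000))
  expect_true(all(segs$length_bp / 1000 / segs$n_snps <=
                    cfg$min_density_kb_per_snp))
  expect_true(all(segs$end_bp > segs$start_bp))
})

test_that("window caller recovers planted tracts and rarely hallucinates", {
  px <- planted_fixture()
  tr2 <- px$truth[px$truth$length_bp >= 2e6, ]
  rec <- roh_recall(tr2, px$calls_window)
  expect_gte(mean(rec$recovered), 0.9)

  # outbred individuals on the same map: LONG false calls are rare
  gmap <- small_gmap()
  wf <- wf_simulate(wf_config(nrow(gmap$markers), 2, 1000, 1000, 0,
                              init_freqs = founder_freq_uniform()),
                    seed = 62)
  g_out <- make_two_deme_cohorts(wf, gmap, 20, 20, seed = 63)
  segs_out <- call_roh_windows(g_out)
  fp <- length(unique(segs_out$sample_id[segs_out$length_bp >= 5e6]))
  expect_lt(fp / 40, 0.05)
})

test_that("window caller is invariant to allele-label swaps", {
  px <- planted_fixture()
  flip <- seq(1, n_loci(px$g), by = 3)
  segs_sw <- call_roh_windows(swap_alleles(px$g, flip))
  expect_equal(segs_sw, px$calls_window)
})

test_that("sensitivity is monotone non-decreasing in tract length", {
  px <- planted_fixture()
  rec <- roh_recall(px$truth, px$calls_window)
  bins <- cut(rec$length_bp, c(0, 2e6, 5e6, Inf))
  rate <- tapply(rec$recovered, bins, mean)
  rate <- rate[!is.na(rate)]
  expect_true(all(diff(rate) >= 0))
})

test_that("HMM caller: all-het individuals yield nothing, homozygous chromosomes one run", {
  g_het <- toy_geno(matrix(1L, 1, 120),
                    pos = seq(1e5, by = 9e4, length.out = 120))
  expect_equal(nrow(call_roh_hmm(g_het, freqs = rep(0.5, 120))), 0)

  set.seed(64)
  g_hom <- toy_geno(matrix(ifelse(runif(120) < 0.5, 0L, 2L), 1),
                    pos = seq(1e5, by = 9e4, length.out = 120))
  segs <- call_roh_hmm(g_hom, freqs = rep(0.5, 120))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 120)
})

test_that("Viterbi decoding equals exhaustive path enumeration on short chains", {
  cfg <- roh_hmm_config()
  set.seed(65)
  for (r in 1:30) {
    m <- sample(3:12, 1)
    x <- sample(c(0L, 1L, 2L, NA), m, replace = TRUE,
                prob = c(0.4, 0.2, 0.3, 0.1))
    p <- runif(m, 0.05, 0.95)
    pos <- sort(sample.int(6e7, m))
    expect_identical(fragdiv:::viterbi_az(x, p, pos, cfg),
                     enumerate_az_path(x, p, pos, cfg))
  }
})

test_that("window and HMM callers agree on planted data", {
  px <- planted_fixture()
  segs_hmm <- call_roh_hmm(px$g)
  expect_gte(roh_jaccard(px$calls_window, segs_hmm), 0.8)
})

test_that("ROH summaries count segments and 5 Mb length classes per group", {
  segs <- data.frame(sample_id = c("a", "a", "b"), chrom = "1",
                     start_bp = c(1e6, 5e6, 1e6),
                     end_bp = c(3e6, 8e6, 7e6),
                     n_snps = 30,
                     length_bp = c(2e6, 3e6, 6e6),
                     length_class = c("SHORT", "SHORT", "LONG"))
  g <- toy_geno(matrix(0L, 3, 2), pops = c("ABS", "ABS", "ABS"),
                years = rep(2000L, 3))
  g$samples$sample_id <- c("a", "b", "c")
  s <- summarize_roh(segs, g)
  expect_equal(s$n_segments, 3)
  expect_equal(s$prop_long, 1 / 3)      # boundary 5 Mb inclusive to LONG
  expect_equal(s$mean_segments_per_ind, 1)

  g_empty <- subset_geno(g, samples = "c")
  s2 <- summarize_roh(segs[0, ], g_empty)
  expect_equal(s2$n_segments, 0)
  expect_true(is.nan(s2$prop_long))
})
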