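test_that("site heterozygosity counts het calls over called loci", {
  g <- toy_geno(rbind(c(0L, 1L, 1L, 2L, NA),
                      c(0L, 0L, 2L, 2L, 0L)))
  h <- site_heterozygosity(g)
  expect_equal(h$het_obs, c(2 / 4, 0))
  expect_equal(h$n_loci_used, c(4L, 5L))
  g_na <- toy_geno(matrix(NA_integer_, 1, 3))
  expect_true(is.nan(site_heterozygosity(g_na)$het_obs))
})

test_that("heterozygosity of an outbred HWE individual matches binomial expectation", {
  g <- hwe_geno(1, rep(0.5, 10000), seed = 41)
  h <- site_heterozygosity(g)$het_obs
  expect_lt(abs(h - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("fhat3 per-locus algebra: het term is -1, hom-alt at p=0.5 is +1", {
  for (p in c(0.1, 0.37, 0.5, 0.8)) {
    g <- toy_geno(matrix(1L, 1, 1))
    expect_equal(fhat3(g, freqs = p)$f3, -1)
  }
  g2 <- toy_geno(matrix(2L, 1, 1))
  expect_equal(fhat3(g2, freqs = 0.5)$f3, 1)
})

test_that("fhat3 is centred at zero for outbred individuals and rises with F", {
  freqs <- founder_freq_uniform()(4000)
  g <- hwe_geno(100, freqs, seed = 42)
  f3 <- fhat3(g, freqs)$f3
  se <- sd(f3) / sqrt(100)
  expect_lt(abs(mean(f3)), 3 * se)

  gmap <- small_gmap()
  means <- vapply(c(0, 1 / 16, 1 / 8, 1 / 4), function(fp) {
    co <- ped_inbred_cohort(fp, 25)
    gd <- gene_drop(co$ped, gmap, seed = 43 + round(fp * 16))
    mean(fhat3(gd$g, gd$freqs)$f3[match(co$focal, gd$g$samples$sample_id)])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(max(abs(means - c(0, 1 / 16, 1 / 8, 1 / 4))), 0.05)
})

test_that("fhat3 and heterozygosity are invariant to allele-label swaps", {
  g <- hwe_geno(30, runif(300, 0.1, 0.9), seed = 44)
  flip <- sample(c(TRUE, FALSE), 300, replace = TRUE)
  g_sw <- swap_alleles(g, flip)
  expect_equal(fhat3(g_sw, allele_frequencies(g_sw))$f3,
               fhat3(g, allele_frequencies(g))$f3)
  expect_equal(site_heterozygosity(g_sw)$het_obs,
               site_heterozygosity(g)$het_obs)
})

test_that("f3 and f_roh are positively correlated on a gene-dropped cohort", {
  gmap <- small_gmap()
  peds <- lapply(c(0, 1 / 16, 1 / 8, 1 / 4), ped_inbred_cohort, n = 25)
  ped_all <- pedigree(
    unlist(lapply(peds, function(x) x$ped$id)),
    unlist(lapply(peds, function(x) x$ped$sire)),
    unlist(lapply(peds, function(x) x$ped$dam)))
  focal <- unlist(lapply(peds, `[[`, "focal"))
  gd <- gene_drop(ped_all, gmap, seed = 45)
  gi <- subset_geno(gd$g, samples = focal)
  f3 <- fhat3(gi, gd$freqs)$f3
  segs <- call_roh_windows(gi)
  fr <- f_roh(segs, covered_genome_bp(gi), focal)$f_roh
  expect_gt(cor(f3, fr), 0.4)
})

test_that("f_roh sums segment lengths over the covered genome", {
  expect_equal(f_roh(data.frame(sample_id = character(), chrom = character(),
                                start_bp = numeric(), end_bp = numeric(),
                                length_bp = numeric()),
                     1e9, "x")$f_roh, 0)
  seg <- data.frame(sample_id = "x", chrom = "1", start_bp = 1e6,
                    end_bp = 11e6, length_bp = 1e7)
  expect_equal(f_roh(seg, 1e9)$f_roh, 0.01)
  overlap <- rbind(seg, data.frame(sample_id = "x", chrom = "1",
                                   start_bp = 5e6, end_bp = 12e6,
                                   length_bp = 7e6))
  expect_error(f_roh(overlap, 1e9), "overlap")
})

test_that("f_roh recovers planted autozygous fraction", {
  px <- planted_fixture()
  ids <- unique(px$truth$sample_id)
  fr <- f_roh(px$calls_window, covered_genome_bp(px$g), ids)
  truth_fr <- vapply(ids, function(s)
    sum(px$truth$length_bp[px$truth$sample_id == s]), numeric(1)) /
    covered_genome_bp(px$g)
  expect_equal(mean(fr$f_roh), mean(truth_fr), tolerance = 0.12)
})

test_that("delta_p is zero for identical cohorts and tracks drift variance", {
  freqs <- runif(500, 0.2, 0.8)
  g1 <- hwe_geno(20, freqs, seed = 46)
  g <- geno_matrix(rbind(g1$dosage, g1$dosage),
                   g1$loci,
                   data.frame(sample_id = sprintf("i%02d", 1:40),
                              population = "ABS",
                              cohort_year = rep(c(2000L, 2008L), each = 20)))
  dp <- delta_p(g, "ABS", 2000, 2008)
  expect_true(all(dp$delta_p == 0))
  expect_equal(dp$var_delta_p, 0)

  # drift over 8 generations in a deme of N=25, cohorts re-sampled:
  # var(dp) ~ mean p0(1-p0)(1-(1-1/2N)^8) plus cohort-sampling noise
  N <- 25; t <- 8
  wf <- wf_simulate(wf_config(2000, t, N, N, 0, init_freqs = 0.5), seed = 47)
  gmap <- genome_map(n_chrom = 4, genome_bp = 2e8, spacing_bp = 1e5,
                     seed = 48)
  mk <- nrow(gmap$markers)
  expect_gte(mk, 2000)
  g0 <- make_two_deme_cohorts(
    wf_simulate(wf_config(mk, 1, 1e6, 1e6, 0, init_freqs = 0.5), seed = 49),
    gmap, 150, 1, seed = 50, cohort_year = 2000L)
  wf2 <- wf_simulate(wf_config(mk, t, N, N, 0, init_freqs = 0.5), seed = 51)
  g8 <- make_two_deme_cohorts(wf2, gmap, 150, 1, seed = 52,
                              cohort_year = 2008L)
  keep0 <- cohort_index(g0, "ABS"); keep8 <- cohort_index(g8, "ABS")
  g_both <- geno_matrix(
    rbind(g0$dosage[keep0, ], g8$dosage[keep8, ]),
    g0$loci,
    data.frame(sample_id = c(paste0("y0_", seq_along(keep0)),
                             paste0("y8_", seq_along(keep8))),
               population = "ABS",
               cohort_year = rep(c(2000L, 2008L),
                                 c(length(keep0), length(keep8)))))
  dp2 <- delta_p(g_both, "ABS", 2000, 2008)
  drift_var <- 0.25 * (1 - (1 - 1 / (2 * N))^t)
  sampling_var <- 2 * 0.25 / (2 * 150)     # two cohorts of 150
  expect_equal(dp2$var_delta_p, drift_var + sampling_var, tolerance = 0.15)
})

test_that("larger demes show smaller delta-p variance", {
  v <- vapply(c(25, 250), function(N) {
    wf <- wf_simulate(wf_config(3000, 8, N, N, 0, init_freqs = 0.5),
                      seed = 53)
    var(wf$p_a - wf$p0)
  }, numeric(1))
  expect_lt(v[2], v[1])
})

test_that("Weir-Cockerham F_ST behaves at the boundaries", {
  freqs <- runif(400, 0.2, 0.8)
  g1 <- hwe_geno(15, freqs, seed = 54)
  g <- geno_matrix(rbind(g1$dosage, g1$dosage), g1$loci,
                   data.frame(sample_id = sprintf("i%02d", 1:30),
                              population = rep(c("ABS", "PLE"), each = 15),
                              cohort_year = 2000L))
  # no differentiation: theta at or below zero up to finite-sample noise
  fst_same <- fst_weir_cockerham(g, "ABS", "PLE")
  expect_lt(fst_same, 0.02)
  expect_gt(fst_same, -0.2)

  # fixed difference at every locus -> theta = 1
  d <- rbind(matrix(0L, 10, 50), matrix(2L, 10, 50))
  gf <- toy_geno(d, pops = rep(c("A", "B"), each = 10),
                 years = rep(2000L, 20))
  expect_equal(fst_weir_cockerham(gf, "A", "B"), 1)

  # monomorphic panel undefined
  gm <- toy_geno(matrix(0L, 10, 20), pops = rep(c("A", "B"), each = 5),
                 years = rep(2000L, 10))
  expect_true(is.nan(fst_weir_cockerham(gm, "A", "B")))
})

test_that("F_ST under island-model migration sits near the drift-migration balance", {
  gmap <- genome_map(n_chrom = 4, genome_bp = 2e8, spacing_bp = 9.5e4,
                     seed = 55)
  nl <- nrow(gmap$markers)
  run_cohorts <- function(N, m, seed) {
    wf <- wf_simulate(wf_config(nl, 300, N, N, m,
                                init_freqs = founder_freq_uniform()),
                      seed = seed)
    make_two_deme_cohorts(wf, gmap, 40, 40, seed = seed + 1)
  }
  g_hi <- run_cohorts(100, 0.05, 56)
  g_lo <- run_cohorts(100, 0.005, 57)
  fst_hi_m <- fst_weir_cockerham(g_hi, "ABS", "PLE")
  fst_lo_m <- fst_weir_cockerham(g_lo, "ABS", "PLE")
  expect_lt(fst_hi_m, fst_lo_m)                 # more migration, less divergence
  approx <- 1 / (1 + 4 * 100 * 0.05)
  expect_gt(fst_hi_m, approx / 4)               # wide band around island formula
  expect_lt(fst_hi_m, approx * 4)
  # Hudson estimator agrees with Weir-Cockerham to first order here
  expect_equal(fst_weir_cockerham(g_lo, "ABS", "PLE", method = "hudson"),
               fst_lo_m, tolerance = 0.25)
})
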