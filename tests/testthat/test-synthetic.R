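test_that("pedigree construction validates ordering and parent pairs", {
  expect_error(pedigree(c("a", "b"), c("b", NA), c("c", NA)), "precede|unknown")
  expect_error(pedigree("a", "b", NA), "both parents")
  p <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"))
  expect_s3_class(p, "pedigree")
})

test_that("pedigree kinship reproduces textbook coefficients", {
  rp <- ped_relationship_pairs("fs", 1)
  kin <- pedigree_kinship(rp$ped)
  expect_equal(kin$phi["fs1_s1", "fs1_s2"], 0.25)
  for (fp in c(0, 1 / 16, 1 / 8, 1 / 4)) {
    co <- ped_inbred_cohort(fp, 1)
    kin <- pedigree_kinship(co$ped)
    expect_equal(unname(kin$f_ped[co$focal]), fp)
  }
  rp2 <- ped_relationship_pairs("fc", 1)
  kin2 <- pedigree_kinship(rp2$ped)
  expect_equal(kin2$phi["fc1_c1", "fc1_c2"], 1 / 16)
})

test_that("founder genotypes match the founder frequencies", {
  gmap <- genome_map(n_chrom = 3, genome_bp = 1.5e8, spacing_bp = 5e4,
                     seed = 111)
  ped <- pedigree(sprintf("f%02d", 1:60), rep(NA, 60), rep(NA, 60))
  gd <- gene_drop(ped, gmap, founder_freqs = 0.3, seed = 112)
  p_hat <- mean(allele_frequencies(gd$g))
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / (120 * nrow(gmap$markers))) * 10)
  # founders carry two independent haplotypes: no autozygosity
  expect_equal(nrow(gd$autozygous_tracts), 0)
  expect_true(all(gd$f_realized == 0))
})

test_that("realized autozygosity is unbiased for the pedigree F", {
  gmap <- small_gmap()
  for (fp in c(1 / 16, 1 / 8, 1 / 4)) {
    co <- ped_inbred_cohort(fp, 40)
    gd <- gene_drop(co$ped, gmap, seed = 113 + round(16 * fp))
    fr <- gd$f_realized[co$focal]
    expect_equal(mean(fr), fp, tolerance = 0.02 / max(fp, 0.07),
                 ignore_attr = TRUE)
    expect_true(all(gd$autozygous_tracts$end_bp >
                      gd$autozygous_tracts$start_bp))
  }
})

test_that("true IBD sharing matches Mendelian expectations", {
  gmap <- small_gmap()
  rp_po <- ped_relationship_pairs("po", 10)
  gd <- gene_drop(rp_po$ped, gmap, seed = 114)
  z_po <- t(sapply(seq_len(10), function(k)
    true_ibd_sharing(gd, rp_po$pairs[k, 1], rp_po$pairs[k, 2])))
  expect_true(all(z_po[, "z1"] == 1))      # PO share one haplotype everywhere

  rp_fs <- ped_relationship_pairs("fs", 30)
  gd_fs <- gene_drop(rp_fs$ped, gmap, seed = 115)
  z_fs <- t(sapply(seq_len(30), function(k)
    true_ibd_sharing(gd_fs, rp_fs$pairs[k, 1], rp_fs$pairs[k, 2])))
  expect_equal(colMeans(z_fs), c(z0 = 0.25, z1 = 0.5, z2 = 0.25),
               tolerance = 0.15)

  rp_hs <- ped_relationship_pairs("hs", 30)
  gd_hs <- gene_drop(rp_hs$ped, gmap, seed = 116)
  z_hs <- t(sapply(seq_len(30), function(k)
    true_ibd_sharing(gd_hs, rp_hs$pairs[k, 1], rp_hs$pairs[k, 2])))
  expect_true(all(z_hs[, "z2"] == 0))      # half sibs can never share both
  expect_equal(mean(z_hs[, "z1"]), 0.5, tolerance = 0.1)
})

test_that("gene dropping is reproducible from its seed", {
  gmap <- genome_map(n_chrom = 3, genome_bp = 1e8, spacing_bp = 1e5,
                     seed = 117)
  rp <- ped_relationship_pairs("fs", 3)
  gd1 <- gene_drop(rp$ped, gmap, seed = 118)
  gd2 <- gene_drop(rp$ped, gmap, seed = 118)
  expect_identical(gd1$g$dosage, gd2$g$dosage)
  expect_identical(gd1$autozygous_tracts, gd2$autozygous_tracts)
})

test_that("planted tracts are recorded and recovered; empty spec is identity", {
  gmap <- small_gmap()
  g <- hwe_geno(5, runif(200, 0.2, 0.8), seed = 119)
  expect_identical(plant_roh(g, g$loci[0, c(1, 2)][0, ], seed = 1)$g$dosage,
                   g$dosage)
  # injected error rate leaves roughly eps * n_markers hets inside tracts
  gmap2 <- genome_map(n_chrom = 1, genome_bp = 5e7, spacing_bp = 4e4,
                      seed = 120)
  wf <- wf_simulate(wf_config(nrow(gmap2$markers), 2, 500, 500, 0,
                              init_freqs = 0.5), seed = 121)
  gg <- make_two_deme_cohorts(wf, gmap2, 30, 1, seed = 122)
  spec <- data.frame(sample_id = gg$samples$sample_id[1:30], chrom = "1",
                     start_bp = 1e6, end_bp = 2.1e7)
  pl <- plant_roh(gg, spec, eps_plant = 0.02, seed = 123)
  li <- which(gg$loci$pos_bp >= 1e6 & gg$loci$pos_bp <= 2.1e7)
  n_het <- sum(pl$g$dosage[1:30, li] == 1L)
  expect_equal(n_het / (30 * length(li)), 0.02, tolerance = 0.5)
  # overlapping intervals merge with a warning
  spec2 <- rbind(spec[1, ], transform(spec[1, ], start_bp = 5e6,
                                      end_bp = 3e7))
  expect_warning(pl2 <- plant_roh(gg, spec2, seed = 124), "merged")
  expect_equal(nrow(pl2$truth), 1)
  expect_equal(pl2$truth$end_bp, 3e7)
})

test_that("two-deme cohorts carry the sampling design of the field study", {
  gmap <- genome_map(n_chrom = 2, genome_bp = 1e8, spacing_bp = 1e5,
                     seed = 125)
  nl <- nrow(gmap$markers)
  wf <- wf_simulate(wf_config(nl, 2, 1000, 1000, 0.5, init_freqs = 0.4),
                    seed = 126)
  g <- make_two_deme_cohorts(wf, gmap, 45, 24, seed = 127,
                             cohort_year = 2000L)
  expect_equal(n_samples(g), 69)
  expect_equal(sum(g$samples$population == "ABS"), 45)
  expect_equal(sum(g$samples$population == "PLE"), 24)
  expect_true(all(g$samples$cohort_year == 2000L))
  # identical deme frequencies give near-zero differentiation
  expect_lt(abs(fst_weir_cockerham(g, "ABS", "PLE")), 0.02)
})

test_that("isolation time increases between-deme differentiation", {
  gmap <- genome_map(n_chrom = 2, genome_bp = 1e8, spacing_bp = 1e5,
                     seed = 128)
  nl <- nrow(gmap$markers)
  fst_at <- function(gen, seed) {
    wf <- wf_simulate(wf_config(nl, gen, 30, 30, 0,
                                init_freqs = founder_freq_uniform()),
                      seed = seed)
    g <- make_two_deme_cohorts(wf, gmap, 25, 25, seed = seed + 1)
    fst_weir_cockerham(g, "ABS", "PLE")
  }
  expect_gt(fst_at(40, 129), fst_at(2, 129))
})
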