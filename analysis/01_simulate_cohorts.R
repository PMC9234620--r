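#!/usr/bin/env Rscript
# Build the synthetic study system: two demes that were one panmictic
# population, one of which (the "PLE" analogue) collapses while the other
# (the "ABS" analogue) stays large, with limited and decaying migration.
# Cohorts of breeders are sampled in two years, two generations apart,
# mirroring the field design (45/24 in the first year, 178/41 in the
# second). Everything downstream (02-05) reads the files written here.

suppressPackageStartupMessages(library(fragdiv))
seed <- 20260901L
out <- "scratch/sim"   # large raw genotypes; summaries land in results/
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gmap <- genome_map(n_chrom = 30, genome_bp = 1e9, spacing_bp = 85500,
                   seed = seed)
nl <- nrow(gmap$markers)
cat("genome:", nrow(gmap$chrom), "chromosomes,", nl, "markers, mean spacing",
    round(sum(gmap$chrom$length_bp) / nl / 1000, 1), "kb\n")

# the demes were panmictic until a handful of generations before the
# first sampling year; since then the small deme shrinks from 60 to 30
# breeders-worth of effective size while migration decays from 0.08 to
# 0.02 — recent, shallow divergence, as in the field system
G <- 4L
size_a <- rep(150L, G)
size_b <- round(seq(60, 30, length.out = G))
mig <- seq(0.08, 0.02, length.out = G)
wf_pre <- wf_simulate(wf_config(nl, G, size_a, size_b, mig,
                                init_freqs = founder_freq_uniform()),
                      seed = seed + 1)
g2000 <- make_two_deme_cohorts(wf_pre, gmap, 45, 24, seed = seed + 2,
                               cohort_year = 2000L)

# two further generations to the second sampling year, near-isolated
wf_a <- wf_simulate(wf_config(nl, 2, 150, 150, 0, init_freqs = wf_pre$p_a),
                    seed = seed + 3)
wf_b <- wf_simulate(wf_config(nl, 2, 25, 25, 0, init_freqs = wf_pre$p_b),
                    seed = seed + 4)
g2008 <- make_two_deme_cohorts(list(p_a = wf_a$p_a, p_b = wf_b$p_a),
                               gmap, 178, 41, seed = seed + 5,
                               cohort_year = 2008L)
g2008$samples$sample_id <- sub("_2008_", "_08_", g2008$samples$sample_id)

g <- geno_matrix(rbind(g2000$dosage, g2008$dosage), g2000$loci,
                 rbind(g2000$samples, g2008$samples))
# consanguineous ancestry in the collapsing deme: a minority of its birds
# (drawn across both years) are offspring of first-cousin or full-sib
# matings gene-dropped on the deme's own frequency spectrum, so F^III and
# multi-megabase ROH have genuine signal there
ple_ids <- g$samples$sample_id[g$samples$population == "PLE"]
founder_p <- pmin(pmax(wf_b$p_a, 0.005), 0.995)   # drift fixes some loci
set.seed(seed + 6)
repl_ids <- sample(ple_ids, 10)
co_fc <- ped_inbred_cohort(1 / 16, 6)             # background inbreeding
co_fs <- ped_inbred_cohort(1 / 4, 4)              # recent close inbreeding
gd_fc <- gene_drop(co_fc$ped, gmap, founder_freqs = founder_p,
                   seed = seed + 7)
gd_fs <- gene_drop(co_fs$ped, gmap, founder_freqs = founder_p,
                   seed = seed + 8)
focal_dosage <- rbind(
  gd_fc$g$dosage[match(co_fc$focal, gd_fc$g$samples$sample_id), ],
  gd_fs$g$dosage[match(co_fs$focal, gd_fs$g$samples$sample_id), ])
g$dosage[match(repl_ids, g$samples$sample_id), ] <- focal_dosage

g <- add_missingness(g, 0.01, seed = seed + 9)
cat("cohorts:\n"); print(table(g$samples$population, g$samples$cohort_year))

write_vcf(g, file.path(out, "cohorts.vcf"))
write_sample_table(g, file.path(out, "cohorts_meta.tsv"))
cat("wrote", file.path(out, "cohorts.vcf"), "and metadata\n")
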