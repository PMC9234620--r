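#!/usr/bin/env Rscript
# Quality control of the simulated cohorts into the two analysis panels:
# the unpruned post-QC panel used for ROH calling, and the LD-pruned
# panel used for heterozygosity, F^III and pairwise IBD.

suppressPackageStartupMessages(library(fragdiv))
dir.create("results", showWarnings = FALSE)

g <- read_vcf("scratch/sim/cohorts.vcf", "scratch/sim/cohorts_meta.tsv")
print(g)

qc <- run_qc(g, qc_config())
rep <- qc$report
cat("\nQC ledger:\n")
cat("  loci dropped (call rate):", length(rep$dropped_loci_call_rate), "\n")
cat("  samples dropped (call rate):", length(rep$dropped_samples_call_rate), "\n")
cat("  loci dropped (HWE):", length(rep$dropped_loci_hwe), "\n")
cat("  loci dropped (excluded chroms):", length(rep$dropped_loci_chrom), "\n")
cat("  loci dropped (LD pruning):", length(rep$dropped_loci_ld), "\n")
cat("  ROH panel:", rep$n_panel_roh, "SNPs; pruned panel:",
    rep$n_panel_pruned, "SNPs\n")

write_vcf(qc$panel_roh, "scratch/sim/panel_roh.vcf")
write_vcf(qc$panel_pruned, "scratch/sim/panel_pruned.vcf")
write_sample_table(qc$panel_roh, "scratch/sim/panel_meta.tsv")
utils::write.table(
  data.frame(stage = c("call_rate_loci", "call_rate_samples", "hwe",
                       "chrom_excluded", "ld_pruned"),
             n_dropped = c(length(rep$dropped_loci_call_rate),
                           length(rep$dropped_samples_call_rate),
                           length(rep$dropped_loci_hwe),
                           length(rep$dropped_loci_chrom),
                           length(rep$dropped_loci_ld))),
  "results/qc_summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
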