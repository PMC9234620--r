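#!/usr/bin/env Rscript
# Per-individual diversity and inbreeding: site-based heterozygosity and
# F^III on the pruned panel, F_ROH from window-called ROH on the unpruned
# panel; group means with Wilcoxon comparisons between the stable and
# declining demes, and the allele-frequency-change (drift) diagnostic.

suppressPackageStartupMessages(library(fragdiv))

panel <- read_vcf("scratch/sim/panel_pruned.vcf", "scratch/sim/panel_meta.tsv")
panel_roh <- read_vcf("scratch/sim/panel_roh.vcf", "scratch/sim/panel_meta.tsv")

freqs <- allele_frequencies(panel)
het <- site_heterozygosity(panel)
f3 <- fhat3(panel, freqs)
segs <- call_roh_windows(panel_roh)
froh <- f_roh(segs, covered_genome_bp(panel_roh),
              panel_roh$samples$sample_id)

ind <- Reduce(function(a, b) merge(a, b, by = "sample_id"),
              list(panel$samples, het[c("sample_id", "het_obs")],
                   f3[c("sample_id", "f3")], froh))
utils::write.table(ind, "results/individual_stats.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("group means (SE):\n")
for (p in unique(ind$population)) for (y in unique(ind$cohort_year)) {
  x <- ind[ind$population == p & ind$cohort_year == y, ]
  cat(sprintf("  %s %s (n=%d): het %.3f (%.3f)  F3 %+.3f (%.3f)  Froh %.4f (%.4f)\n",
              p, y, nrow(x), mean(x$het_obs), sd(x$het_obs) / sqrt(nrow(x)),
              mean(x$f3), sd(x$f3) / sqrt(nrow(x)),
              mean(x$f_roh), sd(x$f_roh) / sqrt(nrow(x))))
}

cat("\nstable vs declining deme, per year:\n")
for (y in unique(ind$cohort_year)) {
  a <- ind[ind$population == "ABS" & ind$cohort_year == y, ]
  b <- ind[ind$population == "PLE" & ind$cohort_year == y, ]
  for (v in c("het_obs", "f3", "f_roh")) {
    w <- wilcoxon_rank_sum(a[[v]], b[[v]])
    cat(sprintf("  %s %s: W = %.1f, p = %.3g\n", y, v, w$statistic,
                w$p_value))
  }
}

# the two inbreeding statistics should agree
cat("\ncor(F3, Froh):", round(cor(ind$f3, ind$f_roh), 3), "\n")

# drift diagnostic: allele-frequency change 2000 -> 2008 per deme
dp_abs <- delta_p(panel, "ABS", 2000, 2008)
dp_ple <- delta_p(panel, "PLE", 2000, 2008)
cmp <- compare_delta_p_variance(dp_abs$delta_p, dp_ple$delta_p, seed = 99)
cat(sprintf("var(dp) stable %.2e vs declining %.2e (ratio %.2f), perm p = %.3g\n",
            cmp$var_a, cmp$var_b, cmp$ratio, cmp$perm_test))
utils::write.table(
  data.frame(population = c("ABS", "PLE"),
             var_delta_p = c(dp_abs$var_delta_p, dp_ple$var_delta_p),
             n_loci_excluded = c(dp_abs$n_loci_excluded,
                                 dp_ple$n_loci_excluded)),
  "results/delta_p_variance.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("F_ST between demes (pooled years):",
    signif(fst_weir_cockerham(panel, "ABS", "PLE"), 3), "\n")
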