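#' Configuration for a full replication run
#'
#' Bundles every stage's settings for the end-to-end workflow
#' (QC, two analysis panels, diversity and inbreeding statistics, ROH by
#' both callers, within/between relatedness, sample-size-matched
#' subsampling, and the convention-pinned tests).
#'
#' @param qc a [qc_config()].
#' @param roh_window a [roh_window_config()].
#' @param roh_hmm a [roh_hmm_config()].
#' @param groups data.frame with columns `population`, `cohort_year`
#'   defining the analysis groups; `NULL` derives all groups from the
#'   metadata.
#' @param subsample_iterations iterations for the subsampling stage.
#' @param min_ibd_loci minimum shared loci per IBD pair.
#' @param seed root seed for every stochastic stage.
#' @return a list of class `run_config`.
#' @export
run_config <- function(qc = qc_config(), roh_window = roh_window_config(),
                       roh_hmm = roh_hmm_config(), groups = NULL,
                       subsample_iterations = 1000L, min_ibd_loci = 500L,
                       seed = 1L) {
  structure(list(qc = qc, roh_window = roh_window, roh_hmm = roh_hmm,
                 groups = groups,
                 subsample_iterations = as.integer(subsample_iterations),
                 min_ibd_loci = as.integer(min_ibd_loci),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg, file = tmp, control = c("keepNA", "keepInteger"))
  unname(tools::md5sum(tmp))
}

#' Run the full replication workflow
#'
#' Stage order: QC (yielding the unpruned ROH panel and the LD-pruned
#' main panel), per-individual diversity/inbreeding on the pruned panel,
#' ROH calling (window caller, and optionally the HMM) and F_ROH on the
#' unpruned panel, group summaries, within- and between-group pairwise
#' IBD with relationship classes, subsampling of the larger population to
#' the smaller one's sample sizes, and Wilcoxon / chi-square comparisons
#' in both correction conventions. Deterministic given `cfg$seed`.
#'
#' @param g a `geno_matrix` with `population` and `cohort_year` metadata.
#' @param cfg a [run_config()].
#' @param out_dir optional directory; when given, every table is written
#'   as TSV (first line a `#config_hash=` comment) plus a JSON-free
#'   manifest `run_manifest.tsv`.
#' @param hmm also run the HMM caller (slower; default TRUE).
#' @return a list of class `run_bundle` with elements `panel_sizes`,
#'   `individual_stats`, `group_summary`, `roh_segments`,
#'   `roh_segments_hmm`, `roh_group`, `ibd_summary`, `class_proportions`,
#'   `subsampling`, `tests`, `config_hash`.
#' @export
run_paper_replication <- function(g, cfg = run_config(), out_dir = NULL,
                                  hmm = TRUE) {
  hash <- config_hash(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }

  qc <- stage("qc", run_qc(g, cfg$qc))
  panel <- qc$panel_pruned
  panel_roh <- qc$panel_roh

  groups <- cfg$groups
  if (is.null(groups)) {
    groups <- unique(panel$samples[, c("population", "cohort_year")])
    groups <- groups[order(groups$population, groups$cohort_year), ,
                     drop = FALSE]
    rownames(groups) <- NULL
  }

  freqs <- allele_frequencies(panel)           # pooled reference frequencies
  het <- stage("heterozygosity", site_heterozygosity(panel))
  f3 <- stage("fhat3", fhat3(panel, freqs))

  segs <- stage("roh_window", call_roh_windows(panel_roh, cfg$roh_window))
  segs_hmm <- if (hmm)
    stage("roh_hmm", call_roh_hmm(panel_roh, cfg = cfg$roh_hmm)) else NULL
  froh <- stage("f_roh",
                f_roh(segs, covered_genome_bp(panel_roh),
                      panel_roh$samples$sample_id))

  ind <- merge(merge(panel$samples, het, by = "sample_id"),
               merge(f3[, c("sample_id", "f3")], froh, by = "sample_id"),
               by = "sample_id")
  ind <- ind[order(ind$population, ind$cohort_year, ind$sample_id), ]
  rownames(ind) <- NULL

  roh_group <- stage("roh_summary", summarize_roh(segs, panel_roh))

  # per-group means +- SE (Table-1-style)
  gsum <- do.call(rbind, lapply(seq_len(nrow(groups)), function(k) {
    sel <- ind$population == groups$population[k] &
      ind$cohort_year == groups$cohort_year[k]
    x <- ind[sel, ]
    data.frame(population = groups$population[k],
               cohort_year = groups$cohort_year[k], n = nrow(x),
               het_mean = mean(x$het_obs), het_se = se(x$het_obs),
               f3_mean = mean(x$f3), f3_se = se(x$f3),
               froh_mean = mean(x$f_roh), froh_se = se(x$f_roh))
  }))

  # pairwise IBD within each group and between populations per year
  ibd_rows <- list(); class_rows <- list(); ibd_by_group <- list()
  for (k in seq_len(nrow(groups))) {
    grp <- list(population = groups$population[k],
                cohort_year = groups$cohort_year[k])
    r <- stage("ibd_within",
               group_relatedness(panel, grp, mode = "within", freqs = freqs,
                                 min_loci = cfg$min_ibd_loci))
    key <- paste0(grp$population, "_", grp$cohort_year)
    ibd_by_group[[key]] <- r
    ibd_rows[[length(ibd_rows) + 1L]] <-
      data.frame(comparison = key, mode = "within",
                 mean_pi_hat = r$mean_pi_hat, se_pi_hat = r$se_pi_hat,
                 n_pairs = r$n_pairs, prop_related = r$prop_related)
    class_rows[[length(class_rows) + 1L]] <-
      data.frame(group = key, class = names(r$class_proportions),
                 proportion = as.numeric(r$class_proportions))
  }
  for (yr in unique(groups$cohort_year)) {
    pops <- groups$population[groups$cohort_year == yr]
    if (length(pops) == 2) {
      r <- stage("ibd_between", group_relatedness(
        panel, list(population = pops[1], cohort_year = yr),
        list(population = pops[2], cohort_year = yr),
        mode = "between", freqs = freqs, min_loci = cfg$min_ibd_loci))
      ibd_rows[[length(ibd_rows) + 1L]] <-
        data.frame(comparison = paste0(pops[1], "v", pops[2], "_", yr),
                   mode = "between",
                   mean_pi_hat = r$mean_pi_hat, se_pi_hat = r$se_pi_hat,
                   n_pairs = r$n_pairs, prop_related = r$prop_related)
    }
  }
  ibd_summary <- do.call(rbind, ibd_rows)
  class_prop <- do.call(rbind, class_rows)

  # subsample the largest population down to the other's size, per year
  sub_rows <- list()
  for (yr in unique(groups$cohort_year)) {
    pops <- groups$population[groups$cohort_year == yr]
    if (length(pops) != 2) next
    sizes <- vapply(pops, function(p)
      length(cohort_index(panel_roh, p, yr)), integer(1))
    big <- pops[which.max(sizes)]; small <- pops[which.min(sizes)]
    ids_big <- panel_roh$samples$sample_id[cohort_index(panel_roh, big, yr)]
    n_small <- min(sizes)
    sub <- stage("subsample", subsample_statistic(
      ids_big, n_small,
      stat_fn = function(ids) sum(segs$sample_id %in% ids),
      iterations = cfg$subsample_iterations, seed = cfg$seed + yr))
    obs_small <- sum(segs$sample_id %in%
                       panel_roh$samples$sample_id[
                         cohort_index(panel_roh, small, yr)])
    sub_rows[[length(sub_rows) + 1L]] <-
      data.frame(cohort_year = yr, statistic = "n_roh_segments",
                 subsampled_pop = big, n_subsample = n_small,
                 mean = sub$mean, se = sub$se,
                 observed_other = obs_small)
  }
  subsampling <- if (length(sub_rows)) do.call(rbind, sub_rows) else NULL

  # comparisons between the two populations per year, both conventions
  test_rows <- list()
  for (yr in unique(groups$cohort_year)) {
    pops <- sort(groups$population[groups$cohort_year == yr])
    if (length(pops) != 2) next
    xa <- ind[ind$population == pops[1] & ind$cohort_year == yr, ]
    xb <- ind[ind$population == pops[2] & ind$cohort_year == yr, ]
    for (v in c("het_obs", "f3", "f_roh")) {
      w <- wilcoxon_rank_sum(xa[[v]], xb[[v]])
      test_rows[[length(test_rows) + 1L]] <-
        data.frame(cohort_year = yr, variable = v, test = w$test,
                   statistic = w$statistic, df = NA, p_value = w$p_value,
                   convention = w$convention)
    }
    ra <- roh_group[roh_group$population == pops[1] &
                      roh_group$cohort_year == yr, ]
    rb <- roh_group[roh_group$population == pops[2] &
                      roh_group$cohort_year == yr, ]
    if (nrow(ra) && nrow(rb) && ra$n_segments > 0 && rb$n_segments > 0 &&
        ra$n_long + rb$n_long > 0 &&
        (ra$n_segments - ra$n_long) + (rb$n_segments - rb$n_long) > 0) {
      tab <- rbind(c(ra$n_long, ra$n_segments - ra$n_long),
                   c(rb$n_long, rb$n_segments - rb$n_long))
      for (yates in c(TRUE, FALSE)) {
        cs <- chi_square_2x2(tab, yates = yates)
        test_rows[[length(test_rows) + 1L]] <-
          data.frame(cohort_year = yr, variable = "roh_long_proportion",
                     test = cs$test, statistic = cs$statistic, df = cs$df,
                     p_value = cs$p_value, convention = cs$convention)
      }
    }
  }
  tests <- if (length(test_rows)) do.call(rbind, test_rows) else NULL

  bundle <- structure(list(
    panel_sizes = data.frame(panel = c("roh", "pruned"),
                             n_loci = c(n_loci(panel_roh), n_loci(panel)),
                             n_samples = c(n_samples(panel_roh),
                                           n_samples(panel))),
    individual_stats = ind, group_summary = gsum,
    roh_segments = segs, roh_segments_hmm = segs_hmm,
    roh_group = roh_group, ibd_summary = ibd_summary,
    class_proportions = class_prop, subsampling = subsampling,
    tests = tests, qc_report = qc$report, config_hash = hash),
    class = "run_bundle")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

se <- function(x) stats::sd(x) / sqrt(length(x))

#' Write a result bundle to TSV files
#'
#' Each table is written with a header line preceded by a
#' `#config_hash=` comment so outputs are traceable to their
#' configuration; identical seeds and inputs yield byte-identical files.
#'
#' @param bundle a `run_bundle`.
#' @param out_dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("panel_sizes", "individual_stats", "group_summary",
            "roh_segments", "roh_segments_hmm", "roh_group", "ibd_summary",
            "class_proportions", "subsampling", "tests")
  for (nm in tabs) {
    x <- bundle[[nm]]
    if (is.null(x)) next
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(paste0("#config_hash=", bundle$config_hash), con)
    utils::write.table(format(x, digits = 10, trim = TRUE, scientific = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(out_dir)
}
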