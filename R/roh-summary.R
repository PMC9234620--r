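#' Summarize ROH segments by group
#'
#' Per population-by-year group: total segment count, count and proportion
#' of LONG segments (length >= 5 Mb, boundary inclusive), and mean segment
#' count per individual. Length-class proportions are the within-group
#' comparison used when sample sizes differ.
#'
#' @param segments data.frame of segments from either caller.
#' @param g the `geno_matrix` the segments were called on (supplies the
#'   sample-to-group mapping and group sizes).
#' @param long_bp LONG-class boundary in bp (default 5 Mb).
#' @return data.frame with one row per (population, cohort_year):
#'   `n_segments`, `n_long`, `prop_long` (`NaN` for an empty group),
#'   `n_individuals`, `mean_segments_per_ind`.
#' @export
summarize_roh <- function(segments, g, long_bp = 5e6) {
  meta <- g$samples
  groups <- unique(meta[, c("population", "cohort_year")])
  groups <- groups[order(groups$population, groups$cohort_year), ,
                   drop = FALSE]
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    ids <- meta$sample_id[meta$population %in% groups$population[k] &
                          meta$cohort_year %in% groups$cohort_year[k]]
    s <- segments[segments$sample_id %in% ids, , drop = FALSE]
    n <- nrow(s)
    nl <- sum(s$length_bp >= long_bp)
    data.frame(population = groups$population[k],
               cohort_year = groups$cohort_year[k],
               n_segments = n, n_long = nl,
               prop_long = if (n) nl / n else NaN,
               n_individuals = length(ids),
               mean_segments_per_ind = if (length(ids)) n / length(ids) else NaN,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Base-pair Jaccard concordance between two segment sets
#'
#' Overlap of called base-pairs between two ROH call sets (e.g. window vs
#' HMM caller, or calls vs planted truth), computed per individual and
#' chromosome and pooled: |intersection| / |union| in bp.
#'
#' @param a,b segment data.frames (`sample_id`, `chrom`, `start_bp`,
#'   `end_bp`).
#' @return Jaccard index in `[0,1]`; `NaN` if both sets are empty.
#' @export
roh_jaccard <- function(a, b) {
  keys <- unique(rbind(a[, c("sample_id", "chrom")],
                       b[, c("sample_id", "chrom")]))
  inter <- 0; uni <- 0
  for (k in seq_len(nrow(keys))) {
    sa <- a[a$sample_id == keys$sample_id[k] & a$chrom == keys$chrom[k], ]
    sb <- b[b$sample_id == keys$sample_id[k] & b$chrom == keys$chrom[k], ]
    ia <- merge_intervals(sa$start_bp, sa$end_bp)
    ib <- merge_intervals(sb$start_bp, sb$end_bp)
    inter <- inter + interval_intersection_len(ia, ib)
    uni <- uni + interval_len(ia) + interval_len(ib) -
      interval_intersection_len(ia, ib)
  }
  if (uni == 0) return(NaN)
  inter / uni
}

merge_intervals <- function(start, end) {
  if (!length(start)) return(cbind(numeric(0), numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- c(); oute <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { outs <- c(outs, ms); oute <- c(oute, me); ms <- start[i]; me <- end[i] }
  }
  cbind(c(outs, ms), c(oute, me))
}

interval_len <- function(iv) if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0

interval_intersection_len <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    tot <- tot + sum(pmax(0, hi - lo))
  }
  tot
}

#' Recall of planted tracts by a caller
#'
#' For each truth tract, the fraction of its base-pairs covered by called
#' segments of the same individual/chromosome; a tract counts as recovered
#' when coverage reaches `min_cov`.
#'
#' @param truth,calls segment data.frames.
#' @param min_cov coverage fraction for a tract to count as recovered.
#' @return data.frame: truth rows plus `coverage` and `recovered`.
#' @export
roh_recall <- function(truth, calls, min_cov = 0.5) {
  cov <- vapply(seq_len(nrow(truth)), function(i) {
    s <- calls[calls$sample_id == truth$sample_id[i] &
               calls$chrom == truth$chrom[i], , drop = FALSE]
    if (!nrow(s)) return(0)
    iv <- merge_intervals(s$start_bp, s$end_bp)
    tr <- cbind(truth$start_bp[i], truth$end_bp[i])
    interval_intersection_len(iv, tr) /
      (truth$end_bp[i] - truth$start_bp[i])
  }, numeric(1))
  truth$coverage <- cov
  truth$recovered <- cov >= min_cov
  truth
}
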