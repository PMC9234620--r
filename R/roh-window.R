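#' Window-caller configuration for runs of homozygosity
#'
#' PLINK `--homozyg`-style sliding-window genotype counting, with defaults
#' tuned for a sparse array (~85.5 kb mean marker spacing): at that density
#' only large (>= 1 Mb) ROH are detectable, so the minimum length is 1 Mb,
#' the density limit 200 kb/SNP, and a run must contain at least 25 SNPs.
#' The scanning window is sized to the minimum SNP count rather than to
#' PLINK's dense-data default of 50: a window larger than the smallest
#' reportable run can never lie inside it, which on a sparse array would
#' silently raise the detection floor to several megabases.
#'
#' @param window_snps SNPs per scanning window.
#' @param window_het_max maximum heterozygous calls tolerated per window.
#' @param window_miss_max maximum missing calls tolerated per window.
#' @param snp_hit_threshold minimum fraction of passing windows containing a
#'   SNP for that SNP to be eligible for a run.
#' @param min_snps minimum SNPs per reported segment.
#' @param min_length_kb minimum segment length (kb).
#' @param min_density_kb_per_snp maximum average marker spacing inside a
#'   segment (kb per SNP).
#' @param max_gap_kb maximum gap between consecutive SNPs inside a segment
#'   (kb); larger gaps split runs.
#' @return a list of class `roh_window_config`.
#' @export
roh_window_config <- function(window_snps = 25L, window_het_max = 1L,
                              window_miss_max = 5L, snp_hit_threshold = 0.05,
                              min_snps = 25L, min_length_kb = 1000,
                              min_density_kb_per_snp = 200,
                              max_gap_kb = 500) {
  stopifnot(window_snps >= 1, min_snps >= 1, min_length_kb >= 1,
            snp_hit_threshold > 0, snp_hit_threshold <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 window_het_max = as.integer(window_het_max),
                 window_miss_max = as.integer(window_miss_max),
                 snp_hit_threshold = snp_hit_threshold,
                 min_snps = as.integer(min_snps),
                 min_length_kb = min_length_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 max_gap_kb = max_gap_kb),
            class = "roh_window_config")
}

#' Call runs of homozygosity by sliding-window genotype counting
#'
#' For each individual and chromosome: every window of `window_snps`
#' consecutive SNPs passes if it holds at most `window_het_max`
#' heterozygous and `window_miss_max` missing calls; a SNP is eligible when
#' the fraction of passing windows among the windows containing it reaches
#' `snp_hit_threshold`; maximal runs of consecutive eligible SNPs are split
#' at inter-marker gaps above `max_gap_kb` and kept when they satisfy the
#' SNP-count, length and density thresholds. A chromosome with fewer SNPs
#' than the window size is scored with a single truncated window rather
#' than skipped, so sparse chromosomes are not lost.
#'
#' Segment length is `end_bp - start_bp` over the first/last marker of the
#' run; segments at or above 5 Mb are classed `LONG`, below it `SHORT`.
#'
#' @param g a `geno_matrix` (typically the unpruned post-QC panel; LD
#'   pruning biases ROH detection downward).
#' @param cfg a [roh_window_config()].
#' @param samples optional sample selector.
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`, `length_class`.
#' @export
call_roh_windows <- function(g, cfg = roh_window_config(), samples = NULL) {
  si <- resolve_samples(g, samples)
  chroms <- unique(g$loci$chrom)
  out <- list()
  for (ch in chroms) {
    li <- which(g$loci$chrom == ch)
    pos <- g$loci$pos_bp[li]
    for (i in si) {
      x <- g$dosage[i, li]
      elig <- eligible_snps(x, cfg)
      segs <- eligible_runs_to_segments(elig, pos, cfg)
      if (!is.null(segs) && nrow(segs)) {
        segs$sample_id <- g$samples$sample_id[i]
        segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  finish_segments(out)
}

# per-SNP eligibility from window scanning on one chromosome
eligible_snps <- function(x, cfg) {
  m <- length(x)
  W <- min(cfg$window_snps, m)           # truncated window on short chroms
  het <- as.integer(!is.na(x) & x == 1L)
  mis <- as.integer(is.na(x))
  ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
  nw <- m - W + 1L
  starts <- seq_len(nw)
  pass <- (ch[starts + W] - ch[starts]) <= cfg$window_het_max &
          (cm[starts + W] - cm[starts]) <= cfg$window_miss_max
  cp <- cumsum(c(0L, as.integer(pass)))
  j <- seq_len(m)
  lo <- pmax(1L, j - W + 1L)
  hi <- pmin(j, nw)
  n_cont <- hi - lo + 1L                  # windows containing SNP j
  n_pass <- cp[hi + 1L] - cp[lo]
  frac <- ifelse(n_cont > 0, n_pass / n_cont, 0)
  frac >= cfg$snp_hit_threshold
}

# turn an eligibility mask plus positions into filtered segments
eligible_runs_to_segments <- function(elig, pos, cfg) {
  r <- rle(elig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    # split at big gaps
    gaps <- diff(pos[idx])
    cut <- which(gaps > cfg$max_gap_kb * 1000)
    piece_start <- c(idx[1], idx[cut + 1])
    piece_end <- c(idx[cut], idx[length(idx)])
    for (q in seq_along(piece_start)) {
      ii <- piece_start[q]:piece_end[q]
      len <- pos[ii[length(ii)]] - pos[ii[1]]
      nsnp <- length(ii)
      if (nsnp >= cfg$min_snps &&
          len >= cfg$min_length_kb * 1000 &&
          (len / 1000) / nsnp <= cfg$min_density_kb_per_snp) {
        segs[[length(segs) + 1L]] <-
          data.frame(start_bp = pos[ii[1]], end_bp = pos[ii[length(ii)]],
                     n_snps = nsnp, length_bp = len)
      }
    }
  }
  if (length(segs)) do.call(rbind, segs) else NULL
}

finish_segments <- function(out) {
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer(),
                      length_class = character(), stringsAsFactors = FALSE))
  }
  segs <- do.call(rbind, out)
  segs <- segs[, c("sample_id", "chrom", "start_bp", "end_bp",
                   "n_snps", "length_bp")]
  segs$length_class <- ifelse(segs$length_bp >= 5e6, "LONG", "SHORT")
  segs <- segs[order(segs$sample_id, chrom_rank(segs$chrom), segs$start_bp), ]
  rownames(segs) <- NULL
  segs
}
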