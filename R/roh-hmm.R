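#' HMM-caller configuration for runs of homozygosity
#'
#' Two-state autozygosity HMM in the style of BCFtools/RoH: a
#' Hardy-Weinberg (HW) state emitting genotypes at their HWE frequencies
#' and an autozygous (AZ) state emitting homozygotes in proportion to
#' allele frequency with a small heterozygote error rate. Transition
#' probability across an inter-marker distance d is
#' `1 - exp(-rate * d)` in each direction. The default per-bp rates are
#' the BCFtools/RoH defaults.
#'
#' @param az_emission_het heterozygote emission probability in the AZ state
#'   (genotyping-error rate epsilon).
#' @param t_hw_to_az per-bp HW-to-AZ transition rate.
#' @param t_az_to_hw per-bp AZ-to-HW transition rate.
#' @param min_report_kb minimum reported AZ run length (kb).
#' @return a list of class `roh_hmm_config`.
#' @export
roh_hmm_config <- function(az_emission_het = 1e-3, t_hw_to_az = 6.7e-8,
                           t_az_to_hw = 5e-9, min_report_kb = 1000) {
  stopifnot(az_emission_het > 0, az_emission_het < 1,
            t_hw_to_az > 0, t_az_to_hw > 0)
  structure(list(az_emission_het = az_emission_het,
                 t_hw_to_az = t_hw_to_az, t_az_to_hw = t_az_to_hw,
                 min_report_kb = min_report_kb),
            class = "roh_hmm_config")
}

# emission probability matrix (2 states x markers) for one individual's
# dosage vector on one chromosome; missing genotypes emit 1 in both states
hmm_emissions <- function(x, p, eps) {
  q <- 1 - p
  e_hw <- ifelse(is.na(x), 1,
                 ifelse(x == 0L, p^2, ifelse(x == 1L, 2 * p * q, q^2)))
  e_az <- ifelse(is.na(x), 1,
                 ifelse(x == 0L, p * (1 - eps),
                        ifelse(x == 1L, eps, q * (1 - eps))))
  rbind(hw = e_hw, az = e_az)
}

# Viterbi decode one chromosome; returns logical AZ mask over markers
viterbi_az <- function(x, p, pos, cfg) {
  m <- length(x)
  em <- log(hmm_emissions(x, p, cfg$az_emission_het))
  d <- diff(pos)
  t_ha <- 1 - exp(-cfg$t_hw_to_az * d)   # HW -> AZ per step
  t_ah <- 1 - exp(-cfg$t_az_to_hw * d)   # AZ -> HW per step
  # delta: best log-prob ending in each state; psi: backpointers
  delta <- matrix(-Inf, 2, m)
  psi <- matrix(1L, 2, m)
  delta[, 1] <- log(0.5) + em[, 1]
  for (j in seq_len(m)[-1]) {
    lt <- log(matrix(c(1 - t_ha[j - 1], t_ah[j - 1],
                       t_ha[j - 1], 1 - t_ah[j - 1]), 2, 2))
    for (s in 1:2) {
      cand <- delta[, j - 1] + lt[, s]
      psi[s, j] <- which.max(cand)
      delta[s, j] <- cand[psi[s, j]] + em[s, j]
    }
  }
  path <- integer(m)
  path[m] <- which.max(delta[, m])
  for (j in rev(seq_len(m - 1L))) path[j] <- psi[path[j + 1L], j + 1L]
  path == 2L
}

#' Call runs of homozygosity with a two-state HMM
#'
#' Viterbi decoding of the HW/AZ chain per individual and chromosome;
#' maximal AZ runs at least `min_report_kb` long are reported. Loci whose
#' reference frequency is 0 or 1 are clamped with a pseudo-frequency
#' `1/(2n+1)` so emissions stay proper.
#'
#' @param g a `geno_matrix`.
#' @param freqs per-locus reference-allele frequencies; defaults to pooled
#'   sample frequencies.
#' @param cfg a [roh_hmm_config()].
#' @param samples optional sample selector.
#' @return data.frame of segments in the same shape as
#'   [call_roh_windows()].
#' @export
call_roh_hmm <- function(g, freqs = NULL, cfg = roh_hmm_config(),
                         samples = NULL) {
  si <- resolve_samples(g, samples)
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  stopifnot(length(freqs) == n_loci(g))
  clamp <- 1 / (2 * n_samples(g) + 1)
  freqs[!is.finite(freqs)] <- 0.5
  freqs <- pmin(pmax(freqs, clamp), 1 - clamp)
  out <- list()
  for (ch in unique(g$loci$chrom)) {
    li <- which(g$loci$chrom == ch)
    pos <- g$loci$pos_bp[li]
    p <- freqs[li]
    for (i in si) {
      x <- g$dosage[i, li]
      az <- viterbi_az(x, p, pos, cfg)
      r <- rle(az)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        len <- pos[ends[k]] - pos[starts[k]]
        if (len >= cfg$min_report_kb * 1000) {
          out[[length(out) + 1L]] <-
            data.frame(sample_id = g$samples$sample_id[i], chrom = ch,
                       start_bp = pos[starts[k]], end_bp = pos[ends[k]],
                       n_snps = ends[k] - starts[k] + 1L, length_bp = len,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  finish_segments(out)
}

#' Brute-force most-likely state path (oracle for tiny chains)
#'
#' Exhaustively maximizes the joint probability over all 2^m state paths of
#' the same HW/AZ chain. Intended as an independent check of the Viterbi
#' recursion on chains of at most ~15 markers.
#'
#' @param x dosage vector.
#' @param p per-locus reference frequencies.
#' @param pos marker positions (bp).
#' @param cfg a [roh_hmm_config()].
#' @return logical AZ mask of the maximizing path.
#' @export
enumerate_az_path <- function(x, p, pos, cfg = roh_hmm_config()) {
  m <- length(x)
  stopifnot(m <= 15)
  em <- log(hmm_emissions(x, p, cfg$az_emission_het))
  d <- diff(pos)
  t_ha <- 1 - exp(-cfg$t_hw_to_az * d)
  t_ah <- 1 - exp(-cfg$t_az_to_hw * d)
  best <- -Inf; best_path <- NULL
  for (code in 0:(2^m - 1)) {
    path <- as.integer(intToBits(code)[seq_len(m)]) + 1L  # 1=HW, 2=AZ
    lp <- log(0.5) + em[path[1], 1]
    for (j in seq_len(m)[-1]) {
      tr <- if (path[j - 1] == 1L) {
        if (path[j] == 2L) t_ha[j - 1] else 1 - t_ha[j - 1]
      } else {
        if (path[j] == 1L) t_ah[j - 1] else 1 - t_ah[j - 1]
      }
      lp <- lp + log(tr) + em[path[j], j]
    }
    if (lp > best) { best <- lp; best_path <- path }
  }
  best_path == 2L
}
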