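#' Founder allele-frequency sampler
#'
#' Default spectrum for synthetic founders: minor-allele frequency uniform
#' on `[lo, hi]`, with the reference allele equally likely to be the minor
#' or major one (folded spectrum, random orientation).
#'
#' @param lo,hi minor-allele-frequency bounds.
#' @return a function `f(n)` returning `n` reference-allele frequencies.
#' @export
founder_freq_uniform <- function(lo = 0.05, hi = 0.5) {
  force(lo); force(hi)
  function(n) {
    maf <- stats::runif(n, lo, hi)
    ifelse(stats::runif(n) < 0.5, maf, 1 - maf)
  }
}

#' Empirical founder-frequency sampler from a genotype panel
#'
#' @param g a `geno_matrix`.
#' @return a function `f(n)` resampling (with replacement) from the
#'   panel's polymorphic allele frequencies.
#' @export
founder_freq_empirical <- function(g) {
  p <- allele_frequencies(g)
  p <- p[is.finite(p) & p > 0 & p < 1]
  if (!length(p)) stop("no polymorphic loci in panel")
  function(n) sample(p, n, replace = TRUE)
}

#' Pedigrees of replicated families for known relationship pairs
#'
#' Builds `n_pairs` independent families whose focal pair has the
#' requested relationship, and returns the pedigree together with the
#' focal pair ids and the expected IBD-state probabilities:
#' parent-offspring (Z = (0,1,0)), full siblings ((1/4,1/2,1/4)),
#' half siblings ((1/2,1/2,0)), first cousins ((3/4,1/4,0)).
#'
#' @param type `"po"`, `"fs"`, `"hs"` or `"fc"`.
#' @param n_pairs number of independent families.
#' @return a list: `ped` ([pedigree()]), `pairs` (2-column matrix of ids),
#'   `expected_z`, `expected_pi_hat`.
#' @export
ped_relationship_pairs <- function(type = c("po", "fs", "hs", "fc"),
                                   n_pairs = 50L) {
  type <- match.arg(type)
  id <- sire <- dam <- character(0)
  pairs <- matrix(character(0), 0, 2)
  add <- function(i, s, d) {
    id <<- c(id, i); sire <<- c(sire, s); dam <<- c(dam, d)
  }
  for (k in seq_len(n_pairs)) {
    p <- function(x) paste0(type, k, "_", x)
    switch(type,
      po = {  # father and child
        add(p("f"), NA, NA); add(p("m"), NA, NA)
        add(p("c"), p("f"), p("m"))
        pairs <- rbind(pairs, c(p("f"), p("c")))
      },
      fs = {
        add(p("f"), NA, NA); add(p("m"), NA, NA)
        add(p("s1"), p("f"), p("m")); add(p("s2"), p("f"), p("m"))
        pairs <- rbind(pairs, c(p("s1"), p("s2")))
      },
      hs = {  # shared sire, unrelated dams
        add(p("f"), NA, NA); add(p("m1"), NA, NA); add(p("m2"), NA, NA)
        add(p("h1"), p("f"), p("m1")); add(p("h2"), p("f"), p("m2"))
        pairs <- rbind(pairs, c(p("h1"), p("h2")))
      },
      fc = {  # children of two full sibs married to unrelated spouses
        add(p("f"), NA, NA); add(p("m"), NA, NA)
        add(p("u1"), NA, NA); add(p("u2"), NA, NA)
        add(p("s1"), p("f"), p("m")); add(p("s2"), p("f"), p("m"))
        add(p("c1"), p("s1"), p("u1")); add(p("c2"), p("s2"), p("u2"))
        pairs <- rbind(pairs, c(p("c1"), p("c2")))
      })
  }
  ez <- switch(type,
               po = c(0, 1, 0), fs = c(0.25, 0.5, 0.25),
               hs = c(0.5, 0.5, 0), fc = c(0.75, 0.25, 0))
  list(ped = pedigree(id, sire, dam), pairs = pairs,
       expected_z = ez, expected_pi_hat = ez[3] + ez[2] / 2)
}

#' Pedigrees producing offspring with a target inbreeding coefficient
#'
#' Consanguineous-mating designs: `f_target` 0 (founder), 1/16 (first-
#' cousin mating), 1/8 (half-sib mating) or 1/4 (full-sib mating). Returns
#' `n` independent families; the focal (inbred) individuals are listed in
#' `focal`.
#'
#' @param f_target one of 0, 1/16, 1/8, 1/4.
#' @param n number of focal individuals.
#' @return a list: `ped`, `focal` (character vector of ids), `f_target`.
#' @export
ped_inbred_cohort <- function(f_target, n = 50L) {
  stopifnot(f_target %in% c(0, 1 / 16, 1 / 8, 1 / 4))
  id <- sire <- dam <- character(0)
  focal <- character(n)
  add <- function(i, s, d) {
    id <<- c(id, i); sire <<- c(sire, s); dam <<- c(dam, d)
  }
  for (k in seq_len(n)) {
    p <- function(x) paste0("F", round(f_target * 16), "_", k, "_", x)
    if (f_target == 0) {
      add(p("x"), NA, NA)
      focal[k] <- p("x")
    } else if (f_target == 1 / 4) {
      add(p("f"), NA, NA); add(p("m"), NA, NA)
      add(p("s1"), p("f"), p("m")); add(p("s2"), p("f"), p("m"))
      add(p("x"), p("s1"), p("s2"))
      focal[k] <- p("x")
    } else if (f_target == 1 / 8) {
      add(p("f"), NA, NA); add(p("m1"), NA, NA); add(p("m2"), NA, NA)
      add(p("h1"), p("f"), p("m1")); add(p("h2"), p("f"), p("m2"))
      add(p("x"), p("h1"), p("h2"))
      focal[k] <- p("x")
    } else {
      add(p("f"), NA, NA); add(p("m"), NA, NA)
      add(p("u1"), NA, NA); add(p("u2"), NA, NA)
      add(p("s1"), p("f"), p("m")); add(p("s2"), p("f"), p("m"))
      add(p("c1"), p("s1"), p("u1")); add(p("c2"), p("s2"), p("u2"))
      add(p("x"), p("c1"), p("c2"))
      focal[k] <- p("x")
    }
  }
  list(ped = pedigree(id, sire, dam), focal = focal, f_target = f_target)
}

#' Plant autozygous tracts into a genotype matrix
#'
#' Inside each specified interval the individual is made homozygous, with
#' the allele drawn per marker from the reference frequency (hom-ref with
#' probability p), mimicking an autozygous segment on a panel of unlinked
#' markers; heterozygotes are injected at rate `eps_plant` to model
#' genotyping error. Overlapping intervals for one individual are merged
#' with a warning. The truth table of planted intervals is returned for
#' caller validation.
#'
#' @param g a `geno_matrix`.
#' @param spec data.frame with columns `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`.
#' @param freqs per-locus reference frequencies (default: pooled from `g`).
#' @param eps_plant heterozygote error rate inside tracts.
#' @param seed integer seed.
#' @return a list: `g` (modified matrix), `truth` (merged intervals with
#'   `length_bp`).
#' @export
plant_roh <- function(g, spec, freqs = NULL, eps_plant = 0, seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  if (!nrow(spec)) return(list(g = g, truth = spec))
  merged <- list()
  for (sid in unique(spec$sample_id)) {
    for (ch in unique(spec$chrom[spec$sample_id == sid])) {
      s <- spec[spec$sample_id == sid & spec$chrom == ch, , drop = FALSE]
      iv <- merge_intervals(s$start_bp, s$end_bp)
      if (nrow(iv) < nrow(s))
        warning("overlapping planted intervals merged for ", sid,
                " chr", ch)
      merged[[length(merged) + 1L]] <-
        data.frame(sample_id = sid, chrom = ch,
                   start_bp = iv[, 1], end_bp = iv[, 2],
                   stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, merged)
  truth$length_bp <- truth$end_bp - truth$start_bp
  d <- g$dosage
  for (k in seq_len(nrow(truth))) {
    i <- match(truth$sample_id[k], g$samples$sample_id)
    if (is.na(i)) stop("unknown sample id in spec: ", truth$sample_id[k])
    li <- which(g$loci$chrom == truth$chrom[k] &
                g$loci$pos_bp >= truth$start_bp[k] &
                g$loci$pos_bp <= truth$end_bp[k])
    hom <- ifelse(stats::runif(length(li)) < freqs[li], 0L, 2L)
    err <- stats::runif(length(li)) < eps_plant
    hom[err] <- 1L
    d[i, li] <- hom
  }
  out <- g
  out$dosage <- d
  list(g = out, truth = truth)
}

#' Sample two population cohorts from a Wright-Fisher endpoint
#'
#' Individuals are drawn as Hardy-Weinberg genotypes from each deme's
#' final-generation allele frequencies and laid out on a genome map, so
#' the drift simulator's output can flow into every estimator in the
#' package.
#'
#' @param wf a [wf_simulate()] result whose `n_loci` matches the map's
#'   marker count.
#' @param gmap a [genome_map()].
#' @param n_a,n_b cohort sizes.
#' @param seed integer seed.
#' @param labels population labels for the two demes.
#' @param cohort_year sampling year recorded in the metadata.
#' @return a `geno_matrix` of `n_a + n_b` samples.
#' @export
make_two_deme_cohorts <- function(wf, gmap, n_a, n_b, seed = 1L,
                                  labels = c("ABS", "PLE"),
                                  cohort_year = 2000L) {
  mk <- gmap$markers
  stopifnot(length(wf$p_a) == nrow(mk))
  set.seed(as.integer(seed))
  draw <- function(p, n) {
    # dosage counts ALT alleles; p is the reference frequency
    matrix(stats::rbinom(n * length(p), 2L, rep(1 - p, each = n)), nrow = n)
  }
  dosage <- rbind(draw(wf$p_a, n_a), draw(wf$p_b, n_b))
  samples <- data.frame(
    sample_id = c(sprintf("%s_%s_%03d", labels[1], cohort_year, seq_len(n_a)),
                  sprintf("%s_%s_%03d", labels[2], cohort_year, seq_len(n_b))),
    population = rep(labels, c(n_a, n_b)),
    cohort_year = as.integer(cohort_year),
    stringsAsFactors = FALSE)
  geno_matrix(dosage,
              data.frame(chrom = mk$chrom, pos_bp = mk$pos_bp,
                         snp_id = mk$snp_id, ref = "A", alt = "G",
                         stringsAsFactors = FALSE),
              samples)
}

#' Inject missing genotype calls
#'
#' @param g a `geno_matrix`.
#' @param rate per-call missingness probability.
#' @param seed integer seed.
#' @return a `geno_matrix` with calls masked at random.
#' @export
add_missingness <- function(g, rate, seed = 1L) {
  set.seed(as.integer(seed))
  d <- g$dosage
  d[stats::runif(length(d)) < rate] <- NA_integer_
  out <- g
  out$dosage <- d
  out
}
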