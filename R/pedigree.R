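#' Construct a pedigree
#'
#' Founder/sire/dam triples in topological order (parents before
#' offspring). Founders have `NA` parents; an individual has either both
#' parents known or none.
#'
#' @param id character vector of individual ids (unique).
#' @param sire,dam character vectors of parent ids (`NA` for founders).
#' @return data.frame of class `pedigree`.
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  stopifnot(length(id) == length(sire), length(id) == length(dam))
  if (anyDuplicated(id)) stop("duplicate pedigree ids")
  if (any(xor(is.na(sire), is.na(dam))))
    stop("individuals must have both parents or neither")
  known <- !is.na(sire)
  if (any(known & (match(sire, id) >= seq_along(id) |
                   match(dam, id) >= seq_along(id)), na.rm = TRUE))
    stop("parents must precede offspring (pedigree cycle or misordering)")
  if (anyNA(match(sire[known], id)) || anyNA(match(dam[known], id)))
    stop("unknown parent id")
  structure(data.frame(id = id, sire = sire, dam = dam,
                       stringsAsFactors = FALSE),
            class = c("pedigree", "data.frame"))
}

#' Pedigree kinship matrix and inbreeding coefficients
#'
#' Recursive (tabular) computation of pairwise kinship phi and the
#' pedigree inbreeding coefficient `F_ped(i) = phi(sire_i, dam_i)`.
#' Expected PI_HAT between two non-inbred individuals is `2 phi`.
#'
#' @param ped a [pedigree()].
#' @return a list: `phi` (n x n kinship matrix), `f_ped` (named vector).
#' @export
pedigree_kinship <- function(ped) {
  n <- nrow(ped)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[si[i], di[i]])
      for (j in seq_len(i - 1L)) {
        phi[i, j] <- phi[j, i] <- 0.5 * (phi[si[i], j] + phi[di[i], j])
      }
    }
  }
  f <- ifelse(is.na(si), 0, phi[cbind(si, di)])
  names(f) <- ped$id
  list(phi = phi, f_ped = f)
}

#' Synthetic genome map
#'
#' A sparse-array genome: `n_chrom` autosomes with sizes decaying like an
#' avian karyotype (a few macrochromosomes, many microchromosomes),
#' totalling `genome_bp`, with markers placed uniformly at random at a
#' mean spacing of `spacing_bp`.
#'
#' @param n_chrom number of autosomes.
#' @param genome_bp total genome length in bp.
#' @param spacing_bp target mean inter-marker distance in bp.
#' @param seed integer seed for marker placement.
#' @return a list of class `genome_map`: `chrom` (data.frame `chrom`,
#'   `length_bp`), `markers` (data.frame `chrom`, `pos_bp`, `snp_id`).
#' @export
genome_map <- function(n_chrom = 30L, genome_bp = 1e9, spacing_bp = 85500,
                       seed = 1L) {
  set.seed(as.integer(seed))
  w <- exp(-0.12 * seq_len(n_chrom))     # geometric size decay
  len <- round(genome_bp * w / sum(w))
  chroms <- data.frame(chrom = as.character(seq_len(n_chrom)),
                       length_bp = len, stringsAsFactors = FALSE)
  mk <- lapply(seq_len(n_chrom), function(c) {
    nm <- max(2L, round(len[c] / spacing_bp))
    pos <- sort(sample.int(len[c] - 1L, nm))
    data.frame(chrom = as.character(c), pos_bp = pos,
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, mk)
  markers$snp_id <- paste0("snp", seq_len(nrow(markers)))
  structure(list(chrom = chroms, markers = markers), class = "genome_map")
}

# --- haplotype segment algebra ----------------------------------------
# a haplotype on one chromosome is a piecewise-constant map from [0, L)
# to founder-haplotype ids: list(brk = segment start positions
# (brk[1] == 0), id = integer ids); segment k covers [brk[k], brk[k+1])

hap_slice <- function(hap, a, b) {
  # segments of hap restricted to [a, b)
  k0 <- findInterval(a, hap$brk)
  k1 <- findInterval(b - 1e-9, hap$brk)
  brk <- hap$brk[k0:k1]; brk[1] <- a
  list(brk = brk, id = hap$id[k0:k1])
}

hap_simplify <- function(hap) {
  keep <- c(TRUE, hap$id[-1] != hap$id[-length(hap$id)])
  list(brk = hap$brk[keep], id = hap$id[keep])
}

# one meiosis on one chromosome: recombine the parent's two haplotypes
# with crossovers as a Poisson process (Haldane, no interference)
meiosis <- function(hap1, hap2, len_bp, cm_per_mb) {
  n_xo <- stats::rpois(1, len_bp / 1e6 * cm_per_mb / 100)
  xo <- sort(stats::runif(n_xo, 0, len_bp))
  phase <- sample.int(2L, 1L)
  bounds <- c(0, xo, len_bp)
  parts <- vector("list", length(bounds) - 1L)
  for (k in seq_along(parts)) {
    src <- if ((phase + k) %% 2L == 0L) hap1 else hap2
    parts[[k]] <- hap_slice(src, bounds[k], bounds[k + 1])
  }
  hap_simplify(list(brk = unlist(lapply(parts, `[[`, "brk")),
                    id = unlist(lapply(parts, `[[`, "id"))))
}

# ids of both haplotypes of one individual at given positions
hap_ids_at <- function(hap, pos) hap$id[findInterval(pos, hap$brk)]

# intervals where the two haplotypes carry the same founder id
autozygous_intervals <- function(hap1, hap2, len_bp) {
  brk <- sort(unique(c(hap1$brk, hap2$brk)))
  id1 <- hap_ids_at(hap1, brk); id2 <- hap_ids_at(hap2, brk)
  eq <- id1 == id2
  ends <- c(brk[-1], len_bp)
  r <- rle(eq)
  ce <- cumsum(r$lengths); cs <- ce - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(NULL)
  data.frame(start_bp = brk[cs[keep]], end_bp = ends[ce[keep]])
}

#' Drop genes through a pedigree with recombination
#'
#' Founders receive two haplotypes whose marker alleles are independent
#' Bernoulli draws from the founder allele frequencies (HWE); each meiosis
#' transmits one recombinant parental haplotype with crossovers as a
#' Poisson process along the map (Haldane model, default 1 cM/Mb).
#' Founder-haplotype identity is tracked as exact segment structure, so
#' the returned truth (autozygous tracts, realized inbreeding, pairwise
#' IBD states) is exact, not marker-approximated.
#'
#' @param ped a [pedigree()].
#' @param gmap a [genome_map()].
#' @param founder_freqs per-marker reference-allele frequencies, a single
#'   value, or a sampler function `f(n)`; default: minor-allele frequency
#'   uniform on `[0.05, 0.5]` with random allele orientation.
#' @param seed integer seed.
#' @param cm_per_mb recombination rate (centimorgan per megabase).
#' @return a list of class `gene_drop`:
#'   `g` (a `geno_matrix`), `freqs` (founder frequencies used),
#'   `f_ped`/`phi` (pedigree expectations), `autozygous_tracts`
#'   (data.frame `sample_id`, `chrom`, `start_bp`, `end_bp`, `length_bp`),
#'   `f_realized` (named vector: realized autozygous genome fraction),
#'   `haplotypes` (internal segment structures for [true_ibd_sharing()]).
#' @export
gene_drop <- function(ped, gmap, founder_freqs = NULL, seed = 1L,
                      cm_per_mb = 1.0) {
  set.seed(as.integer(seed))
  mk <- gmap$markers
  nm <- nrow(mk)
  if (is.null(founder_freqs)) {
    maf <- stats::runif(nm, 0.05, 0.5)
    flip <- stats::runif(nm) < 0.5
    freqs <- ifelse(flip, maf, 1 - maf)
  } else if (is.function(founder_freqs)) {
    freqs <- founder_freqs(nm)
  } else if (length(founder_freqs) == 1L) {
    freqs <- rep(founder_freqs, nm)
  } else {
    stopifnot(length(founder_freqs) == nm)
    freqs <- founder_freqs
  }
  stopifnot(all(freqs > 0), all(freqs < 1))

  n <- nrow(ped)
  founders <- which(is.na(ped$sire))
  n_hap <- 2L * length(founders)
  # founder haplotype alleles at markers: 0 = ref, 1 = alt
  founder_alleles <- matrix(stats::rbinom(n_hap * nm, 1L,
                                          rep(1 - freqs, each = n_hap)),
                            nrow = n_hap)
  hap_no <- integer(n)                      # founder index per individual
  hap_no[founders] <- seq_along(founders)
  chroms <- gmap$chrom
  nchr <- nrow(chroms)
  # haplotypes[[i]][[c]] = list(h1, h2)
  haplotypes <- vector("list", n)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    haplotypes[[i]] <- vector("list", nchr)
    for (c in seq_len(nchr)) {
      L <- chroms$length_bp[c]
      if (is.na(si[i])) {
        f <- hap_no[i]
        haplotypes[[i]][[c]] <- list(h1 = list(brk = 0, id = 2L * f - 1L),
                                     h2 = list(brk = 0, id = 2L * f))
      } else {
        hs <- haplotypes[[si[i]]][[c]]
        hd <- haplotypes[[di[i]]][[c]]
        haplotypes[[i]][[c]] <-
          list(h1 = meiosis(hs$h1, hs$h2, L, cm_per_mb),
               h2 = meiosis(hd$h1, hd$h2, L, cm_per_mb))
      }
    }
  }

  # genotypes at markers + autozygosity truth
  dosage <- matrix(NA_integer_, n, nm)
  tracts <- list()
  f_real <- numeric(n)
  genome_bp <- sum(chroms$length_bp)
  mk_idx <- split(seq_len(nm), factor(mk$chrom, levels = chroms$chrom))
  for (i in seq_len(n)) {
    az_total <- 0
    for (c in seq_len(nchr)) {
      idx <- mk_idx[[c]]
      pos <- mk$pos_bp[idx]
      hp <- haplotypes[[i]][[c]]
      id1 <- hap_ids_at(hp$h1, pos)
      id2 <- hap_ids_at(hp$h2, pos)
      a1 <- founder_alleles[cbind(id1, idx)]
      a2 <- founder_alleles[cbind(id2, idx)]
      dosage[i, idx] <- a1 + a2
      az <- autozygous_intervals(hp$h1, hp$h2, chroms$length_bp[c])
      if (!is.null(az)) {
        az$sample_id <- ped$id[i]; az$chrom <- chroms$chrom[c]
        az_total <- az_total + sum(az$end_bp - az$start_bp)
        tracts[[length(tracts) + 1L]] <- az
      }
    }
    f_real[i] <- az_total / genome_bp
  }
  names(f_real) <- ped$id
  kin <- pedigree_kinship(ped)
  tr <- if (length(tracts)) {
    tr <- do.call(rbind, tracts)
    tr$length_bp <- tr$end_bp - tr$start_bp
    tr[, c("sample_id", "chrom", "start_bp", "end_bp", "length_bp")]
  } else {
    data.frame(sample_id = character(), chrom = character(),
               start_bp = numeric(), end_bp = numeric(),
               length_bp = numeric())
  }
  g <- geno_matrix(dosage,
                   data.frame(chrom = mk$chrom, pos_bp = mk$pos_bp,
                              snp_id = mk$snp_id, ref = "A", alt = "G",
                              stringsAsFactors = FALSE),
                   data.frame(sample_id = ped$id, stringsAsFactors = FALSE))
  structure(list(g = g, freqs = freqs, f_ped = kin$f_ped, phi = kin$phi,
                 autozygous_tracts = tr, f_realized = f_real,
                 haplotypes = haplotypes, ped = ped, gmap = gmap),
            class = "gene_drop")
}

#' True genome-wide IBD sharing between two gene-dropped individuals
#'
#' Fractions of the genome where the pair shares 0, 1 or 2 founder
#' haplotypes, computed exactly from the segment structures.
#'
#' @param gd a [gene_drop()] result.
#' @param id_a,id_b individual ids.
#' @return named numeric vector `(z0, z1, z2)` summing to 1.
#' @export
true_ibd_sharing <- function(gd, id_a, id_b) {
  ia <- match(id_a, gd$ped$id); ib <- match(id_b, gd$ped$id)
  stopifnot(!is.na(ia), !is.na(ib))
  tot <- c(0, 0, 0)
  for (c in seq_len(nrow(gd$gmap$chrom))) {
    L <- gd$gmap$chrom$length_bp[c]
    ha <- gd$haplotypes[[ia]][[c]]; hb <- gd$haplotypes[[ib]][[c]]
    brk <- sort(unique(c(ha$h1$brk, ha$h2$brk, hb$h1$brk, hb$h2$brk)))
    ends <- c(brk[-1], L)
    a1 <- hap_ids_at(ha$h1, brk); a2 <- hap_ids_at(ha$h2, brk)
    b1 <- hap_ids_at(hb$h1, brk); b2 <- hap_ids_at(hb$h2, brk)
    shared <- ifelse((a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1), 2L,
                     ifelse(a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2,
                            1L, 0L))
    w <- ends - brk
    for (s in 0:2) tot[s + 1] <- tot[s + 1] + sum(w[shared == s])
  }
  tot <- tot / sum(tot)
  c(z0 = tot[1], z1 = tot[2], z2 = tot[3])
}
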