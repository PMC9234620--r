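#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses PLINK's whitespace-separated text dialect. The `.map` file gives
#' one row per SNP (chrom, snp_id, cM, bp); the `.ped` file gives six
#' mandatory columns (family, individual, father, mother, sex, phenotype)
#' followed by two allele columns per SNP, with `0` marking a missing
#' allele. The reference allele for dosage coding is the first non-missing
#' allele encountered at each SNP (recorded in the locus table), so a file
#' written by [write_plink_text()] round-trips bit-exactly up to allele
#' order.
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @return a `geno_matrix`; `population` is filled from the family column.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos_bp"))
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop(".ped has ", ncol(ped), " columns but .map implies ", 6 + 2 * m)
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    warning(sum(half), " half-missing genotype(s) set to missing")
    a1[half] <- "0"; a2[half] <- "0"
  }
  dosage <- matrix(NA_integer_, nrow(ped), m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    obs <- c(rbind(a1[, j], a2[, j]))
    seen <- unique(obs[obs != "0"])
    if (length(seen) > 2)
      stop("more than two alleles at ", map$snp_id[j], ": ",
           paste(seen, collapse = ","))
    ref[j] <- if (length(seen) >= 1) seen[1] else "A"
    alt[j] <- if (length(seen) == 2) seen[2] else "G"
    ok <- a1[, j] != "0"
    dosage[ok, j] <- (a1[ok, j] != ref[j]) + (a2[ok, j] != ref[j])
  }
  loci <- data.frame(chrom = as.character(map$chrom), pos_bp = map$pos_bp,
                     snp_id = map$snp_id, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = ped[[2]],
                        population = ifelse(ped[[1]] == "0", NA, ped[[1]]),
                        stringsAsFactors = FALSE)
  geno_matrix(dosage, loci, samples)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' @param g a `geno_matrix`.
#' @param ped_path,map_path output file paths.
#' @return the two paths, invisibly.
#' @export
write_plink_text <- function(g, ped_path, map_path) {
  loci <- g$loci
  ref <- if ("ref" %in% names(loci)) loci$ref else rep("A", nrow(loci))
  alt <- if ("alt" %in% names(loci)) loci$alt else rep("G", nrow(loci))
  utils::write.table(
    data.frame(loci$chrom, loci$snp_id, 0, loci$pos_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  d <- g$dosage
  n <- nrow(d); m <- ncol(d)
  refm <- matrix(rep(ref, each = n), n, m)
  altm <- matrix(rep(alt, each = n), n, m)
  hom_alt <- !is.na(d) & d == 2L
  hom_ref <- !is.na(d) & d == 0L
  a1 <- refm; a1[hom_alt] <- altm[hom_alt]   # first allele: ref unless hom-alt
  a2 <- altm; a2[hom_ref] <- refm[hom_ref]   # second allele: alt unless hom-ref
  a1[is.na(d)] <- "0"; a2[is.na(d)] <- "0"
  inter <- matrix("", n, 2 * m)
  inter[, 2 * seq_len(m) - 1] <- a1
  inter[, 2 * seq_len(m)] <- a2
  fam <- ifelse(is.na(g$samples$population), "0", g$samples$population)
  lines <- vapply(seq_len(n), function(i)
    paste(c(fam[i], g$samples$sample_id[i], "0", "0", "0", "-9",
            inter[i, ]), collapse = " "), character(1))
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}
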