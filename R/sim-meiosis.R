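#' Simulate one gamete by meiosis
#'
#' Recombines the two phased haplotypes of a parent into a gamete. Crossover
#' counts per chromosome are Poisson with mean equal to the chromosome map
#' length in Morgans, crossover positions are uniform (no interference),
#' chromosomes assort independently, and there is no mutation.
#'
#' @param hap1,hap2 Integer vectors of 0/1 alleles, one entry per locus in
#'   `locus_map` order.
#' @param locus_map A locus map tibble with columns `chrom`, `pos` (Morgans)
#'   and chromosome lengths taken from `chrom_length` (single value, in
#'   Morgans).
#' @param chrom_length Chromosome map length in Morgans (default 0.1).
#' @return Integer vector of alleles: a legal mosaic of `hap1` and `hap2`.
#' @export
meiosis_gamete <- function(hap1, hap2, locus_map, chrom_length = 0.1) {
  gamete <- hap1
  chroms <- unique(locus_map$chrom)
  for (ch in chroms) {
    at <- which(locus_map$chrom == ch)
    pos <- locus_map$pos[at]
    n_x <- rpois(1L, chrom_length)
    start <- rbinom(1L, 1L, 0.5)
    if (n_x == 0L) {
      if (start == 1L) gamete[at] <- hap2[at]
    } else {
      cuts <- sort(runif(n_x, 0, chrom_length))
      seg <- findInterval(pos, cuts)
      use2 <- (seg + start) %% 2L == 1L
      gamete[at] <- ifelse(use2, hap2[at], hap1[at])
    }
  }
  gamete
}

# Drop gametes for a whole offspring generation.
# hap1/hap2: parent haplotype matrices (individuals x loci).
# sire_row/dam_row: parent row indices per offspring.
# Returns list(hap1, hap2) for the offspring (paternal, maternal gamete).
drop_generation <- function(hap1, hap2, sire_row, dam_row, locus_map,
                            chrom_length = 0.1) {
  n_off <- length(sire_row)
  L <- ncol(hap1)
  chr_idx <- split(seq_len(L), locus_map$chrom)
  chr_pos <- lapply(chr_idx, function(at) locus_map$pos[at])
  n_chr <- length(chr_idx)
  gamete_core <- function(h1, h2) {
    g <- h1
    for (c_ in seq_len(n_chr)) {
      at <- chr_idx[[c_]]
      n_x <- rpois(1L, chrom_length)
      start <- rbinom(1L, 1L, 0.5)
      if (n_x == 0L) {
        if (start == 1L) g[at] <- h2[at]
      } else {
        cuts <- sort(runif(n_x, 0, chrom_length))
        use2 <- (findInterval(chr_pos[[c_]], cuts) + start) %% 2L == 1L
        g[at[use2]] <- h2[at[use2]]
      }
    }
    g
  }
  off1 <- matrix(0L, n_off, L)
  off2 <- matrix(0L, n_off, L)
  for (o in seq_len(n_off)) {
    sr <- sire_row[o]
    dr <- dam_row[o]
    off1[o, ] <- gamete_core(hap1[sr, ], hap2[sr, ])
    off2[o, ] <- gamete_core(hap1[dr, ], hap2[dr, ])
  }
  if ("locus" %in% names(locus_map)) {
    colnames(off1) <- locus_map$locus
    colnames(off2) <- locus_map$locus
  }
  list(hap1 = off1, hap2 = off2)
}
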