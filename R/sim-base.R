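#' Mean linkage disequilibrium between adjacent loci
#'
#' Computes LD between each pair of adjacent loci within chromosomes from
#' phased haplotypes, as squared correlation `r2` (default) or absolute
#' correlation `r` of allele indicators across haplotypes. Pairs involving a
#' monomorphic locus are skipped.
#'
#' @param haps List with `hap1`, `hap2` matrices (individuals x loci).
#' @param locus_map Locus map tibble (`chrom`, `pos`).
#' @param stat `"r2"` or `"r"`.
#' @param maf_min Loci with minor allele frequency below this are skipped.
#' @return Mean adjacent-locus LD (scalar).
#' @export
mean_adjacent_ld <- function(haps, locus_map, stat = c("r2", "r"),
                             maf_min = 0) {
  stat <- match.arg(stat)
  H <- rbind(haps$hap1, haps$hap2)
  p <- colMeans(H)
  maf <- pmin(p, 1 - p)
  vals <- c()
  for (ch in unique(locus_map$chrom)) {
    at <- which(locus_map$chrom == ch)
    if (length(at) < 2) next
    for (k in seq_len(length(at) - 1L)) {
      a <- at[k]; b <- at[k + 1L]
      if (maf[a] < maf_min || maf[b] < maf_min) next
      if (maf[a] == 0 || maf[b] == 0) next
      r <- suppressWarnings(cor(H[, a], H[, b]))
      if (is.na(r)) next
      vals <- c(vals, if (stat == "r2") r^2 else abs(r))
    }
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals)
}

#' Generate an LD-bearing base population
#'
#' Builds the set of base diplotypes from which the whole study population
#' is gene-dropped. An ancestral pool is initialised at linkage equilibrium
#' with allele frequencies drawn uniformly on `freq_range`; small-population
#' random-mating generations (with meiosis) are then iterated, which builds
#' linkage disequilibrium by drift, until the measured mean adjacent-locus
#' LD reaches `ld_target` (within `ld_tol`). Finally `n_individuals` base
#' diplotypes are produced by one more round of random mating, and the panel
#' of `n_per_chrom` loci per chromosome is selected from candidate loci that
#' pass the MAF filter (the generator oversamples candidate loci because
#' drift fixes some).
#'
#' @param n_individuals Number of base diplotypes (default 721; the first
#'   half, rounded down, are labelled male and the rest female).
#' @param n_per_chrom Loci retained per chromosome in the returned map.
#' @param n_chrom Number of chromosomes (default 10).
#' @param chrom_length Chromosome length in Morgans (default 0.1).
#' @param maf_min Minimum minor allele frequency in the base (default 0.01).
#' @param ld_target Target mean adjacent-locus LD (default 0.30).
#' @param ld_stat LD statistic, `"r2"` (default) or `"r"`.
#' @param ld_tol Half-width of the acceptable LD band (default 0.05).
#' @param pool_size Size of the drifting ancestral pool (default 100).
#' @param freq_range Range of initial allele frequencies (default c(0.2, 0.8)).
#' @param oversample Candidate loci simulated per retained locus (default 8).
#' @param max_generations Cap on drift generations before giving up.
#' @return List with `locus_map` (tibble: `locus`, `chrom`, `pos`, `is_qtl`
#'   initialised to `FALSE`), `haplotypes` (list `hap1`, `hap2`), `sex`
#'   (character vector), and attributes `ld` (measured) and
#'   `drift_generations`.
#' @export
sim_base_population <- function(n_individuals = 721,
                                n_per_chrom = 20,
                                n_chrom = 10,
                                chrom_length = 0.1,
                                maf_min = 0.01,
                                ld_target = 0.30,
                                ld_stat = c("r2", "r"),
                                ld_tol = 0.05,
                                pool_size = 100,
                                freq_range = c(0.2, 0.8),
                                oversample = 8,
                                max_generations = 400) {
  ld_stat <- match.arg(ld_stat)
  m_per <- ceiling(n_per_chrom * oversample)
  cand_map <- tibble(
    chrom = rep(seq_len(n_chrom), each = m_per),
    pos = rep((seq_len(m_per) - 0.5) / m_per * chrom_length, n_chrom)
  )
  L <- nrow(cand_map)
  p0 <- runif(L, freq_range[1], freq_range[2])
  # linkage-equilibrium start: independent Bernoulli alleles per haplotype
  hap1 <- matrix(rbinom(pool_size * L, 1L, rep(p0, each = pool_size)),
                 pool_size, L, byrow = FALSE)
  hap2 <- matrix(rbinom(pool_size * L, 1L, rep(p0, each = pool_size)),
                 pool_size, L, byrow = FALSE)
  sex <- rep(c("male", "female"), length.out = pool_size)
  males <- which(sex == "male"); females <- which(sex == "female")

  # panel selection rule used both for LD monitoring during the drift and
  # for the final returned panel: per chromosome, n_per_chrom loci passing
  # the MAF filter, spread as evenly as possible over qualifying candidates
  select_panel <- function(hap1, hap2) {
    maf <- {
      p <- (colMeans(hap1) + colMeans(hap2)) / 2
      pmin(p, 1 - p)
    }
    keep <- integer(0)
    for (ch in seq_len(n_chrom)) {
      at <- which(cand_map$chrom == ch)
      ok <- at[maf[at] >= maf_min]
      if (length(ok) < n_per_chrom) return(NULL)
      pick <- ok[unique(round(seq(1, length(ok), length.out = n_per_chrom)))]
      # rounding can collide; fill from unused qualifying loci
      while (length(pick) < n_per_chrom) {
        extra <- setdiff(ok, pick)
        pick <- sort(c(pick, extra[1]))
      }
      keep <- c(keep, pick)
    }
    keep
  }
  panel_ld <- function(hap1, hap2, keep) {
    mean_adjacent_ld(list(hap1 = hap1[, keep, drop = FALSE],
                          hap2 = hap2[, keep, drop = FALSE]),
                     cand_map[keep, , drop = FALSE], stat = ld_stat)
  }

  gens <- 0L
  repeat {
    keep <- select_panel(hap1, hap2)
    if (is.null(keep)) {
      abort(paste0(
        "drift fixed too many candidate loci before reaching the LD ",
        "target; increase oversample or pool_size"
      ))
    }
    ld <- panel_ld(hap1, hap2, keep)
    if (!is.na(ld) && ld >= ld_target) break
    if (gens >= max_generations) {
      abort(paste0(
        "adjacent-locus LD target ", ld_target, " not reached after ",
        max_generations, " drift generations (measured ", round(ld, 3),
        "); try a smaller pool_size"
      ))
    }
    sire_row <- sample(males, pool_size, replace = TRUE)
    dam_row <- sample(females, pool_size, replace = TRUE)
    off <- drop_generation(hap1, hap2, sire_row, dam_row, cand_map, chrom_length)
    hap1 <- off$hap1; hap2 <- off$hap2
    gens <- gens + 1L
  }

  # expand the pool into the base diplotypes by one round of random mating
  sire_row <- sample(males, n_individuals, replace = TRUE)
  dam_row <- sample(females, n_individuals, replace = TRUE)
  base <- drop_generation(hap1, hap2, sire_row, dam_row, cand_map, chrom_length)

  keep <- select_panel(base$hap1, base$hap2)
  if (is.null(keep)) {
    abort(paste0("a chromosome has fewer than ", n_per_chrom,
                 " loci with MAF >= ", maf_min,
                 " in the base; increase oversample or pool_size"))
  }
  locus_names <- unlist(lapply(seq_len(n_chrom), function(ch)
    paste0("c", ch, "_l", seq_len(n_per_chrom))))
  locus_map <- tibble(
    locus = locus_names,
    chrom = cand_map$chrom[keep],
    pos = cand_map$pos[keep],
    is_qtl = FALSE
  )
  haps <- list(hap1 = base$hap1[, keep, drop = FALSE],
               hap2 = base$hap2[, keep, drop = FALSE])
  colnames(haps$hap1) <- locus_map$locus
  colnames(haps$hap2) <- locus_map$locus
  n_male <- floor(n_individuals / 2)
  out <- list(
    locus_map = locus_map,
    haplotypes = haps,
    sex = c(rep("male", n_male), rep("female", n_individuals - n_male))
  )
  attr(out, "ld") <- mean_adjacent_ld(haps, locus_map, stat = ld_stat,
                                      maf_min = 0)
  attr(out, "drift_generations") <- gens
  out
}

#' Flag QTL on a locus map
#'
#' Randomly designates `n_qtl_per_chrom` loci per chromosome as QTL; the
#' rest are markers.
#'
#' @param locus_map A locus map tibble (`locus`, `chrom`, `pos`, `is_qtl`).
#' @param n_qtl_per_chrom QTL per chromosome (e.g. 5 for the 200-locus
#'   panel, 50 for the 2000-locus panel).
#' @return The locus map with `is_qtl` set.
#' @export
assign_qtl <- function(locus_map, n_qtl_per_chrom) {
  locus_map$is_qtl <- FALSE
  for (ch in unique(locus_map$chrom)) {
    at <- which(locus_map$chrom == ch)
    if (n_qtl_per_chrom > length(at)) {
      abort("n_qtl_per_chrom exceeds loci on a chromosome")
    }
    locus_map$is_qtl[sample(at, n_qtl_per_chrom)] <- TRUE
  }
  locus_map
}

#' Sample QTL substitution effects
#'
#' Effects are i.i.d. Normal with mean `mu_alpha` and standard deviation
#' `sd_alpha`. Only the ratio of `mu_alpha` to `sd_alpha` matters for how
#' far the founder genotypic mean departs from zero, because the trait is
#' subsequently calibrated to a target heritability.
#'
#' @param n_qtl Number of QTL.
#' @param mu_alpha Mean substitution effect (the study's selected scenarios
#'   use 0.2; 0 gives the sign-balanced regime).
#' @param sd_alpha Standard deviation of effects (default 0.08).
#' @return Numeric vector of effects.
#' @export
sample_qtl_effects <- function(n_qtl, mu_alpha = 0.2, sd_alpha = 0.08) {
  rnorm(n_qtl, mu_alpha, sd_alpha)
}

#' Calibrate trait variances to a target heritability
#'
#' The genetic variance is the sample variance of the true breeding values
#' in the founder generation G0; the residual variance is scaled so that the
#' founder-generation heritability equals `h2`.
#'
#' @param tbv_g0 True breeding values of the G0 individuals.
#' @param h2 Target heritability, in (0, 1).
#' @return List with `sigma2_g` and `sigma2_e`.
#' @export
calibrate_trait <- function(tbv_g0, h2) {
  if (!is.numeric(h2) || length(h2) != 1 || h2 <= 0 || h2 >= 1) {
    abort("h2 must be a single value in (0, 1)")
  }
  sigma2_g <- var(tbv_g0)
  list(sigma2_g = sigma2_g, sigma2_e = sigma2_g * (1 - h2) / h2)
}
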