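#' Configuration for a simulated breeding study
#'
#' Collects every simulator parameter with defaults equal to the study
#' conditions: 721 base diplotypes, ten 0.1 Morgan chromosomes, a 200-locus
#' panel with 5 QTL and 15 markers per chromosome, adjacent-locus LD target
#' 0.30, MAF filter 0.01, 4000 dams, truncation selection of the top 200
#' males on own phenotype for five generations, heritability 0.5 and mean
#' QTL effect 0.2.
#'
#' @param n_base Number of base diplotypes.
#' @param n_dams Number of breeding females per generation (each produces
#'   one male and one female offspring, so generations have `2 * n_dams`
#'   members).
#' @param n_sires Number of males selected as sires each generation.
#' @param n_per_chrom,n_chrom,chrom_length,n_qtl_per_chrom Genome layout:
#'   loci per chromosome, chromosome count, map length (Morgans), and QTL
#'   per chromosome.
#' @param mu_alpha,sd_alpha Mean and SD of QTL substitution effects.
#' @param h2 Founder-generation heritability, in (0, 1).
#' @param maf_min,ld_target,ld_stat,ld_tol,pool_size,oversample,max_generations
#'   Base-population generator controls; see [sim_base_population()].
#' @param n_random_gens Random-mating generations between the first recorded
#'   offspring generation and the founder generation G0 (default 4).
#' @param n_select_gens Selection generations after G0 (default 5; the last
#'   is the validation generation).
#' @param independent_sires If `TRUE` (default) the two offspring of a dam
#'   may have different sires (two independent draws); if `FALSE` one sire
#'   is drawn per dam per generation.
#' @param random_sires If `TRUE`, sires are drawn at random instead of by
#'   truncation on phenotype (a no-selection control).
#' @param keep_haplotypes Keep phased haplotypes of all individuals in the
#'   returned dataset (memory-hungry; default `FALSE`).
#' @param seed Master seed for the replicate; every stage draws from a
#'   named substream derived from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_base = 721, n_dams = 4000, n_sires = 200,
                         n_per_chrom = 20, n_chrom = 10, chrom_length = 0.1,
                         n_qtl_per_chrom = 5,
                         mu_alpha = 0.2, sd_alpha = 0.08, h2 = 0.5,
                         maf_min = 0.01, ld_target = 0.30,
                         ld_stat = "r2", ld_tol = 0.05,
                         pool_size = 100, oversample = 8,
                         max_generations = 400,
                         n_random_gens = 4, n_select_gens = 5,
                         independent_sires = TRUE, random_sires = FALSE,
                         keep_haplotypes = FALSE, seed = 1) {
  cfg <- as.list(environment())
  if (h2 <= 0 || h2 >= 1) abort("h2 must be in (0, 1)")
  if (n_sires > n_dams) abort("n_sires cannot exceed the number of males")
  structure(cfg, class = "study_config")
}

# named substream seeds derived from one master seed
substream_seeds <- function(master, names) {
  set.seed(master)
  setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

#' Simulate a complete breeding study
#'
#' Runs the full generator: LD-bearing base population, expansion by random
#' mating into the founder generation G0, and `n_select_gens` generations of
#' mass phenotypic selection of sires. Returns the dataset consumed by the
#' model fitters: pedigree (recorded from the first offspring generation
#' onward), phenotypes for the training generations G0 to G(n-1), true
#' breeding values for everyone, and genotypes for the selected sires plus
#' the whole final (validation) generation.
#'
#' @param config A [study_config()].
#' @return An object of class `study_dataset`: a list with elements
#'   `pedigree` (tibble: id, sire, dam, generation, sex), `samples` (tibble:
#'   id, generation, sex, tbv, phenotype, phenotyped, genotyped),
#'   `genotypes` (integer matrix, genotyped individuals x panel loci, allele
#'   counts 0/1/2), `locus_map`, `trait` (effects and variances),
#'   `fixed_loci`, `sires_by_gen`, `config`, and optionally `haplotypes`.
#' @examples
#' \donttest{
#' cfg <- study_config(n_dams = 40, n_sires = 4, n_base = 60, pool_size = 40)
#' ds <- sim_study(cfg)
#' ds
#' }
#' @export
sim_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  sub <- substream_seeds(cfg$seed, c("base", "qtl", "expansion", "selection"))

  set.seed(sub[["base"]])
  base <- sim_base_population(
    n_individuals = cfg$n_base, n_per_chrom = cfg$n_per_chrom,
    n_chrom = cfg$n_chrom, chrom_length = cfg$chrom_length,
    maf_min = cfg$maf_min, ld_target = cfg$ld_target,
    ld_stat = cfg$ld_stat, ld_tol = cfg$ld_tol,
    pool_size = cfg$pool_size, oversample = cfg$oversample,
    max_generations = cfg$max_generations
  )
  map <- base$locus_map

  set.seed(sub[["qtl"]])
  map <- assign_qtl(map, cfg$n_qtl_per_chrom)
  qtl_cols <- which(map$is_qtl)
  alpha <- sample_qtl_effects(length(qtl_cols), cfg$mu_alpha, cfg$sd_alpha)
  names(alpha) <- map$locus[qtl_cols]

  tbv_of <- function(h) {
    drop((h$hap1[, qtl_cols, drop = FALSE] +
            h$hap2[, qtl_cols, drop = FALSE]) %*% alpha)
  }

  n_dams <- cfg$n_dams
  gen_size <- 2L * n_dams
  counter <- 0L
  new_ids <- function(n) {
    out <- as.character(counter + seq_len(n))
    counter <<- counter + n
    out
  }

  ped_rows <- list()
  samp_rows <- list()
  hap_store <- if (cfg$keep_haplotypes) list() else NULL
  geno_rows <- list()

  # --- expansion phase ------------------------------------------------------
  set.seed(sub[["expansion"]])
  base_males <- which(base$sex == "male")
  base_females <- which(base$sex == "female")

  # first recorded generation: base diplotypes sampled in pairs with
  # replacement, one male and one female offspring per pair
  pair_s <- sample(base_males, n_dams, replace = TRUE)
  pair_d <- sample(base_females, n_dams, replace = TRUE)
  off <- drop_generation(base$haplotypes$hap1, base$haplotypes$hap2,
                         rep(pair_s, 2L), rep(pair_d, 2L),
                         map, cfg$chrom_length)
  gen_label <- -(cfg$n_random_gens) # e.g. -4 for the default layout
  cur <- list(
    id = new_ids(gen_size),
    sex = rep(c("male", "female"), each = n_dams),
    hap1 = off$hap1, hap2 = off$hap2
  )
  ped_rows[[length(ped_rows) + 1L]] <- tibble(
    id = cur$id, sire = NA_character_, dam = NA_character_,
    generation = gen_label, sex = cur$sex
  )
  record_samples <- function(cur, gen_label, tbv, phen) {
    tibble(id = cur$id, generation = gen_label, sex = cur$sex,
           tbv = tbv, phenotype = phen)
  }
  samp_rows[[length(samp_rows) + 1L]] <-
    record_samples(cur, gen_label, tbv_of(cur), NA_real_)
  if (cfg$keep_haplotypes) hap_store[[length(hap_store) + 1L]] <- cur[c("id", "hap1", "hap2")]

  random_mating_step <- function(cur, gen_label) {
    males <- which(cur$sex == "male")
    females <- which(cur$sex == "female")
    # one male and one female offspring per dam, sires drawn at random
    sire_row <- c(sample(males, n_dams, replace = TRUE),
                  sample(males, n_dams, replace = TRUE))
    dam_row <- rep(females, 2L)
    off <- drop_generation(cur$hap1, cur$hap2, sire_row, dam_row,
                           map, cfg$chrom_length)
    nxt <- list(
      id = new_ids(gen_size),
      sex = rep(c("male", "female"), each = n_dams),
      hap1 = off$hap1, hap2 = off$hap2
    )
    ped_rows[[length(ped_rows) + 1L]] <<- tibble(
      id = nxt$id, sire = cur$id[sire_row], dam = cur$id[dam_row],
      generation = gen_label, sex = nxt$sex
    )
    nxt
  }

  for (g in seq_len(cfg$n_random_gens)) {
    gen_label <- gen_label + 1L
    cur <- random_mating_step(cur, gen_label)
    samp_rows[[length(samp_rows) + 1L]] <-
      record_samples(cur, gen_label,
                     tbv_of(cur),
                     NA_real_)
    if (cfg$keep_haplotypes) hap_store[[length(hap_store) + 1L]] <- cur[c("id", "hap1", "hap2")]
  }
  stopifnot(gen_label == 0L) # founder generation G0

  # --- trait calibration on G0 ---------------------------------------------
  tbv_g0 <- samp_rows[[length(samp_rows)]]$tbv
  vars <- calibrate_trait(tbv_g0, cfg$h2)
  sigma_e <- sqrt(vars$sigma2_e)
  g0_geno <- (cur$hap1 + cur$hap2)
  k_founder <- colMeans(g0_geno)

  # --- selection phase ------------------------------------------------------
  set.seed(sub[["selection"]])
  # phenotype G0 now that the residual scale is known
  samp_rows[[length(samp_rows)]]$phenotype <-
    tbv_g0 + rnorm(gen_size, 0, sigma_e)
  sires_by_gen <- list()

  for (g in seq_len(cfg$n_select_gens)) {
    cur_samp <- samp_rows[[length(samp_rows)]]
    males <- which(cur$sex == "male")
    if (length(males) < cfg$n_sires) abort("fewer males than n_sires")
    if (cfg$random_sires) {
      sel <- sample(males, cfg$n_sires)
    } else {
      phen_m <- cur_samp$phenotype[males]
      # truncation on own phenotype; ties broken by id order for determinism
      sel <- males[order(-phen_m, males)][seq_len(cfg$n_sires)]
    }
    sires_by_gen[[g]] <- cur$id[sel]
    geno_rows[[length(geno_rows) + 1L]] <- list(
      ids = cur$id[sel],
      geno = (cur$hap1[sel, , drop = FALSE] + cur$hap2[sel, , drop = FALSE])
    )
    females <- which(cur$sex == "female")
    sire_row_m <- sel[sample.int(cfg$n_sires, n_dams, replace = TRUE)]
    sire_row_f <- if (cfg$independent_sires) {
      sel[sample.int(cfg$n_sires, n_dams, replace = TRUE)]
    } else {
      sire_row_m
    }
    sire_row <- c(sire_row_m, sire_row_f)
    dam_row <- rep(females, 2L)
    off <- drop_generation(cur$hap1, cur$hap2, sire_row, dam_row,
                           map, cfg$chrom_length)
    gen_label <- gen_label + 1L
    nxt <- list(
      id = new_ids(gen_size),
      sex = rep(c("male", "female"), each = n_dams),
      hap1 = off$hap1, hap2 = off$hap2
    )
    ped_rows[[length(ped_rows) + 1L]] <- tibble(
      id = nxt$id, sire = cur$id[sire_row], dam = cur$id[dam_row],
      generation = gen_label, sex = nxt$sex
    )
    tbv <- tbv_of(nxt)
    samp_rows[[length(samp_rows) + 1L]] <-
      record_samples(nxt, gen_label, tbv, tbv + rnorm(gen_size, 0, sigma_e))
    if (cfg$keep_haplotypes) hap_store[[length(hap_store) + 1L]] <- nxt[c("id", "hap1", "hap2")]
    cur <- nxt
  }

  # --- assembly -------------------------------------------------------------
  g_last <- cfg$n_select_gens
  geno_rows[[length(geno_rows) + 1L]] <- list(
    ids = cur$id, geno = cur$hap1 + cur$hap2
  )
  geno_ids <- unlist(lapply(geno_rows, `[[`, "ids"))
  genotypes <- do.call(rbind, lapply(geno_rows, `[[`, "geno"))
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- geno_ids
  colnames(genotypes) <- map$locus

  pedigree <- dplyr::bind_rows(ped_rows)
  samples <- dplyr::bind_rows(samp_rows)
  samples$phenotyped <- samples$generation >= 0L & samples$generation < g_last
  samples$genotyped <- samples$id %in% geno_ids
  # validation phenotypes are withheld from fitting but kept for evaluation
  samples$phenotype[samples$generation == g_last] <- NA_real_

  fixed <- apply(genotypes, 2, function(col) length(unique(col)) == 1L)
  ds <- list(
    pedigree = pedigree,
    samples = samples,
    genotypes = genotypes,
    locus_map = map,
    trait = list(alpha = alpha, mu_alpha = cfg$mu_alpha,
                 sd_alpha = cfg$sd_alpha, beta = 0, h2 = cfg$h2,
                 sigma2_g = vars$sigma2_g, sigma2_e = vars$sigma2_e,
                 k = k_founder),
    fixed_loci = map$locus[fixed],
    sires_by_gen = sires_by_gen,
    config = cfg
  )
  if (cfg$keep_haplotypes) ds$haplotypes <- hap_store
  attr(ds, "ld") <- attr(base, "ld")
  attr(ds, "drift_generations") <- attr(base, "drift_generations")
  structure(ds, class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  g_last <- x$config$n_select_gens
  cat("<study_dataset>\n")
  cat("  pedigree members:", nrow(x$pedigree), "\n")
  cat("  phenotyped (training):", sum(x$samples$phenotyped), "\n")
  cat("  genotyped:", nrow(x$genotypes),
      sprintf("(%d sires + %d validation G%d)\n",
              length(unlist(x$sires_by_gen)),
              sum(x$samples$generation == g_last), g_last))
  cat("  panel loci:", nrow(x$locus_map),
      sprintf("(%d QTL, %d markers; %d fixed)\n", sum(x$locus_map$is_qtl),
              sum(!x$locus_map$is_qtl), length(x$fixed_loci)))
  cat("  h2:", x$config$h2, " mu_alpha:", x$config$mu_alpha,
      " adjacent LD:", round(attr(x, "ld"), 3), "\n")
  invisible(x)
}

#' Panel locus selection
#'
#' Returns the locus names making up a genotype panel: all loci, only QTL,
#' or only markers, always with loci fixed among the genotyped individuals
#' removed.
#'
#' @param dataset A [sim_study()] dataset.
#' @param panel One of `"qtl_plus_markers"`, `"qtl_only"`, `"markers_only"`.
#' @return Character vector of locus names.
#' @export
panel_loci <- function(dataset,
                       panel = c("qtl_plus_markers", "qtl_only", "markers_only")) {
  panel <- match.arg(panel)
  map <- dataset$locus_map
  keep <- switch(panel,
    qtl_plus_markers = rep(TRUE, nrow(map)),
    qtl_only = map$is_qtl,
    markers_only = !map$is_qtl
  )
  setdiff(map$locus[keep], dataset$fixed_loci)
}
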