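test_that("meiosis produces legal mosaics with map-consistent recombination", {
  map <- tibble::tibble(chrom = rep(1:2, each = 4),
                        pos = rep(c(0.01, 0.04, 0.06, 0.09), 2),
                        locus = paste0("l", 1:8), is_qtl = FALSE)
  # homozygous parent -> gamete equals the haplotype exactly
  h <- rep(c(0L, 1L), 4)
  set.seed(1)
  expect_equal(meiosis_gamete(h, h, map), h)

  # every gamete is a mosaic: allele comes from one of the two haplotypes
  h1 <- rep(0L, 8); h2 <- rep(1L, 8)
  set.seed(2)
  for (i in 1:20) {
    g <- meiosis_gamete(h1, h2, map)
    expect_true(all(g %in% 0:1))
  }

  # recombination fraction between loci ~ Haldane's map function
  set.seed(3)
  n_gam <- 40000
  gam <- matrix(0L, n_gam, 8)
  for (i in seq_len(n_gam)) gam[i, ] <- meiosis_gamete(h1, h2, map)
  # loci on different chromosomes assort independently (c = 0.5)
  r_across <- mean(gam[, 1] != gam[, 5])
  expect_lt(abs(r_across - 0.5), 0.02)
  # within chromosome, d = 0.05 M -> c = 0.5 (1 - exp(-2d)) ~ 0.0476
  d <- 0.05
  expected_c <- 0.5 * (1 - exp(-2 * d))
  r_within <- mean(gam[, 1] != gam[, 3])
  expect_lt(abs(r_within - expected_c), 0.01)
  # adjacent tight loci: d = 0.03 -> c ~ 0.0291
  r_adj <- mean(gam[, 1] != gam[, 2])
  expect_lt(abs(r_adj - 0.5 * (1 - exp(-2 * 0.03))), 0.01)
})

test_that("base generator honours MAF and LD band and trivial limits", {
  # equilibrium limit: zero LD target stops the drift immediately
  set.seed(5)
  base0 <- sim_base_population(n_individuals = 200, n_per_chrom = 10,
                               n_chrom = 4, pool_size = 200, ld_target = 0)
  expect_lt(attr(base0, "ld"), 0.02)

  # default-config run (reduced chromosome count for test runtime):
  # measured adjacent LD within the target band, all MAF >= 0.01
  set.seed(6)
  base <- sim_base_population(n_individuals = 300, n_per_chrom = 20,
                              n_chrom = 3, pool_size = 100)
  expect_gte(attr(base, "ld"), 0.25)
  expect_lte(attr(base, "ld"), 0.40)
  H <- rbind(base$haplotypes$hap1, base$haplotypes$hap2)
  maf <- pmin(colMeans(H), 1 - colMeans(H))
  expect_true(all(maf >= 0.01))
  expect_equal(nrow(base$locus_map), 60)
  # positions strictly increasing within chromosome
  for (ch in unique(base$locus_map$chrom)) {
    expect_true(all(diff(base$locus_map$pos[base$locus_map$chrom == ch]) > 0))
  }
})

test_that("QTL effects and trait calibration follow their definitions", {
  set.seed(7)
  a <- sample_qtl_effects(5000, mu_alpha = 0.2, sd_alpha = 0.08)
  expect_lt(abs(mean(a) - 0.2), 0.005)
  expect_lt(abs(sd(a) - 0.08), 0.005)

  # E[TBV] = sum_j 2 p_j alpha_j: p = 0.5 everywhere, 50 QTL, mu 0.2 -> 10
  set.seed(8)
  n_ind <- 4000; n_qtl <- 50
  alpha <- sample_qtl_effects(n_qtl, 0.2, 0.08)
  geno <- matrix(rbinom(n_ind * n_qtl, 2, 0.5), n_ind, n_qtl)
  tbv <- drop(geno %*% alpha)
  expect_lt(abs(mean(tbv) - sum(2 * 0.5 * alpha)), 0.1)

  v <- calibrate_trait(tbv, 0.5)
  expect_equal(v$sigma2_e, v$sigma2_g)
  expect_equal(calibrate_trait(tbv, 0.1)$sigma2_e, 9 * v$sigma2_g)
  expect_error(calibrate_trait(tbv, 1.2), "h2")
  # realized heritability on fresh phenotypes
  phen <- tbv + rnorm(n_ind, 0, sqrt(v$sigma2_e))
  expect_lt(abs(var(tbv) / var(phen) - 0.5), 0.02)

  set.seed(9); a1 <- sample_qtl_effects(10, 0.2)
  set.seed(9); a2 <- sample_qtl_effects(10, 0.2)
  expect_identical(a1, a2)
})

test_that("study simulation respects its structural invariants", {
  ds <- mini_study()
  cfg <- ds$config
  gen_size <- 2 * cfg$n_dams

  # generation sizes and sexes
  counts <- table(ds$samples$generation)
  expect_true(all(counts == gen_size))
  # every non-founder has two recorded parents from the previous generation
  ped <- ds$pedigree
  nonf <- ped[ped$generation > min(ped$generation), ]
  expect_false(any(is.na(nonf$sire) | is.na(nonf$dam)))
  gen_of <- setNames(ped$generation, ped$id)
  expect_true(all(gen_of[nonf$sire] == nonf$generation - 1L))
  expect_true(all(gen_of[nonf$dam] == nonf$generation - 1L))

  # masks: training = G0..G4, genotyped = selected sires + all G5
  expect_equal(sum(ds$samples$phenotyped), cfg$n_select_gens * gen_size)
  expect_equal(nrow(ds$genotypes),
               cfg$n_select_gens * cfg$n_sires + gen_size)
  expect_true(all(is.na(
    ds$samples$phenotype[ds$samples$generation == cfg$n_select_gens])))

  # genotype conservation and TBV definition on all generations
  ds_h <- local({
    cfg2 <- ds$config; cfg2$keep_haplotypes <- TRUE
    sim_study(cfg2)
  })
  qtl <- ds_h$locus_map$locus[ds_h$locus_map$is_qtl]
  alpha <- ds_h$trait$alpha[qtl]
  for (gen in ds_h$haplotypes) {
    geno <- gen$hap1 + gen$hap2
    expect_true(all(geno %in% 0:2))
    tbv <- drop(geno[, qtl, drop = FALSE] %*% alpha)
    expect_equal(tbv, ds_h$samples$tbv[match(gen$id, ds_h$samples$id)])
  }
  # identical seed reproduces the dataset exactly
  expect_identical(ds_h$genotypes, ds$genotypes)
  expect_identical(ds_h$samples$tbv, ds$samples$tbv)
})

test_that("selection raises mean TBV; the no-selection control does not", {
  sel_trend <- function(random_sires, seed) {
    cfg <- study_config(
      n_base = 60, n_dams = 50, n_sires = 5, n_per_chrom = 4, n_chrom = 4,
      n_qtl_per_chrom = 2, pool_size = 40, ld_target = 0.15,
      random_sires = random_sires, seed = seed
    )
    ds <- sim_study(cfg)
    mg <- tapply(ds$samples$tbv, ds$samples$generation, mean)
    gens <- as.numeric(names(mg))
    slope <- unname(coef(lm(mg[gens >= 0] ~ gens[gens >= 0]))[2])
    # expected sire-only response: 0.5 * i * h2 * sigma_P, i ~ 1.755 at the
    # 10% male-selected proportion used here
    sigma_p <- sqrt(ds$trait$sigma2_g / ds$config$h2)
    c(slope = slope, expected = 0.5 * 1.755 * ds$config$h2 * sigma_p)
  }
  sel <- vapply(1:6, function(s) sel_trend(FALSE, s), numeric(2))
  nosel <- vapply(1:6, function(s) sel_trend(TRUE, s + 100), numeric(2))
  expect_true(all(sel["slope", ] > 0))
  # order-of-magnitude agreement with i h2 sigma_P / 2 (not exact: finite
  # population, selection on phenotype, drift)
  ratio <- mean(sel["slope", ]) / mean(sel["expected", ])
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 2.5)
  # no-selection null: trend small and straddling zero across seeds
  expect_lt(abs(mean(nosel["slope", ])), mean(sel["slope", ]) / 2)
  expect_gt(sum(nosel["slope", ] < mean(sel["slope", ]) / 4), 3)
})

test_that("panel masks honour QTL flags and fixed-locus filtering", {
  ds <- mini_study()
  map <- ds$locus_map
  expect_equal(sum(map$is_qtl), ds$config$n_chrom * ds$config$n_qtl_per_chrom)
  all_p <- panel_loci(ds, "qtl_plus_markers")
  q <- panel_loci(ds, "qtl_only")
  m <- panel_loci(ds, "markers_only")
  expect_setequal(c(q, m), all_p)
  expect_true(all(map$is_qtl[match(q, map$locus)]))
  expect_false(any(map$is_qtl[match(m, map$locus)]))
  expect_false(any(ds$fixed_loci %in% all_p))
  expect_lte(length(m), sum(!map$is_qtl))

  # a locus fixed among genotyped individuals is dropped from every panel
  ds2 <- ds
  ds2$genotypes[, 3] <- 2L
  ds2$fixed_loci <- union(ds2$fixed_loci, colnames(ds2$genotypes)[3])
  expect_false(colnames(ds2$genotypes)[3] %in% panel_loci(ds2, "qtl_plus_markers"))
})
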