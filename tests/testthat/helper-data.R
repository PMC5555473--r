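# Shared fixtures, all generated in code.

# random but reproducible pedigree: nf founders, then offspring of any two
# distinct earlier individuals
rand_ped <- function(n, nf = 5, seed = 1) {
  set.seed(seed)
  id <- as.character(seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    s <- sample(seq_len(i - 1), 1)
    d <- sample(setdiff(seq_len(i - 1), s), 1)
    sire[i] <- as.character(s)
    dam[i] <- as.character(d)
  }
  tibble::tibble(id = id, sire = sire, dam = dam,
                 generation = 0L, sex = "male")
}

# trio: two genotyped founders and their nongenotyped child
trio_ped <- function() {
  tibble::tibble(id = c("s", "d", "k"),
                 sire = c(NA, NA, "s"),
                 dam = c(NA, NA, "d"))
}

# small complete study used across model tests; memoised per seed
.fixture_cache <- new.env(parent = emptyenv())

mini_study <- function(seed = 11) {
  key <- paste0("mini_", seed)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- study_config(
      n_base = 80, n_dams = 60, n_sires = 6,
      n_per_chrom = 4, n_chrom = 5, n_qtl_per_chrom = 2,
      pool_size = 40, ld_target = 0.2, seed = seed
    )
    .fixture_cache[[key]] <- sim_study(cfg)
  }
  .fixture_cache[[key]]
}

mini_context <- function(seed = 11) {
  key <- paste0("ctx_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- ssbr_context(mini_study(seed))
  }
  .fixture_cache[[key]]
}

# hand-built all-genotyped dataset (founders only) for ridge checks
allgeno_dataset <- function(seed = 4, n = 12, m = 6, n_pheno = 8) {
  set.seed(seed)
  ped <- tibble::tibble(id = as.character(seq_len(n)), sire = NA, dam = NA)
  geno <- matrix(sample(0:2, n * m, TRUE), n, m,
                 dimnames = list(ped$id, paste0("m", seq_len(m))))
  samp <- tibble::tibble(
    id = ped$id,
    generation = c(rep(0L, n_pheno), rep(1L, n - n_pheno)),
    phenotype = c(rnorm(n_pheno, 5), rep(NA_real_, n - n_pheno))
  )
  study_dataset(ped, samp, geno, sigma2_g = 2, sigma2_e = 3)
}
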