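#' Read and write the study's delimited interchange files
#'
#' All interchange formats are plain tab-delimited text with a header row:
#' pedigree (`id`, `sire`, `dam`, `generation`, `sex`; `0` or empty marks an
#' unknown parent), genotypes (individuals as rows, first column `id`, one
#' column of 0/1/2 allele counts per locus), locus map (`locus`, `chrom`,
#' `pos`, `is_qtl`), phenotypes (`id`, `generation`, `tbv`, `phenotype`),
#' and GEBV tables as written by [write_gebv()]. Readers validate the
#' schema and report the offending row/column on failure.
#'
#' @param path File path.
#' @param pedigree,genotypes,locus_map,phenotypes,fit Objects to write.
#' @name study_io
NULL

read_tsv_strict <- function(path, col_types) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # parse problems are surfaced through readr::problems() below, so the
  # missing-parser warning for truncated files is redundant noise here
  out <- suppressWarnings(
    readr::read_tsv(path, col_types = col_types, progress = FALSE)
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(paste0("parse error in ", path, " at row ", p$row, ", column ",
                 p$col, ": expected ", p$expected))
  }
  expected <- names(col_types$cols)
  extra <- setdiff(names(out), expected)
  missing_cols <- setdiff(expected, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (length(extra) > 0) {
    abort(paste0(path, " has unexpected column(s): ",
                 paste(extra, collapse = ", ")))
  }
  out
}

#' @rdname study_io
#' @export
read_pedigree <- function(path) {
  ped <- read_tsv_strict(path, readr::cols(
    id = readr::col_character(), sire = readr::col_character(),
    dam = readr::col_character(), generation = readr::col_integer(),
    sex = readr::col_character()
  ))
  sort_pedigree(ped)
}

#' @rdname study_io
#' @export
write_pedigree <- function(pedigree, path) {
  ped <- as_tibble(pedigree)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  readr::write_tsv(ped, path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  if (names(tab)[1] != "id") abort(paste0(path, ": first column must be 'id'"))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$id
  bad <- which(!(m %in% c(0L, 1L, 2L)) | is.na(m))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(m))
    abort(paste0(path, ": invalid genotype value at row ", rc[1],
                 " (id ", tab$id[rc[1]], "), locus ", colnames(m)[rc[2]],
                 "; allele counts must be 0, 1 or 2"))
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname study_io
#' @export
write_genotypes <- function(genotypes, path) {
  tab <- as_tibble(as.data.frame(genotypes))
  tab <- dplyr::bind_cols(tibble(id = rownames(genotypes)), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_locus_map <- function(path) {
  read_tsv_strict(path, readr::cols(
    locus = readr::col_character(), chrom = readr::col_integer(),
    pos = readr::col_double(), is_qtl = readr::col_logical()
  ))
}

#' @rdname study_io
#' @export
write_locus_map <- function(locus_map, path) {
  readr::write_tsv(locus_map[, c("locus", "chrom", "pos", "is_qtl")], path)
  invisible(path)
}

#' @rdname study_io
#' @export
read_phenotypes <- function(path) {
  read_tsv_strict(path, readr::cols(
    id = readr::col_character(), generation = readr::col_integer(),
    tbv = readr::col_double(), phenotype = readr::col_double()
  ))
}

#' @rdname study_io
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes[, c("id", "generation", "tbv", "phenotype")],
                   path)
  invisible(path)
}

#' @rdname study_io
#' @export
write_gebv <- function(fit, path) {
  stopifnot(inherits(fit, "ssbr_fit"))
  readr::write_tsv(fit$gebv, path)
  invisible(path)
}

#' Write a study dataset to a directory of delimited files
#'
#' @param dataset A `study_dataset`.
#' @param dir Output directory (created if needed). Files written:
#'   `pedigree.tsv`, `genotypes.tsv`, `locus_map.tsv`, `phenotypes.tsv`,
#'   and `manifest.tsv` (seed and variance components).
#' @return `dir`, invisibly.
#' @export
write_study_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pedigree(dataset$pedigree, file.path(dir, "pedigree.tsv"))
  write_genotypes(dataset$genotypes, file.path(dir, "genotypes.tsv"))
  write_locus_map(dataset$locus_map, file.path(dir, "locus_map.tsv"))
  write_phenotypes(dataset$samples, file.path(dir, "phenotypes.tsv"))
  manifest <- tibble(
    key = c("seed", "sigma2_g", "sigma2_e", "h2"),
    value = c(if (!is.null(dataset$config)) dataset$config$seed else NA,
              dataset$trait$sigma2_g, dataset$trait$sigma2_e,
              if (!is.null(dataset$config)) dataset$config$h2 else NA)
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Read a study dataset from a directory of delimited files
#'
#' Reads the files written by [write_study_dataset()] and revalidates all
#' cross-references (ids in the genotype and phenotype files must appear in
#' the pedigree).
#'
#' @param dir Directory containing the dataset files.
#' @return A `study_dataset`.
#' @export
read_study_dataset <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.tsv"))
  geno <- read_genotypes(file.path(dir, "genotypes.tsv"))
  map <- read_locus_map(file.path(dir, "locus_map.tsv"))
  phen <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              col_types = readr::cols(
                                key = readr::col_character(),
                                value = readr::col_double()
                              ), progress = FALSE)
  get <- function(k) manifest$value[manifest$key == k]
  if (!setequal(colnames(geno), map$locus)) {
    abort("genotype columns do not match the locus map")
  }
  g_last <- max(phen$generation)
  samples <- phen
  samples$phenotyped <- !is.na(samples$phenotype)
  ds <- study_dataset(ped, samples, geno, map,
                      sigma2_g = get("sigma2_g"), sigma2_e = get("sigma2_e"))
  ds
}
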