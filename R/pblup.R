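#' Pedigree BLUP of breeding values
#'
#' Fits the animal model `y = 1 mu + Z u + e` with `Var(u) = A sigma2_g`
#' and `Var(e) = I sigma2_e`, solving the mixed model equations by sparse
#' Cholesky factorisation with A-inverse built directly from the pedigree.
#' Returns estimated breeding values for every pedigree member, including
#' individuals without phenotypes.
#'
#' @param dataset A `study_dataset`.
#' @param sigma2_g,sigma2_e Variance components; default to the dataset's
#'   values.
#' @return An object of class `pblup_fit` with `mu_hat` and `ebv` (tibble:
#'   `id`, `generation`, `ebv`).
#' @export
pblup_fit <- function(dataset, sigma2_g = dataset$trait$sigma2_g,
                      sigma2_e = dataset$trait$sigma2_e) {
  stopifnot(inherits(dataset, "study_dataset"))
  ped <- sort_pedigree(dataset$pedigree)
  n_ind <- nrow(ped)
  ainv <- build_A_inverse(ped)
  samples <- dataset$samples
  ph <- samples[samples$phenotyped & !is.na(samples$phenotype), ]
  y <- ph$phenotype
  n <- length(y)
  lambda <- sigma2_e / sigma2_g

  if (n == 0) {
    fit <- list(mu_hat = 0,
                ebv = tibble(id = ped$id,
                             generation = samples$generation[
                               match(ped$id, samples$id)],
                             ebv = rep(0, n_ind)))
    return(structure(fit, class = "pblup_fit"))
  }

  idx <- match(ph$id, ped$id)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = idx, x = 1,
                            dims = c(n, n_ind))
  X <- Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                            dims = c(n, 1))
  WZ <- cbind(X, Z)
  C <- Matrix::crossprod(WZ) +
    Matrix::bdiag(Matrix::Matrix(0, 1, 1), lambda * ainv)
  rhs <- as.numeric(Matrix::crossprod(WZ, y))
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::forceSymmetric(C), rhs)),
    error = function(e) abort(paste0("singular PBLUP equations: ",
                                     conditionMessage(e)))
  )
  fit <- list(
    mu_hat = sol[1],
    ebv = tibble(
      id = ped$id,
      generation = samples$generation[match(ped$id, samples$id)],
      ebv = sol[-1]
    ),
    sigma2 = list(g = sigma2_g, e = sigma2_e),
    n_pheno = n
  )
  structure(fit, class = "pblup_fit")
}

#' @export
print.pblup_fit <- function(x, ...) {
  cat("<pblup_fit> mu_hat:", signif(x$mu_hat, 4), "| EBVs for",
      nrow(x$ebv), "individuals\n")
  invisible(x)
}

#' @rdname pblup_fit
#' @param x A `pblup_fit` object.
#' @param ... Unused.
#' @export
tidy.pblup_fit <- function(x, ...) {
  dplyr::rename(x$ebv, estimate = "ebv")
}

#' @rdname pblup_fit
#' @export
glance.pblup_fit <- function(x, ...) {
  tibble(mu_hat = x$mu_hat, n_pheno = x$n_pheno,
         sigma2_g = x$sigma2$g, sigma2_e = x$sigma2$e)
}
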