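#' Assemble a study dataset from its component tables
#'
#' Builds the dataset object consumed by the model fitters from plain
#' tables, validating cross-references. [sim_study()] returns the same
#' structure; this constructor is the entry point for data read from files.
#'
#' @param pedigree Pedigree table accepted by [sort_pedigree()].
#' @param samples Tibble with columns `id`, `generation`, `phenotype`
#'   (NA allowed), and optionally `tbv`, `sex`; `phenotyped` defaults to
#'   `!is.na(phenotype)` and `genotyped` to presence in `genotypes`.
#' @param genotypes Integer matrix of allele counts (0/1/2), rownames =
#'   individual ids, colnames = locus names.
#' @param locus_map Tibble `locus`, `chrom`, `pos`, `is_qtl`; defaults to a
#'   single-chromosome map over the genotype columns with no QTL flags.
#' @param sigma2_g,sigma2_e Genetic and residual variances used by the
#'   fitters (fixed, known).
#' @return A `study_dataset`.
#' @export
study_dataset <- function(pedigree, samples, genotypes, locus_map = NULL,
                          sigma2_g, sigma2_e) {
  ped <- sort_pedigree(pedigree)
  samples <- as_tibble(samples)
  samples$id <- as.character(samples$id)
  if (!all(samples$id %in% ped$id)) {
    abort("samples contain ids missing from the pedigree")
  }
  if (!all(rownames(genotypes) %in% ped$id)) {
    abort("genotype rows contain ids missing from the pedigree")
  }
  if (!all(genotypes %in% 0:2)) abort("genotype values must be 0, 1 or 2")
  if (is.null(locus_map)) {
    locus_map <- tibble(locus = colnames(genotypes), chrom = 1L,
                        pos = seq_len(ncol(genotypes)) * 0.001,
                        is_qtl = FALSE)
  }
  if (!("phenotyped" %in% names(samples))) {
    samples$phenotyped <- !is.na(samples$phenotype)
  }
  if (!("genotyped" %in% names(samples))) {
    samples$genotyped <- samples$id %in% rownames(genotypes)
  }
  if (!("tbv" %in% names(samples))) samples$tbv <- NA_real_
  fixed <- apply(genotypes, 2, function(col) length(unique(col)) == 1L)
  structure(list(
    pedigree = ped, samples = samples, genotypes = genotypes,
    locus_map = locus_map,
    trait = list(sigma2_g = sigma2_g, sigma2_e = sigma2_e),
    fixed_loci = colnames(genotypes)[fixed],
    config = NULL
  ), class = "study_dataset")
}

#' Model variant lookup
#'
#' Maps the six analysis labels to their two ingredients: whether the J
#' covariate for the founder genotypic mean is fitted, and how genotype
#' covariates are centered (`"none"`, `"all"` = observed + imputed rows,
#' `"observed"` = observed rows only, the single-step GBLUP convention).
#'
#' @param variant One of `"J"`, `"N"`, `"JC"`, `"C"`, `"JCstar"`, `"Cstar"`.
#' @return List with `fit_j` and `centering`.
#' @export
ssbr_variant <- function(variant = c("J", "N", "JC", "C", "JCstar", "Cstar")) {
  variant <- match.arg(variant)
  switch(variant,
    J = list(fit_j = TRUE, centering = "none"),
    N = list(fit_j = FALSE, centering = "none"),
    JC = list(fit_j = TRUE, centering = "all"),
    C = list(fit_j = FALSE, centering = "all"),
    JCstar = list(fit_j = TRUE, centering = "observed"),
    Cstar = list(fit_j = FALSE, centering = "observed")
  )
}

#' J covariate over all pedigree members
#'
#' The covariate whose coefficient estimates the genotypic mean of
#' unselected founders: -1 for every genotyped individual, and
#' `Ang Agg^-1 (-1)` for nongenotyped individuals.
#'
#' @param operator A [relationship_operator()].
#' @return Tibble with columns `id` and `j`, in pedigree order.
#' @export
compute_J_covariate <- function(operator) {
  stopifnot(inherits(operator, "rel_operator"))
  ng <- length(operator$genotyped_ids)
  j <- numeric(nrow(operator$pedigree))
  names(j) <- operator$pedigree$id
  j[operator$genotyped_ids] <- -1
  if (length(operator$nongenotyped_ids) > 0) {
    jn <- solve_nn_block(operator, matrix(-1, ng, 1))
    j[operator$nongenotyped_ids] <- jn[, 1]
  }
  tibble(id = operator$pedigree$id, j = unname(j[operator$pedigree$id]))
}

#' Impute marker covariates for nongenotyped individuals
#'
#' Best linear prediction of the missing genotype covariates from the
#' observed ones: `Mhat_n = Ang Agg^-1 Mg`, computed column-by-column
#' through the sparse nn-block factorisation (the founder-mean terms of the
#' imputation cancel into the J covariate, so the uncentered form is exact).
#'
#' @param operator A [relationship_operator()].
#' @param Mg Matrix of observed genotype covariates, rows ordered as
#'   `operator$genotyped_ids`.
#' @return Matrix with one row per nongenotyped individual.
#' @export
impute_marker_covariates <- function(operator, Mg) {
  solve_nn_block(operator, Mg)
}

#' Center genotype covariates
#'
#' @param Mg Observed genotype covariates (genotyped individuals x loci).
#' @param Mn Imputed covariates (nongenotyped individuals x loci).
#' @param mode `"none"`, `"all"` (subtract column means over observed +
#'   imputed rows from every row) or `"observed"` (subtract column means of
#'   the observed rows from the observed rows, then re-impute; equivalent to
#'   `Mn + Jn v'`).
#' @param jn J covariate entries of the nongenotyped individuals (needed for
#'   `mode = "observed"`).
#' @return List `Mg`, `Mn`, `v` (the centering vector applied to observed
#'   covariates; zero for `"none"`).
#' @export
center_genotypes <- function(Mg, Mn, mode = c("none", "all", "observed"),
                             jn = NULL) {
  mode <- match.arg(mode)
  p <- ncol(Mg)
  if (mode == "none") {
    return(list(Mg = Mg, Mn = Mn, v = numeric(p)))
  }
  if (mode == "all") {
    v <- colMeans(rbind(Mn, Mg))
    return(list(Mg = sweep(Mg, 2, v), Mn = sweep(Mn, 2, v), v = v))
  }
  v <- colMeans(Mg)
  Mg_c <- sweep(Mg, 2, v)
  if (nrow(Mn) > 0) {
    if (is.null(jn)) abort("jn required for observed-only centering")
    # Mhat_n from centered observed covariates: Mn - (Ang Agg^-1 1) v' =
    # Mn + Jn v'
    Mn_c <- Mn + outer(as.numeric(jn), v)
  } else {
    Mn_c <- Mn
  }
  list(Mg = Mg_c, Mn = Mn_c, v = v)
}

#' Precompute the relationship machinery for repeated fits
#'
#' Builds the relationship operator, the J covariate, and the imputed
#' marker covariates for the full (non-fixed) panel once, so that all model
#' variants and panel subsets reuse the same sparse factorisations.
#'
#' @param dataset A `study_dataset`.
#' @return An object of class `ssbr_context`.
#' @export
ssbr_context <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  gids <- rownames(dataset$genotypes)
  op <- relationship_operator(dataset$pedigree, gids)
  loci <- setdiff(colnames(dataset$genotypes), dataset$fixed_loci)
  Mg <- dataset$genotypes[op$genotyped_ids, loci, drop = FALSE]
  storage.mode(Mg) <- "double"
  Mn <- impute_marker_covariates(op, Mg)
  Jtab <- compute_J_covariate(op)
  j_full <- setNames(Jtab$j, Jtab$id)
  structure(list(op = op, loci = loci, Mg = Mg, Mn = Mn, j = j_full),
            class = "ssbr_context")
}

# cached Cholesky of C33 = U'U + lambda_g * A^nn for a dataset context
c33_factor <- function(ctx, n_pheno_per_eps, lambda_g) {
  key <- paste0("C33_", format(lambda_g, digits = 17))
  cache <- ctx$op$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  Q <- ctx$op$ainv_nn
  C33 <- lambda_g * Q + Matrix::Diagonal(x = n_pheno_per_eps)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(C33), LDL = FALSE, perm = TRUE)
  cache[[key]] <- ch
  ch
}

#' Fit a single-step marker effects model
#'
#' Fits the single-step regression `y = 1 mu + Z J mu_g + Z M alpha +
#' U eps + e` for one of the six analysis variants, either by direct
#' solution of the mixed model equations (exact, deterministic) or by
#' single-site Gibbs sampling with Gaussian marker priors (BayesC with
#' pi = 0). Variance components are fixed at the dataset's values.
#'
#' @param dataset A `study_dataset`.
#' @param variant Analysis label, see [ssbr_variant()].
#' @param panel Which loci enter the model, see [panel_loci()].
#' @param method `"mme"` (default) or `"gibbs"`.
#' @param context Optional [ssbr_context()] to reuse factorisations across
#'   fits; computed if missing.
#' @param sigma2_alpha_rule Per-marker prior variance: `"sum2pq"` (default;
#'   `sigma2_g / sum(2 p q)` with allele frequencies from the observed
#'   genotypes of the fitted panel) or `"per_marker"` (`sigma2_g / m`).
#' @param chain_length,burn_in Gibbs chain controls (defaults 50000, 5000).
#' @param n_batch Batches for Monte Carlo standard errors (Gibbs).
#' @param seed Seed for the Gibbs sampler (ignored for `"mme"`).
#' @param keep_design Keep the assembled design matrices in the fit object
#'   (needed by [compute_gebv()]; default `FALSE`).
#' @param coding_shift Optional numeric vector (one entry per panel locus)
#'   subtracted from the observed genotype covariates before fitting, with
#'   the imputed covariates rebuilt from the shifted observed ones. With the
#'   J covariate in the model, inference about the marker effects does not
#'   depend on this coding choice; the option exists to make that property
#'   checkable.
#' @return An object of class `ssbr_fit` with elements `mu_hat`, `mu_g_hat`,
#'   `alpha` (tibble), `epsilon` (tibble), `gebv` (tibble with per-term
#'   components), and fit metadata.
#' @export
ssbr_fit <- function(dataset,
                     variant = c("J", "N", "JC", "C", "JCstar", "Cstar"),
                     panel = c("qtl_plus_markers", "qtl_only", "markers_only"),
                     method = c("mme", "gibbs"),
                     context = NULL,
                     sigma2_alpha_rule = c("sum2pq", "per_marker"),
                     chain_length = 50000, burn_in = 5000, n_batch = 50,
                     seed = NULL, keep_design = FALSE, coding_shift = NULL) {
  variant <- match.arg(variant)
  panel <- match.arg(panel)
  method <- match.arg(method)
  sigma2_alpha_rule <- match.arg(sigma2_alpha_rule)
  vv <- ssbr_variant(variant)
  if (is.null(context)) context <- ssbr_context(dataset)
  op <- context$op

  loci <- intersect(context$loci, panel_loci(dataset, panel))
  if (length(loci) == 0) abort("empty genotype panel")
  Mg <- context$Mg[, loci, drop = FALSE]
  Mn <- context$Mn[, loci, drop = FALSE]
  nn_ids <- op$nongenotyped_ids
  jn <- context$j[nn_ids]
  # allele frequencies (for the marker prior variance) always come from the
  # observed allele counts, before any coding shift or centering
  p_freq <- colMeans(Mg) / 2
  sum2pq <- sum(2 * p_freq * (1 - p_freq))
  if (!is.null(coding_shift)) {
    if (length(coding_shift) != ncol(Mg)) {
      abort("coding_shift must have one entry per panel locus")
    }
    Mg <- sweep(Mg, 2, coding_shift)
    # re-imputation under the shifted coding: Mn - (Ang Agg^-1 1) v' = Mn + Jn v'
    if (nrow(Mn) > 0) Mn <- Mn + outer(as.numeric(jn), coding_shift)
  }
  cen <- center_genotypes(Mg, Mn, mode = switch(vv$centering,
    none = "none", all = "all", observed = "observed"), jn = jn)

  samples <- dataset$samples
  ph <- samples[samples$phenotyped & !is.na(samples$phenotype), ]
  y <- ph$phenotype
  n <- length(y)
  sigma2_g <- dataset$trait$sigma2_g
  sigma2_e <- dataset$trait$sigma2_e
  sigma2_alpha <- switch(sigma2_alpha_rule,
    sum2pq = sigma2_g / sum2pq,
    per_marker = sigma2_g / length(loci)
  )
  lambda_a <- sigma2_e / sigma2_alpha
  lambda_g <- sigma2_e / sigma2_g

  # marker covariate rows and eps mapping for the phenotyped individuals
  is_g <- ph$id %in% op$genotyped_ids
  if (vv$fit_j && n > 0 && all(is_g)) {
    abort(paste0(
      "all phenotyped individuals are genotyped, so the J covariate is ",
      "collinear with the intercept; drop mu_g (use variant N or C)"
    ))
  }
  M_ph <- matrix(0, n, length(loci))
  M_ph[is_g, ] <- cen$Mg[ph$id[is_g], , drop = FALSE]
  nn_pos <- setNames(seq_along(nn_ids), nn_ids)
  if (any(!is_g)) {
    M_ph[!is_g, ] <- cen$Mn[ph$id[!is_g], , drop = FALSE]
  }
  eps_map <- integer(n)
  eps_map[!is_g] <- nn_pos[ph$id[!is_g]]
  j_ph <- unname(context$j[ph$id])

  X <- if (vv$fit_j) cbind(`(Intercept)` = rep(1, n), J = j_ph) else
    cbind(`(Intercept)` = rep(1, n))
  W <- cbind(X, M_ph)
  q <- ncol(X)
  k <- ncol(W)
  lambda_w <- c(rep(0, q), rep(lambda_a, length(loci)))
  n_eps <- length(nn_ids)

  if (n == 0) {
    theta <- rep(0, k)
    eps <- rep(0, n_eps)
    diagnostics <- list()
  } else if (method == "mme") {
    if (n_eps > 0) {
      n_per_eps <- tabulate(eps_map[eps_map > 0], nbins = n_eps)
      ch <- c33_factor(context, n_per_eps, lambda_g)
      UtW <- matrix(0, n_eps, k)
      Uty <- numeric(n_eps)
      rows_n <- which(eps_map > 0)
      for (r in rows_n) {
        UtW[eps_map[r], ] <- UtW[eps_map[r], ] + W[r, ]
        Uty[eps_map[r]] <- Uty[eps_map[r]] + y[r]
      }
      TW <- as.matrix(Matrix::solve(ch, UtW, system = "A"))
      Ty <- as.numeric(Matrix::solve(ch, Uty, system = "A"))
      S <- crossprod(W) + diag(lambda_w, k) - crossprod(UtW, TW)
      rhs <- crossprod(W, y) - crossprod(UtW, Ty)
      theta <- tryCatch(drop(solve(S, rhs)), error = function(e) {
        abort(paste0("singular mixed model equations: ", conditionMessage(e)))
      })
      eps <- Ty - drop(TW %*% theta)
    } else {
      S <- crossprod(W) + diag(lambda_w, k)
      theta <- tryCatch(drop(solve(S, crossprod(W, y))), error = function(e) {
        abort(paste0("singular mixed model equations: ", conditionMessage(e)))
      })
      eps <- numeric(0)
    }
    diagnostics <- list()
  } else {
    if (chain_length <= burn_in) abort("chain_length must exceed burn_in")
    if (!is.null(seed)) set.seed(seed)
    if (n_eps > 0) {
      Qg <- as(as(op$ainv_nn, "generalMatrix"), "CsparseMatrix")
      Qp <- Qg@p; Qi <- Qg@i; Qx <- Qg@x
    } else {
      Qp <- integer(1); Qi <- integer(0); Qx <- numeric(0)
    }
    gs <- gibbs_ssbr_cpp(y, W, lambda_w, as.integer(eps_map), n_eps,
                         Qp, Qi, Qx, lambda_g, sigma2_e,
                         as.integer(chain_length), as.integer(burn_in),
                         as.integer(n_batch))
    theta <- colMeans(gs$beta_chain)
    eps <- as.numeric(gs$eps_mean)
    bm <- batch_means(gs$beta_chain, n_batch)
    eps_se <- if (n_eps > 0) {
      apply(gs$eps_batch_means, 1, sd) / sqrt(ncol(gs$eps_batch_means))
    } else numeric(0)
    diagnostics <- list(
      chain_length = chain_length, burn_in = burn_in,
      kept = chain_length - burn_in,
      beta_mc_se = bm, eps_mc_se = eps_se
    )
  }

  mu_hat <- unname(theta[1])
  mu_g_hat <- if (vv$fit_j) unname(theta[2]) else NA_real_
  alpha_hat <- theta[(q + 1):k]
  names(alpha_hat) <- loci
  names(eps) <- nn_ids

  gebv <- gebv_table(dataset, op, cen, loci, vv$fit_j, context$j,
                     mu_g_hat, alpha_hat, eps)

  out <- list(
    variant = variant, panel = panel, method = method,
    fit_j = vv$fit_j, centering = vv$centering,
    mu_hat = mu_hat, mu_g_hat = mu_g_hat,
    alpha = tibble(locus = loci, estimate = unname(alpha_hat)),
    epsilon = tibble(id = nn_ids, estimate = unname(eps)),
    gebv = gebv,
    centering_vector = cen$v,
    sigma2 = list(g = sigma2_g, e = sigma2_e, alpha = sigma2_alpha),
    n_pheno = n, n_geno = length(op$genotyped_ids), n_loci = length(loci),
    diagnostics = diagnostics
  )
  if (keep_design) {
    out$design <- list(Mg = cen$Mg, Mn = cen$Mn, j = context$j, op = op)
  }
  structure(out, class = "ssbr_fit")
}

batch_means <- function(chain, n_batch) {
  n <- nrow(chain)
  if (n < 2 * n_batch) n_batch <- max(2L, n %/% 2L)
  b <- rep(seq_len(n_batch), each = ceiling(n / n_batch))[seq_len(n)]
  means <- apply(chain, 2, function(col) tapply(col, b, mean))
  apply(means, 2, sd) / sqrt(n_batch)
}

# GEBV per pedigree member: genotyped g = Jg mu_g + Mg alpha;
# nongenotyped g = Jn mu_g + Mn alpha + eps (mu_g term dropped when J absent)
gebv_table <- function(dataset, op, cen, loci, fit_j, j_full,
                       mu_g_hat, alpha_hat, eps) {
  ped <- op$pedigree
  mk <- numeric(nrow(ped))
  names(mk) <- ped$id
  if (length(op$genotyped_ids) > 0) {
    mk[op$genotyped_ids] <- drop(cen$Mg %*% alpha_hat)
  }
  if (length(op$nongenotyped_ids) > 0) {
    mk[op$nongenotyped_ids] <- drop(cen$Mn %*% alpha_hat)
  }
  jt <- if (fit_j) unname(j_full[ped$id]) * mu_g_hat else rep(0, nrow(ped))
  et <- numeric(nrow(ped))
  names(et) <- ped$id
  if (length(eps) > 0) et[names(eps)] <- eps
  gen <- dataset$samples$generation[match(ped$id, dataset$samples$id)]
  tibble(
    id = ped$id,
    generation = gen,
    genotyped = ped$id %in% op$genotyped_ids,
    term_mu_g = jt,
    term_markers = unname(mk[ped$id]),
    term_epsilon = unname(et[ped$id]),
    gebv = jt + unname(mk[ped$id]) + unname(et[ped$id])
  )
}

#' Recompute GEBVs from a fit's components
#'
#' Rebuilds the GEBV table from the stored estimates and design (the fit
#' must have been made with `keep_design = TRUE`). Useful for verifying
#' that the reported GEBVs decompose exactly as
#' `J mu_g + M alpha + U eps`.
#'
#' @param fit An [ssbr_fit()] object with a stored design.
#' @return The GEBV tibble.
#' @export
compute_gebv <- function(fit) {
  stopifnot(inherits(fit, "ssbr_fit"))
  if (is.null(fit$design)) {
    abort("fit was made with keep_design = FALSE; refit with keep_design = TRUE")
  }
  op <- fit$design$op
  alpha_hat <- setNames(fit$alpha$estimate, fit$alpha$locus)
  eps <- setNames(fit$epsilon$estimate, fit$epsilon$id)
  cen <- list(Mg = fit$design$Mg, Mn = fit$design$Mn)
  gen <- tibble(id = op$pedigree$id)
  ds_stub <- list(samples = tibble(id = op$pedigree$id,
                                   generation = NA_integer_))
  gebv_table(ds_stub, op, cen, fit$alpha$locus, fit$fit_j, fit$design$j,
             fit$mu_g_hat, alpha_hat, eps)
}

#' @export
print.ssbr_fit <- function(x, ...) {
  cat("<ssbr_fit> variant", x$variant, "| panel", x$panel, "| method",
      x$method, "\n")
  cat("  n_pheno:", x$n_pheno, " n_geno:", x$n_geno, " loci:", x$n_loci, "\n")
  cat("  mu_hat:", signif(x$mu_hat, 4),
      if (x$fit_j) paste(" mu_g_hat:", signif(x$mu_g_hat, 4)) else "", "\n")
  invisible(x)
}

#' @rdname ssbr_fit
#' @param x An `ssbr_fit` object.
#' @param ... Unused.
#' @export
tidy.ssbr_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "mu", estimate = x$mu_hat),
    if (x$fit_j) tibble(term = "mu_g", estimate = x$mu_g_hat),
    tibble(term = x$alpha$locus, estimate = x$alpha$estimate)
  )
}

#' @rdname ssbr_fit
#' @export
glance.ssbr_fit <- function(x, ...) {
  tibble(
    variant = x$variant, panel = x$panel, method = x$method,
    n_pheno = x$n_pheno, n_geno = x$n_geno, n_loci = x$n_loci,
    mu_hat = x$mu_hat, mu_g_hat = x$mu_g_hat,
    sigma2_g = x$sigma2$g, sigma2_e = x$sigma2$e, sigma2_alpha = x$sigma2$alpha
  )
}
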