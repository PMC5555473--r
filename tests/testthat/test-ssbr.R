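test_that("J covariate is -1 for genotyped and dense-oracle exact otherwise", {
  # child of two genotyped parents gets Jn = -1 (midparent of -1s)
  op2 <- relationship_operator(trio_ped(), c("s", "d"))
  J <- compute_J_covariate(op2)
  expect_equal(J$j, c(-1, -1, -1), ignore_attr = TRUE)

  # toy pedigree against the dense Ang Agg^-1 (-1) computation
  ped <- rand_ped(60, seed = 21)
  gids <- as.character(sample(1:60, 25))
  op <- relationship_operator(ped, gids)
  A <- build_A_tabular(ped)
  dense <- A[op$nongenotyped_ids, op$genotyped_ids] %*%
    solve(A[op$genotyped_ids, op$genotyped_ids]) %*% rep(-1, 25)
  J2 <- compute_J_covariate(op)
  expect_lt(max(abs(J2$j[match(op$nongenotyped_ids, J2$id)] - drop(dense))),
            1e-8)
  expect_true(all(J2$j[match(op$genotyped_ids, J2$id)] == -1))
})

test_that("marker imputation is the best-linear-prediction block product", {
  # midparent imputation
  op2 <- relationship_operator(trio_ped(), c("s", "d"))
  Mg <- matrix(c(2, 1, 0, 2), 2, 2,
               dimnames = list(c("s", "d"), c("l1", "l2")))
  expect_equal(impute_marker_covariates(op2, Mg),
               matrix(c(1.5, 1), 1, 2, dimnames = list("k", c("l1", "l2"))))

  ped <- rand_ped(60, seed = 22)
  gids <- as.character(sample(1:60, 25))
  op <- relationship_operator(ped, gids)
  A <- build_A_tabular(ped)
  Mg2 <- matrix(sample(0:2, 25 * 4, TRUE), 25, 4)
  rownames(Mg2) <- op$genotyped_ids
  dense <- A[op$nongenotyped_ids, op$genotyped_ids] %*%
    solve(A[op$genotyped_ids, op$genotyped_ids]) %*% Mg2
  expect_lt(max(abs(impute_marker_covariates(op, Mg2) - dense)), 1e-8)

  # linearity: a constant column c imputes to c * (-Jn)
  Jn <- compute_J_covariate(op)$j
  names(Jn) <- compute_J_covariate(op)$id
  const <- matrix(3, 25, 1, dimnames = list(op$genotyped_ids, "c"))
  imp <- impute_marker_covariates(op, const)
  expect_equal(drop(imp), 3 * -Jn[op$nongenotyped_ids],
               tolerance = 1e-10)
})

test_that("centering modes transform covariates as defined", {
  Mg <- matrix(c(0, 1, 2, 2, 2, 2), 3, 2,
               dimnames = list(c("a", "b", "c"), c("l1", "l2")))
  Mn <- matrix(c(1, 1, 2, 2), 2, 2,
               dimnames = list(c("x", "y"), c("l1", "l2")))
  # none -> identity
  none <- center_genotypes(Mg, Mn, "none")
  expect_identical(none$Mg, Mg)
  expect_identical(none$Mn, Mn)

  # a column 0,1,2 with mean 1 becomes -1,0,1
  all_c <- center_genotypes(Mg, Mg * 0 + 1, "all")[["Mg"]]
  one_col <- center_genotypes(Mg[, 1, drop = FALSE],
                              matrix(1, 0, 1), "all")
  expect_equal(drop(one_col$Mg), c(a = -1, b = 0, c = 1))

  # whole-matrix centering: every column of the stacked block sums to 0
  allm <- center_genotypes(Mg, Mn, "all")
  expect_equal(colSums(rbind(allm$Mn, allm$Mg)), c(l1 = 0, l2 = 0))

  # observed-only: observed rows centered by observed means; imputed rows
  # re-imputed, equivalent to Mn + Jn v'
  jn <- c(-0.5, -1)
  obs <- center_genotypes(Mg, Mn, "observed", jn = jn)
  expect_equal(colSums(obs$Mg), c(l1 = 0, l2 = 0))
  expect_equal(obs$Mn, Mn + outer(jn, colMeans(Mg)))
})

test_that("MME solution matches a dense generalized least squares oracle", {
  # 1 marker, hand-built system: genotyped trio parents, nongenotyped child,
  # and an unrelated nongenotyped founder (which keeps J and the intercept
  # distinguishable: its Jn entry is 0)
  ped <- tibble::tibble(id = c("s", "d", "k", "f"),
                        sire = c(NA, NA, "s", NA),
                        dam = c(NA, NA, "d", NA))
  geno <- matrix(c(2L, 0L), 2, 1, dimnames = list(c("s", "d"), "m1"))
  samp <- tibble::tibble(id = c("s", "d", "k", "f"),
                         generation = c(0L, 0L, 1L, 0L),
                         phenotype = c(3.0, 1.0, 2.5, 1.5))
  ds <- study_dataset(ped, samp, geno, sigma2_g = 1, sigma2_e = 2)
  fit <- ssbr_fit(ds, "J", "qtl_plus_markers")

  # dense oracle: unknowns (mu, mu_g, alpha, eps_k, eps_f); J = (-1,-1,-1,0),
  # imputed covariates: midparent 1 for k, 0 for f; eps prior precision is
  # lambda_g times the Schur complement inverse diag(2, 1)
  lam_a <- 2 / (ds$trait$sigma2_g / (2 * 0.5 * 0.5))
  W <- rbind(c(1, -1, 2, 0, 0),
             c(1, -1, 0, 0, 0),
             c(1, -1, 1, 1, 0),
             c(1,  0, 0, 0, 1))
  y <- c(3, 1, 2.5, 1.5)
  lam_g <- 2 / 1
  P <- diag(c(0, 0, lam_a, lam_g * 2, lam_g * 1))
  sol <- drop(solve(crossprod(W) + P, crossprod(W, y)))
  expect_equal(fit$mu_hat, sol[1], tolerance = 1e-10)
  expect_equal(fit$mu_g_hat, sol[2], tolerance = 1e-10)
  expect_equal(fit$alpha$estimate, sol[3], tolerance = 1e-10)
  eps <- setNames(fit$epsilon$estimate, fit$epsilon$id)
  expect_equal(unname(eps[c("k", "f")]), sol[4:5], tolerance = 1e-10)

  # normal equations: residuals orthogonal to the unpenalised columns
  resid <- y - drop(W %*% sol)
  expect_lt(max(abs(crossprod(W[, 1:2], resid))), 1e-10)

  # no phenotypes -> alpha and eps at their prior mean 0
  samp0 <- samp; samp0$phenotype <- NA_real_
  ds0 <- study_dataset(ped, samp0, geno, sigma2_g = 1, sigma2_e = 2)
  fit0 <- ssbr_fit(ds0, "J", "qtl_plus_markers")
  expect_equal(fit0$alpha$estimate, 0)
  expect_true(all(fit0$epsilon$estimate == 0))
})

test_that("all-genotyped no-J model reduces to plain marker ridge regression", {
  ds <- allgeno_dataset()
  fit <- ssbr_fit(ds, "N", "qtl_plus_markers")
  lam <- fit$sigma2$e / fit$sigma2$alpha
  ph <- ds$samples[!is.na(ds$samples$phenotype), ]
  W <- cbind(1, ds$genotypes[ph$id, , drop = FALSE])
  sol <- solve(crossprod(W) + diag(c(0, rep(lam, ncol(ds$genotypes)))),
               crossprod(W, ph$phenotype))
  expect_equal(fit$alpha$estimate, unname(sol[-1]), tolerance = 1e-10)
  expect_equal(fit$gebv$gebv,
               unname(drop(ds$genotypes %*% sol[-1])), tolerance = 1e-10)

  # J cannot be fitted when everyone with a phenotype is genotyped
  expect_error(ssbr_fit(ds, "J", "qtl_plus_markers"), "collinear")
})

test_that("coding invariance holds when J is fitted", {
  ds <- mini_study()
  ctx <- mini_context()
  fJ <- ssbr_fit(ds, "J", "qtl_plus_markers", context = ctx)
  set.seed(3)
  v <- rnorm(fJ$n_loci, 1, 0.5)
  fS <- ssbr_fit(ds, "J", "qtl_plus_markers", context = ctx,
                 coding_shift = v)
  expect_lt(max(abs(fJ$alpha$estimate - fS$alpha$estimate)), 1e-6)
  # mu_g absorbs the shift: mu_g(shifted) = mu_g - v' alpha is the
  # reparameterisation identity
  expect_lt(abs((fS$mu_g_hat - fJ$mu_g_hat) + sum(v * fJ$alpha$estimate)),
            1e-6)
  val <- ds$samples[ds$samples$generation == max(ds$samples$generation), ]
  aJ <- accuracy(val$tbv, fJ$gebv$gebv[match(val$id, fJ$gebv$id)])
  aS <- accuracy(val$tbv, fS$gebv$gebv[match(val$id, fS$gebv$id)])
  expect_equal(aJ, aS, tolerance = 1e-10)
})

test_that("observed-only centering satisfies mu_g* = mu_g - v' alpha", {
  ds <- mini_study()
  ctx <- mini_context()
  fJ <- ssbr_fit(ds, "J", "qtl_plus_markers", context = ctx)
  fJs <- ssbr_fit(ds, "JCstar", "qtl_plus_markers", context = ctx)
  v <- fJs$centering_vector
  expect_lt(max(abs(fJs$alpha$estimate - fJ$alpha$estimate)), 1e-6)
  expect_lt(abs(fJs$mu_g_hat - (fJ$mu_g_hat - sum(v * fJ$alpha$estimate))),
            1e-6)
})

test_that("whole-matrix centering changes nothing but the intercept split", {
  ds <- mini_study()
  ctx <- mini_context()
  fits <- lapply(c("J", "JC", "N", "C"), function(vv)
    ssbr_fit(ds, vv, "qtl_plus_markers", context = ctx))
  names(fits) <- c("J", "JC", "N", "C")
  expect_lt(max(abs(fits$J$alpha$estimate - fits$JC$alpha$estimate)), 1e-8)
  expect_lt(max(abs(fits$N$alpha$estimate - fits$C$alpha$estimate)), 1e-8)
  # the GEBV difference JC - J is one constant shift for every individual
  d <- fits$JC$gebv$gebv - fits$J$gebv$gebv
  expect_lt(max(d) - min(d), 1e-8)
  # metrics agree to numerical precision
  val <- ds$samples[ds$samples$generation == max(ds$samples$generation), ]
  met <- lapply(fits, function(f) {
    est <- f$gebv$gebv[match(val$id, f$gebv$id)]
    c(accuracy(val$tbv, est), bias_slope(val$tbv, est))
  })
  expect_equal(met$J, met$JC, tolerance = 1e-10)
  expect_equal(met$N, met$C, tolerance = 1e-10)
})

test_that("Gibbs sampling agrees with the exact MME solution", {
  ds <- mini_study()
  ctx <- mini_context()
  fm <- ssbr_fit(ds, "J", "qtl_plus_markers", context = ctx)
  fg <- ssbr_fit(ds, "J", "qtl_plus_markers", method = "gibbs",
                 context = ctx, chain_length = 8000, burn_in = 2000,
                 seed = 99)
  se <- pmax(fg$diagnostics$beta_mc_se, 1e-8)
  z_mu_g <- abs(fg$mu_g_hat - fm$mu_g_hat) / se[2]
  z_alpha <- abs(fg$alpha$estimate - fm$alpha$estimate) / se[-(1:2)]
  expect_lt(z_mu_g, 3)
  expect_lt(max(z_alpha), 4) # 40 marker effects: allow one near-3 excursion
  expect_gt(mean(z_alpha < 3), 0.95)
  z_eps <- abs(fg$epsilon$estimate - fm$epsilon$estimate) /
    pmax(fg$diagnostics$eps_mc_se, 1e-8)
  expect_gt(mean(z_eps < 3), 0.95)

  # two chains with different seeds agree closely on GEBVs
  fg2 <- ssbr_fit(ds, "J", "qtl_plus_markers", method = "gibbs",
                  context = ctx, chain_length = 8000, burn_in = 2000,
                  seed = 100)
  expect_gt(cor(fg$gebv$gebv, fg2$gebv$gebv), 0.999)

  expect_error(ssbr_fit(ds, "J", "qtl_plus_markers", method = "gibbs",
                        chain_length = 100, burn_in = 200), "burn_in")
})

test_that("GEBV decomposition is recomputable and respects fit_j", {
  ds <- mini_study()
  ctx <- mini_context()
  fit <- ssbr_fit(ds, "J", "qtl_plus_markers", context = ctx,
                  keep_design = TRUE)
  re <- compute_gebv(fit)
  expect_equal(re$gebv, fit$gebv$gebv)
  expect_equal(fit$gebv$gebv,
               fit$gebv$term_mu_g + fit$gebv$term_markers +
                 fit$gebv$term_epsilon)
  # genotyped validation individuals carry no epsilon term
  g5 <- fit$gebv[fit$gebv$genotyped, ]
  expect_true(all(g5$term_epsilon == 0))
  # without J the mu_g term vanishes
  fN <- ssbr_fit(ds, "N", "qtl_plus_markers", context = ctx)
  expect_true(all(fN$gebv$term_mu_g == 0))
  expect_true(is.na(fN$mu_g_hat))

  # alpha-hat = 0 and eps-hat = 0 make the GEBV equal to J mu_g
  fit0 <- fit
  expect_equal(fit$gebv$term_mu_g,
               fit$mu_g_hat * unname(ctx$j[fit$gebv$id]))

  # tidy/glance interfaces
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "mu_g"], fit$mu_g_hat)
  expect_equal(nrow(glance(fit)), 1)
})
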