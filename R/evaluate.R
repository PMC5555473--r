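#' Prediction accuracy
#'
#' Accuracy of genomic (or pedigree) prediction: the Pearson correlation
#' between true and estimated breeding values, expressed as a percentage.
#'
#' @param tbv,gebv Numeric vectors of true and estimated breeding values.
#' @return Correlation x 100, or `NA` if either vector has zero variance.
#' @export
accuracy <- function(tbv, gebv) {
  if (length(tbv) != length(gebv)) abort("tbv and gebv lengths differ")
  if (sd(tbv) == 0 || sd(gebv) == 0) return(NA_real_)
  100 * cor(tbv, gebv)
}

#' Prediction bias (dispersion) slope
#'
#' The ordinary least squares regression coefficient of TBV on (G)EBV;
#' deviation from 1 indicates over- or under-dispersion of the predictions.
#'
#' @param tbv,gebv Numeric vectors of true and estimated breeding values.
#' @return OLS slope of `tbv ~ gebv`, or `NA` if `gebv` has zero variance.
#' @export
bias_slope <- function(tbv, gebv) {
  if (length(tbv) != length(gebv)) abort("tbv and gebv lengths differ")
  if (sd(gebv) == 0) return(NA_real_)
  cov(tbv, gebv) / var(gebv)
}

#' Accuracy and bias of a fit in the validation generation
#'
#' @param fit An `ssbr_fit` or `pblup_fit`.
#' @param dataset The `study_dataset` the fit was made on.
#' @return One-row tibble: `variant`, `panel`, `accuracy` (%), `slope`, `n`.
#' @export
evaluate_fit <- function(fit, dataset) {
  g_last <- if (!is.null(dataset$config)) dataset$config$n_select_gens else
    max(dataset$samples$generation, na.rm = TRUE)
  val <- dataset$samples[dataset$samples$generation == g_last, ]
  if (inherits(fit, "ssbr_fit")) {
    est <- fit$gebv$gebv[match(val$id, fit$gebv$id)]
    variant <- fit$variant
    panel <- fit$panel
  } else if (inherits(fit, "pblup_fit")) {
    est <- fit$ebv$ebv[match(val$id, fit$ebv$id)]
    variant <- "PBLUP"
    panel <- "none"
  } else {
    abort("fit must be an ssbr_fit or pblup_fit")
  }
  tibble(
    variant = variant, panel = panel,
    accuracy = accuracy(val$tbv, est),
    slope = bias_slope(val$tbv, est),
    n = nrow(val)
  )
}

#' Scenario configuration for replicated evaluation
#'
#' Describes one cell (or grid) of the study: the genetic architecture,
#' heritability, genotype panels, model variants and replicate count, plus
#' the population scale. Defaults are the full study conditions; the
#' `scale` shortcut switches to the reduced desk-scale population (800
#' dams, 40 sires, same 5% selected proportion).
#'
#' @param n_per_chrom,n_qtl_per_chrom Panel layout per chromosome.
#' @param h2 Heritability.
#' @param mu_alpha Mean QTL effect.
#' @param panels Character vector of panels to analyse.
#' @param variants Character vector of model variants (see [ssbr_variant()]);
#'   `"PBLUP"` adds the pedigree baseline.
#' @param n_replicates Number of replicates (default 10).
#' @param seed Master seed; replicate r uses substream seeds derived from
#'   `seed + r`.
#' @param scale `"full"` (4000 dams / 200 sires) or `"reduced"` (800 / 40).
#' @param method Fitting method for the marker models.
#' @param ... Further arguments passed to [study_config()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_per_chrom = 20, n_qtl_per_chrom = 5,
                            h2 = 0.5, mu_alpha = 0.2,
                            panels = "qtl_plus_markers",
                            variants = c("JC", "J", "C", "N", "PBLUP"),
                            n_replicates = 10, seed = 1,
                            scale = c("full", "reduced"),
                            method = "mme", ...) {
  scale <- match.arg(scale)
  pop <- if (scale == "full") list(n_dams = 4000, n_sires = 200) else
    list(n_dams = 800, n_sires = 40)
  extra <- list(...)
  for (nm in names(extra)) pop[[nm]] <- extra[[nm]]
  structure(list(
    n_per_chrom = n_per_chrom, n_qtl_per_chrom = n_qtl_per_chrom,
    h2 = h2, mu_alpha = mu_alpha, panels = panels, variants = variants,
    n_replicates = n_replicates, seed = seed, scale = scale,
    method = method, pop = pop
  ), class = "scenario_config")
}

#' Run a replicated evaluation scenario
#'
#' For each replicate: simulate a fresh population from a substream of the
#' master seed, fit every requested (variant, panel) combination (sharing
#' the sparse factorisations within the replicate), and measure accuracy
#' and bias in the validation generation.
#'
#' @param config A [scenario_config()].
#' @param progress Print per-replicate progress to stderr.
#' @return An object of class `evaluation_result`: list with `replicates`
#'   (tidy tibble: replicate, variant, panel, accuracy, slope) and
#'   `summary` (means and standard errors of the replicate means).
#' @export
run_replicates <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  res <- list()
  for (r in seq_len(config$n_replicates)) {
    if (progress) message("replicate ", r, "/", config$n_replicates)
    rep_res <- tryCatch(
      run_one_replicate(config, r),
      error = function(e) {
        warn(paste0("replicate ", r, " failed: ", conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(rep_res)) res[[length(res) + 1L]] <- rep_res
  }
  if (length(res) == 0) abort("all replicates failed")
  replicates <- dplyr::bind_rows(res)
  summary <- replicates |>
    dplyr::group_by(.data$variant, .data$panel) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      se_accuracy = sd(.data$accuracy) / sqrt(dplyr::n()),
      mean_slope = mean(.data$slope),
      se_slope = sd(.data$slope) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  structure(list(config = config, replicates = replicates, summary = summary),
            class = "evaluation_result")
}

run_one_replicate <- function(config, r) {
  cfg_args <- c(list(
    n_per_chrom = config$n_per_chrom,
    n_qtl_per_chrom = config$n_qtl_per_chrom,
    h2 = config$h2, mu_alpha = config$mu_alpha,
    seed = config$seed + r
  ), config$pop)
  ds <- sim_study(do.call(study_config, cfg_args))
  ctx <- NULL
  out <- list()
  for (variant in config$variants) {
    if (identical(variant, "PBLUP")) {
      fit <- pblup_fit(ds)
      out[[length(out) + 1L]] <-
        dplyr::mutate(evaluate_fit(fit, ds), replicate = r)
      next
    }
    if (is.null(ctx)) ctx <- ssbr_context(ds)
    for (panel in config$panels) {
      fit <- ssbr_fit(ds, variant = variant, panel = panel,
                      method = config$method, context = ctx)
      out[[length(out) + 1L]] <-
        dplyr::mutate(evaluate_fit(fit, ds), replicate = r)
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result>",
      max(x$summary$n_replicates), "replicates |",
      nrow(x$summary), "variant x panel cells\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_replicates
#' @param x An `evaluation_result`.
#' @param ... Unused.
#' @export
tidy.evaluation_result <- function(x, ...) x$replicates

#' @rdname run_replicates
#' @export
glance.evaluation_result <- function(x, ...) x$summary

#' Plot an evaluation result
#'
#' Accuracy (with +/- 1 SE bars) by model variant and genotype panel.
#'
#' @param object An `evaluation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_result <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$variant, y = .data$mean_accuracy,
                                  fill = .data$panel)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$se_accuracy,
                   ymax = .data$mean_accuracy + .data$se_accuracy),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3
    ) +
    ggplot2::labs(x = "analysis variant", y = "accuracy (%)",
                  fill = "genotype panel") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
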