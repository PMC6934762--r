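#' Binary coverage indicator
#'
#' Records whether a confidence interval contains the true value: 1 if
#' `ci_low <= true_value <= ci_high` (endpoints inclusive; ties are
#' measure-zero), else 0. Non-finite bounds are counted as non-coverage and
#' flagged.
#'
#' @param ci_low,ci_high Interval bounds (vectors allowed).
#' @param true_value True parameter value(s).
#' @return Integer 0/1 vector with a logical `"nonfinite"` attribute.
#' @examples
#' coverage_indicator(1, 3, 3)       # 1 (inclusive endpoint)
#' coverage_indicator(1, 3, 3.0001)  # 0
#' @export
coverage_indicator <- function(ci_low, ci_high, true_value) {
  bad <- !is.finite(ci_low) | !is.finite(ci_high)
  if (any(ci_low[!bad] > ci_high[!bad])) {
    stop("ci_low must not exceed ci_high", call. = FALSE)
  }
  out <- as.integer(!bad & ci_low <= true_value & true_value <= ci_high)
  attr(out, "nonfinite") <- bad
  out
}

#' Configuration of the empirical coverage study
#'
#' Describes the simulation experiment: a generating process (by default
#' the zero-inflated NB process of [coverage_generator()]), the number of
#' simulated experiments per batch and number of batches, the models to fit
#' to every experiment (by default the eight-model ladder: Gaussian, the
#' three transformed-Gaussian variants, Poisson, NB, ZINB and HNB with
#' per-genotype inflation), and the nominal interval level.
#'
#' `drop_subsampling = TRUE` (default) omits the whole-plot random term
#' from all fitted models, and `include_block = FALSE` additionally omits
#' the block term — the generating process of the study carries no
#' block/plot heterogeneity, so its true head-level genotype mean is exactly
#' `(1 - pi_g) * lambda_g`.
#'
#' @param generator A [crossing_block_config()] generating one experiment.
#' @param n_experiments Simulated experiments per batch.
#' @param n_batches Number of independently seeded batches (results are
#'   reported per batch and pooled).
#' @param models Optional named list of [model_spec()]s.
#' @param nominal_level Nominal confidence level of the intervals.
#' @param drop_subsampling Omit whole-plot random effects from the fits.
#' @param include_block Keep the block random term in the fits.
#' @param truth `"component_mean"` (default) scores intervals against the
#'   generating count-component mean `lambda_g` — the genotype mean seed
#'   count that every model in the ladder reports through
#'   [genotype_count_means()]; `"head_mean"` scores against the data-scale
#'   head-level mean `(1 - pi_g) * lambda_g`, with the ZINB interval then
#'   built on its inflation-adjusted mean (see the vignette's discussion of
#'   this choice).
#' @param seed Master seed; all per-experiment seeds derive from it.
#' @return An object of class `"coverage_config"`.
#' @export
coverage_config <- function(generator = coverage_generator(),
                            n_experiments = 500L, n_batches = 2L,
                            models = NULL, nominal_level = 0.95,
                            drop_subsampling = TRUE, include_block = FALSE,
                            truth = c("component_mean", "head_mean"),
                            seed = 1L) {
  truth <- match.arg(truth)
  stopifnot(inherits(generator, "crossing_block_config"),
            n_experiments >= 1, n_batches >= 1,
            nominal_level > 0, nominal_level < 1)
  if (is.null(models)) {
    rnd <- c(if (include_block) "block",
             if (!drop_subsampling) "wholeplot")
    if (is.null(rnd)) rnd <- character(0)
    models <- list(
      gaussian = model_spec("gaussian", random = rnd),
      LT = model_spec("gaussian", transform = "log_plus_one", random = rnd),
      ST = model_spec("gaussian", transform = "sqrt_three_eighths", random = rnd),
      ET = model_spec("gaussian", transform = "two_thirds_power", random = rnd),
      poisson = model_spec("poisson", random = rnd),
      negbin = model_spec("negbin", random = rnd),
      HNB = model_spec("hnb", inflation = "per_genotype", random = rnd),
      ZINB = model_spec("zinb", inflation = "per_genotype", random = rnd))
  }
  if (length(models) && is.null(names(models))) {
    stop("'models' must be a named list", call. = FALSE)
  }
  structure(list(generator = generator,
                 n_experiments = as.integer(n_experiments),
                 n_batches = as.integer(n_batches), models = models,
                 nominal_level = nominal_level,
                 drop_subsampling = drop_subsampling,
                 include_block = include_block, truth = truth,
                 seed = as.integer(seed)),
            class = "coverage_config")
}

## true per-genotype value of the generating process on the requested scale
.coverage_truth <- function(gen, truth) {
  if (truth == "component_mean") {
    gen$lambda
  } else {
    mixture_mean(gen$pi, gen$lambda, gen$dispersion,
                 kind = gen$process)
  }
}

#' Run the empirical coverage study
#'
#' For each simulated experiment: generate a dataset from the configured
#' process, fit every model, build nominal-level confidence intervals for
#' each genotype's reported seed-count estimate on the data scale (see
#' [genotype_count_means()]), and score the binary coverage indicator
#' against the generating truth. Per-model coverage is the average
#' indicator; fits that fail to converge are logged and excluded from that
#' model's denominator (the exclusion count is reported so the opposite
#' convention can be reconstructed), while non-finite intervals from
#' converged fits count as non-coverage. The run is fully reproducible from
#' the config seed.
#'
#' @param config A [coverage_config()].
#' @param progress Print a dot per completed experiment?
#' @return An object of class `"coverage_result"`; see [coverage_report()].
#' @export
run_coverage_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "coverage_config"))
  gen <- config$generator
  truth <- .coverage_truth(gen, config$truth)
  n_tot <- config$n_experiments * config$n_batches
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  mnames <- names(config$models)
  cov_mat <- matrix(NA_real_, n_tot, length(mnames),
                    dimnames = list(NULL, mnames))
  width_mat <- matrix(NA_real_, n_tot, length(mnames),
                      dimnames = list(NULL, mnames))
  n_int <- n_bad <- stats::setNames(integer(length(mnames)), mnames)
  n_fail <- stats::setNames(integer(length(mnames)), mnames)
  indicators <- stats::setNames(vector("list", length(mnames)), mnames)
  for (m in mnames) indicators[[m]] <- list()
  for (e in seq_len(n_tot)) {
    g_e <- gen; g_e$seed <- seeds[e]
    d <- simulate_crossing_block(g_e)
    for (m in mnames) {
      fit <- tryCatch(fit_sterility_model(d, config$models[[m]]),
                      error = function(err) NULL)
      if (is.null(fit) || !fit$converged) {
        n_fail[m] <- n_fail[m] + 1L
        next
      }
      est <- tryCatch(
        genotype_count_means(fit, level = config$nominal_level,
                             inflation_adjusted = config$truth == "head_mean"),
        error = function(err) NULL)
      if (is.null(est)) { n_fail[m] <- n_fail[m] + 1L; next }
      if (fit$spec$family == "gaussian" && fit$spec$transform != "identity") {
        # transformed families: symmetric data-scale intervals from the
        # delta-method standard error, as in the source analysis
        z <- stats::qnorm(1 - (1 - config$nominal_level) / 2)
        est$ci_low <- est$estimate - z * est$se_data
        est$ci_high <- est$estimate + z * est$se_data
      }
      tr <- truth[est$genotype]
      ind <- coverage_indicator(est$ci_low, est$ci_high, tr)
      indicators[[m]][[length(indicators[[m]]) + 1L]] <- as.integer(ind)
      n_int[m] <- n_int[m] + length(ind)
      n_bad[m] <- n_bad[m] + sum(attr(ind, "nonfinite"))
      cov_mat[e, m] <- mean(ind)
      width_mat[e, m] <- mean(est$ci_high - est$ci_low)
    }
    if (progress) cat(".", if (e %% 50 == 0) paste0(" ", e, "\n"))
  }
  batch <- rep(seq_len(config$n_batches), each = config$n_experiments)
  structure(list(config = config, coverage_by_experiment = cov_mat,
                 width_by_experiment = width_mat, batch = batch,
                 indicators = lapply(indicators, function(x) unlist(x)),
                 n_intervals = n_int, n_nonfinite = n_bad,
                 n_failed_fits = n_fail, seeds = seeds),
            class = "coverage_result")
}

#' Tabulate a coverage study
#'
#' One row per model: empirical coverage (mean binary indicator across all
#' genotype-by-experiment intervals), the standard deviation of the
#' indicator `sqrt(p(1-p))`, the Monte-Carlo standard error of the coverage
#' estimate, interval counts, excluded (non-converged) fit counts, and mean
#' data-scale interval width. With `by_batch = TRUE`, per-batch coverage
#' columns are appended.
#'
#' @param result A `coverage_result`.
#' @param by_batch Append per-batch coverage columns?
#' @return A `data.frame`.
#' @export
coverage_report <- function(result, by_batch = FALSE) {
  stopifnot(inherits(result, "coverage_result"))
  mnames <- names(result$config$models)
  rows <- lapply(mnames, function(m) {
    ind <- result$indicators[[m]]
    p <- if (length(ind)) mean(ind) else NA_real_
    data.frame(model = m,
               coverage = p,
               sd_coverage = if (length(ind)) sqrt(p * (1 - p)) else NA_real_,
               mc_se = if (length(ind)) stats::sd(ind) / sqrt(length(ind))
                       else NA_real_,
               n_intervals = result$n_intervals[[m]],
               n_nonfinite = result$n_nonfinite[[m]],
               n_failed_fits = result$n_failed_fits[[m]],
               mean_ci_width = mean(result$width_by_experiment[, m],
                                    na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(model = character(0), coverage = numeric(0),
                      sd_coverage = numeric(0), mc_se = numeric(0),
                      n_intervals = integer(0), n_nonfinite = integer(0),
                      n_failed_fits = integer(0), mean_ci_width = numeric(0)))
  }
  out <- do.call(rbind, rows)
  if (by_batch) {
    for (b in unique(result$batch)) {
      out[[paste0("coverage_batch", b)]] <- vapply(mnames, function(m) {
        mean(result$coverage_by_experiment[result$batch == b, m], na.rm = TRUE)
      }, numeric(1))
    }
  }
  rownames(out) <- NULL
  out
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("Coverage study: %d experiment(s) x %d batch(es), %d model(s), truth = %s\n",
              x$config$n_experiments, x$config$n_batches,
              length(x$config$models), x$config$truth))
  print(coverage_report(x), digits = 3)
  invisible(x)
}
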