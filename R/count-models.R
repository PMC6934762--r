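#' Fit one model of the seed-count analysis ladder
#'
#' Convenience wrapper building a [model_spec()] and delegating to
#' [fit_sterility_model()]. For the transformed-Gaussian families the
#' response is transformed before a REML fit; count families are fitted by
#' marginal ML (Laplace approximation).
#'
#' @param data Seed-count data for a single year.
#' @param family Model family (see [model_spec()]).
#' @param transform Response transformation for `family = "gaussian"`.
#' @param inflation Inflation structure for the mixture families
#'   (`"single"` or `"per_genotype"`).
#' @param random Random-effect terms; defaults as in [model_spec()].
#' @param ... Passed to [fit_sterility_model()].
#' @return A `sterility_fit`.
#' @export
fit_count_model <- function(data, family = "negbin", transform = "identity",
                            inflation = NULL, random = NULL, ...) {
  spec <- model_spec(family = family, transform = transform,
                     inflation = inflation, random = random)
  fit_sterility_model(data, spec, ...)
}

#' Genotype seed-count estimates on the data scale
#'
#' Data-scale genotype means with 95% Wald confidence intervals built on the
#' link (or transformed) scale and back-transformed, so interval endpoints
#' are order-preserved by the inverse link:
#'
#' * log-link count families (Poisson, NB, and the count component of the
#'   mixtures): `exp(alpha_i)`, the genotype mean seed count of the
#'   seed-forming process (for the hurdle model, the seed count expected if
#'   the head is not fully sterilized);
#' * zero-inflated NB with `inflation_adjusted = TRUE` (default): the
#'   model-implied head-level mean `(1 - pi_i) * lambda_i`, since the ZINB
#'   analysis reports an inflation probability alongside the count mean;
#' * transformed-Gaussian families: the naive back-transformation of the
#'   genotype mean, with a delta-method standard error in `se_data`;
#'   deliberately without bias correction, mirroring the approach whose
#'   failure modes the coverage study quantifies. Back-transformed values
#'   corresponding to negative counts are flagged `nonsensical`.
#'
#' @param fit A converged count-family `sterility_fit`.
#' @param level Confidence level.
#' @param inflation_adjusted For ZINB fits, report the head-level mean
#'   `(1 - pi) * lambda` (delta-method interval on the log scale) instead of
#'   the count-component mean.
#' @return A `data.frame` with `genotype`, `estimate`, `ci_low`, `ci_high`,
#'   `se_data`, `scale = "count"`, `boundary`, `nonsensical`.
#' @export
genotype_count_means <- function(fit, level = 0.95, inflation_adjusted = TRUE) {
  stopifnot(inherits(fit, "sterility_fit"))
  if (!fit$converged) {
    stop("fit did not converge; refusing to report genotype means", call. = FALSE)
  }
  fam <- fit$spec$family
  if (fam %in% c("binary_logit", "binary_probit")) {
    stop("use genotype_proportions() for threshold fits", call. = FALSE)
  }
  fr <- fit$frame
  anm <- paste0("alpha.", fr$glabels)
  a <- fit$params[anm]
  va <- diag(fit$vcov)[anm]
  z <- stats::qnorm(1 - (1 - level) / 2)
  boundary <- anm %in% fit$non_estimable
  nonsens <- rep(FALSE, fr$G)
  if (fam == "gaussian") {
    tr <- fit$spec$transform
    se <- sqrt(pmax(va, 0))
    est <- count_transform_inverse(a, tr)
    lo <- count_transform_inverse(a - z * se, tr)
    hi <- count_transform_inverse(a + z * se, tr)
    nonsens <- attr(est, "nonsensical") | attr(lo, "nonsensical")
    se_data <- as.numeric(delta_method_se(tr, a, se))
    est <- as.numeric(est); lo <- as.numeric(lo); hi <- as.numeric(hi)
  } else if (fam == "zinb" && inflation_adjusted) {
    ext <- .par_extract(fr, fit$params)
    znm <- if (fit$spec$inflation == "single") rep("zi.overall", fr$G)
           else paste0("zi.", fr$glabels)
    q <- a + log(1 - ext$pi_g)               # log head-level mean
    dq_dpsi <- -ext$pi_g                     # d log(1-plogis(psi)) / d psi
    vq <- va + dq_dpsi^2 * diag(fit$vcov)[znm] +
      2 * dq_dpsi * fit$vcov[cbind(anm, znm)]
    se <- sqrt(pmax(vq, 0))
    est <- exp(q); lo <- exp(q - z * se); hi <- exp(q + z * se)
    se_data <- est * se
    boundary <- boundary | znm %in% fit$non_estimable
  } else {
    se <- sqrt(pmax(va, 0))
    est <- exp(a); lo <- exp(a - z * se); hi <- exp(a + z * se)
    se_data <- est * se
  }
  data.frame(genotype = fr$glabels, estimate = est, ci_low = lo, ci_high = hi,
             se_data = se_data, scale = "count", boundary = boundary,
             nonsensical = nonsens, row.names = NULL, stringsAsFactors = FALSE)
}

#' Inflation probability estimates from a mixture fit
#'
#' Inverse-logit estimates of the inflation probabilities with Wald
#' confidence intervals built on the logit scale, plus a Wald test of each
#' probability against the no-zero-inflation null (pi = 0, standard error
#' mapped to the probability scale by the delta method; approximate near
#' the boundary, where the flag column marks estimates whose interval
#' reaches below 1%).
#'
#' @param fit A `sterility_fit` with family `"zinb"` or `"hnb"`.
#' @param level Confidence level.
#' @return A `data.frame` with `genotype` (or `"overall"` for single-pi
#'   fits), `pi`, `ci_low`, `ci_high`, `se`, `z`, `p_value`,
#'   `near_zero_boundary`.
#' @export
inflation_probabilities <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sterility_fit"))
  if (!fit$spec$family %in% c("zinb", "hnb")) {
    stop("inflation probabilities require a zinb or hnb fit", call. = FALSE)
  }
  znm <- if (fit$spec$inflation == "single") "zi.overall"
         else paste0("zi.", fit$frame$glabels)
  psi <- fit$params[znm]
  se_psi <- sqrt(pmax(diag(fit$vcov)[znm], 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- stats::plogis(psi)
  se_p <- p * (1 - p) * se_psi
  zstat <- ifelse(se_p > 0, p / se_p, Inf)
  data.frame(
    genotype = if (fit$spec$inflation == "single") "overall"
               else fit$frame$glabels,
    pi = p, ci_low = stats::plogis(psi - z * se_psi),
    ci_high = stats::plogis(psi + z * se_psi), se = se_p, z = zstat,
    p_value = 2 * stats::pnorm(-abs(zstat)),
    near_zero_boundary = stats::plogis(psi - z * se_psi) < 0.01 |
      znm %in% fit$non_estimable,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare candidate models on one dataset
#'
#' Fits every spec and tabulates fit statistics. Models are only directly
#' rankable within a likelihood type: transformed-response Gaussian fits
#' have likelihoods on the transformed scale, not comparable with the count
#' likelihoods, and the table marks each row's `likelihood_type`
#' accordingly. Rows are sorted by AICc within type; non-converged fits are
#' retained and flagged.
#'
#' @param data Seed-count data for a single year.
#' @param specs Named list of [model_spec()] objects (at least 2).
#' @return A `data.frame` of class `"model_comparison"` with one row per
#'   spec, plus a `"fits"` attribute holding the fitted models.
#' @export
compare_count_models <- function(data, specs) {
  if (length(specs) < 2) stop("need at least 2 model specs", call. = FALSE)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, function(s) {
      if (s$transform != "identity") paste0(s$family, "_", s$transform)
      else s$family
    }, character(1))
  }
  fits <- lapply(specs, function(s) fit_sterility_model(data, s))
  rows <- lapply(names(specs), function(nm) {
    f <- fits[[nm]]
    ic <- suppressWarnings(information_criteria(f))
    chi <- if (f$spec$family %in% c("poisson", "negbin", "zinb", "hnb")) {
      tryCatch(suppressWarnings(pearson_overdispersion(f)),
               error = function(e) NA_real_)
    } else NA_real_
    data.frame(model = nm, family = f$spec$family,
               transform = f$spec$transform,
               likelihood_type = if (f$spec$family == "gaussian" &&
                                     f$spec$transform != "identity")
                 "transformed_scale" else if (f$spec$family == "gaussian")
                 "gaussian" else "count",
               AICc = ic[["AICc"]], BIC = ic[["BIC"]],
               minus2LL = ic[["minus2LL"]], pearson_ratio = chi,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$likelihood_type, out$AICc), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  class(out) <- c("model_comparison", class(out))
  out
}
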