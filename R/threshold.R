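#' Binarize seed counts at a sterility threshold
#'
#' Classifies every bagged head as a success (`1`, seed count at or below
#' the threshold, i.e. adequate sterility) or failure (`0`). The default
#' threshold of 7 seeds corresponds to roughly 75% sterility of a healthy
#' Great Plains winter wheat head of about 30 seeds; it is a configuration
#' value, not a constant.
#'
#' @param data Seed-count data.
#' @param threshold Non-negative integer cutoff; a head with
#'   `seed_count <= threshold` is a success. Infinite or negative thresholds
#'   are rejected (every-head-success makes the model degenerate).
#' @return `data` with an added 0/1 `success` column.
#' @examples
#' d <- data.frame(seed_count = c(0, 7, 8))
#' binarize_counts(d)$success  # 1 1 0
#' @export
binarize_counts <- function(data, threshold = 7) {
  if (!is.finite(threshold) || threshold < 0 || threshold != floor(threshold)) {
    stop("'threshold' must be a finite non-negative integer", call. = FALSE)
  }
  stopifnot("seed_count" %in% names(data))
  data$success <- as.integer(data$seed_count <= threshold)
  data
}

#' Fit a threshold (logit or probit) sterility GLMM
#'
#' Binary GLMM for the frequency of meeting the sterility threshold, with
#' genotype fixed effects and block plus whole-plot random effects, fitted
#' by adaptive Gauss-Hermite quadrature. With a single block the block
#' variance is not estimable; it is dropped with a warning.
#'
#' Genotypes observed as all-success or all-failure (complete separation)
#' have boundary estimates with inflated standard errors; they are flagged
#' in the fit's `non_estimable` field rather than corrected.
#'
#' @param data Seed-count data.
#' @param threshold Cutoff passed to [binarize_counts()].
#' @param link `"logit"` or `"probit"`.
#' @param random Random-effect terms, default block + whole-plot.
#' @param nodes Quadrature nodes.
#' @return A `sterility_fit` with a `threshold` attribute.
#' @export
fit_threshold_model <- function(data, threshold = 7,
                                link = c("logit", "probit"),
                                random = c("block", "wholeplot"),
                                nodes = 9L) {
  link <- match.arg(link)
  data <- binarize_counts(data, threshold)
  if (length(unique(data$block)) < 2 && "block" %in% random) {
    warning("fewer than 2 blocks: block variance fixed at zero", call. = FALSE)
    random <- setdiff(random, "block")
  }
  spec <- model_spec(family = paste0("binary_", link), random = random,
                     nodes = nodes)
  fit <- fit_sterility_model(data, spec)
  attr(fit, "threshold") <- threshold
  fit
}

#' Genotype sterility proportions from a threshold fit
#'
#' Inverse-link estimates of each genotype's probability of meeting the
#' sterility threshold, with 95% Wald confidence intervals built on the link
#' scale and back-transformed (so the interval respects `[0, 1]`). Boundary
#' genotypes (estimate at the search bound, e.g. complete separation) are
#' reported with their interval clipped to `[0, 1]` and flagged.
#'
#' @param fit A threshold-model `sterility_fit`.
#' @param level Confidence level.
#' @return A `data.frame` with columns `genotype`, `estimate`, `ci_low`,
#'   `ci_high`, `scale` (`"proportion"`), and `boundary`.
#' @export
genotype_proportions <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "sterility_fit"))
  if (!fit$spec$family %in% c("binary_logit", "binary_probit")) {
    stop("not a threshold-model fit", call. = FALSE)
  }
  linkinv <- link_functions(sub("binary_", "", fit$spec$family))$linkinv
  fr <- fit$frame
  anm <- paste0("alpha.", fr$glabels)
  a <- fit$params[anm]
  se <- sqrt(pmax(diag(fit$vcov)[anm], 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  boundary <- anm %in% fit$non_estimable
  lo <- linkinv(a - z * se)
  hi <- linkinv(a + z * se)
  data.frame(genotype = fr$glabels,
             estimate = pmin(pmax(linkinv(a), 0), 1),
             ci_low = pmin(pmax(lo, 0), 1), ci_high = pmin(pmax(hi, 0), 1),
             scale = "proportion", boundary = boundary,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Type III test for genotype effects
#'
#' Wald-type F statistic for the joint null of equal genotype effects.
#' Mixed-model denominator-df conventions differ across software; the
#' default `"residual"` rule (`n - p`) tracks the large-sample Wald
#' reference, which simulation shows is close to nominal under a clean
#' null, while the `"containment"` rule (`(G-1)(J-1)`, the whole-plot
#' stratum of the blocked design) is markedly conservative for this
#' statistic at trial-sized designs (see the vignette).
#'
#' @param fit A converged `sterility_fit` with at least two genotypes.
#' @param ddf `"residual"` or `"containment"`.
#' @return Named vector `c(F, ndf, ddf, p)`.
#' @export
type3_genotype_test <- function(fit, ddf = c("residual", "containment")) {
  stopifnot(inherits(fit, "sterility_fit"))
  .type3_F(fit, ddf_method = match.arg(ddf))
}
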