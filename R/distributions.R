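#' Base count probability mass function (NB2 or its Poisson limit)
#'
#' Negative binomial pmf in the NB2 (mean/dispersion) parameterization with
#' mean `mu` and dispersion `size` (often written k), so that
#' `Var(Y) = mu + mu^2/size`. An infinite `size` gives the Poisson limit.
#'
#' @param y Vector of non-negative integer counts.
#' @param mu Positive mean of the count distribution.
#' @param size Positive NB2 dispersion k; `Inf` selects the Poisson pmf.
#' @param log Return log-probabilities?
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' base_pmf(0, mu = 1, size = Inf)  # exp(-1)
#' base_pmf(0, mu = 1, size = 1)    # (k/(k+mu))^k = 0.5
#' @export
base_pmf <- function(y, mu, size = Inf, log = FALSE) {
  if (any(y < 0) || any(y != floor(y))) {
    stop("'y' must contain non-negative integers", call. = FALSE)
  }
  if (any(mu <= 0) || any(size <= 0)) {
    stop("'mu' and 'size' must be positive", call. = FALSE)
  }
  if (all(is.infinite(size))) {
    stats::dpois(y, lambda = mu, log = log)
  } else {
    stats::dnbinom(y, size = size, mu = mu, log = log)
  }
}

## log Pr(Y = 0) for the base distribution, numerically stable
.log_p0 <- function(mu, size) {
  if (all(is.infinite(size))) -mu else size * (log(size) - log(size + mu))
}

#' Zero-inflated and hurdle count mixture pmf
#'
#' Probability mass function of a two-component count model. For the
#' zero-inflated kind, a structural zero occurs with mixture weight `pi`
#' (the inflation probability) and otherwise the count follows the base
#' distribution, so `Pr(0) = pi + (1 - pi) f(0)` and
#' `Pr(y) = (1 - pi) f(y)` for positive y. For the hurdle kind, zero occurs
#' with probability `pi` exactly and positive counts follow the
#' zero-truncated base distribution: `Pr(y) = (1 - pi) f(y) / (1 - f(0))`.
#'
#' The zero cell of the zero-inflated form is evaluated by log-sum-exp; all
#' values are exact pmf evaluations, not normalized numerically.
#'
#' @param y Vector of non-negative integer counts.
#' @param pi Inflation probability in `[0, 1]` (scalar or per-observation).
#' @param mu Mean of the base count distribution (lambda), positive.
#' @param size NB2 dispersion k; `Inf` for a Poisson base.
#' @param kind `"zero_inflated"` or `"hurdle"`.
#' @param log Return log-probabilities?
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' mixture_pmf(0, pi = 0.4, mu = 2, size = Inf)  # 0.4 + 0.6 * exp(-2)
#' mixture_pmf(0, pi = 0.3, mu = 5, size = 1, kind = "hurdle")  # exactly 0.3
#' @export
mixture_pmf <- function(y, pi, mu, size = Inf,
                        kind = c("zero_inflated", "hurdle"), log = FALSE) {
  kind <- match.arg(kind)
  if (any(pi < 0) || any(pi > 1)) stop("'pi' must lie in [0, 1]", call. = FALSE)
  n <- max(length(y), length(pi), length(mu), length(size))
  y <- rep_len(y, n); pi <- rep_len(pi, n)
  mu <- rep_len(mu, n); size <- rep_len(size, n)
  lf <- base_pmf(y, mu, size, log = TRUE)
  lp0 <- .log_p0(mu, size)
  out <- numeric(n)
  z <- y == 0
  if (kind == "zero_inflated") {
    # log(pi + (1 - pi) f(0)) via log-sum-exp; handles pi in {0, 1} exactly
    l1 <- ifelse(pi[z] > 0, log(pi[z]), -Inf)
    l2 <- ifelse(pi[z] < 1, log1p(-pi[z]) + lp0[z], -Inf)
    m <- pmax(l1, l2)
    out[z] <- ifelse(is.finite(m), m + log(exp(l1 - m) + exp(l2 - m)), -Inf)
    out[!z] <- ifelse(pi[!z] < 1, log1p(-pi[!z]) + lf[!z], -Inf)
  } else {
    if (any(lp0[!z] >= 0)) {
      stop("hurdle model degenerate: base distribution has all mass at zero",
           call. = FALSE)
    }
    out[z] <- ifelse(pi[z] > 0, log(pi[z]), -Inf)
    # log(1 - f(0)) = log(-expm1(log f(0)))
    out[!z] <- ifelse(pi[!z] < 1,
                      log1p(-pi[!z]) + lf[!z] - log(-expm1(lp0[!z])), -Inf)
  }
  if (log) return(out)
  p <- exp(out)
  # the hurdle zero cell is pi by definition; avoid the exp(log(.)) ulp
  if (kind == "hurdle") p[z] <- pi[z]
  p
}

#' Mean of the mixture distribution on the data scale
#'
#' Head-level expected count implied by the mixture parameters:
#' `(1 - pi) * mu` for the zero-inflated kind and
#' `(1 - pi) * mu / (1 - f(0))` for the hurdle kind.
#'
#' @inheritParams mixture_pmf
#' @return Numeric vector of expected counts.
#' @export
mixture_mean <- function(pi, mu, size = Inf,
                         kind = c("zero_inflated", "hurdle")) {
  kind <- match.arg(kind)
  if (kind == "zero_inflated") {
    (1 - pi) * mu
  } else {
    (1 - pi) * mu / (-expm1(.log_p0(mu, size)))
  }
}

## ---- response transformations -------------------------------------------

.transform_names <- c("identity", "log_plus_one", "sqrt_three_eighths",
                      "two_thirds_power")

#' Variance-stabilizing response transformations for seed counts
#'
#' Forward transformations used by the normal-approximation analyses:
#' `log_plus_one` is `log(y + 1)`, `sqrt_three_eighths` is `sqrt(y + 3/8)`,
#' `two_thirds_power` is `y^(2/3)`, and `identity` leaves counts unchanged.
#'
#' @param y Non-negative counts (forward) or reals in the forward range
#'   (inverse).
#' @param name One of `"identity"`, `"log_plus_one"`, `"sqrt_three_eighths"`,
#'   `"two_thirds_power"`.
#' @return Transformed values. The inverse attaches a logical attribute
#'   `"nonsensical"` marking back-transformed values that would correspond to
#'   negative counts.
#' @examples
#' count_transform(8, "two_thirds_power")        # 4
#' count_transform_inverse(4, "two_thirds_power")  # 8
#' @export
count_transform <- function(y, name = .transform_names) {
  name <- match.arg(name)
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  switch(name,
         identity = y,
         log_plus_one = log(y + 1),
         sqrt_three_eighths = sqrt(y + 3 / 8),
         two_thirds_power = y^(2 / 3))
}

#' @rdname count_transform
#' @param x Values on the transformed scale.
#' @export
count_transform_inverse <- function(x, name = .transform_names) {
  name <- match.arg(name)
  out <- switch(name,
                identity = x,
                log_plus_one = exp(x) - 1,
                sqrt_three_eighths = x^2 - 3 / 8,
                two_thirds_power = sign(x) * abs(x)^(3 / 2))
  flag <- out < 0
  # negative back-transformed counts are nonsensical on the data scale
  attr(out, "nonsensical") <- flag
  out
}

## derivative of the inverse transformation, for delta-method SEs
.transform_inverse_deriv <- function(x, name) {
  switch(name,
         identity = rep_len(1, length(x)),
         log_plus_one = exp(x),
         sqrt_three_eighths = 2 * x,
         two_thirds_power = 1.5 * abs(x)^(1 / 2))
}

## ---- link functions ------------------------------------------------------

#' Link function pairs
#'
#' Returns the forward (mean to linear predictor) and inverse maps for the
#' links used across the package's models.
#'
#' @param name One of `"logit"`, `"probit"`, `"log"`, `"identity"`.
#' @return List with elements `linkfun`, `linkinv`, and `mu.eta` (derivative
#'   of the inverse link).
#' @examples
#' link_functions("logit")$linkinv(0)  # 0.5
#' @export
link_functions <- function(name = c("logit", "probit", "log", "identity")) {
  name <- match.arg(name)
  switch(name,
         logit = list(linkfun = stats::qlogis, linkinv = stats::plogis,
                      mu.eta = function(eta) stats::dlogis(eta)),
         probit = list(linkfun = stats::qnorm, linkinv = stats::pnorm,
                       mu.eta = function(eta) stats::dnorm(eta)),
         log = list(linkfun = log, linkinv = exp, mu.eta = exp),
         identity = list(linkfun = identity, linkinv = identity,
                         mu.eta = function(eta) rep_len(1, length(eta))))
}

#' Delta-method standard error of a transformed estimate
#'
#' First-order propagation of a standard error through a differentiable map
#' g: `se(g(x)) ~= |g'(x)| * se_x`.
#'
#' @param g Function of one argument, or one of the transformation names
#'   accepted by [count_transform_inverse()] (in which case its inverse map's
#'   derivative is used in closed form).
#' @param x Point estimate on the original scale.
#' @param se_x Standard error of `x`.
#' @return Standard error of `g(x)`. Zero derivatives yield an SE of 0 with a
#'   `"degenerate"` attribute flag.
#' @examples
#' delta_method_se(exp, 0, 0.1)  # 0.1
#' @export
delta_method_se <- function(g, x, se_x) {
  if (is.character(g)) {
    d <- .transform_inverse_deriv(x, match.arg(g, .transform_names))
  } else {
    h <- 1e-6 * pmax(abs(x), 1)
    d <- (g(x + h) - g(x - h)) / (2 * h)
  }
  out <- abs(d) * se_x
  attr(out, "degenerate") <- d == 0
  out
}
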