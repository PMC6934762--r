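#' Model specification for sterility mixed models
#'
#' Declarative description of one model in the analysis ladder: response
#' family, response transformation (Gaussian family only), inflation
#' structure for the mixture families, random-effect terms, and estimation
#' method. The linear predictor is always
#' `eta_ijk = alpha_i + b_j + (ab)_ij`, with genotype fixed effects
#' `alpha_i`, i.i.d. normal block effects `b_j ~ N(0, sigma_b^2)` and
#' whole-plot (genotype-by-block experimental unit) effects
#' `(ab)_ij ~ N(0, sigma_ab^2)`. For the mixture families the random effects
#' enter the count component's log mean only; the inflation probability
#' carries genotype fixed effects (`per_genotype`) or a single intercept
#' (`single`) on the logit scale.
#'
#' Default estimation follows the family: restricted maximum likelihood for
#' the (transformed-)Gaussian families, marginal ML with the Laplace
#' approximation for the count families, and adaptive Gauss-Hermite
#' quadrature for the binary threshold families.
#'
#' @param family One of `"gaussian"`, `"poisson"`, `"negbin"`, `"zinb"`,
#'   `"hnb"`, `"binary_logit"`, `"binary_probit"`.
#' @param transform Response transformation name (Gaussian family only); see
#'   [count_transform()].
#' @param inflation `"none"`, `"single"`, or `"per_genotype"`; must be
#'   `"none"` exactly when the family is not a mixture.
#' @param random Character subset of `c("block", "wholeplot")` (possibly
#'   empty). Defaults: both terms for Gaussian/Poisson/NB/binary families,
#'   block only for the mixture families.
#' @param estimation `"REML_normal"`, `"ML_laplace"`, or `"ML_agq"`;
#'   defaulted by family as above.
#' @param nodes Number of quadrature nodes for adaptive Gauss-Hermite.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(family = c("gaussian", "poisson", "negbin", "zinb",
                                  "hnb", "binary_logit", "binary_probit"),
                       transform = "identity", inflation = NULL,
                       random = NULL, estimation = NULL, nodes = 9L) {
  family <- match.arg(family)
  mixture <- family %in% c("zinb", "hnb")
  if (is.null(inflation)) inflation <- if (mixture) "per_genotype" else "none"
  inflation <- match.arg(inflation, c("none", "single", "per_genotype"))
  if (mixture && inflation == "none") {
    stop("mixture families require an inflation structure", call. = FALSE)
  }
  if (!mixture && inflation != "none") {
    stop("inflation structure only applies to zinb/hnb families", call. = FALSE)
  }
  transform <- match.arg(transform, .transform_names)
  if (transform != "identity" && family != "gaussian") {
    stop("response transformations apply to the gaussian family only",
         call. = FALSE)
  }
  if (is.null(random)) {
    random <- if (mixture) "block" else c("block", "wholeplot")
  }
  if (length(random)) random <- match.arg(random, c("block", "wholeplot"),
                                          several.ok = TRUE)
  if (is.null(estimation)) {
    estimation <- switch(family,
                         gaussian = "REML_normal",
                         binary_logit = , binary_probit = "ML_agq",
                         "ML_laplace")
  }
  estimation <- match.arg(estimation, c("REML_normal", "ML_laplace", "ML_agq"))
  if (estimation == "REML_normal" && family != "gaussian") {
    stop("REML estimation applies to the gaussian family only", call. = FALSE)
  }
  structure(list(family = family, transform = transform,
                 inflation = inflation, random = random,
                 estimation = estimation, nodes = as.integer(nodes)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec: %s (transform: %s, inflation: %s)\n",
              x$family, x$transform, x$inflation))
  cat(sprintf("  random: %s; estimation: %s (%d nodes)\n",
              if (length(x$random)) paste(x$random, collapse = " + ") else "none",
              x$estimation, x$nodes))
  invisible(x)
}

## ---- internal model frame ------------------------------------------------

## Builds the numeric structures used by the likelihood machinery. The
## response is seed_count for count families, a 0/1 `success` column for the
## binary families, and the transformed count for the gaussian family.
.build_frame <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c("genotype", "block")
  if (!all(need %in% names(data))) {
    stop("data must contain columns 'genotype' and 'block'", call. = FALSE)
  }
  if ("year" %in% names(data) && length(unique(data$year)) > 1) {
    stop("data span several years; fit each year separately ",
         "(combined across-year models are out of scope)", call. = FALSE)
  }
  binaryfam <- spec$family %in% c("binary_logit", "binary_probit")
  if (binaryfam) {
    if (!"success" %in% names(data)) {
      stop("binary families require a 0/1 'success' column; see binarize_counts()",
           call. = FALSE)
    }
    y <- as.numeric(data$success)
    if (!all(y %in% c(0, 1))) stop("'success' must be 0/1", call. = FALSE)
  } else {
    if (!"seed_count" %in% names(data)) {
      stop("data must contain a 'seed_count' column", call. = FALSE)
    }
    y <- as.numeric(data$seed_count)
    if (spec$family == "gaussian") y <- count_transform(y, spec$transform)
  }
  gl <- sort(unique(as.character(data$genotype)))
  bl <- sort(unique(as.character(data$block)))
  gi <- match(as.character(data$genotype), gl)
  bi <- match(as.character(data$block), bl)
  plot_key <- paste(gi, bi, sep = ":")
  pl <- unique(plot_key)
  pli <- match(plot_key, pl)
  list(y = y, n = length(y), gi = gi, G = length(gl), glabels = gl,
       bi = bi, J = length(bl), blabels = bl,
       pli = pli, P = length(pl),
       block_of_plot = bi[match(pl, plot_key)],
       counts_per_geno = tabulate(gi, length(gl)),
       spec = spec, cache = new.env(parent = emptyenv()))
}

## parameter vector layout; returns named start values and box bounds
.par_layout <- function(fr) {
  sp <- fr$spec
  nm <- paste0("alpha.", fr$glabels)
  lo <- rep(if (sp$family %in% c("binary_logit", "binary_probit")) -12 else -10,
            fr$G)
  hi <- rep(12, fr$G)
  if (sp$family == "gaussian") { lo[] <- -1e3; hi[] <- 1e3 }
  if (sp$inflation == "single") {
    nm <- c(nm, "zi.overall"); lo <- c(lo, -9); hi <- c(hi, 9)
  } else if (sp$inflation == "per_genotype") {
    nm <- c(nm, paste0("zi.", fr$glabels)); lo <- c(lo, rep(-9, fr$G))
    hi <- c(hi, rep(9, fr$G))
  }
  if (sp$family %in% c("negbin", "zinb", "hnb")) {
    nm <- c(nm, "log_k"); lo <- c(lo, log(0.02)); hi <- c(hi, log(1e6))
  }
  if (sp$family == "gaussian") {
    nm <- c(nm, "log_sigma_e"); lo <- c(lo, log(1e-6)); hi <- c(hi, log(1e3))
  }
  if ("block" %in% sp$random) {
    nm <- c(nm, "log_sigma_b"); lo <- c(lo, log(1e-4)); hi <- c(hi, log(5))
  }
  if ("wholeplot" %in% sp$random) {
    nm <- c(nm, "log_sigma_ab"); lo <- c(lo, log(1e-4)); hi <- c(hi, log(5))
  }
  list(names = nm, lower = stats::setNames(lo, nm), upper = stats::setNames(hi, nm))
}

.par_extract <- function(fr, par) {
  sp <- fr$spec
  alpha <- par[paste0("alpha.", fr$glabels)]
  pi_g <- NULL
  if (sp$inflation == "single") {
    pi_g <- rep(stats::plogis(par[["zi.overall"]]), fr$G)
  } else if (sp$inflation == "per_genotype") {
    pi_g <- stats::plogis(par[paste0("zi.", fr$glabels)])
  }
  k <- if (sp$family %in% c("negbin", "zinb", "hnb")) exp(par[["log_k"]])
       else Inf
  list(alpha = unname(alpha), pi_g = unname(pi_g), k = k,
       sigma_e = if (sp$family == "gaussian") exp(par[["log_sigma_e"]]) else NULL,
       sigma_b = if ("block" %in% sp$random) exp(par[["log_sigma_b"]]) else 0,
       sigma_ab = if ("wholeplot" %in% sp$random) exp(par[["log_sigma_ab"]]) else 0)
}

## per-observation conditional log-likelihood as a function of the random
## offset u (vector over observations); random effects enter the count/link
## linear predictor only
.make_ll_obs <- function(fr, ext) {
  sp <- fr$spec
  y <- fr$y
  eta0 <- ext$alpha[fr$gi]
  switch(sp$family,
    gaussian = function(u) stats::dnorm(y, eta0 + u, ext$sigma_e, log = TRUE),
    poisson = function(u) {
      stats::dpois(y, exp(pmin(pmax(eta0 + u, -30), 30)), log = TRUE)
    },
    negbin = function(u) {
      stats::dnbinom(y, size = ext$k, mu = exp(pmin(pmax(eta0 + u, -30), 30)),
                     log = TRUE)
    },
    binary_logit = function(u) {
      eta <- eta0 + u
      y * stats::plogis(eta, log.p = TRUE) + (1 - y) * stats::plogis(-eta, log.p = TRUE)
    },
    binary_probit = function(u) {
      eta <- eta0 + u
      y * stats::pnorm(eta, log.p = TRUE) + (1 - y) * stats::pnorm(-eta, log.p = TRUE)
    },
    zinb = , hnb = {
      pi_obs <- ext$pi_g[fr$gi]
      kind <- if (sp$family == "zinb") "zero_inflated" else "hurdle"
      function(u) {
        mixture_pmf(y, pi = pi_obs, mu = exp(pmin(pmax(eta0 + u, -30), 30)),
                    size = ext$k, kind = kind, log = TRUE)
      }
    })
}

## ---- 1-D integration machinery ------------------------------------------

.gh_cache <- new.env(parent = emptyenv())
.gh_nodes <- function(Q) {
  key <- as.character(Q)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(Q)
  .gh_cache[[key]]
}

## Analytic first and second derivatives of the per-observation conditional
## log-likelihood with respect to the random offset u (which enters the
## linear predictor additively). Returns function(u_obs) -> list(g, H).
.make_ll_deriv <- function(fr, ext) {
  sp <- fr$spec
  y <- fr$y
  eta0 <- ext$alpha[fr$gi]
  k <- ext$k
  switch(sp$family,
    gaussian = function(u) {
      list(g = (y - eta0 - u) / ext$sigma_e^2,
           H = rep(-1 / ext$sigma_e^2, fr$n))
    },
    poisson = function(u) {
      mu <- exp(pmin(pmax(eta0 + u, -30), 30))
      list(g = y - mu, H = -mu)
    },
    negbin = function(u) {
      mu <- exp(pmin(pmax(eta0 + u, -30), 30))
      list(g = y - (y + k) * mu / (k + mu),
           H = -(y + k) * k * mu / (k + mu)^2)
    },
    binary_logit = function(u) {
      p <- stats::plogis(eta0 + u)
      list(g = y - p, H = -p * (1 - p))
    },
    binary_probit = function(u) {
      eta <- pmin(pmax(eta0 + u, -30), 30)
      phi <- stats::dnorm(eta)
      m1 <- phi / pmax(stats::pnorm(eta), 1e-300)
      m0 <- phi / pmax(stats::pnorm(-eta), 1e-300)
      g <- ifelse(y == 1, m1, -m0)
      H <- ifelse(y == 1, -m1 * (eta + m1), m0 * (eta - m0))
      list(g = g, H = pmin(H, -1e-12))
    },
    zinb = , hnb = {
      p_obs <- ext$pi_g[fr$gi]
      z <- y == 0
      function(u) {
        mu <- exp(pmin(pmax(eta0 + u, -30), 30))
        t1 <- -k * mu / (k + mu)            # d log f0 / d eta
        dt1 <- -k^2 * mu / (k + mu)^2       # d t1 / d eta
        gNB <- y - (y + k) * mu / (k + mu)
        HNB <- -(y + k) * k * mu / (k + mu)^2
        f0 <- exp(k * (log(k) - log(k + mu)))
        g <- gNB; H <- HNB
        if (sp$family == "zinb") {
          A <- p_obs + (1 - p_obs) * f0
          r <- (1 - p_obs) * f0 / A
          g[z] <- (r * t1)[z]
          H[z] <- (r * t1^2 * (1 - r) + r * dt1)[z]
        } else {
          q <- f0 / pmax(1 - f0, 1e-300)
          g[!z] <- (gNB + q * t1)[!z]
          H[!z] <- (HNB + q * (1 + q) * t1^2 + q * dt1)[!z]
          g[z] <- 0; H[z] <- 0
        }
        list(g = g, H = H)
      }
    })
}

## per-group sums respecting empty groups
.grp_sum <- function(x, grp, M) {
  v <- rowsum(x, grp, reorder = TRUE)[, 1]
  out <- numeric(M)
  out[sort(unique(grp))] <- v
  out
}

## Vectorized Newton ascent for the per-group posterior modes of
## h_j(u) = fgrp_j(u) + log phi(u; 0, sigma). `dgrp` returns the per-group
## summed analytic first/second conditional derivatives; when NULL, central
## differences of fgrp are used. `u0` is a warm start.
.newton_modes <- function(fgrp, M, sigma, dgrp = NULL, u0 = NULL,
                          h = 1e-4, maxit = 60L) {
  u <- if (is.null(u0) || length(u0) != M) numeric(M) else u0
  curv <- rep(-1 / sigma^2, M)
  for (it in seq_len(maxit)) {
    if (is.null(dgrp)) {
      f0 <- fgrp(u); fp <- fgrp(u + h); fm <- fgrp(u - h)
      grad <- (fp - fm) / (2 * h) - u / sigma^2
      curv <- pmin((fp - 2 * f0 + fm) / h^2 - 1 / sigma^2, -1e-10)
    } else {
      d <- dgrp(u)
      grad <- d$g - u / sigma^2
      curv <- pmin(d$H - 1 / sigma^2, -1e-10)
    }
    step <- grad / curv
    step <- sign(step) * pmin(abs(step), 2 + 3 * sigma)  # trust region
    u <- u - step
    if (max(abs(step)) < 1e-9) break
  }
  list(u = u, curv = curv)
}

## log of integral_u exp(fgrp_j(u)) phi(u; 0, sigma) du for each group j.
## method: "laplace", "agq" (adaptive, Q nodes), "gh" (non-adaptive dense).
.integrate_1d <- function(fgrp, M, sigma, method, Q, dgrp = NULL, u0 = NULL) {
  if (sigma < 1e-8) return(fgrp(numeric(M)))
  if (method == "gh") {
    gh <- .gh_nodes(Q)
    A <- vapply(seq_len(Q), function(q) fgrp(rep(sqrt(2) * sigma * gh$x[q], M)),
                numeric(M))
    A <- matrix(A, nrow = M) + rep(log(gh$w), each = M)
    mx <- apply(A, 1, max)
    return(mx + log(rowSums(exp(A - mx))) - 0.5 * log(pi))
  }
  md <- .newton_modes(fgrp, M, sigma, dgrp = dgrp, u0 = u0)
  hval <- function(u) fgrp(u) + stats::dnorm(u, 0, sigma, log = TRUE)
  out <- if (method == "laplace") {
    hval(md$u) + 0.5 * log(2 * pi) - 0.5 * log(-md$curv)
  } else {  # adaptive Gauss-Hermite centered at the mode
    gh <- .gh_nodes(Q)
    s <- 1 / sqrt(-md$curv)
    A <- vapply(seq_len(Q),
                function(q) hval(md$u + sqrt(2) * s * gh$x[q]) + gh$x[q]^2,
                numeric(M))
    A <- matrix(A, nrow = M) + rep(log(gh$w), each = M)
    mx <- apply(A, 1, max)
    mx + log(rowSums(exp(A - mx))) + log(sqrt(2) * s)
  }
  attr(out, "modes") <- md$u
  out
}

## ---- marginal log-likelihood --------------------------------------------

.eng_method <- function(spec, method = NULL) {
  if (!is.null(method)) return(method)
  switch(spec$estimation, REML_normal = "reml", ML_laplace = "laplace",
         ML_agq = "agq")
}

.eng_loglik <- function(fr, par, method, Q) {
  ext <- .par_extract(fr, par)
  ll_obs <- .make_ll_obs(fr, ext)
  has_b <- ext$sigma_b > 1e-8
  has_w <- ext$sigma_ab > 1e-8
  if (!has_b && !has_w) return(sum(ll_obs(numeric(fr$n))))
  dv_obs <- .make_ll_deriv(fr, ext)
  cache <- fr$cache
  if (xor(has_b, has_w)) {
    grp <- if (has_b) fr$bi else fr$pli
    M <- if (has_b) fr$J else fr$P
    sigma <- if (has_b) ext$sigma_b else ext$sigma_ab
    fgrp <- function(u) .grp_sum(ll_obs(u[grp]), grp, M)
    dgrp <- function(u) {
      d <- dv_obs(u[grp])
      list(g = .grp_sum(d$g, grp, M), H = .grp_sum(d$H, grp, M))
    }
    vals <- .integrate_1d(fgrp, M, sigma, method, Q, dgrp = dgrp,
                          u0 = cache$u_single)
    cache$u_single <- attr(vals, "modes")
    return(sum(vals))
  }
  # nested: outer block integral, inner whole-plot integrals per plot.
  # Inner modes are warm-started from the previous inner solution.
  inner_vals <- function(b_by_block, cache_key = NULL) {
    off <- b_by_block[fr$block_of_plot]          # per plot
    fplots <- function(w) .grp_sum(ll_obs(off[fr$pli] + w[fr$pli]), fr$pli, fr$P)
    dplots <- function(w) {
      d <- dv_obs(off[fr$pli] + w[fr$pli])
      list(g = .grp_sum(d$g, fr$pli, fr$P), H = .grp_sum(d$H, fr$pli, fr$P))
    }
    vals <- .integrate_1d(fplots, fr$P, ext$sigma_ab, method, Q,
                          dgrp = dplots, u0 = cache$w_inner)
    if (!is.null(cache_key)) cache$w_inner <- attr(vals, "modes")
    as.numeric(vals)
  }
  fblocks <- function(b) .grp_sum(inner_vals(b, "w"), fr$block_of_plot, fr$J)
  vals <- .integrate_1d(fblocks, fr$J, ext$sigma_b, method, Q,
                        u0 = cache$b_outer)
  cache$b_outer <- attr(vals, "modes")
  sum(vals)
}

## ---- closed-form Gaussian marginal likelihoods ---------------------------

.gaussian_V <- function(fr, ext) {
  V <- diag(ext$sigma_e^2, fr$n)
  if (ext$sigma_b > 0) {
    Zb <- outer(fr$bi, seq_len(fr$J), `==`) * 1
    V <- V + ext$sigma_b^2 * tcrossprod(Zb)
  }
  if (ext$sigma_ab > 0) {
    Zw <- outer(fr$pli, seq_len(fr$P), `==`) * 1
    V <- V + ext$sigma_ab^2 * tcrossprod(Zw)
  }
  V
}

## Gaussian LMM marginal log-likelihood via the dense marginal covariance.
## With profile = FALSE the alpha values in `par` are used as given (exact
## ML density at those parameters); with profile = TRUE alpha is replaced by
## its GLS estimate, and reml = TRUE adds the REML adjustment.
.gaussian_loglik <- function(fr, par, reml = FALSE, profile = reml,
                             return_beta = FALSE) {
  ext <- .par_extract(fr, par)
  if (ext$sigma_b <= 0 && ext$sigma_ab <= 0) {
    # no variance components: V = sigma_e^2 I, closed scalar forms
    s2 <- ext$sigma_e^2
    ybar <- as.numeric(tapply(fr$y, fr$gi, mean))
    beta <- if (profile || return_beta) ybar else ext$alpha
    rss <- sum((fr$y - beta[fr$gi])^2)
    ll <- -0.5 * (fr$n * log(2 * pi * s2) + rss / s2)
    ng <- tabulate(fr$gi, fr$G)
    if (reml) ll <- ll + 0.5 * fr$G * log(2 * pi) - 0.5 * sum(log(ng / s2))
    if (return_beta) {
      return(list(loglik = ll, beta = beta, vcov_beta = diag(s2 / ng, fr$G)))
    }
    return(ll)
  }
  X <- outer(fr$gi, seq_len(fr$G), `==`) * 1
  V <- .gaussian_V(fr, ext)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- if (profile || return_beta) {
    Vi_y <- backsolve(ch, forwardsolve(t(ch), fr$y))
    solve(XtViX, crossprod(X, Vi_y))
  } else {
    ext$alpha
  }
  r <- fr$y - drop(X %*% beta)
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  ldV <- 2 * sum(log(diag(ch)))
  quad <- drop(crossprod(r, Vi_r))
  ll <- -0.5 * (ldV + quad + fr$n * log(2 * pi))
  if (reml) {
    ll <- ll + 0.5 * fr$G * log(2 * pi) -
      0.5 * as.numeric(determinant(XtViX)$modulus)
  }
  if (return_beta) {
    list(loglik = as.numeric(ll), beta = as.numeric(beta),
         vcov_beta = solve(XtViX))
  } else {
    as.numeric(ll)
  }
}

#' Marginal log-likelihood with random effects integrated out
#'
#' Evaluates the marginal log-likelihood of a model at given parameter
#' values, integrating the normal block and whole-plot effects out of the
#' conditional likelihood. Three approximations are available: the Laplace
#' approximation (one mode search per random-effect level and a second-order
#' expansion), adaptive Gauss-Hermite quadrature (nodes centered and scaled
#' at each level's mode), and dense non-adaptive Gauss-Hermite quadrature
#' (useful as a brute-force reference on small data). When both random terms
#' are present the block integral is evaluated by nesting the whole-plot
#' integrals inside each outer evaluation; when all variance components are
#' zero the marginal reduces exactly to the sum of conditional log-densities.
#' For the Gaussian family a closed form via the dense marginal covariance
#' is also available (`method = "exact"`), as is the REML criterion
#' (`method = "reml"`).
#'
#' @param spec A [model_spec()].
#' @param params Named parameter vector: `alpha.<genotype>` fixed effects on
#'   the link scale, `zi.*` inflation parameters on the logit scale,
#'   `log_k`, `log_sigma_e`, `log_sigma_b`, `log_sigma_ab` as applicable.
#' @param data Seed-count data (with a `success` column for binary families).
#' @param method `NULL` (derive from `spec$estimation`), `"laplace"`,
#'   `"agq"`, `"gh"`, `"exact"`, or `"reml"`.
#' @param nodes Quadrature nodes for `"agq"`/`"gh"`.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(spec, params, data, method = NULL, nodes = NULL) {
  fr <- .build_frame(data, spec)
  lay <- .par_layout(fr)
  if (!all(lay$names %in% names(params))) {
    stop("params must contain: ", paste(setdiff(lay$names, names(params)),
                                        collapse = ", "), call. = FALSE)
  }
  params <- params[lay$names]
  method <- .eng_method(spec, method)
  Q <- if (is.null(nodes)) spec$nodes else as.integer(nodes)
  if (method %in% c("exact", "reml")) {
    if (spec$family != "gaussian") {
      stop("closed-form evaluation applies to the gaussian family only",
           call. = FALSE)
    }
    return(.gaussian_loglik(fr, params, reml = method == "reml"))
  }
  .eng_loglik(fr, params, method, Q)
}
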