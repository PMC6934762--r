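## ---- starting values -----------------------------------------------------

.start_values <- function(fr) {
  sp <- fr$spec
  lay <- .par_layout(fr)
  st <- stats::setNames(numeric(length(lay$names)), lay$names)
  ybar <- as.numeric(tapply(fr$y, fr$gi, mean))
  p0 <- as.numeric(tapply(fr$y == 0, fr$gi, mean))
  posmean <- vapply(seq_len(fr$G), function(g) {
    v <- fr$y[fr$gi == g & fr$y > 0]
    if (length(v)) mean(v) else max(mean(fr$y[fr$y > 0]), 0.5)
  }, numeric(1))
  m <- mean(fr$y); v <- stats::var(fr$y)
  k0 <- if (is.finite(v) && v > m) min(max(m^2 / (v - m), 0.05), 50) else 5
  anm <- paste0("alpha.", fr$glabels)
  if (sp$family == "gaussian") {
    st[anm] <- ybar
    resid <- fr$y - ybar[fr$gi]
    st["log_sigma_e"] <- log(max(stats::sd(resid), 1e-3))
  } else if (sp$family %in% c("binary_logit", "binary_probit")) {
    pr <- pmin(pmax(ybar, 0.03), 0.97)
    st[anm] <- if (sp$family == "binary_logit") stats::qlogis(pr) else stats::qnorm(pr)
  } else if (sp$family %in% c("poisson", "negbin")) {
    st[anm] <- log(pmax(ybar, 0.05))
    if (sp$family == "negbin") st["log_k"] <- log(k0)
  } else {  # mixture families
    f0 <- exp(.log_p0(pmax(posmean, 0.5), k0))
    pi0 <- if (sp$family == "hnb") p0 else pmax((p0 - f0) / pmax(1 - f0, 0.05), 0)
    pi0 <- pmin(pmax(pi0, 0.03), 0.95)
    lam0 <- if (sp$family == "hnb") {
      posmean * (1 - exp(.log_p0(posmean, k0)))  # undo truncation roughly
    } else {
      pmax(ybar / (1 - pi0), 0.05)
    }
    st[anm] <- log(pmax(lam0, 0.05))
    st["log_k"] <- log(k0)
    if (sp$inflation == "single") {
      st["zi.overall"] <- stats::qlogis(min(max(mean(pi0), 0.03), 0.95))
    } else {
      st[paste0("zi.", fr$glabels)] <- stats::qlogis(pi0)
    }
  }
  if ("log_sigma_b" %in% lay$names) st["log_sigma_b"] <- log(0.2)
  if ("log_sigma_ab" %in% lay$names) st["log_sigma_ab"] <- log(0.3)
  st
}

## ---- analytic score for models without random effects --------------------

## Gradient of the (conditional) log-likelihood in the transformed parameter
## space, for the families fitted without random terms. Returns the gradient
## of the NEGATIVE log-likelihood for the optimizer.
.score_noRE <- function(fr, par) {
  sp <- fr$spec
  ext <- .par_extract(fr, par)
  y <- fr$y
  eta <- pmin(pmax(ext$alpha[fr$gi], -30), 30)
  k <- ext$k
  d_eta <- d_psi <- NULL
  d_logk <- 0
  if (sp$family == "poisson") {
    d_eta <- y - exp(eta)
  } else if (sp$family == "binary_logit") {
    d_eta <- y - stats::plogis(eta)
  } else if (sp$family == "binary_probit") {
    p <- stats::pnorm(eta)
    d_eta <- stats::dnorm(eta) * (y - p) / pmax(p * (1 - p), 1e-300)
  } else {
    mu <- exp(eta)
    nb_deta <- y - (y + k) * mu / (k + mu)
    nb_dk <- digamma(y + k) - digamma(k) + log(k) + 1 - log(k + mu) -
      (y + k) / (k + mu)
    lf0 <- k * (log(k) - log(k + mu))
    f0 <- exp(lf0)
    dlf0_deta <- -k * mu / (k + mu)
    dlf0_dk <- log(k) + 1 - log(k + mu) - k / (k + mu)
    if (sp$family == "negbin") {
      d_eta <- nb_deta
      d_logk <- sum(nb_dk) * k
    } else {
      p <- ext$pi_g[fr$gi]
      z <- y == 0
      d_eta <- d_psi <- dk_obs <- numeric(fr$n)
      if (sp$family == "zinb") {
        A <- p + (1 - p) * f0
        d_psi[z] <- (p * (1 - p) * (1 - f0) / A)[z]
        d_psi[!z] <- -p[!z]
        d_eta[z] <- ((1 - p) * f0 * dlf0_deta / A)[z]
        d_eta[!z] <- nb_deta[!z]
        dk_obs[z] <- ((1 - p) * f0 * dlf0_dk / A)[z]
        dk_obs[!z] <- nb_dk[!z]
      } else {  # hurdle
        d_psi[z] <- (1 - p)[z]
        d_psi[!z] <- -p[!z]
        r <- f0 / pmax(1 - f0, 1e-300)
        d_eta[!z] <- nb_deta[!z] + (r * dlf0_deta)[!z]
        dk_obs[!z] <- nb_dk[!z] + (r * dlf0_dk)[!z]
      }
      d_logk <- sum(dk_obs) * k
    }
  }
  g <- stats::setNames(numeric(length(par)), names(par))
  g[paste0("alpha.", fr$glabels)] <-
    as.numeric(rowsum(d_eta, fr$gi, reorder = TRUE))
  if (!is.null(d_psi)) {
    if (sp$inflation == "single") {
      g["zi.overall"] <- sum(d_psi)
    } else {
      g[paste0("zi.", fr$glabels)] <-
        as.numeric(rowsum(d_psi, fr$gi, reorder = TRUE))
    }
  }
  if ("log_k" %in% names(par)) g["log_k"] <- d_logk
  -g
}

## ---- fitting -------------------------------------------------------------

#' Fit a sterility mixed model by marginal maximum likelihood
#'
#' Maximizes the marginal likelihood of [marginal_loglik()] (or the REML
#' criterion for the Gaussian family) over the model's parameters, using
#' bounded quasi-Newton (`L-BFGS-B`) on a transformed parameter space: fixed
#' effects on the link scale, inflation probabilities on the logit scale,
#' and dispersion/variance components on the log scale. For the mixture
#' families a small set of deterministic restarts (jittered inflation and
#' dispersion starts) guards against local optima. Non-convergence is never
#' an exception: the returned fit carries `converged = FALSE`. Parameters at
#' the search bounds or with unusable curvature are flagged non-estimable.
#'
#' @param data Seed-count data (binary families additionally need a
#'   `success` column; see [binarize_counts()]).
#' @param spec A [model_spec()].
#' @param start Optional named starting values overriding the defaults.
#' @param restarts Maximum number of additional deterministic restarts for
#'   mixture families.
#' @param control Passed to [stats::optim()] (sensible defaults supplied).
#' @return An object of class `"sterility_fit"`: estimates `params`,
#'   covariance `vcov` (inverse observed information on the transformed
#'   scale), `loglik`, `n_params`, `n_obs`, `converged`, `gradient_norm`,
#'   `hessian_condition`, and `non_estimable` flags.
#' @export
fit_sterility_model <- function(data, spec, start = NULL, restarts = 3L,
                                control = list()) {
  fr <- .build_frame(data, spec)
  lay <- .par_layout(fr)
  if (any(fr$counts_per_geno < 2)) {
    warning("fewer than 2 observations for genotype(s): ",
            paste(fr$glabels[fr$counts_per_geno < 2], collapse = ", "),
            call. = FALSE)
  }
  method <- .eng_method(spec)
  if (method == "reml") {
    return(.fit_reml_gaussian(fr, lay))
  }
  objective <- function(p) {
    names(p) <- lay$names
    ll <- tryCatch(.eng_loglik(fr, p, method, spec$nodes),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }
  st <- .start_values(fr)
  if (!is.null(start)) st[names(start)] <- start
  st <- pmin(pmax(st, lay$lower + 1e-6), lay$upper - 1e-6)
  ctl <- utils::modifyList(list(maxit = 600L, factr = 1e7), control)
  use_score <- length(spec$random) == 0 && spec$family != "gaussian"
  gradient <- if (use_score) {
    function(p) { names(p) <- lay$names; .score_noRE(fr, p) }
  } else NULL
  run <- function(s) {
    tryCatch(stats::optim(s, objective, gr = gradient, method = "L-BFGS-B",
                          lower = lay$lower, upper = lay$upper, control = ctl),
             error = function(e) list(par = s, value = objective(s),
                                      convergence = 99L, message = conditionMessage(e)))
  }
  opt <- run(st)
  if (spec$family %in% c("zinb", "hnb") &&
      (opt$convergence != 0 || restarts > 0)) {
    # deterministic jitters of the mixture starts; keep the best optimum
    jitters <- list(c(zi = 1, k = 0), c(zi = -1, k = 0.7), c(zi = 0.5, k = -0.7))
    for (j in seq_len(min(restarts, length(jitters)))) {
      if (opt$convergence == 0 && j > 1) break
      s2 <- st
      zi_idx <- grep("^zi\\.", names(s2))
      s2[zi_idx] <- s2[zi_idx] + jitters[[j]]["zi"]
      s2["log_k"] <- s2["log_k"] + jitters[[j]]["k"]
      s2 <- pmin(pmax(s2, lay$lower + 1e-6), lay$upper - 1e-6)
      o2 <- run(s2)
      if (o2$value < opt$value - 1e-6) opt <- o2
    }
  }
  par <- stats::setNames(opt$par, lay$names)
  # gradient at the optimum (analytic when available, else central diff)
  gr <- if (use_score) {
    gradient(par)
  } else {
    vapply(seq_along(par), function(i) {
      h <- 1e-5 * max(abs(par[i]), 1)
      e <- numeric(length(par)); e[i] <- h
      (objective(par + e) - objective(par - e)) / (2 * h)
    }, numeric(1))
  }
  at_bound <- par <= lay$lower + 1e-4 | par >= lay$upper - 1e-4
  H <- tryCatch(stats::optimHess(par, objective, gr = gradient),
                error = function(e) NULL)
  vc <- NULL; kappa_h <- NA_real_; bad_curv <- rep(FALSE, length(par))
  if (!is.null(H)) {
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    kappa_h <- max(ev$values) / max(min(ev$values), 1e-300)
    pos <- ev$values > max(ev$values) * 1e-10
    vc <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    dimnames(vc) <- list(lay$names, lay$names)
    bad_curv <- diag(vc) <= 0 | !is.finite(diag(vc))
  }
  non_est <- lay$names[at_bound | bad_curv]
  # boundary flags on variance/dispersion transforms are expected, keep the
  # flags on effects and inflation parameters prominent
  # scale-aware gradient check: the score of a well-converged ML fit is tiny
  # relative to the log-likelihood magnitude
  converged <- opt$convergence == 0 &&
    max(abs(gr)) < max(0.05, 1e-4 * abs(opt$value))
  structure(list(params = par, vcov = vc, loglik = -opt$value,
                 n_params = length(par), n_obs = fr$n,
                 converged = converged, gradient_norm = max(abs(gr)),
                 hessian_condition = kappa_h,
                 non_estimable = non_est,
                 spec = spec, frame = fr,
                 optim_convergence = opt$convergence,
                 message = opt$message %||% ""),
            class = "sterility_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## REML fit of the (transformed-)Gaussian LMM: the genotype effects are
## profiled out of the REML criterion, so the search runs over the variance
## parameters only; alpha is then restored at its GLS estimate with
## covariance (X' V^-1 X)^-1, and the variance-parameter covariance comes
## from the observed information of the REML criterion (cross-covariances
## between the two sets are zero to this order).
.fit_reml_gaussian <- function(fr, lay) {
  vnames <- intersect(c("log_sigma_e", "log_sigma_b", "log_sigma_ab"),
                      lay$names)
  st_all <- .start_values(fr)
  obj <- function(v) {
    p <- st_all
    p[vnames] <- v
    ll <- .gaussian_loglik(fr, p, reml = TRUE)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(st_all[vnames], obj, method = "L-BFGS-B",
                      lower = lay$lower[vnames], upper = lay$upper[vnames],
                      control = list(maxit = 500L, factr = 1e7))
  par <- st_all
  par[vnames] <- opt$par
  gls <- .gaussian_loglik(fr, par, reml = TRUE, return_beta = TRUE)
  anm <- paste0("alpha.", fr$glabels)
  par[anm] <- gls$beta
  vc <- matrix(0, length(lay$names), length(lay$names),
               dimnames = list(lay$names, lay$names))
  vc[anm, anm] <- gls$vcov_beta
  Hv <- tryCatch(stats::optimHess(opt$par, obj), error = function(e) NULL)
  kappa_h <- NA_real_
  if (!is.null(Hv)) {
    ev <- eigen((Hv + t(Hv)) / 2, symmetric = TRUE)
    kappa_h <- max(ev$values) / max(min(ev$values), 1e-300)
    pos <- ev$values > max(ev$values) * 1e-10
    vc[vnames, vnames] <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  }
  at_bound <- vnames[opt$par <= lay$lower[vnames] + 1e-4 |
                       opt$par >= lay$upper[vnames] - 1e-4]
  structure(list(params = par, vcov = vc, loglik = gls$loglik,
                 n_params = length(par), n_obs = fr$n,
                 converged = opt$convergence == 0, gradient_norm = NA_real_,
                 hessian_condition = kappa_h, non_estimable = at_bound,
                 spec = fr$spec, frame = fr,
                 optim_convergence = opt$convergence,
                 message = opt$message %||% ""),
            class = "sterility_fit")
}

#' @export
print.sterility_fit <- function(x, ...) {
  cat(sprintf("Sterility %s model (%s): %d obs, %d parameters\n",
              x$spec$family, x$spec$estimation, x$n_obs, x$n_params))
  cat(sprintf("  logLik = %.3f; converged: %s (|grad| = %.2e)\n",
              x$loglik, x$converged, x$gradient_norm))
  if (length(x$non_estimable)) {
    cat("  non-estimable/boundary: ", paste(x$non_estimable, collapse = ", "),
        "\n", sep = "")
  }
  ic <- information_criteria(x)
  cat(sprintf("  AICc = %.2f, BIC = %.2f, -2LL = %.2f\n",
              ic[["AICc"]], ic[["BIC"]], ic[["minus2LL"]]))
  invisible(x)
}

#' @export
logLik.sterility_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
coef.sterility_fit <- function(object, ...) object$params

#' @export
vcov.sterility_fit <- function(object, ...) object$vcov

#' Information criteria of a fitted model
#'
#' Small-sample corrected AIC, `AICc = -2l + 2p + 2p(p+1)/(n-p-1)`, BIC
#' `-2l + p log(n)`, and `-2l`, with `p` the number of estimated parameters
#' and `n` the number of observations (bagged heads, not experimental
#' units). AICc is reported missing with a warning when `n <= p + 1`.
#'
#' @param fit A `sterility_fit`.
#' @return Named numeric vector `c(AICc, BIC, minus2LL)`.
#' @export
information_criteria <- function(fit) {
  l <- fit$loglik; p <- fit$n_params; n <- fit$n_obs
  aicc <- if (n > p + 1) {
    -2 * l + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  } else {
    warning("AICc undefined: n <= p + 1", call. = FALSE)
    NA_real_
  }
  c(AICc = aicc, BIC = -2 * l + p * log(n), minus2LL = -2 * l)
}

## model-implied mean and variance function per observation, conditional on
## random effects at their EB modes (zero when no random terms)
.fitted_mean_var <- function(fit) {
  fr <- fit$frame
  ext <- .par_extract(fr, fit$params)
  u <- .eb_modes_obs(fit)
  eta <- ext$alpha[fr$gi] + u
  fam <- fit$spec$family
  if (fam == "poisson") {
    mu <- exp(eta); list(mean = mu, var = mu)
  } else if (fam == "negbin") {
    mu <- exp(eta); list(mean = mu, var = mu + mu^2 / ext$k)
  } else if (fam %in% c("zinb", "hnb")) {
    lam <- exp(eta); p <- ext$pi_g[fr$gi]
    kind <- if (fam == "zinb") "zero_inflated" else "hurdle"
    m <- mixture_mean(p, lam, ext$k, kind)
    if (fam == "zinb") {
      ey2 <- (1 - p) * (lam + lam^2 / ext$k + lam^2)
    } else {
      f0 <- exp(.log_p0(lam, ext$k))
      ey2 <- (1 - p) * (lam + lam^2 / ext$k + lam^2 - 0) / (1 - f0)
    }
    list(mean = m, var = pmax(ey2 - m^2, 0))
  } else {
    stop("overdispersion diagnostics apply to count families", call. = FALSE)
  }
}

## empirical Bayes modes of the summed random offset, per observation
.eb_modes_obs <- function(fit) {
  fr <- fit$frame
  ext <- .par_extract(fr, fit$params)
  u <- numeric(fr$n)
  ll_obs <- .make_ll_obs(fr, ext)
  if (ext$sigma_b > 1e-8 && ext$sigma_ab <= 1e-8) {
    md <- .newton_modes(function(ub) {
      v <- rowsum(ll_obs(ub[fr$bi]), fr$bi, reorder = TRUE)[, 1]
      out <- numeric(fr$J); out[sort(unique(fr$bi))] <- v; out
    }, fr$J, ext$sigma_b)
    u <- md$u[fr$bi]
  } else if (ext$sigma_b > 1e-8 || ext$sigma_ab > 1e-8) {
    # whole-plot (possibly plus block): mode of the total plot-level offset
    sig <- sqrt(ext$sigma_b^2 + ext$sigma_ab^2)
    md <- .newton_modes(function(up) {
      v <- rowsum(ll_obs(up[fr$pli]), fr$pli, reorder = TRUE)[, 1]
      out <- numeric(fr$P); out[sort(unique(fr$pli))] <- v; out
    }, fr$P, sig)
    u <- md$u[fr$pli]
  }
  u
}

#' Pearson chi-square overdispersion ratio
#'
#' `sum((y - mu)^2 / v(mu)) / (n - p)` with `v` the family variance
#' function, the standard check that a Poisson fit's variance assumption
#' holds (values near 1 are acceptable; large values indicate
#' overdispersion). Observations with a zero variance function are excluded
#' with a warning.
#'
#' @param fit A converged count-family `sterility_fit`.
#' @return The Pearson chi-square / d.f. ratio.
#' @export
pearson_overdispersion <- function(fit) {
  mv <- .fitted_mean_var(fit)
  y <- fit$frame$y
  ok <- mv$var > 0
  if (!all(ok)) {
    warning(sum(!ok), " observation(s) with zero variance function excluded",
            call. = FALSE)
  }
  sum((y[ok] - mv$mean[ok])^2 / mv$var[ok]) / (fit$n_obs - fit$n_params)
}

## Wald-type type III F test of equal genotype effects.
## Denominator df: "residual" (n - p, the large-sample Wald reference,
## default) or "containment" ((G-1)(J-1), the whole-plot stratum of the
## RCBD, which is markedly conservative for this test in simulation).
.type3_F <- function(fit, ddf_method = c("residual", "containment")) {
  ddf_method <- match.arg(ddf_method)
  fr <- fit$frame
  G <- fr$G
  if (G < 2) stop("at least 2 genotypes required", call. = FALSE)
  if (is.null(fit$vcov)) stop("no covariance available for the fit", call. = FALSE)
  anm <- paste0("alpha.", fr$glabels)
  a <- fit$params[anm]
  V <- fit$vcov[anm, anm, drop = FALSE]
  C <- cbind(diag(G - 1), -1)  # alpha_i - alpha_G
  M <- C %*% V %*% t(C)
  qrM <- qr(M)
  if (qrM$rank < G - 1) stop("singular contrast covariance", call. = FALSE)
  W <- drop(t(C %*% a) %*% solve(M, C %*% a))
  ndf <- G - 1
  ddf <- if (ddf_method == "containment" && fr$J >= 2) {
    (G - 1) * (fr$J - 1)
  } else {
    max(fit$n_obs - fit$n_params, 1)
  }
  Fstat <- W / ndf
  c(F = Fstat, ndf = ndf, ddf = ddf,
    p = stats::pf(Fstat, ndf, ddf, lower.tail = FALSE))
}
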