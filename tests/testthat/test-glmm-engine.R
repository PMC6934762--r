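test_that("model specs enforce family/inflation/transform consistency", {
  expect_error(model_spec("poisson", inflation = "single"), "zinb/hnb")
  expect_error(model_spec("zinb", inflation = "none"), "inflation")
  expect_error(model_spec("negbin", transform = "log_plus_one"), "gaussian")
  expect_error(model_spec("poisson", estimation = "REML_normal"), "REML")
  sp <- model_spec("hnb")
  expect_equal(sp$inflation, "per_genotype")
  expect_equal(sp$estimation, "ML_laplace")
  expect_equal(model_spec("binary_probit")$estimation, "ML_agq")
})

test_that("zero variance components collapse the marginal to the conditional sum", {
  d <- binarize_counts(toy_two_block(), 7)
  spec <- model_spec("binary_logit", random = "block")
  par <- c("alpha.A" = 0.4, "alpha.B" = -0.3, "log_sigma_b" = log(1e-10))
  eta <- ifelse(d$genotype == "A", 0.4, -0.3)
  cond <- sum(dbinom(d$success, 1, plogis(eta), log = TRUE))
  expect_equal(marginal_loglik(spec, par, d, method = "laplace"), cond)
  # Poisson family, both terms nominally present but at zero variance
  spec2 <- model_spec("poisson", random = c("block", "wholeplot"))
  par2 <- c("alpha.A" = 1, "alpha.B" = 2, "log_sigma_b" = log(1e-10),
            "log_sigma_ab" = log(1e-10))
  mu <- exp(ifelse(toy_two_block()$genotype == "A", 1, 2))
  expect_equal(marginal_loglik(spec2, par2, toy_two_block(), method = "laplace"),
               sum(dpois(toy_two_block()$seed_count, mu, log = TRUE)))
})

test_that("Laplace and AGQ agree with dense quadrature and direct integration", {
  d <- binarize_counts(toy_two_block(), 7)
  spec <- model_spec("binary_logit", random = "block")
  par <- c("alpha.A" = 0.6, "alpha.B" = -0.2, "log_sigma_b" = log(0.3))
  gh41 <- marginal_loglik(spec, par, d, method = "gh", nodes = 41)
  # fully independent oracle: adaptive numerical integration per block
  ora <- 0
  for (b in c("B1", "B2")) {
    db <- d[d$block == b, ]
    eta0 <- ifelse(db$genotype == "A", 0.6, -0.2)
    f <- function(u) vapply(u, function(ui) {
      p <- plogis(eta0 + ui)
      exp(sum(dbinom(db$success, 1, p, log = TRUE))) * dnorm(ui, 0, 0.3)
    }, numeric(1))
    ora <- ora + log(integrate(f, -6, 6, rel.tol = 1e-12)$value)
  }
  expect_equal(gh41, ora, tolerance = 1e-9)
  expect_lt(abs(marginal_loglik(spec, par, d, method = "laplace") - gh41), 1e-3)
  expect_lt(abs(marginal_loglik(spec, par, d, method = "agq", nodes = 15) - gh41),
            1e-9)
  # count family at sigma_b^2 = 0.25
  dc <- toy_two_block()
  spec2 <- model_spec("negbin", random = "block")
  par2 <- c("alpha.A" = 1.2, "alpha.B" = 1.6, "log_k" = log(1.5),
            "log_sigma_b" = log(0.25))
  gh2 <- marginal_loglik(spec2, par2, dc, method = "gh", nodes = 41)
  expect_lt(abs(marginal_loglik(spec2, par2, dc, method = "laplace") - gh2), 1e-3)
  expect_lt(abs(marginal_loglik(spec2, par2, dc, method = "agq", nodes = 15) - gh2),
            1e-8)
})

test_that("AGQ error against a 101-node reference decreases with node count", {
  d <- binarize_counts(toy_two_block(), 7)
  spec <- model_spec("binary_logit", random = "block")
  par <- c("alpha.A" = 0.6, "alpha.B" = -0.2, "log_sigma_b" = log(0.8))
  ref <- marginal_loglik(spec, par, d, method = "gh", nodes = 101)
  errs <- vapply(c(3, 5, 9, 21),
                 function(q) abs(marginal_loglik(spec, par, d, method = "agq",
                                                 nodes = q) - ref),
                 numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4], 1e-10)
})

test_that("Gaussian marginal likelihood matches the closed form and lme4 REML", {
  d <- toy_two_block()
  spec <- model_spec("gaussian", random = "block", estimation = "REML_normal")
  par <- c("alpha.A" = 2.1, "alpha.B" = 5.4, "log_sigma_e" = log(3),
           "log_sigma_b" = log(1.2))
  exact <- marginal_loglik(spec, par, d, method = "exact")
  lap <- marginal_loglik(spec, par, d, method = "laplace")
  expect_equal(lap, exact, tolerance = 1e-8)
  skip_if_not_installed("lme4")
  set.seed(2)
  cfg <- crossing_block_config(paste0("g", 1:4), pi = 0, lambda = c(3, 6, 9, 12),
                               dispersion = 5, n_blocks = 4, heads_per_plot = 6,
                               block_sd = 0.3, seed = 14)
  dd <- simulate_crossing_block(cfg)
  fit <- fit_sterility_model(dd, spec)
  lmm <- lme4::lmer(seed_count ~ 0 + genotype + (1 | block), data = dd,
                    REML = TRUE)
  expect_equal(fit$loglik, as.numeric(logLik(lmm)), tolerance = 1e-4)
  expect_equal(unname(sort(fit$params[1:4])),
               unname(sort(lme4::fixef(lmm))), tolerance = 1e-4)
})

test_that("likelihood is invariant to relabeling blocks and genotypes", {
  d <- toy_two_block()
  spec <- model_spec("negbin", random = "block")
  par <- c("alpha.A" = 1.2, "alpha.B" = 1.6, "log_k" = log(1.5),
           "log_sigma_b" = log(0.5))
  base <- marginal_loglik(spec, par, d, method = "agq", nodes = 11)
  d2 <- d
  d2$block <- c(B1 = "ZZ", B2 = "AA")[d2$block]
  d2$genotype <- c(A = "gen_x", B = "gen_a")[d2$genotype]
  par2 <- c("alpha.gen_x" = 1.2, "alpha.gen_a" = 1.6, "log_k" = log(1.5),
            "log_sigma_b" = log(0.5))
  expect_equal(marginal_loglik(spec, par2, d2, method = "agq", nodes = 11),
               base, tolerance = 1e-10)
})

test_that("fitted mixed models agree with independent implementations", {
  skip_if_not_installed("glmmTMB")
  set.seed(42)
  cfg <- crossing_block_config(paste0("g", 1:4), pi = c(0.2, 0.4, 0.5, 0.3),
                               lambda = c(3, 8, 15, 5), dispersion = 1,
                               n_blocks = 4, heads_per_plot = 25, seed = 5)
  dd <- simulate_crossing_block(cfg)
  fit <- fit_count_model(dd, "zinb", inflation = "per_genotype",
                         random = character(0))
  tmb <- suppressWarnings(glmmTMB::glmmTMB(
    seed_count ~ 0 + genotype, ziformula = ~ 0 + genotype,
    family = glmmTMB::nbinom2, data = dd))
  expect_equal(fit$loglik, as.numeric(logLik(tmb)), tolerance = 1e-4)
  expect_equal(max(abs(fit$params[1:4] - unname(glmmTMB::fixef(tmb)$cond))), 0,
               tolerance = 1e-3)
  # negative binomial with a block random intercept (Laplace vs TMB Laplace)
  cfgb <- crossing_block_config(paste0("g", 1:5), pi = 0,
                                lambda = c(2, 5, 9, 4, 7), dispersion = 1.5,
                                n_blocks = 4, heads_per_plot = 10,
                                block_sd = 0.4, seed = 11)
  db <- simulate_crossing_block(cfgb)
  fb <- fit_count_model(db, "negbin", random = "block")
  tmb2 <- glmmTMB::glmmTMB(seed_count ~ 0 + genotype + (1 | block),
                           family = glmmTMB::nbinom2, data = db)
  expect_equal(fb$loglik, as.numeric(logLik(tmb2)), tolerance = 1e-4)
  expect_equal(max(abs(fb$params[1:5] - unname(glmmTMB::fixef(tmb2)$cond))), 0,
               tolerance = 1e-3)
})

test_that("richer nested families never lose log-likelihood", {
  set.seed(31)
  d <- simulate_mixture_iid(31, 300, pi = 0.35, lambda = 7, k = 1)
  d$genotype <- rep(c("A", "B"), length.out = nrow(d))
  fits <- lapply(c("poisson", "negbin", "zinb"), function(f) {
    fit_count_model(d, f, inflation = if (f == "zinb") "single" else NULL,
                    random = character(0))
  })
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  expect_true(ll[2] >= ll[1] - 1e-6)  # NB nests Poisson (k -> Inf)
  expect_true(ll[3] >= ll[2] - 1e-4)  # ZINB nests NB (pi -> 0)
})

test_that("information criteria match their closed forms", {
  ic <- information_criteria(fake_fit(-100, 3, 20))
  expect_equal(unname(ic["AICc"]), 207.5)
  expect_equal(unname(ic["BIC"]), -2 * (-100) + 3 * log(20))
  expect_equal(unname(ic["minus2LL"]), 200)
  # the small-sample correction vanishes as n grows
  big <- information_criteria(fake_fit(-100, 3, 1e6))
  expect_lt(abs(big[["AICc"]] - (200 + 6)), 1e-4)
  expect_warning(information_criteria(fake_fit(-10, 5, 6)), "AICc undefined")
})

test_that("Pearson overdispersion diagnoses the Poisson variance assumption", {
  set.seed(5)
  d <- data.frame(genotype = "A", block = "B1",
                  head = paste0("H", 1:4000),
                  seed_count = rpois(4000, 5))
  f <- fit_count_model(d, "poisson", random = character(0))
  expect_lt(abs(pearson_overdispersion(f) - 1), 0.1)
  # NB(k = 1, lambda = 5) data under a Poisson fit: ratio ~ 1 + lambda/k = 6
  d$seed_count <- rnbinom(4000, size = 1, mu = 5)
  f2 <- fit_count_model(d, "poisson", random = character(0))
  expect_lt(abs(pearson_overdispersion(f2) - 6), 0.8)
  # a perfectly fitted mean gives ratio 0
  d3 <- data.frame(genotype = rep(c("A", "B"), each = 2), block = "B1",
                   head = paste0("H", 1:4), seed_count = c(3L, 3L, 8L, 8L))
  f3 <- fit_count_model(d3, "poisson", random = character(0))
  expect_equal(pearson_overdispersion(f3), 0, tolerance = 1e-6)
})

test_that("degenerate fits are flagged rather than raised", {
  d <- data.frame(genotype = rep(c("A", "B"), each = 10), block = "B1",
                  head = paste0("H", 1:20), seed_count = 0L)
  fit <- fit_count_model(d, "zinb", inflation = "single", random = character(0))
  expect_s3_class(fit, "sterility_fit")
  # all-zero response: lambda is unidentified, flags raised at the boundary
  expect_true(length(fit$non_estimable) > 0)
  # one observation per genotype: over-parameterized per-genotype mixture
  d2 <- data.frame(genotype = paste0("g", 1:6), block = "B1",
                   head = paste0("H", 1:6), seed_count = c(0L, 3L, 0L, 9L, 1L, 0L))
  expect_warning(
    fit2 <- fit_count_model(d2, "hnb", inflation = "per_genotype",
                            random = character(0)),
    "fewer than 2")
  expect_s3_class(fit2, "sterility_fit")
  expect_true(length(fit2$non_estimable) > 0 || !fit2$converged)
})

test_that("multi-year data are refused by the fitting frame", {
  d <- toy_two_block()
  d$year <- rep(c("2015", "2016"), length.out = nrow(d))
  expect_error(fit_count_model(d, "poisson"), "separately")
})
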