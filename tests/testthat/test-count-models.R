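test_that("log-link genotype means are exactly the exponentiated effects", {
  set.seed(12)
  cfg <- crossing_block_config(paste0("g", 1:3), pi = 0, lambda = c(2, 6, 14),
                               dispersion = 1.5, n_blocks = 2,
                               heads_per_plot = 30, seed = 12)
  d <- simulate_crossing_block(cfg)
  fit <- fit_count_model(d, "negbin", random = character(0))
  gm <- genotype_count_means(fit)
  anm <- paste0("alpha.", gm$genotype)
  expect_equal(gm$estimate, unname(exp(fit$params[anm])))
  # interval endpoints are order-preserved by the inverse link
  expect_true(all(gm$ci_low <= gm$estimate & gm$estimate <= gm$ci_high))
  # without dispersion the NB point estimate is the genotype sample mean
  ybar <- tapply(d$seed_count, d$genotype, mean)
  expect_equal(gm$estimate, as.numeric(ybar[gm$genotype]), tolerance = 1e-5)
})

test_that("hurdle fits reproduce the observed zero fraction exactly", {
  set.seed(13)
  cfg <- crossing_block_config(paste0("g", 1:4), pi = c(0.2, 0.35, 0.5, 0.65),
                               lambda = c(3, 6, 10, 18), dispersion = 1,
                               n_blocks = 2, heads_per_plot = 25,
                               process = "hurdle", seed = 13)
  d <- simulate_crossing_block(cfg)
  fit <- fit_count_model(d, "hnb", inflation = "per_genotype",
                         random = character(0))
  ip <- inflation_probabilities(fit)
  zfrac <- tapply(d$seed_count == 0, d$genotype, mean)
  # structural property of the hurdle likelihood: Pr(y = 0 | g) = pi_g
  expect_equal(ip$pi, as.numeric(zfrac[ip$genotype]), tolerance = 1e-5)
  expect_true(all(ip$ci_low <= ip$pi & ip$pi <= ip$ci_high))
})

test_that("zinb reporting offers component and inflation-adjusted means", {
  set.seed(14)
  cfg <- crossing_block_config(paste0("g", 1:3), pi = c(0.25, 0.45, 0.6),
                               lambda = c(4, 9, 16), dispersion = 1,
                               n_blocks = 2, heads_per_plot = 40, seed = 14)
  d <- simulate_crossing_block(cfg)
  fit <- fit_count_model(d, "zinb", inflation = "per_genotype",
                         random = character(0))
  comp <- genotype_count_means(fit, inflation_adjusted = FALSE)
  head_mean <- genotype_count_means(fit, inflation_adjusted = TRUE)
  pi_hat <- inflation_probabilities(fit)$pi
  expect_equal(head_mean$estimate, comp$estimate * (1 - pi_hat),
               tolerance = 1e-8)
  # an inflation parameter at logit zero means pi = 1/2
  fit$params["zi.g1"] <- 0
  expect_equal(inflation_probabilities(fit)$pi[1], 0.5)
})

test_that("zinb constrained toward zero inflation matches the plain NB fit", {
  set.seed(15)
  d <- simulate_mixture_iid(15, 400, pi = 0, lambda = 6, k = 1.2)
  nb <- fit_count_model(d, "negbin", random = character(0))
  zi <- fit_count_model(d, "zinb", inflation = "single", random = character(0))
  expect_lt(abs(zi$loglik - nb$loglik), 0.51)
  ip <- inflation_probabilities(zi)
  expect_lt(ip$pi, 0.1)
  expect_true(ip$near_zero_boundary)
  expect_equal(ip$genotype, "overall")
})

test_that("transformed-Gaussian reporting flags nonsensical back-transforms", {
  set.seed(16)
  # a genotype with nearly all zero counts drives the sqrt-scale interval low
  d <- data.frame(genotype = rep(c("lowG", "highG"), each = 12), block = "B1",
                  head = paste0("H", 1:24),
                  seed_count = c(rep(0L, 11), 1L, rpois(12, 20)))
  fit <- fit_count_model(d, "gaussian", transform = "sqrt_three_eighths",
                         random = character(0))
  gm <- genotype_count_means(fit)
  low <- gm[gm$genotype == "lowG", ]
  expect_true(low$ci_low < 0 || low$nonsensical)
  expect_equal(gm$se_data,
               as.numeric(delta_method_se("sqrt_three_eighths",
                                          fit$params[paste0("alpha.", gm$genotype)],
                                          sqrt(diag(fit$vcov)[paste0("alpha.", gm$genotype)]))),
               tolerance = 1e-8)
})

test_that("non-converged fits refuse to report genotype means", {
  bad <- fake_fit(-10, 2, 10, converged = FALSE)
  bad$spec <- model_spec("negbin")
  expect_error(genotype_count_means(bad), "did not converge")
})

test_that("model comparison ranks within comparable likelihood types", {
  set.seed(17)
  d <- simulate_mixture_iid(17, 300, pi = 0.4, lambda = 8, k = 1)
  d$genotype <- rep(paste0("g", 1:3), length.out = nrow(d))
  specs <- list(poisson = model_spec("poisson", random = character(0)),
                negbin = model_spec("negbin", random = character(0)),
                LT = model_spec("gaussian", transform = "log_plus_one",
                                random = character(0)),
                zinb = model_spec("zinb", inflation = "single",
                                  random = character(0)))
  cmp <- compare_count_models(d, specs)
  expect_s3_class(cmp, "model_comparison")
  expect_equal(nrow(cmp), 4)
  # overdispersed zero-heavy data: NB beats Poisson on AICc
  expect_lt(cmp$AICc[cmp$model == "negbin"], cmp$AICc[cmp$model == "poisson"])
  # transformed-scale fits are not rankable against count likelihoods
  expect_equal(cmp$likelihood_type[cmp$model == "LT"], "transformed_scale")
  expect_true(all(cmp$likelihood_type[cmp$model %in%
                                        c("poisson", "negbin", "zinb")] == "count"))
  # identical specs produce identical statistics
  cmp2 <- compare_count_models(d, list(a = specs$negbin, b = specs$negbin))
  expect_equal(cmp2$AICc[1], cmp2$AICc[2])
  expect_error(compare_count_models(d, specs["poisson"]), "at least 2")
})
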