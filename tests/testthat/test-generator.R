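test_that("degenerate and exact-size cases behave", {
  cfg <- crossing_block_config(sprintf("g%02d", 1:27), pi = 1, lambda = 5,
                               n_blocks = 4, heads_per_plot = 5, seed = 3)
  d <- simulate_crossing_block(cfg)
  expect_equal(nrow(d), 27 * 4 * 5)
  expect_true(all(d$seed_count == 0))
  key <- paste(d$year, d$genotype, d$block, d$head)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("configuration invariants are enforced", {
  expect_error(crossing_block_config(character(0), 0.5, 5), "empty")
  expect_error(crossing_block_config("A", pi = 1.4, lambda = 5), "pi")
  expect_error(crossing_block_config("A", pi = 0.5, lambda = -1), "lambda")
  expect_error(crossing_block_config("A", 0.5, 5, dispersion = 0), "dispersion")
  expect_error(crossing_block_config("A", 0.5, 5, bag_loss_prob = 1), "bag_loss")
  expect_error(crossing_block_config(c("A", "A"), 0.5, 5), "duplicated")
})

test_that("empirical zero proportion matches the closed-form zero mass", {
  # zero-inflated: Pr(0) = pi + (1 - pi) f(0); hurdle: Pr(0) = pi
  n <- 20000
  for (kind in c("zero_inflated", "hurdle")) {
    cfg <- crossing_block_config("A", pi = 0.38, lambda = 6, dispersion = 1,
                                 n_blocks = 1, heads_per_plot = n,
                                 process = kind, seed = 42)
    d <- simulate_crossing_block(cfg)
    p0 <- if (kind == "zero_inflated") 0.38 + 0.62 * base_pmf(0, 6, 1) else 0.38
    se <- sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(mean(d$seed_count == 0) - p0), 3 * se)
  }
})

test_that("non-structural component mean converges to lambda", {
  cfg <- crossing_block_config("A", pi = 0.4, lambda = 9, dispersion = 2,
                               n_blocks = 1, heads_per_plot = 40000, seed = 9)
  d <- simulate_crossing_block(cfg)
  # overall mean of the zero-inflated process is (1 - pi) * lambda
  expect_lt(abs(mean(d$seed_count) - 0.6 * 9), 0.15)
})

test_that("generation is reproducible and bag loss is MCAR", {
  cfg <- crossing_block_config(c("A", "B"), pi = c(0.3, 0.5), lambda = c(4, 9),
                               n_blocks = 4, heads_per_plot = 5,
                               bag_loss_prob = 0.3, seed = 11)
  d1 <- simulate_crossing_block(cfg)
  d2 <- simulate_crossing_block(cfg)
  expect_identical(d1, d2)
  cfg2 <- cfg; cfg2$seed <- 12L
  expect_false(identical(simulate_crossing_block(cfg2)$seed_count,
                         d1$seed_count))
  # expected record count under independent deletion
  cfgN <- crossing_block_config("A", 0.5, 5, n_blocks = 1,
                                heads_per_plot = 20000,
                                bag_loss_prob = 0.3, seed = 5)
  n_kept <- nrow(simulate_crossing_block(cfgN))
  expect_lt(abs(n_kept - 14000), 3 * sqrt(20000 * 0.3 * 0.7))
})

test_that("2015 reference config carries the genotype-level estimates", {
  cfg <- trial_config(2015)
  expect_length(cfg$genotypes, 26)
  expect_true("NE10478-1" %in% cfg$genotypes)
  expect_false("Harry" %in% cfg$genotypes)
  expect_equal(unname(cfg$lambda[["TX12M4063"]]), 25.749)
  expect_equal(unname(cfg$pi[["TX12M4065"]]), 0.119)
  expect_equal(cfg$process, "hurdle")
  # bag loss calibrated so the expected record count matches the season
  expect_equal((1 - cfg$bag_loss_prob) * 26 * 4 * 5, 371, tolerance = 1e-10)
  expect_error(trial_config(2014), "unknown year")
})

test_that("2016 config reproduces the season's aggregate statistics", {
  cfg <- trial_config(2016)
  expect_length(cfg$genotypes, 26)
  expect_true("Harry" %in% cfg$genotypes)
  expect_false("NE10478-1" %in% cfg$genotypes)
  big <- crossing_block_config(cfg$genotypes, cfg$pi, cfg$lambda,
                               dispersion = cfg$dispersion, n_blocks = 80,
                               heads_per_plot = 5, process = "hurdle",
                               seed = 21)
  d <- simulate_crossing_block(big)   # > 10^4 heads
  n <- nrow(d)
  expect_lt(abs(mean(d$seed_count == 0) - 0.64),
            3 * sqrt(0.64 * 0.36 / n))
  expect_lt(abs(mean(d$seed_count) - 2.6), 0.2)
})

test_that("coverage generator exposes the zero-inflated study process", {
  gen <- coverage_generator()
  expect_equal(gen$process, "zero_inflated")
  expect_length(gen$genotypes, 8)
  expect_equal(gen$block_sd, 0)
  full <- coverage_generator(all_genotypes = TRUE)
  expect_length(full$genotypes, 26)
  expect_error(coverage_generator(genotypes = "NotAGenotype"), "unknown")
})
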