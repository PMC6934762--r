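# Small deterministic fixtures shared across test files.

# a tiny two-block dataset with mixed outcomes around the 7-seed threshold
toy_two_block <- function(counts = c(0, 10, 3, 0, 2, 9, 0, 0, 11, 1)) {
  n <- length(counts)
  data.frame(genotype = rep(c("A", "B"), length.out = n),
             block = rep(c("B1", "B2"), each = ceiling(n / 2))[1:n],
             head = paste0("H", seq_len(n)), seed_count = counts,
             stringsAsFactors = FALSE)
}

# balanced RCBD binary-outcome data with known success probabilities;
# returns seed counts of 0 (success) or 10 (failure) so any threshold < 10
# reproduces the intended binary pattern
simulate_binary_rcbd <- function(seed, prob, n_blocks = 4, heads = 5,
                                 block_sd = 0.25) {
  set.seed(seed)
  G <- length(prob)
  d <- expand.grid(head = paste0("H", seq_len(heads)),
                   genotype = sprintf("g%02d", seq_len(G)),
                   block = paste0("B", seq_len(n_blocks)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  b <- rnorm(n_blocks, 0, block_sd)
  eta <- qlogis(prob)[match(d$genotype, sprintf("g%02d", seq_len(G)))] +
    b[match(d$block, paste0("B", seq_len(n_blocks)))]
  d$seed_count <- ifelse(runif(nrow(d)) < plogis(eta), 0L, 10L)
  d
}

# single-genotype mixture data for parameter-recovery checks
simulate_mixture_iid <- function(seed, n, pi, lambda, k,
                                 kind = "zero_inflated") {
  cfg <- crossing_block_config("G1", pi = pi, lambda = lambda, dispersion = k,
                               n_blocks = 1, heads_per_plot = n,
                               process = kind, seed = seed)
  simulate_crossing_block(cfg)
}

# minimal hand-built fit object for closed-form method checks
fake_fit <- function(loglik, n_params, n_obs, converged = TRUE) {
  structure(list(loglik = loglik, n_params = n_params, n_obs = n_obs,
                 converged = converged, params = numeric(0), vcov = NULL,
                 non_estimable = character(0)),
            class = "sterility_fit")
}
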