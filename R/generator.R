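#' Configuration for a synthetic crossing-block sterility trial
#'
#' Describes the generating process for seed counts on bagged heads in a
#' randomized complete block crossing-block design: per-genotype inflation
#' probabilities `pi` (the probability that a head is fully sterilized and
#' structurally zero), per-genotype mean seed counts `lambda` for the
#' seed-forming (negative binomial) component, a shared NB2 dispersion `k`,
#' block and whole-plot (genotype-by-block) random effects on the log-mean
#' scale, and missing-completely-at-random bag loss.
#'
#' @param genotypes Character vector of genotype labels.
#' @param pi Numeric vector of inflation probabilities in `[0, 1]`, one per
#'   genotype (recycled if scalar).
#' @param lambda Positive per-genotype means of the count component
#'   (recycled if scalar).
#' @param dispersion Positive NB2 dispersion k (variance
#'   `lambda + lambda^2/k`); `Inf` gives a Poisson count component.
#' @param n_blocks Number of complete blocks.
#' @param heads_per_plot Number of bagged heads (sampling units) per
#'   genotype-by-block plot.
#' @param bag_loss_prob Probability that any given head record is lost
#'   (independently, e.g. bags blown off by wind).
#' @param block_sd,wholeplot_sd Standard deviations of the normal block and
#'   whole-plot effects added to `log(lambda)`.
#' @param process `"zero_inflated"` (structural zeros in excess of natural
#'   NB zeros) or `"hurdle"` (all zeros structural; positive counts
#'   zero-truncated NB).
#' @param year Label stored in the generated records.
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `"crossing_block_config"`.
#' @seealso [simulate_crossing_block()], [trial_config()]
#' @export
crossing_block_config <- function(genotypes, pi, lambda, dispersion = 1,
                                  n_blocks = 4, heads_per_plot = 5,
                                  bag_loss_prob = 0, block_sd = 0,
                                  wholeplot_sd = 0,
                                  process = c("zero_inflated", "hurdle"),
                                  year = "synthetic", seed = 1L) {
  process <- match.arg(process)
  genotypes <- as.character(genotypes)
  if (length(genotypes) == 0) stop("empty genotype list", call. = FALSE)
  if (anyDuplicated(genotypes)) stop("duplicated genotype labels", call. = FALSE)
  pi <- rep_len(pi, length(genotypes))
  lambda <- rep_len(lambda, length(genotypes))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(all(is.finite(pi)) && all(pi >= 0 & pi <= 1),
      "'pi' must be finite probabilities in [0, 1]")
  chk(all(is.finite(lambda)) && all(lambda > 0), "'lambda' must be positive")
  chk(is.finite(dispersion) && dispersion > 0 || is.infinite(dispersion),
      "'dispersion' must be positive (possibly Inf)")
  chk(n_blocks >= 1 && n_blocks == floor(n_blocks), "'n_blocks' must be a positive integer")
  chk(heads_per_plot >= 1 && heads_per_plot == floor(heads_per_plot),
      "'heads_per_plot' must be a positive integer")
  chk(is.finite(bag_loss_prob) && bag_loss_prob >= 0 && bag_loss_prob < 1,
      "'bag_loss_prob' must be a probability below 1")
  chk(is.finite(block_sd) && block_sd >= 0, "'block_sd' must be non-negative")
  chk(is.finite(wholeplot_sd) && wholeplot_sd >= 0, "'wholeplot_sd' must be non-negative")
  structure(list(genotypes = genotypes, pi = stats::setNames(pi, genotypes),
                 lambda = stats::setNames(lambda, genotypes),
                 dispersion = dispersion, n_blocks = as.integer(n_blocks),
                 heads_per_plot = as.integer(heads_per_plot),
                 bag_loss_prob = bag_loss_prob, block_sd = block_sd,
                 wholeplot_sd = wholeplot_sd, process = process,
                 year = as.character(year), seed = as.integer(seed)),
            class = "crossing_block_config")
}

#' @export
print.crossing_block_config <- function(x, ...) {
  cat("Crossing-block generator config (", x$process, " process)\n", sep = "")
  cat(sprintf("  %d genotypes x %d blocks x %d heads; k = %g; bag loss = %g\n",
              length(x$genotypes), x$n_blocks, x$heads_per_plot,
              x$dispersion, x$bag_loss_prob))
  cat(sprintf("  block sd = %g, whole-plot sd = %g (log scale); year = %s; seed = %d\n",
              x$block_sd, x$wholeplot_sd, x$year, x$seed))
  invisible(x)
}

## zero-truncated NB draw: inverse-cdf on the conditional distribution
.rtrunc_nb <- function(n, mu, size) {
  p0 <- exp(.log_p0(mu, size))
  u <- stats::runif(n, min = p0, max = 1)
  if (is.infinite(size[1])) {
    stats::qpois(u, lambda = mu)
  } else {
    stats::qnbinom(u, size = size, mu = mu)
  }
}

#' Simulate a crossing-block sterility dataset
#'
#' Draws one dataset from the generating process in `config`. For every
#' genotype-by-block-by-head cell a Bernoulli(`pi_g`) indicator decides
#' whether the head is a structural zero; otherwise the seed count is drawn
#' from the NB2 distribution with mean
#' `exp(log(lambda_g) + block effect + whole-plot effect)` and dispersion k
#' (zero-truncated under the hurdle process). Records are then deleted
#' independently with probability `bag_loss_prob`. The same config (including
#' its seed) always yields the identical dataset.
#'
#' @param config A [crossing_block_config()].
#' @return A `data.frame` with columns `year`, `genotype`, `block`, `head`,
#'   `seed_count`, carrying the config and seed in attributes.
#' @examples
#' cfg <- crossing_block_config(c("A", "B"), pi = c(0.3, 0.6),
#'                              lambda = c(4, 10), seed = 42)
#' head(simulate_crossing_block(cfg))
#' @export
simulate_crossing_block <- function(config) {
  stopifnot(inherits(config, "crossing_block_config"))
  G <- length(config$genotypes); J <- config$n_blocks; H <- config$heads_per_plot
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  blocks <- sprintf("B%d", seq_len(J))
  grid <- expand.grid(head = sprintf("H%d", seq_len(H)),
                      genotype = config$genotypes, block = blocks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  b_eff <- stats::rnorm(J, 0, config$block_sd)
  w_eff <- matrix(stats::rnorm(G * J, 0, config$wholeplot_sd), G, J)
  gi <- match(grid$genotype, config$genotypes)
  ji <- match(grid$block, blocks)
  mu <- exp(log(config$lambda[gi]) + b_eff[ji] + w_eff[cbind(gi, ji)])
  n <- nrow(grid)
  structural <- stats::runif(n) < config$pi[gi]
  counts <- integer(n)
  idx <- which(!structural)
  if (length(idx)) {
    if (config$process == "zero_inflated") {
      counts[idx] <- if (is.infinite(config$dispersion)) {
        stats::rpois(length(idx), mu[idx])
      } else {
        stats::rnbinom(length(idx), size = config$dispersion, mu = mu[idx])
      }
    } else {
      counts[idx] <- .rtrunc_nb(length(idx), mu[idx],
                                rep_len(config$dispersion, length(idx)))
    }
  }
  keep <- stats::runif(n) >= config$bag_loss_prob
  out <- data.frame(year = config$year, genotype = grid$genotype,
                    block = grid$block, head = grid$head,
                    seed_count = counts, stringsAsFactors = FALSE)[keep, ,
                                                                  drop = FALSE]
  rownames(out) <- NULL
  attr(out, "generator") <- config
  attr(out, "seed") <- config$seed
  out
}

## save/restore the global RNG state so simulation is side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
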