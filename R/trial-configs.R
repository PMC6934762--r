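## Reference genotype-level hurdle-NB parameter estimates from a two-year
## CHA (sintofen) sterility assay on Great Plains winter wheat: 27 genotypes,
## randomized complete blocks, five bagged heads per plot. `lambda` is the
## genotype mean seed count of the seed-forming (NB) component and `pi` the
## inflation probability, both from the genotype-specific hurdle NB analysis
## of the 2015 season. Entry 3 (Harry) was grown only in 2016 and entry 27
## (NE10478-1) only in 2015, so per-genotype estimates exist for the 26
## genotypes of 2015.
.genotype_reference <- data.frame(
  entry = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L,
            15L, 16L, 17L, 18L, 19L, 20L, 21L, 22L, 23L, 24L, 25L, 26L, 27L),
  genotype = c("Freeman", "Goodstreak", "Harry", "LCH13NEDH-11-24", "NE07531",
               "NE09517-1", "Ruth", "NE10683", "Overland", "Panhandle",
               "PSB13NEDH-15-58W", "Robidoux", "Settler CL", "TX09D1172",
               "TX10D2063", "TX10D2230", "TX10D2363", "TX11D3008",
               "TX11D3026", "TX11D3049", "TX11D3112", "TX11D3129",
               "TX12M4004", "TX12M4063", "TX12M4065", "Wesley", "NE10478-1"),
  in_2015 = c(TRUE, TRUE, FALSE, rep(TRUE, 24)),
  in_2016 = c(rep(TRUE, 26), FALSE),
  lambda_2015 = c(5.466, 4.266, NA, 2.557, 4.315, 8.060, 4.725, 8.502, 4.142,
                  5.161, 7.510, 8.053, 13.166, 9.246, 7.782, 11.113, 7.229,
                  7.498, 12.435, 3.691, 7.436, 16.109, 8.780, 25.749, 15.721,
                  7.568, 9.017),
  pi_2015 = c(0.384, 0.463, NA, 0.306, 0.444, 0.446, 0.500, 0.411, 0.167,
              0.363, 0.380, 0.333, 0.668, 0.286, 0.400, 0.353, 0.498, 0.230,
              0.312, 0.498, 0.332, 0.400, 0.280, 0.532, 0.119, 0.663, 0.334),
  stringsAsFactors = FALSE
)

## Aggregate descriptive targets of the two seasons used to calibrate the
## 2016 config, for which genotype-level estimates were not reported.
.trial_aggregates <- list(
  `2015` = list(n_obs = 371L, mean = 5.7, prop_zero = 0.38),
  `2016` = list(n_obs = 182L, mean = 2.6, prop_zero = 0.64)
)

#' Built-in reference parameter table for the sterility trial genotypes
#'
#' Genotype-level hurdle-NB estimates (count-component mean `lambda_2015`
#' and inflation probability `pi_2015`) for the 26 winter wheat genotypes of
#' the 2015 crossing-block season, plus season membership for all 27
#' genotypes tested across 2015-2016.
#'
#' @return A `data.frame` with one row per genotype.
#' @export
genotype_reference <- function() .genotype_reference

#' Generator configuration emulating a trial season
#'
#' Builds a [crossing_block_config()] whose structure and parameters emulate
#' one season of the reference CHA sterility trial: 4 blocks of 5 bagged
#' heads per genotype plot, a hurdle-NB generating process, and bag loss
#' chosen so the expected number of surviving records matches the season's
#' observed count (371 in 2015, 182 in 2016).
#'
#' For 2015 the per-genotype `lambda` and `pi` are the genotype-specific
#' hurdle-NB estimates in [genotype_reference()]. Genotype-level estimates
#' were not reported for 2016, so the 2016 config uses a common `lambda` and
#' `pi` for all genotypes, solved at run time (given the NB dispersion) so
#' that the marginal zero proportion equals 0.64 and the marginal mean seed
#' count equals 2.6, the season's aggregate statistics.
#'
#' @param year 2015 or 2016.
#' @param dispersion NB2 dispersion k of the count component. The default
#'   k = 1 reproduces the heavy right tail of the observed counts (see the
#'   package vignette).
#' @param block_sd,wholeplot_sd Random-effect SDs on the log-mean scale;
#'   zero by default so the configured `pi`/`lambda` are exactly the
#'   marginal head-level parameters.
#' @param seed Seed stored in the config.
#' @return A `crossing_block_config`.
#' @examples
#' cfg <- trial_config(2015)
#' length(cfg$genotypes)      # 26
#' cfg$lambda[["TX12M4063"]]  # 25.749
#' @export
trial_config <- function(year = 2015, dispersion = 1, block_sd = 0,
                         wholeplot_sd = 0, seed = 1L) {
  year <- as.character(year)
  if (!year %in% c("2015", "2016")) {
    stop("unknown year: ", year, " (available: 2015, 2016)", call. = FALSE)
  }
  agg <- .trial_aggregates[[year]]
  ref <- .genotype_reference
  if (year == "2015") {
    ref <- ref[ref$in_2015, ]
    genotypes <- ref$genotype
    pi <- ref$pi_2015
    lambda <- ref$lambda_2015
  } else {
    genotypes <- ref$genotype[ref$in_2016]
    # hurdle process: Pr(0) = pi, so pi is the zero proportion; lambda solves
    # (1 - pi) * lambda / (1 - f0(lambda)) = mean
    pi <- agg$prop_zero
    target <- agg$mean
    lambda <- stats::uniroot(function(l) {
      (1 - pi) * l / (-expm1(.log_p0(l, dispersion))) - target
    }, interval = c(1e-3, 1e3), tol = 1e-10)$root
  }
  n_cells <- length(genotypes) * 4L * 5L
  crossing_block_config(
    genotypes = genotypes, pi = pi, lambda = lambda, dispersion = dispersion,
    n_blocks = 4, heads_per_plot = 5,
    bag_loss_prob = 1 - agg$n_obs / n_cells,
    block_sd = block_sd, wholeplot_sd = wholeplot_sd,
    process = "hurdle", year = year, seed = seed)
}

#' Zero-inflated generator for the coverage simulation study
#'
#' Configuration of the zero-inflated NB process used by the empirical
#' coverage study: genotype count-component means and inflation
#' probabilities taken from the 2015 genotype-specific hurdle-NB estimates,
#' no block or whole-plot heterogeneity (so the true head-level mean of
#' genotype g is exactly `(1 - pi_g) * lambda_g`), no bag loss, and 4 blocks
#' of 5 heads (20 heads per genotype).
#'
#' @param genotypes Genotype labels to include. The default is an 8-genotype
#'   subset spanning the observed range of `lambda` (2.6 to 25.7) and `pi`
#'   (0.12 to 0.67); `coverage_generator(all_genotypes = TRUE)` uses all 26.
#' @param all_genotypes Use all 26 genotypes of 2015.
#' @param dispersion NB2 dispersion k of the count component.
#' @param seed Seed stored in the config.
#' @return A `crossing_block_config` with `process = "zero_inflated"`.
#' @export
coverage_generator <- function(genotypes = NULL, all_genotypes = FALSE,
                               dispersion = 1, seed = 1L) {
  ref <- .genotype_reference[.genotype_reference$in_2015, ]
  if (is.null(genotypes)) {
    genotypes <- if (all_genotypes) ref$genotype else
      c("LCH13NEDH-11-24", "Overland", "Freeman", "Wesley", "NE10683",
        "Settler CL", "TX12M4065", "TX12M4063")
  }
  i <- match(genotypes, ref$genotype)
  if (anyNA(i)) stop("unknown genotype(s): ",
                     paste(genotypes[is.na(i)], collapse = ", "), call. = FALSE)
  crossing_block_config(
    genotypes = genotypes, pi = ref$pi_2015[i], lambda = ref$lambda_2015[i],
    dispersion = dispersion, n_blocks = 4, heads_per_plot = 5,
    bag_loss_prob = 0, block_sd = 0, wholeplot_sd = 0,
    process = "zero_inflated", year = "sim", seed = seed)
}
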