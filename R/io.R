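#' Read and write seed-count datasets
#'
#' Seed-count data are exchanged as long-format CSV with the header
#' `year,genotype,block,head,seed_count`, one row per bagged head. On
#' reading, rows with a missing `seed_count` are dropped with a warning;
#' negative or non-integer counts and missing required columns are errors
#' naming the offending rows.
#'
#' @param path Path to a CSV file.
#' @return `read_seed_counts()` returns a `data.frame` of validated records;
#'   `write_seed_counts()` invisibly returns `path`.
#' @export
read_seed_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "genotype", "block", "head", "seed_count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[required]
  x$year <- as.character(x$year)
  x$genotype <- as.character(x$genotype)
  x$block <- as.character(x$block)
  x$head <- as.character(x$head)
  if (anyNA(x$seed_count)) {
    drop <- which(is.na(x$seed_count))
    warning("dropping ", length(drop), " row(s) with missing seed_count",
            call. = FALSE)
    x <- x[-drop, , drop = FALSE]
  }
  bad <- which(!is.finite(x$seed_count) | x$seed_count < 0 |
                 x$seed_count != floor(x$seed_count))
  if (length(bad)) {
    stop("seed_count must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(x[c("year", "genotype", "block", "head")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicated (year, genotype, block, head) record(s); first at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  x$seed_count <- as.integer(x$seed_count)
  rownames(x) <- NULL
  x
}

#' @rdname read_seed_counts
#' @param x A seed-count `data.frame` (as from [simulate_crossing_block()]).
#' @export
write_seed_counts <- function(x, path) {
  required <- c("year", "genotype", "block", "head", "seed_count")
  stopifnot(all(required %in% names(x)))
  utils::write.csv(x[required], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## adjusted Fisher-Pearson standardized moment coefficient,
## G1 = g1 * sqrt(n(n-1))/(n-2); NA when undefined (n < 3 or zero variance)
.skewness_adj <- function(y) {
  n <- length(y)
  s <- stats::sd(y)
  if (n < 3 || s == 0) return(NA_real_)
  g1 <- mean((y - mean(y))^3) / (mean((y - mean(y))^2))^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

## smallest most frequent value
.count_mode <- function(y) {
  tab <- table(y)
  as.integer(names(tab)[which.max(tab)][1])
}

#' Descriptive statistics of seed-count data
#'
#' Summary statistics of raw seed counts in the layout of a trial summary
#' table: number of observations, mean, variance, standard deviation,
#' proportion of zero counts, skewness (adjusted Fisher-Pearson sample
#' coefficient), median, mode (smallest on ties), minimum and maximum.
#' Undefined statistics (skewness with fewer than 3 observations or zero
#' variance) are reported as `NA` rather than raised as errors.
#'
#' @param x Seed-count `data.frame` with at least `seed_count` (and `year`
#'   when `by_year = TRUE`).
#' @param by_year Summarize each year separately?
#' @return A `data.frame` with one row per group and a
#'   `skewness_estimator` attribute recording the formula used.
#' @examples
#' d <- data.frame(year = "y", genotype = "g", block = "b",
#'                 head = paste0("H", 1:4), seed_count = c(0, 0, 0, 30))
#' summarize_seed_counts(d)  # prop_zero 0.75, mean 7.5, mode 0
#' @export
summarize_seed_counts <- function(x, by_year = TRUE) {
  stopifnot("seed_count" %in% names(x))
  if (nrow(x) == 0) stop("empty group", call. = FALSE)
  groups <- if (by_year && "year" %in% names(x)) {
    split(x$seed_count, x$year)
  } else {
    list(all = x$seed_count)
  }
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  rows <- lapply(names(groups), function(g) {
    y <- groups[[g]]
    data.frame(year = g, n_obs = length(y), mean = mean(y),
               variance = if (length(y) > 1) stats::var(y) else NA_real_,
               sd = if (length(y) > 1) stats::sd(y) else NA_real_,
               prop_zero = mean(y == 0), skewness = .skewness_adj(y),
               median = stats::median(y), mode = .count_mode(y),
               min = min(y), max = max(y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skewness_estimator") <- "adjusted Fisher-Pearson (G1)"
  out
}
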