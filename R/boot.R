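#' Bootstrap the pixel-weighted color statistics of a green profile
#'
#' Approximates the sampling distribution of the five weighted statistics by
#' resampling green codes with probability `W_i`. Each replicate draws
#' `n_draw` codes i.i.d. from the categorical distribution given by the
#' profile weights (realized as one multinomial count vector), forms the
#' empirical weights, and recomputes the statistics. Percentile confidence
#' intervals at level `1 - alpha` are attached per statistic.
#'
#' A single-code profile is a degenerate categorical distribution: every
#' replicate reproduces the observed value exactly and the intervals have
#' zero width.
#'
#' @param profile A `green_profile` from [build_profile()].
#' @param n_rep Number of bootstrap replicates (default 2000).
#' @param n_draw Codes drawn per replicate. Default: the profile's total
#'   green pixel count, capped at `1e5` — resampling the empirical pixel
#'   population at its own size, the standard nonparametric bootstrap.
#' @param alpha Interval level is `1 - alpha` (default 0.05, i.e. 95%).
#' @param seed Optional integer seed; the same seed reproduces the replicate
#'   vectors bit for bit. The caller's RNG state is left untouched.
#' @return An object of class `greenness_boot`: a list with `stats` (data
#'   frame: `statistic` in R, G, B, R/G, B/G; `point`; `ci_low`; `ci_high`),
#'   `replicates` (an `n_rep` x 5 matrix), and the settings `n_rep`,
#'   `n_draw`, `alpha`, `seed`.
#' @examples
#' p <- build_profile(data.frame(r = c(0, 102), g = c(43, 128),
#'                               b = c(0, 102), pixels = c(60, 40)))
#' b <- bootstrap_stats(p, n_rep = 200, seed = 1)
#' b$stats
#' @export
bootstrap_stats <- function(profile, n_rep = 2000, n_draw = NULL,
                            alpha = 0.05, seed = NULL) {
  stopifnot(inherits(profile, "green_profile"), nrow(profile) >= 1L)
  if (length(n_rep) != 1L || is.na(n_rep) || n_rep < 1) {
    stop("`n_rep` must be a positive integer", call. = FALSE)
  }
  if (is.null(n_draw)) n_draw <- min(sum(profile$pixels), 1e5)
  if (length(n_draw) != 1L || is.na(n_draw) || n_draw < 1) {
    stop("`n_draw` must be a positive integer", call. = FALSE)
  }
  vals <- stat_matrix(profile)
  point <- drop(profile$weight %*% vals)

  draw <- function() {
    counts <- rmultinom(n_rep, size = n_draw, prob = profile$weight)
    t(counts) %*% vals / n_draw
  }
  reps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  ci <- apply(reps, 2L, ci_percentile, alpha = alpha)
  structure(list(
    stats = data.frame(statistic = colnames(vals), point = point,
                       ci_low = ci[1L, ], ci_high = ci[2L, ],
                       row.names = NULL),
    replicates = reps,
    n_rep = n_rep, n_draw = n_draw, alpha = alpha, seed = seed
  ), class = "greenness_boot")
}

#' Bootstrap contrast between two groups
#'
#' Replicate-wise differences of the five weighted statistics between two
#' bootstrap results (paired by replicate index; the two groups must have
#' been resampled independently, e.g. with different seeds, as befits
#' independent field plots), with percentile intervals for each difference.
#' Reversing the argument order negates the point estimates and mirrors the
#' interval bounds.
#'
#' @param result_a,result_b `greenness_boot` objects with equal `n_rep` and
#'   `alpha`. The contrast reported is `a - b`.
#' @param pair Optional label, e.g. `"S-C"`.
#' @return An object of class `greenness_contrast`: list with `stats` (data
#'   frame: `statistic`, `point`, `ci_low`, `ci_high`), `replicates`, `pair`.
#' @export
boot_contrast <- function(result_a, result_b, pair = NULL) {
  stopifnot(inherits(result_a, "greenness_boot"),
            inherits(result_b, "greenness_boot"))
  if (result_a$n_rep != result_b$n_rep) {
    stop("bootstrap results have different `n_rep` and cannot be paired",
         call. = FALSE)
  }
  reps <- result_a$replicates - result_b$replicates
  ci <- apply(reps, 2L, ci_percentile, alpha = result_a$alpha)
  structure(list(
    stats = data.frame(statistic = result_a$stats$statistic,
                       point = result_a$stats$point - result_b$stats$point,
                       ci_low = ci[1L, ], ci_high = ci[2L, ],
                       row.names = NULL),
    replicates = reps, pair = pair, n_rep = result_a$n_rep,
    alpha = result_a$alpha
  ), class = "greenness_contrast")
}

#' Percentile bootstrap confidence interval
#'
#' Empirical `alpha/2` and `1 - alpha/2` quantiles of a replicate vector,
#' using the linear-interpolation quantile definition (R's default, type 7).
#' A constant replicate vector yields a zero-width interval.
#'
#' @param replicates Numeric vector of at least 2 finite values.
#' @param alpha Level in (0, 1); the interval has coverage `1 - alpha`.
#' @return Numeric length-2 vector `(low, high)`.
#' @examples
#' ci_percentile(1:100, 0.05)  # (3.475, 97.525)
#' @export
ci_percentile <- function(replicates, alpha = 0.05) {
  replicates <- replicates[is.finite(replicates)]
  if (length(replicates) < 2L) {
    stop("need at least 2 finite replicates", call. = FALSE)
  }
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  unname(quantile(replicates, c(alpha / 2, 1 - alpha / 2), type = 7))
}

# values of the five statistics contributed by each code, m x 5
stat_matrix <- function(profile) {
  cbind(R = profile$r, G = profile$g, B = profile$b,
        `R/G` = profile$r / profile$g, `B/G` = profile$b / profile$g)
}

#' @export
print.greenness_boot <- function(x, ...) {
  cat(sprintf("Weighted-statistic bootstrap: %d replicates, %g draws, %d%% CI\n",
              x$n_rep, x$n_draw, round(100 * (1 - x$alpha))))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' @export
print.greenness_contrast <- function(x, ...) {
  cat(sprintf("Bootstrap contrast%s: %d replicates, %d%% CI\n",
              if (is.null(x$pair)) "" else paste0(" ", x$pair),
              x$n_rep, round(100 * (1 - x$alpha))))
  print(x$stats, row.names = FALSE)
  invisible(x)
}
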