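#' Specify a synthetic field trial
#'
#' Describes the generative model behind [simulate_trial()]: a small
#' replicated field experiment (by default 3 treatments x 4 plots, observed
#' in May/June/July of 2 trial years) in which each canopy image is a
#' palette color table. Each treatment has a mixture over the green palette
#' codes; soil-disinfestation treatments (steam, chloropicrin) place more
#' mass on dark green than light green while the untreated control does the
#' reverse. Plot-to-plot variation acts on the mixture logits along the
#' dark-light axis, so a plot effect of size `b` shifts the plot's expected
#' log dark:light ratio by exactly `b`; month effects act on the same axis.
#' Image-to-image jitter is a Dirichlet perturbation of the mixture, and
#' pixels are allocated multinomially. Cumulative fruit yield is linear in
#' the plot's realized May log ratio with Gaussian noise.
#'
#' @param treatments Named list of mixture weight vectors over the rows of
#'   `palette`, each summing to 1. Default: control light-dominant, steam and
#'   chloropicrin dark-dominant.
#' @param palette Data frame of green palette codes (columns `r`, `g`, `b`);
#'   default [common_green_codes()].
#' @param n_plots Plots per treatment (default 4, as in a 4-replicate
#'   randomized complete block design).
#' @param months Month labels (default May, June, July).
#' @param years Trial-year labels (default `"Y1"`, `"Y2"`); plots are
#'   re-randomized between years.
#' @param pixels_green Green pixels per image (default `1e5`).
#' @param background_codes Non-green codes appended to every table (default a
#'   fruit red and a soil brown); `background_frac` is their fraction of the
#'   whole image (default 0.3).
#' @param background_frac See `background_codes`.
#' @param plot_random_sd SD of the per-plot shift on the log dark:light
#'   ratio scale (default 0.2).
#' @param within_image_noise Dirichlet concentration for per-image mixture
#'   jitter (default 200; larger = less jitter, `Inf` = none).
#' @param month_shift Named numeric of per-month shifts on the log-ratio
#'   scale (default 0, 0.2, 0.4 for May, June, July: canopies darken as the
#'   season progresses).
#' @param yield_link List with `intercept` (g/plant at log ratio 0),
#'   `slope` (g/plant per unit May log ratio) and `resid_sd`; defaults
#'   1000, 400, 150. `NULL` disables yield generation (then mixtures need
#'   not cover the dark and light codes).
#' @param dark,light The designated dark and light codes used for the ratio
#'   (defaults `(0,43,0)` and `(102,128,102)`).
#' @return A validated list of class `trial_spec`.
#' @export
trial_spec <- function(treatments = NULL,
                       palette = common_green_codes(),
                       n_plots = 4,
                       months = c("May", "June", "July"),
                       years = c("Y1", "Y2"),
                       pixels_green = 1e5,
                       background_codes = data.frame(
                         r = c(180L, 120L), g = c(40L, 90L), b = c(40L, 60L)),
                       background_frac = 0.3,
                       plot_random_sd = 0.2,
                       within_image_noise = 200,
                       month_shift = NULL,
                       yield_link = list(intercept = 1000, slope = 400,
                                         resid_sd = 150),
                       dark = c(0, 43, 0),
                       light = c(102, 128, 102)) {
  if (is.null(treatments)) {
    treatments <- list(
      control      = c(0.10, 0.15, 0.15, 0.25, 0.35),
      steam        = c(0.35, 0.20, 0.15, 0.15, 0.15),
      chloropicrin = c(0.33, 0.20, 0.16, 0.16, 0.15)
    )
  }
  if (is.null(month_shift)) {
    month_shift <- setNames(0.2 * (seq_along(months) - 1), months)
  }
  palette <- as.data.frame(as_palette_matrix(palette))
  if (!all(is_green(palette$r, palette$g, palette$b))) {
    stop("all palette codes must be green (G > R and G > B)", call. = FALSE)
  }
  if (is.null(names(treatments)) || any(names(treatments) == "")) {
    stop("`treatments` must be a named list of mixtures", call. = FALSE)
  }
  for (tn in names(treatments)) {
    w <- treatments[[tn]]
    if (length(w) != nrow(palette) || any(w < 0) ||
        abs(sum(w) - 1) > 1e-8) {
      stop("mixture for `", tn, "` must be length ", nrow(palette),
           ", nonnegative, summing to 1", call. = FALSE)
    }
  }
  if (n_plots < 2) stop("`n_plots` must be >= 2", call. = FALSE)
  if (plot_random_sd < 0 || background_frac < 0 || background_frac >= 1) {
    stop("invalid `plot_random_sd` or `background_frac`", call. = FALSE)
  }
  if (!setequal(names(month_shift), months)) {
    stop("`month_shift` must be named by `months`", call. = FALSE)
  }
  di <- code_row(palette, dark)
  li <- code_row(palette, light)
  if (!is.null(yield_link)) {
    stopifnot(all(c("intercept", "slope", "resid_sd") %in% names(yield_link)))
    if (is.na(di) || is.na(li)) {
      stop("the designated dark and light codes must be in the palette ",
           "when `yield_link` is set", call. = FALSE)
    }
    zero <- vapply(treatments, function(w) w[di] == 0 || w[li] == 0,
                   logical(1))
    if (any(zero)) {
      stop("treatment(s) ", paste(names(treatments)[zero], collapse = ", "),
           " put zero weight on the dark or light code; the yield link ",
           "needs a finite log ratio", call. = FALSE)
    }
  }
  structure(list(
    treatments = treatments, palette = palette, n_plots = n_plots,
    months = months, years = years, pixels_green = pixels_green,
    background_codes = as.data.frame(as_palette_matrix(background_codes)),
    background_frac = background_frac, plot_random_sd = plot_random_sd,
    within_image_noise = within_image_noise, month_shift = month_shift,
    yield_link = yield_link, dark = dark, light = light,
    dark_index = di, light_index = li
  ), class = "trial_spec")
}

code_row <- function(palette, code) {
  m <- which(palette$r == code[1] & palette$g == code[2] & palette$b == code[3])
  if (length(m) == 0L) NA_integer_ else m[1]
}

#' Simulate a synthetic field trial
#'
#' Generates palette color tables, plot metadata and cumulative yields under
#' the generative model described in [trial_spec()]. For each plot a single
#' random dark-light shift is drawn; each image's mixture is the treatment
#' mixture moved along the dark-light logit axis by the plot and month
#' shifts, Dirichlet-jittered, and realized as a multinomial pixel
#' allocation; background pixels are appended. Yield per plot-year follows
#' the linear link on the realized May log dark:light ratio.
#'
#' @param spec A [trial_spec()].
#' @param seed Optional integer seed for full reproducibility; the caller's
#'   RNG state is left untouched.
#' @return A list with `tables` (a `color_table_set` data frame:
#'   `image_id`, `plot_id`, `treatment`, `month`, `year`, `r`, `g`, `b`,
#'   `pixels`), `yields` (`plot_id`, `treatment`, `year`,
#'   `grams_per_plant`; `NULL` when the spec has no yield link), and `truth`
#'   (generating parameters: the spec, per-plot shifts, and the expected log
#'   dark:light ratio per treatment and month at plot effect zero).
#' @examples
#' trial <- simulate_trial(trial_spec(), seed = 1)
#' head(trial$tables)
#' @export
simulate_trial <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  run <- function() simulate_trial_impl(spec)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_trial_impl <- function(spec) {
  pal <- spec$palette
  score <- darkness_score(pal)
  n_bg <- round(spec$pixels_green * spec$background_frac /
                  (1 - spec$background_frac))
  bg <- spec$background_codes

  rows <- list()
  yield_rows <- list()
  plot_effects <- list()

  for (yr in spec$years) {
    for (trt in names(spec$treatments)) {
      w0 <- spec$treatments[[trt]]
      for (p in seq_len(spec$n_plots)) {
        plot_id <- sprintf("%s_%s_p%d", yr, trt, p)
        b <- rnorm(1, 0, spec$plot_random_sd)
        plot_effects[[plot_id]] <- b
        may_log_ratio <- NA_real_
        for (mo in spec$months) {
          shift <- b + spec$month_shift[[mo]]
          w <- softmax(log(pmax(w0, 1e-12)) + shift * score)
          w[w0 == 0] <- 0
          w <- w / sum(w)
          if (is.finite(spec$within_image_noise)) {
            g <- rgamma(length(w), shape = spec$within_image_noise * w)
            if (sum(g) > 0) w <- g / sum(g)
          }
          counts <- drop(rmultinom(1, spec$pixels_green, w))
          bg_counts <- if (n_bg > 0) {
            drop(rmultinom(1, n_bg, rep(1 / nrow(bg), nrow(bg))))
          } else {
            rep(0, nrow(bg))
          }
          keep <- counts > 0
          keep_bg <- bg_counts > 0
          rows[[length(rows) + 1L]] <- data.frame(
            image_id = sprintf("%s_%s", plot_id, mo),
            plot_id = plot_id, treatment = trt, month = mo, year = yr,
            r = c(pal$r[keep], bg$r[keep_bg]),
            g = c(pal$g[keep], bg$g[keep_bg]),
            b = c(pal$b[keep], bg$b[keep_bg]),
            pixels = c(counts[keep], bg_counts[keep_bg])
          )
          if (mo == spec$months[1] && !is.na(spec$dark_index)) {
            dk <- counts[spec$dark_index]
            lt <- counts[spec$light_index]
            if (dk >= 1 && lt >= 1) may_log_ratio <- log(dk / lt)
          }
        }
        if (!is.null(spec$yield_link)) {
          yl <- spec$yield_link
          yield_rows[[length(yield_rows) + 1L]] <- data.frame(
            plot_id = plot_id, treatment = trt, year = yr,
            grams_per_plant = yl$intercept + yl$slope * may_log_ratio +
              rnorm(1, 0, yl$resid_sd)
          )
        }
      }
    }
  }

  tables <- validate_color_table_set(do.call(rbind, rows))
  yields <- if (length(yield_rows)) do.call(rbind, yield_rows) else NULL

  expected <- expand.grid(treatment = names(spec$treatments),
                          month = spec$months, stringsAsFactors = FALSE)
  expected$log_ratio <- mapply(function(trt, mo) {
    if (is.na(spec$dark_index)) return(NA_real_)
    w0 <- spec$treatments[[trt]]
    w <- softmax(log(pmax(w0, 1e-12)) + spec$month_shift[[mo]] * score)
    log(w[spec$dark_index] / w[spec$light_index])
  }, expected$treatment, expected$month)

  list(tables = tables, yields = yields,
       truth = list(spec = spec,
                    plot_effects = unlist(plot_effects),
                    expected_log_ratio = expected))
}

# Centered dark-light scores: +0.5 for the darkest code, -0.5 for the
# lightest, linear in darkness rank, so a logit shift of b moves the log
# dark:light ratio by exactly b.
darkness_score <- function(palette) {
  d <- darkness_index(palette$r, palette$g, palette$b)
  if (nrow(palette) == 1L) return(0)
  rk <- rank(d, ties.method = "first") - 1
  0.5 - rk / max(rk)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Simulate log dark:light ratio records directly
#'
#' Generates per-image ratio records on the log scale without going through
#' pixel tables: `log_ratio = mu + effect[treatment] + month_shift[month] +
#' plot effect + noise`, with the plot effect drawn once per plot. This is
#' the generator used for parameter-recovery and type-I-error studies of
#' [fit_ratio_model()], where only the linear-model structure matters.
#'
#' @param effects Named numeric of treatment effects on the log-ratio scale
#'   (default control 0, steam 1, chloropicrin 1 — the two disinfestation
#'   treatments darken the canopy equally, so their mutual contrast is null).
#' @param n_plots Plots per treatment (default 4).
#' @param months Month labels (default May, June, July).
#' @param mu Baseline log ratio (default 0).
#' @param month_shift Named per-month shifts; default 0, 0.2, 0.4.
#' @param plot_sd Plot random-effect SD (default 0.2).
#' @param resid_sd Residual SD per image (default 0.3).
#' @param seed Optional integer seed.
#' @return A data frame with columns `plot_id`, `treatment`, `month`,
#'   `ratio`, `log_ratio`, `ok`, suitable for [fit_ratio_model()].
#' @export
simulate_ratio_records <- function(effects = c(control = 0, steam = 1,
                                               chloropicrin = 1),
                                   n_plots = 4,
                                   months = c("May", "June", "July"),
                                   mu = 0, month_shift = NULL,
                                   plot_sd = 0.2, resid_sd = 0.3,
                                   seed = NULL) {
  if (is.null(month_shift)) {
    month_shift <- setNames(0.2 * (seq_along(months) - 1), months)
  }
  stopifnot(!is.null(names(effects)), setequal(names(month_shift), months))
  run <- function() {
    d <- expand.grid(plot = seq_len(n_plots), treatment = names(effects),
                     month = months, stringsAsFactors = FALSE)
    d$plot_id <- paste0(d$treatment, "_p", d$plot)
    b <- rnorm(n_plots * length(effects), 0, plot_sd)
    names(b) <- unique(d$plot_id)
    d$log_ratio <- mu + effects[d$treatment] + month_shift[d$month] +
      b[d$plot_id] + rnorm(nrow(d), 0, resid_sd)
    d$ratio <- exp(d$log_ratio)
    d$ok <- TRUE
    d[, c("plot_id", "treatment", "month", "ratio", "log_ratio", "ok")]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Render a color table as an image
#'
#' Places each palette code's pixels at seeded random positions in a
#' `height x width` RGB raster, closing the loop with [quantize_image()]:
#' quantizing a rendered table with a palette containing its codes (or any
#' `palette_size` at least its number of codes) returns the table exactly.
#'
#' @param table Data frame with columns `r`, `g`, `b`, `pixels`;
#'   `sum(pixels)` must equal `width * height`.
#' @param width,height Image dimensions in pixels.
#' @param seed Optional integer seed for the pixel arrangement.
#' @return A `height x width x 3` numeric array with values in `[0, 1]`,
#'   ready for [png::writePNG()].
#' @export
render_image <- function(table, width, height, seed = NULL) {
  stopifnot(all(c("r", "g", "b", "pixels") %in% names(table)))
  n <- width * height
  if (sum(table$pixels) != n) {
    stop("sum(pixels) = ", sum(table$pixels), " but width * height = ", n,
         call. = FALSE)
  }
  run <- function() sample.int(n)
  perm <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  idx <- rep(seq_len(nrow(table)), times = table$pixels)[perm]
  arr <- array(0, dim = c(height, width, 3))
  arr[, , 1] <- matrix(table$r[idx], height, width) / 255
  arr[, , 2] <- matrix(table$g[idx], height, width) / 255
  arr[, , 3] <- matrix(table$b[idx], height, width) / 255
  arr
}
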