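#' Dark:light green area ratio
#'
#' Computes, per image, the ratio of the area occupied by a designated dark
#' green code to the area occupied by a designated light green code, together
#' with its natural logarithm. A ratio above one indicates a darker (by
#' convention healthier) green canopy. The ratio depends only on the two
#' pixel counts' quotient and is invariant to total image size.
#'
#' Images in which either code is absent have no finite (log) ratio: such
#' records are flagged (`ok = FALSE`) with a warning and should be excluded
#' from modeling, unless `haldane = TRUE` adds the classical +0.5 continuity
#' correction to both counts.
#'
#' @param table A data frame with columns `r`, `g`, `b`, `pixels`; if an
#'   `image_id` column is present, one record per image is returned and any
#'   metadata columns (`plot_id`, `treatment`, `month`, `year`) are carried
#'   through.
#' @param dark,light Length-3 integer RGB codes; defaults are the canonical
#'   dark green `(0,43,0)` and light green `(102,128,102)`.
#' @param haldane Add 0.5 to both counts instead of flagging zero counts
#'   (default `FALSE`).
#' @return A data frame of class `ratio_records` with columns (metadata if
#'   available,) `dark_pixels`, `light_pixels`, `ratio`, `log_ratio`, `ok`.
#' @examples
#' tab <- data.frame(r = c(0, 102), g = c(43, 128), b = c(0, 102),
#'                   pixels = c(300, 100))
#' dark_light_ratio(tab)  # ratio 3, log_ratio log(3)
#' @export
dark_light_ratio <- function(table, dark = c(0, 43, 0),
                             light = c(102, 128, 102), haldane = FALSE) {
  stopifnot(all(c("r", "g", "b", "pixels") %in% names(table)))
  if (!"image_id" %in% names(table)) table$image_id <- "image"
  meta_cols <- intersect(c("image_id", "plot_id", "treatment", "month", "year"),
                         names(table))
  meta <- unique(table[, meta_cols, drop = FALSE])
  if (anyDuplicated(meta$image_id)) {
    stop("inconsistent metadata within image_id", call. = FALSE)
  }

  count_code <- function(code) {
    hit <- table$r == code[1] & table$g == code[2] & table$b == code[3]
    v <- rowsum(table$pixels * hit, group = table$image_id)
    setNames(v[, 1], rownames(v))
  }
  dk <- count_code(dark)
  lt <- count_code(light)

  rec <- meta[order(meta$image_id), , drop = FALSE]
  rec$dark_pixels <- dk[rec$image_id]
  rec$light_pixels <- lt[rec$image_id]
  if (haldane) {
    rec$dark_pixels <- rec$dark_pixels + 0.5
    rec$light_pixels <- rec$light_pixels + 0.5
  }
  rec$ratio <- rec$dark_pixels / rec$light_pixels
  rec$log_ratio <- log(rec$ratio)
  rec$ok <- rec$dark_pixels >= 1 & rec$light_pixels >= 1
  if (haldane) rec$ok <- rec$light_pixels > 0
  if (any(!rec$ok)) {
    warning(sum(!rec$ok), " image(s) lack the dark or light code; ",
            "their ratio records are flagged ok = FALSE", call. = FALSE)
  }
  rownames(rec) <- NULL
  class(rec) <- c("ratio_records", "data.frame")
  rec
}

#' Mixed-model comparison of treatments on the log dark:light ratio
#'
#' Fits a linear mixed-effects model to the log-transformed dark:light ratio:
#' fixed effects for treatment, month and their interaction (month drops out
#' when only one month is present), and a random intercept per plot to
#' account for repeated observations of the same experimental unit over
#' months. Estimation is REML via \pkg{lme4}. Treatment contrasts, averaged
#' over months, are tested with Satterthwaite denominator degrees of freedom
#' (\pkg{lmerTest} / \pkg{emmeans}), a small-sample correction appropriate
#' for a handful of plots per treatment; no multiplicity adjustment is
#' applied. Residual normality — the assumption the log transform is meant to
#' secure — is checked with the Shapiro–Wilk test.
#'
#' @param records A `ratio_records` data frame (see [dark_light_ratio()]) or
#'   any data frame with columns `plot_id`, `treatment`, `month`,
#'   `log_ratio` (and optionally `ok`; flagged rows are dropped with a
#'   warning). Fit one year at a time: subset by `year` first if the records
#'   span several trials.
#' @param contrasts Optional list of `c(a, b)` treatment label pairs, each
#'   tested as `a - b`. Default: all pairwise differences, later level minus
#'   earlier (so with levels ordered control first, treated-minus-control
#'   contrasts are reported).
#' @param alpha Significance level used only for the printed summary
#'   (default 0.05).
#' @return An object of class `ratio_fit`: list with `model` (the
#'   `lmerModLmerTest` or `lm` fit), `fixed_effects`, `random_intercept_var`,
#'   `residual_var`, `contrasts` (data frame: `pair`, `estimate`, `se`, `df`,
#'   `p_value`), `normality_p`, `alpha`.
#' @export
fit_ratio_model <- function(records, contrasts = NULL, alpha = 0.05) {
  req <- c("plot_id", "treatment", "month", "log_ratio")
  stopifnot(all(req %in% names(records)))
  records <- as.data.frame(records)
  if ("ok" %in% names(records) && any(!records$ok)) {
    warning("dropping ", sum(!records$ok),
            " flagged record(s) with undefined ratio", call. = FALSE)
    records <- records[records$ok, , drop = FALSE]
  }
  if ("year" %in% names(records) && length(unique(records$year)) > 1L) {
    stop("records span several years; fit one trial at a time", call. = FALSE)
  }
  records$treatment <- if (is.factor(records$treatment)) {
    droplevels(records$treatment)
  } else {
    factor(records$treatment, levels = unique(records$treatment))
  }
  records$month <- factor(records$month, levels = unique(records$month))
  records$plot_id <- factor(records$plot_id)

  if (nlevels(records$treatment) < 2L) {
    stop("design is deficient in `treatment`: need at least 2 treatments",
         call. = FALSE)
  }
  plots_per_trt <- tapply(records$plot_id, records$treatment,
                          function(p) length(unique(p)))
  if (any(plots_per_trt < 2L)) {
    stop("design is deficient in `plot_id`: treatment(s) ",
         paste(names(plots_per_trt)[plots_per_trt < 2L], collapse = ", "),
         " have fewer than 2 plots", call. = FALSE)
  }

  # with a single observation per plot the random intercept is confounded
  # with the residual; the model then reduces to ordinary least squares
  repeated <- max(table(records$plot_id)) > 1L
  fe <- if (nlevels(records$month) > 1L) {
    log_ratio ~ treatment * month
  } else {
    log_ratio ~ treatment
  }
  if (repeated) {
    form <- update(fe, . ~ . + (1 | plot_id))
    fit <- suppressMessages(lmerTest::lmer(form, data = records, REML = TRUE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    plot_var <- vc$vcov[vc$grp == "plot_id"]
    resid_var <- vc$vcov[vc$grp == "Residual"]
    fixed <- lme4::fixef(fit)
  } else {
    fit <- lm(fe, data = records)
    plot_var <- 0
    resid_var <- summary(fit)$sigma^2
    fixed <- coef(fit)
  }

  # averaging over months is the intended summary; silence emmeans' note
  emm <- suppressMessages(
    emmeans::emmeans(fit, ~treatment, lmer.df = "satterthwaite"))
  if (is.null(contrasts)) {
    cons <- emmeans::contrast(emm, method = "revpairwise", adjust = "none")
  } else {
    lv <- levels(records$treatment)
    coefs <- lapply(contrasts, function(p) {
      if (!all(p %in% lv)) {
        stop("unknown treatment in contrast: ",
             paste(setdiff(p, lv), collapse = ", "), call. = FALSE)
      }
      (lv == p[1]) - (lv == p[2])
    })
    names(coefs) <- vapply(contrasts, function(p)
      paste(p[1], "-", p[2]), character(1))
    cons <- emmeans::contrast(emm, method = coefs, adjust = "none")
  }
  cdf <- as.data.frame(cons)
  contrast_tab <- data.frame(pair = as.character(cdf$contrast),
                             estimate = cdf$estimate, se = cdf$SE,
                             df = cdf$df, p_value = cdf$p.value)

  sw <- tryCatch(shapiro.test(resid(fit))$p.value, error = function(e) NA_real_)

  structure(list(
    model = fit,
    fixed_effects = fixed,
    random_intercept_var = plot_var,
    residual_var = resid_var,
    contrasts = contrast_tab,
    normality_p = sw,
    alpha = alpha,
    n = nrow(records)
  ), class = "ratio_fit")
}

#' @export
print.ratio_fit <- function(x, ...) {
  cat(sprintf("Log dark:light ratio mixed model (n = %d)\n", x$n))
  cat(sprintf("  plot random-intercept variance: %.4g, residual variance: %.4g\n",
              x$random_intercept_var, x$residual_var))
  cat(sprintf("  Shapiro-Wilk residual normality p = %.3g\n", x$normality_p))
  cat("Treatment contrasts (averaged over months, Satterthwaite df):\n")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Regression of fruit yield on the early-season dark:light ratio
#'
#' Ordinary least squares of cumulative fruit yield (g/plant) on the
#' dark:light green area ratio observed in a single month (conventionally the
#' first month of the season, May), matching plots between the two tables.
#'
#' @param yields Data frame with columns `plot_id` and `grams_per_plant`
#'   (a `year` column, if present in both tables, is also matched on).
#' @param ratios A `ratio_records` data frame restricted to one month;
#'   flagged records are dropped.
#' @return An object of class `yield_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value` (slope t-test), `n`, and `model` (the `lm` fit).
#' @export
fit_yield_regression <- function(yields, ratios) {
  stopifnot(all(c("plot_id", "grams_per_plant") %in% names(yields)),
            all(c("plot_id", "ratio") %in% names(ratios)))
  ratios <- as.data.frame(ratios)
  if ("month" %in% names(ratios) && length(unique(ratios$month)) > 1L) {
    stop("`ratios` spans several months; restrict to one month (e.g. May)",
         call. = FALSE)
  }
  if ("ok" %in% names(ratios)) ratios <- ratios[ratios$ok, , drop = FALSE]
  by <- intersect(c("plot_id", "year"), intersect(names(yields), names(ratios)))
  d <- merge(yields, ratios[, c(by, "ratio")], by = by)
  if (nrow(d) < 3L) {
    stop("need at least 3 matched plots for the yield regression",
         call. = FALSE)
  }
  if (var(d$ratio) == 0) {
    stop("ratio has zero variance across plots; slope is undefined",
         call. = FALSE)
  }
  fit <- lm(grams_per_plant ~ ratio, data = d)
  s <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = s$coefficients[2, 4],
    n = nrow(d),
    model = fit
  ), class = "yield_fit")
}

#' @export
print.yield_fit <- function(x, ...) {
  cat(sprintf("Yield ~ dark:light ratio OLS (n = %d plots)\n", x$n))
  cat(sprintf("  yield = %.1f + %.1f * ratio,  R^2 = %.3f,  slope p = %.3g\n",
              x$intercept, x$slope, x$r_squared, x$p_value))
  invisible(x)
}
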