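test_that("dark:light ratio and its log are computed per image", {
  tab <- data.frame(r = c(0, 102), g = c(43, 128), b = c(0, 102),
                    pixels = c(300, 100))
  rec <- dark_light_ratio(tab)
  expect_equal(rec$ratio, 3)
  expect_equal(rec$log_ratio, log(3))  # 1.0986...
  expect_true(rec$ok)

  tab$pixels <- c(100, 100)
  expect_equal(dark_light_ratio(tab)$ratio, 1)
  expect_equal(dark_light_ratio(tab)$log_ratio, 0)

  tab$pixels <- c(50, 200)
  expect_equal(dark_light_ratio(tab)$ratio, 0.25)
})

test_that("the ratio is invariant to total image size", {
  tab <- data.frame(r = c(0, 102, 51), g = c(43, 128, 85),
                    b = c(0, 102, 0), pixels = c(120, 40, 999))
  r1 <- dark_light_ratio(tab)$ratio
  tab$pixels <- tab$pixels * 11
  expect_equal(dark_light_ratio(tab)$ratio, r1)
})

test_that("images missing a designated code are flagged, not errored", {
  tab <- data.frame(image_id = c("a", "a", "b"),
                    r = c(0, 102, 0), g = c(43, 128, 43), b = c(0, 102, 0),
                    pixels = c(10, 20, 30))
  expect_warning(rec <- dark_light_ratio(tab), "flagged")
  rec <- rec[order(rec$image_id), ]
  expect_equal(rec$ok, c(TRUE, FALSE))
  expect_equal(rec$ratio[1], 0.5)

  # Haldane correction keeps the record usable
  rec2 <- dark_light_ratio(tab, haldane = TRUE)
  expect_true(all(rec2$ok))
  expect_equal(rec2$ratio[rec2$image_id == "b"], 30.5 / 0.5)
})

test_that("metadata columns are carried through to ratio records", {
  trial <- simulate_trial(trial_spec(years = "Y1", n_plots = 2,
                                     pixels_green = 2000), seed = 8)
  rec <- dark_light_ratio(trial$tables)
  expect_true(all(c("plot_id", "treatment", "month", "year") %in% names(rec)))
  expect_equal(nrow(rec), 3 * 2 * 3)  # treatments x plots x months
  expect_equal(order(rec$ratio), order(rec$log_ratio))  # log is monotone
})

test_that("noise-free data are interpolated exactly by the mixed model", {
  d <- expand.grid(plot = 1:2, treatment = c("control", "steam", "chloropicrin"),
                   month = c("May", "June"), stringsAsFactors = FALSE)
  d$plot_id <- paste0(d$treatment, d$plot)
  eff <- c(control = 0, steam = 1, chloropicrin = 1)
  d$log_ratio <- eff[d$treatment] + ifelse(d$month == "June", 0.5, 0)
  f <- suppressWarnings(fit_ratio_model(d))
  expect_equal(unname(f$fixed_effects["treatmentsteam"]), 1, tolerance = 1e-6)
  expect_equal(unname(f$fixed_effects["monthJune"]), 0.5, tolerance = 1e-6)
  expect_lt(f$random_intercept_var, 1e-8)
  # agrees with ordinary regression when plot variance is zero
  ols <- coef(lm(log_ratio ~ treatment * month,
                 data = transform(
                   d,
                   treatment = factor(treatment,
                                      levels = c("control", "steam",
                                                 "chloropicrin")),
                   month = factor(month, levels = c("May", "June")))))
  expect_equal(unname(f$fixed_effects), unname(ols), tolerance = 1e-6)
})

test_that("single-month contrasts match the pooled-variance two-sample test", {
  withr::with_seed(2, {
    d <- data.frame(plot_id = paste0(rep(c("a", "b"), each = 4), 1:4),
                    treatment = rep(c("A", "B"), each = 4), month = "May",
                    log_ratio = c(rnorm(4, 0, 0.3), rnorm(4, 0.8, 0.3)))
  })
  f <- fit_ratio_model(d)
  tt <- t.test(log_ratio ~ treatment, data = d, var.equal = TRUE)
  expect_equal(f$contrasts$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(f$contrasts$estimate,
               mean(d$log_ratio[d$treatment == "B"]) -
                 mean(d$log_ratio[d$treatment == "A"]),
               tolerance = 1e-10)
  expect_equal(f$random_intercept_var, 0)
})

test_that("deficient designs raise errors naming the deficient factor", {
  d <- simulate_ratio_records(seed = 1)
  expect_error(fit_ratio_model(d[d$treatment == "control", ]), "treatment")
  d1 <- d[d$plot_id %in% c("control_p1", "steam_p1", "steam_p2",
                           "chloropicrin_p1", "chloropicrin_p2"), ]
  expect_error(fit_ratio_model(d1), "plot_id.*control")
})

test_that("flagged ratio records are dropped with a warning", {
  d <- simulate_ratio_records(seed = 3)
  d$ok[1] <- FALSE
  expect_warning(f <- fit_ratio_model(d), "flagged")
  expect_equal(f$n, nrow(d) - 1L)
})

test_that("custom contrasts are honored and signed as requested", {
  d <- simulate_ratio_records(seed = 9)
  f <- fit_ratio_model(d, contrasts = list(c("steam", "control"),
                                           c("control", "steam")))
  expect_equal(f$contrasts$pair, c("steam - control", "control - steam"))
  expect_equal(f$contrasts$estimate[1], -f$contrasts$estimate[2])
  expect_equal(f$contrasts$p_value[1], f$contrasts$p_value[2])
  expect_error(fit_ratio_model(d, contrasts = list(c("steam", "fire"))),
               "unknown treatment")
  expect_true(f$normality_p >= 0 && f$normality_p <= 1)
})

test_that("treatment-effect estimates are unbiased with sane spread", {
  est <- vapply(1:40, function(i) {
    d <- simulate_ratio_records(seed = 4000 + i)
    f <- suppressWarnings(
      fit_ratio_model(d, contrasts = list(c("steam", "control"))))
    f$contrasts$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.1)
  # closed-form SE for the balanced design: sqrt(2*(0.04/4 + 0.09/12)) = 0.187
  expect_gt(sd(est), 0.10)
  expect_lt(sd(est), 0.30)
})

test_that("yield regression recovers an exact line and rejects degenerate input", {
  ratios <- data.frame(plot_id = paste0("p", 1:12), month = "May",
                       ratio = seq(0.2, 3, length.out = 12),
                       ok = TRUE)
  yields <- data.frame(plot_id = paste0("p", 1:12),
                       grams_per_plant = 200 * ratios$ratio + 500)
  f <- suppressWarnings(fit_yield_regression(yields, ratios))  # perfect fit
  expect_equal(f$slope, 200, tolerance = 1e-9)
  expect_equal(f$intercept, 500, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  ratios$ratio <- 1.5
  expect_error(fit_yield_regression(yields, ratios), "zero variance")
  expect_error(fit_yield_regression(yields[1:2, ], ratios[1:2, ]),
               "at least 3")
  ratios$month <- rep(c("May", "June"), 6)
  expect_error(fit_yield_regression(yields, ratios), "one month")
})

test_that("yields unrelated to the ratio give a slope CI covering zero", {
  withr::with_seed(21, {
    ratios <- data.frame(plot_id = paste0("p", 1:12), month = "May",
                         ratio = exp(rnorm(12, 0, 0.5)), ok = TRUE)
    yields <- data.frame(plot_id = paste0("p", 1:12),
                         grams_per_plant = rnorm(12, 1000, 150))
  })
  f <- fit_yield_regression(yields, ratios)
  ci <- confint(f$model)["ratio", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_lt(f$r_squared, 0.3)
})
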