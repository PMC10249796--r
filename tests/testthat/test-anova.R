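make_desc <- function(y, g, p, t) {
  tibble::tibble(group = g, period = p, day = t, SM = y, LS = y, B = y)
}

test_that("descriptive statistics reproduce hand arithmetic", {
  d <- make_desc(c(1, 2, 3), rep("High", 3), rep("depletion", 3), 1:3)
  st <- descriptive_stats(d, features = "SM")
  cell <- st[st$period == "depletion", ]
  expect_equal(cell$mean, 2)
  expect_equal(cell$se, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(cell$se, 4), 0.5774)
  # a single-value cell has no SE and is flagged
  d1 <- make_desc(c(1, 2), c("High", "High"), c("depletion", "repletion"), 1:2)
  st1 <- descriptive_stats(d1, features = "SM")
  single <- st1[st1$period == "repletion", ]
  expect_true(is.na(single$se))
  expect_false(single$se_defined)
  # Overall rows pool the periods
  overall <- st1[st1$period == "Overall", ]
  expect_equal(overall$n, 2L)
  expect_equal(overall$mean, 1.5)
})

test_that("F statistics match the brute-force nested least squares oracle", {
  set.seed(31)
  # balanced 2x2x2 and an unbalanced layout
  layouts <- list(
    expand.grid(group = c("High", "Low"), period = c("depletion", "repletion"),
                time = factor(1:2))[rep(1:8, each = 3), ],
    expand.grid(group = c("High", "Low"), period = c("depletion", "repletion"),
                time = factor(1:4))[rep(1:16, times = rep(c(2, 4), 8)), ])
  for (lay in layouts) {
    d <- tibble::as_tibble(lay)
    d$group <- factor(d$group); d$period <- factor(d$period)
    d$y <- rnorm(nrow(d)) + as.integer(d$group) * 0.5
    desc <- tibble::tibble(group = d$group, period = d$period,
                           day = d$time, SM = d$y)
    fit <- fit_threeway_anova(desc, "day", "SM")
    eff <- tidy(fit)
    for (i in seq_len(3)) {
      oracle <- oracle_anova_F(d, eff$term[i])
      expect_equal(eff$F[i], oracle$F, tolerance = 1e-10)
      expect_equal(eff$df[i], oracle$df)
      expect_equal(eff$p[i], oracle$p, tolerance = 1e-10)
    }
    expect_equal(fit$residual_df, oracle_anova_F(d, "group")$df_res)
  }
})

test_that("the implementation agrees with car's Type III table", {
  skip_if_not_installed("car")
  d <- simulate_descriptors("day", seed = 5)
  fit <- fit_threeway_anova(d, "day", "SM")
  ca <- car::Anova(fit$fit, type = 3)
  expect_equal(tidy(fit)$F, ca$`F value`[2:4], tolerance = 1e-10)
  expect_equal(tidy(fit)$p, ca$`Pr(>F)`[2:4], tolerance = 1e-10)
})

test_that("effect degrees of freedom follow the two designs", {
  day <- simulate_descriptors("day", seed = 2)
  expect_equal(tidy(fit_threeway_anova(day, "day", "SM"))$df, c(1, 1, 4))
  hour <- simulate_descriptors("hour", seed = 2)
  expect_equal(tidy(fit_threeway_anova(hour, "hour", "B"))$df, c(1, 1, 6))
})

test_that("statistics are invariant to row permutation", {
  d <- simulate_descriptors("day", seed = 8)
  fit1 <- tidy(fit_threeway_anova(d, "day", "LS"))
  fit2 <- tidy(fit_threeway_anova(d[sample(nrow(d)), ], "day", "LS"))
  expect_equal(fit1, fit2, tolerance = 1e-12)
})

test_that("null balanced data give F near 1 and uniform p-values", {
  set.seed(77)
  ps <- replicate(200, {
    lay <- expand.grid(group = c("High", "Low"), period = c("d", "r"),
                       day = 1:2)[rep(1:8, each = 3), ]
    lay$SM <- rnorm(nrow(lay))
    tidy(fit_threeway_anova(tibble::as_tibble(lay), "day", "SM"))$p[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the generator's null depletion/repletion effect controls type I error", {
  hits <- vapply(1:200, function(s) {
    d <- simulate_descriptors("day", seed = 30000 + s,
                              calibration = descriptor_calibration("day", per_period = FALSE))
    tidy(fit_threeway_anova(d, "day", "SM"))$p[2] > 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.88)
})

test_that("empty or singleton factor levels raise a model error naming them", {
  d <- simulate_descriptors("day", seed = 3)
  d_one_group <- d[d$group == "High", ]
  err <- tryCatch(fit_threeway_anova(d_one_group, "day", "SM"),
                  error = function(e) e)
  expect_s3_class(err, "mfspectra_error_input")
  expect_match(conditionMessage(err), "group")
})

test_that("the rendered table lays p-values out by model, effect and feature", {
  d <- simulate_descriptors("day", seed = 4)
  h <- simulate_descriptors("hour", seed = 4)
  tab <- anova_table(day_descriptors = d, hour_descriptors = h)
  expect_equal(nrow(tab), 6L)
  expect_named(tab, c("model", "effect", "SM", "LS", "B"))
  expect_true(all(tab$SM >= 0 & tab$SM <= 1))
  # the calibrated group effect is overwhelmingly significant
  expect_lt(tab$SM[tab$model == "day" & tab$effect == "Group"], 1e-4)
})
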