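test_that("a noiseless half-decrement recovers slope 0.5 with a degenerate interval", {
  pre <- c(800, 1200, 1600, 2000, 2400)
  reg <- fit_post_pre(pre, 0.5 * pre)
  expect_equal(unname(coef(reg)), 0.5, tolerance = 1e-12)
  ci <- confint(reg)
  expect_lt(ci[2] - ci[1], 1e-8)
  expect_lt(reg$p_value, 1e-12)
  expect_equal(unname(predict(reg)), 0.5 * pre, tolerance = 1e-10)
  expect_equal(max(abs(residuals(reg))), 0, tolerance = 1e-10)
})

test_that("the fitted slope equals the textbook cov/var closed form", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(10:100, 1)
    pre <- rnorm(n, 1500, 400)
    post <- 0.6 * pre + rnorm(n, 0, 200)
    reg <- fit_post_pre(pre, post)
    expect_equal(unname(coef(reg)), cov(pre, post) / var(pre), tolerance = 1e-10)
  }
})

test_that("degenerate or undersized designs are rejected", {
  expect_error(fit_post_pre(c(1, 2), c(1, 2)), class = "ctb_input_error")
  expect_error(fit_post_pre(rep(5, 10), rnorm(10)), class = "ctb_input_error")
  expect_error(fit_per_minute(1:3, 1:3, 1:3), class = "ctb_input_error")
  pre <- c(1, 2, 3, 4)
  expect_error(fit_per_minute(pre, pre, post_minutes = 2 * pre),
               class = "ctb_input_error")   # collinear design
})

test_that("constant post-season minutes reduce the controlled model to the crude one", {
  set.seed(4)
  pre <- rnorm(30, 1500, 300)
  post <- 0.5 * pre + rnorm(30, 0, 100)
  crude <- fit_post_pre(pre, post)
  ctrl <- fit_per_minute(pre, post, post_minutes = rep(1200, 30))
  expect_equal(coef(ctrl), coef(crude), tolerance = 1e-12)
})

test_that("a decrement acting only through minutes attenuates the controlled pre coefficient", {
  set.seed(5)
  n <- 300
  pre_minutes <- rnorm(n, 1700, 300)
  post_minutes <- 0.5 * pre_minutes + rnorm(n, 0, 80)
  pre_points <- 0.43 * pre_minutes + rnorm(n, 0, 30)
  post_points <- 0.43 * post_minutes + rnorm(n, 0, 30)   # points track minutes only
  crude <- fit_post_pre(pre_points, post_points)
  ctrl <- fit_per_minute(pre_points, post_points, post_minutes)
  expect_gt(unname(coef(crude)), 0.35)
  expect_lt(abs(unname(coef(ctrl))), unname(coef(crude)) / 2)
})

test_that("the ratio-outcome per-minute variant regresses rates on rates", {
  set.seed(6)
  n <- 100
  pre_minutes <- rnorm(n, 1700, 200)
  post_minutes <- rnorm(n, 1200, 200)
  rate <- rnorm(n, 0.43, 0.08)
  reg <- fit_per_minute(rate * pre_minutes, 0.5 * rate * post_minutes,
                        post_minutes, pre_minutes, ratio_outcome = TRUE)
  expect_equal(unname(coef(reg)), 0.5, tolerance = 0.02)
})

test_that("adjusting for covariates unrelated to the outcome leaves the slope unchanged", {
  set.seed(7)
  n <- 150
  d <- data.frame(pre = rnorm(n, 1500, 350))
  d$post <- 0.6 * d$pre + rnorm(n, 0, 150)
  d$age <- rnorm(n, 27, 3)
  d$seasons <- sample(3:12, n, replace = TRUE)
  d$year_of_injury <- sample(2009:2019, n, replace = TRUE)
  d$region <- sample(c("knee", "ankle", "groin/hip/thigh"), n, replace = TRUE)
  d$position <- sample(c("guard", "forward", "center"), n, replace = TRUE)
  adj <- fit_adjusted(d)
  crude <- fit_post_pre(d$pre, d$post)
  expect_lt(abs(unname(coef(adj)) - unname(coef(crude))), 0.05)
  expect_true(all(c("age", "region", "position", "age:seasons") %in% adj$covariates))
})

test_that("adjustment removes a planted confounder from the crude slope", {
  set.seed(8)
  n <- 400
  age <- rnorm(n, 27, 3)
  d <- data.frame(age = age, pre = 50 * age + rnorm(n, 0, 50))
  d$post <- 0.5 * d$pre + 40 * age + rnorm(n, 0, 30)
  d$seasons <- sample(3:12, n, replace = TRUE)
  d$year_of_injury <- sample(2009:2019, n, replace = TRUE)
  d$region <- sample(c("knee", "ankle"), n, replace = TRUE)
  d$position <- sample(c("guard", "forward"), n, replace = TRUE)
  crude <- fit_post_pre(d$pre, d$post)
  adj <- fit_adjusted(d)
  expect_gt(unname(coef(crude)), 0.9)              # confounded upward
  expect_lt(abs(unname(coef(adj)) - 0.5), 0.1)     # recovered after adjustment
})

test_that("single-level factors are dropped rather than breaking the adjusted fit", {
  set.seed(9)
  n <- 60
  d <- data.frame(pre = rnorm(n, 1500, 300), age = rnorm(n, 27, 3),
                  seasons = sample(3:10, n, replace = TRUE),
                  year_of_injury = sample(2010:2018, n, replace = TRUE),
                  region = "knee",
                  position = sample(c("guard", "forward"), n, replace = TRUE))
  d$post <- 0.7 * d$pre + rnorm(n, 0, 120)
  adj <- fit_adjusted(d)
  expect_identical(adj$dropped, "region")
  expect_error(fit_adjusted(d[0, ]), class = "ctb_input_error")
})

test_that("the restricted cubic spline basis has linear tails and spans the line", {
  set.seed(10)
  x <- c(runif(80, 0, 10))
  des <- rcs_design(x, 3)
  expect_identical(unname(des$knots),
                   unname(quantile(x, c(0.1, 0.5, 0.9), type = 7)))
  expect_identical(ncol(des$X), 2L)                  # k - 1 columns, linear first
  expect_identical(des$X[, 1], x)
  expect_error(rcs_design(c(1, 1, 1), 3), class = "ctb_input_error")
  expect_error(rcs_design(x, knots = c(1, 1, 5)), class = "ctb_input_error")

  y <- 2 + 0.5 * x + sin(x)
  f <- fit_rcs(x, y, 5)
  # beyond the boundary knots the fitted function is exactly linear
  for (x0 in c(max(des$knots) + 3, min(des$knots) - 3)) {
    h <- 0.5
    d2 <- predict(f, x0 + h) - 2 * predict(f, x0) + predict(f, x0 - h)
    expect_lt(abs(d2), 1e-8)
  }
})

test_that("spline fits on straight-line data collapse to the least-squares line", {
  x <- seq(1, 100, length.out = 120)
  y <- 3 + 0.4 * x
  f <- fit_rcs(x, y, 4)
  ols <- lm(y ~ x)
  expect_lt(max(abs(predict(f, x) - predict(ols, data.frame(x = x)))), 1e-8)
  # nonlinear coefficients vanish
  expect_lt(max(abs(f$coefficients[-(1:2)])), 1e-8)
  # with only the linear basis column the fit IS the least-squares line
  lin <- lm(y ~ rcs_design(x, 4)$X[, 1])
  expect_equal(unname(fitted(lin)), unname(fitted(ols)), tolerance = 1e-10)
})

test_that("spline fits agree with the natural-spline oracle on noisy data", {
  skip_if_not_installed("splines")
  set.seed(11)
  x <- runif(150, 0, 20)
  y <- 5 + 0.3 * x + 0.05 * (x - 10)^2 + rnorm(150)
  f <- fit_rcs(x, y, 4)
  k <- f$knots
  ns_fit <- lm(y ~ splines::ns(x, knots = k[2:3], Boundary.knots = k[c(1, 4)]))
  # same function space -> identical least-squares fitted values
  expect_equal(unname(fitted(f$fit)), unname(fitted(ns_fit)), tolerance = 1e-8)
})

test_that("one-way ANOVA matches the F = t^2 identity and degenerate expectations", {
  res <- anova_return_days(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_identical(res$df_between, 1L)
  expect_identical(res$df_within, 4L)

  set.seed(12)
  for (i in 1:5) {
    d1 <- rnorm(20, 250, 80); d2 <- rnorm(25, 280, 80)
    res <- anova_return_days(c(d1, d2), rep(c("a", "b"), c(20, 25)))
    tt <- t.test(d1, d2, var.equal = TRUE)
    expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }

  expect_error(anova_return_days(1:5, rep("a", 5)), class = "ctb_input_error")
  expect_error(anova_return_days(c(1, 2, 3), c("a", "a", "b")),
               class = "ctb_input_error")
})

test_that("ANOVA detects a one-SD mean shift at n = 50 per group", {
  set.seed(13)
  hits <- vapply(1:100, function(i) {
    days <- c(rnorm(50, 250, 80), rnorm(50, 250, 80), rnorm(50, 330, 80))
    anova_return_days(days, rep(c("a", "b", "c"), each = 50))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("planted decrements are recovered across metrics by the post-on-pre slope", {
  set.seed(14)
  cover <- matrix(NA, 100, 3)
  est <- matrix(NA, 100, 3)
  for (r in 1:100) {
    d <- simulate_post_pre(100, decrement = 0.6)
    for (j in seq_along(c("minutes", "points", "rebounds"))) {
      m <- c("minutes", "points", "rebounds")[j]
      reg <- fit_post_pre(d[[paste0("pre_", m)]], d[[paste0("post_", m)]])
      ci <- confint(reg)
      cover[r, j] <- ci[1] <= 0.6 && 0.6 <= ci[2]
      est[r, j] <- coef(reg)
    }
  }
  for (j in 1:3) {
    expect_gte(mean(cover[, j]), 0.87)   # nominal 95% at 100 replicates
    expect_lte(mean(cover[, j]), 1.0)
    expect_lt(abs(mean(est[, j]) - 0.6), 0.03)
  }
})

test_that("the cohort model battery reports crude, controlled, knee-only and adjusted fits", {
  lg <- generate_league(synthetic_config(n_teams = 10, games_per_team = 60,
                                         n_seasons = 3, roster_size = 10,
                                         injury_hazard = 0.012,
                                         severity_mix = c(Slight = 0.1, Minor = 0.1,
                                                          Moderate = 0.2, Severe = 0.6),
                                         dropout_prob = 0, seed = 71))
  ev <- classify_events(link_injury_events(lg$transactions, lg$game_records,
                                           lg$schedule)$events)
  cohort <- build_cohort(ev, lg$game_records, lg$roster)
  mods <- cohort_models(cohort, lg$game_records, years = 1L)
  res <- mods$results
  expect_true(all(c("post_pre", "per_minute", "adjusted") %in% res$model_id))
  expect_true("knee" %in% res$stratum)
  expect_true(all(res$ci_low <= res$coefficient & res$coefficient <= res$ci_high))
  expect_true(all(res$n >= 3))
  expect_s3_class(mods$anova, "ctb_anova")
  expect_identical(sort(mods$anova$groups),
                   sort(unique(cohort$entries$body_region)))
  expect_s3_class(mods$rcs_fits[["rcs.minutes_total.1"]], "ctb_rcs")
})
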