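# Prognostic models: post-on-pre linear regressions (crude,
# minutes-controlled, covariate-adjusted), one-way ANOVA of return-to-sport
# time by body region, and restricted cubic spline sensitivity fits.
# Ordinary least squares is delegated to stats::lm; the classes here carry
# the focal coefficient, its t-based interval, and the underlying fit.

new_reg <- function(model_id, metric, year, fit, term, covariates) {
  sm <- withCallingHandlers(
    stats::coef(summary(fit)),
    warning = function(w) {
      # noiseless fixtures legitimately produce zero-residual fits
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  n <- length(stats::residuals(fit))
  dfree <- fit$df.residual
  tq <- stats::qt(0.975, dfree)
  p <- if (se == 0) if (est == 0) 1 else 0 else
    2 * stats::pt(-abs(est / se), dfree)
  structure(list(model_id = model_id, metric = metric, year = year,
                 coefficient = unname(est),
                 ci_low = unname(est - tq * se), ci_high = unname(est + tq * se),
                 p_value = unname(p), n = n, term = term,
                 covariates = covariates, fit = fit),
            class = "ctb_reg")
}

#' Post-on-pre prognostic regression
#'
#' Ordinary least squares of a post-injury season value on the pre-injury
#' season value of the same metric, with intercept. The slope is the
#' prognostic coefficient: the expected post-season value per unit of
#' pre-season value. Confidence interval and p-value are t-based with
#' `n - 2` degrees of freedom.
#'
#' @param pre,post numeric vectors, paired by player; incomplete pairs are
#'   dropped. At least 3 complete pairs are required.
#' @param metric,year optional labels carried on the result.
#' @return `"ctb_reg"` object; `coef()` gives the slope, `confint()` its 95%
#'   interval, and `summary()`, `predict()`, `residuals()` delegate to the
#'   underlying [stats::lm] fit.
#' @examples
#' fit_post_pre(c(100, 200, 300, 400), c(50, 100, 150, 200))  # slope 0.5
#' @export
fit_post_pre <- function(pre, post, metric = NA_character_, year = NA_integer_) {
  ok <- stats::complete.cases(pre, post)
  pre <- pre[ok]; post <- post[ok]
  if (length(pre) < 3) stop_input("at least 3 complete (pre, post) pairs are required")
  if (stats::var(pre) == 0)
    stop_input("degenerate design: the pre-injury values have zero variance")
  fit <- stats::lm(post ~ pre, data = data.frame(pre = pre, post = post))
  new_reg("post_pre", metric, year, fit, "pre", character(0))
}

#' Minutes-controlled post-on-pre regression
#'
#' The secondary analysis for counting metrics: the post-season value is
#' regressed on the pre-season value with post-season minutes played entered
#' as an additional covariate; the reported coefficient is still the
#' pre-season slope. When post-season minutes are constant they carry no
#' information and the model reduces to [fit_post_pre()]. A ratio-outcome
#' variant (`ratio_outcome = TRUE`) instead regresses post-season value per
#' minute on pre-season value per minute, for readings of "per minute played"
#' as a rate outcome; the covariate form is the default.
#'
#' @inheritParams fit_post_pre
#' @param post_minutes post-season minutes played, paired with `post`.
#' @param pre_minutes pre-season minutes (required for the ratio variant).
#' @param ratio_outcome use the per-minute-rate formulation.
#' @return `"ctb_reg"` with the pre-season coefficient.
#' @export
fit_per_minute <- function(pre, post, post_minutes, pre_minutes = NULL,
                           metric = NA_character_, year = NA_integer_,
                           ratio_outcome = FALSE) {
  if (ratio_outcome) {
    if (is.null(pre_minutes))
      stop_input("'pre_minutes' is required for the ratio-outcome variant")
    ok <- stats::complete.cases(pre, post, post_minutes, pre_minutes) &
      post_minutes > 0 & pre_minutes > 0
    d <- data.frame(pre = pre[ok] / pre_minutes[ok], post = post[ok] / post_minutes[ok])
    if (nrow(d) < 4) stop_input("at least 4 complete cases are required")
    if (stats::var(d$pre) == 0) stop_input("degenerate design: zero variance in pre rate")
    fit <- stats::lm(post ~ pre, data = d)
    return(new_reg("per_minute_ratio", metric, year, fit, "pre", character(0)))
  }
  ok <- stats::complete.cases(pre, post, post_minutes)
  d <- data.frame(pre = pre[ok], post = post[ok], post_minutes = post_minutes[ok])
  if (nrow(d) < 4) stop_input("at least 4 complete (pre, post, minutes) triples are required")
  if (stats::var(d$pre) == 0)
    stop_input("degenerate design: the pre-injury values have zero variance")
  if (stats::var(d$post_minutes) == 0) {
    fit <- stats::lm(post ~ pre, data = d)
    return(new_reg("per_minute", metric, year, fit, "pre", character(0)))
  }
  X <- cbind(1, d$pre, d$post_minutes)
  if (qr(X)$rank < 3L)
    stop_input(sprintf(
      "collinear design: pre and post minutes are linearly dependent (condition number %.3g)",
      kappa(X)))
  fit <- stats::lm(post ~ pre + post_minutes, data = d)
  new_reg("per_minute", metric, year, fit, "pre", "post_minutes")
}

#' Covariate-adjusted post-on-pre regression
#'
#' Adds age at primary severe injury, seasons played at injury, calendar year
#' of injury, body region (reference: knee), position (reference: guard) and
#' the age-by-seasons interaction to the post-on-pre model, on complete cases
#' only. Categorical covariates observed at a single level are dropped from
#' the design (and recorded on the result) rather than producing a singular
#' fit.
#'
#' @param data data frame with columns `pre`, `post`, `age`, `seasons`,
#'   `year_of_injury`, `region`, `position`.
#' @inheritParams fit_post_pre
#' @return `"ctb_reg"` with the pre-season coefficient; dropped terms are in
#'   `$dropped`.
#' @export
fit_adjusted <- function(data, metric = NA_character_, year = NA_integer_) {
  need <- c("pre", "post", "age", "seasons", "year_of_injury", "region", "position")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop_input(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  d <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
  if (nrow(d) == 0) stop_input("no complete cases for the adjusted model")
  d$region <- stats::relevel(factor(d$region), ref =
                               if ("knee" %in% d$region) "knee" else levels(factor(d$region))[1])
  d$position <- stats::relevel(factor(d$position), ref =
                                 if ("guard" %in% d$position) "guard" else levels(factor(d$position))[1])
  terms <- c("pre", "age", "seasons", "year_of_injury", "region", "position",
             "age:seasons")
  dropped <- character(0)
  for (fac in c("region", "position"))
    if (nlevels(droplevels(d[[fac]])) < 2) {
      terms <- setdiff(terms, fac); dropped <- c(dropped, fac)
    }
  if (nrow(d) < length(terms) + 3)
    stop_input("too few complete cases for the adjusted model")
  fml <- stats::reformulate(terms, response = "post")
  fit <- stats::lm(fml, data = d)
  out <- new_reg("adjusted", metric, year, fit, "pre", setdiff(terms, "pre"))
  out$dropped <- dropped
  out
}

#' @export
print.ctb_reg <- function(x, ...) {
  lab <- if (!is.na(x$metric)) paste0(" [", x$metric,
                                      if (!is.na(x$year)) paste0(", year ", x$year), "]") else ""
  cat(sprintf("%s regression%s (n = %d)\n", x$model_id, lab, x$n))
  cat(sprintf("  %s coefficient: %.3f (95%% CI: %.3f, %.3f), p = %.3g\n",
              x$term, x$coefficient, x$ci_low, x$ci_high, x$p_value))
  if (length(x$covariates) > 0)
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ctb_reg <- function(object, ...) stats::setNames(object$coefficient, object$term)

#' @export
confint.ctb_reg <- function(object, ...) c(object$ci_low, object$ci_high)

#' @export
summary.ctb_reg <- function(object, ...) summary(object$fit, ...)

#' @export
predict.ctb_reg <- function(object, ...) stats::predict(object$fit, ...)

#' @export
residuals.ctb_reg <- function(object, ...) stats::residuals(object$fit, ...)

# ---- restricted cubic splines -------------------------------------------

rcs_quantile_probs <- function(k) {
  switch(as.character(k),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
         "7" = c(0.025, 0.1833, 0.3417, 0.50, 0.6583, 0.8167, 0.975),
         seq(0.05, 0.95, length.out = k))
}

rcs_basis <- function(x, knots) {
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  X <- matrix(0, length(x), k - 1L)
  X[, 1] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    X[, j + 1L] <- (pos3(x - tj) -
                      pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                      pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(X) <- paste0("rcs", seq_len(k - 1L))
  X
}

#' Restricted cubic spline design
#'
#' Truncated-power restricted cubic spline basis: with `k` knots it yields
#' `k - 1` regression columns (the linear term plus `k - 2` cubic terms),
#' piecewise cubic with continuous second derivatives, and linear beyond the
#' boundary knots. Knots default to the conventional quantiles of `x` (for 3
#' knots: the 10th, 50th and 90th percentiles).
#'
#' @param x numeric predictor.
#' @param n_knots number of knots (3 or more).
#' @param knots explicit knot locations (overrides `n_knots`).
#' @return `"ctb_rcs_basis"`: list with `knots` and the design matrix `X`.
#' @export
rcs_design <- function(x, n_knots = 3L, knots = NULL) {
  if (is.null(knots)) {
    if (n_knots < 3) stop_input("a restricted cubic spline needs at least 3 knots")
    if (length(unique(x)) < n_knots)
      stop_input("fewer distinct x values than requested knots")
    knots <- unname(stats::quantile(x, rcs_quantile_probs(n_knots), type = 7))
  }
  knots <- sort(knots)
  if (anyDuplicated(knots)) stop_input("duplicate knots")
  structure(list(knots = knots, X = rcs_basis(x, knots)),
            class = "ctb_rcs_basis")
}

#' Fit a restricted cubic spline regression
#'
#' Least-squares fit of `y` on the restricted-cubic-spline expansion of `x`;
#' the nonlinear sensitivity analysis companion to [fit_post_pre()]. With all
#' nonlinear coefficients at zero the fit reduces exactly to the straight
#' line.
#'
#' @inheritParams rcs_design
#' @param y response.
#' @return `"ctb_rcs"` with `predict()` and `plot()` methods.
#' @examples
#' x <- seq(0, 10, length.out = 50)
#' f <- fit_rcs(x, sin(x) + 0.2 * x)
#' max(abs(predict(f, x) - (sin(x) + 0.2 * x)))
#' @export
fit_rcs <- function(x, y, n_knots = 3L, knots = NULL) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  des <- rcs_design(x, n_knots, knots)
  fit <- stats::lm(y ~ des$X)
  structure(list(knots = des$knots, fit = fit,
                 coefficients = stats::coef(fit), x = x, y = y),
            class = "ctb_rcs")
}

#' @export
predict.ctb_rcs <- function(object, newx = NULL, ...) {
  if (is.null(newx)) return(stats::fitted(object$fit))
  X <- rcs_basis(newx, object$knots)
  drop(cbind(1, X) %*% object$coefficients)
}

#' @export
print.ctb_rcs <- function(x, ...) {
  cat(sprintf("Restricted cubic spline fit: %d knots at %s (n = %d)\n",
              length(x$knots), paste(signif(x$knots, 4), collapse = ", "),
              length(x$x)))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
plot.ctb_rcs <- function(x, ...) {
  ord <- order(x$x)
  graphics::plot(x$x, x$y, xlab = "pre-injury value", ylab = "post-injury value",
                 pch = 16, col = "grey50", ...)
  graphics::lines(x$x[ord], stats::fitted(x$fit)[ord], lwd = 2)
  graphics::abline(v = x$knots, lty = 3)
  invisible(x)
}

# ---- ANOVA of return-to-sport time --------------------------------------

#' One-way ANOVA of days to return to sport by body region
#'
#' Fixed-effects one-way analysis of variance (via [stats::lm]/[stats::anova])
#' comparing mean days to return across injury regions; with two groups the F
#' statistic equals the squared pooled two-sample t statistic.
#'
#' @param days numeric vector of days to return to sport.
#' @param group group labels (body regions), parallel to `days`.
#' @return `"ctb_anova"`: group labels, means, SDs and sizes, `f_statistic`,
#'   `p_value`, `df_between`, `df_within`.
#' @export
anova_return_days <- function(days, group) {
  ok <- stats::complete.cases(days, group)
  days <- days[ok]; group <- factor(group[ok])
  sizes <- table(group)
  if (length(sizes) < 2) stop_input("at least 2 groups are required")
  if (any(sizes < 2)) stop_input("every group needs at least 2 observations")
  fit <- stats::lm(days ~ group)
  a <- stats::anova(fit)
  structure(list(groups = names(sizes),
                 n = as.integer(sizes),
                 means = as.numeric(tapply(days, group, mean)),
                 sds = as.numeric(tapply(days, group, stats::sd)),
                 f_statistic = a[["F value"]][1],
                 p_value = a[["Pr(>F)"]][1],
                 df_between = a[["Df"]][1],
                 df_within = a[["Df"]][2]),
            class = "ctb_anova")
}

#' @export
print.ctb_anova <- function(x, ...) {
  cat("One-way ANOVA of days to return to sport\n")
  for (i in seq_along(x$groups))
    cat(sprintf("  %-18s %s (n = %d)\n", x$groups[i],
                fmt_mean_sd(x$means[i], x$sds[i], 0), x$n[i]))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3f\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}

# ---- model battery over a cohort ----------------------------------------

#' Fit the full prognostic model battery for a cohort
#'
#' Crude post-on-pre regressions for season minutes, points and rebounds in
#' each post-injury year; minutes-controlled models for points and rebounds;
#' the same crude models on the knee-only stratum; the covariate-adjusted
#' model; restricted-cubic-spline sensitivity fits; and the ANOVA of days to
#' return by region. Strata too small for a model are skipped.
#'
#' @param cohort a `"ctb_cohort"`.
#' @param game_records game-record data frame.
#' @param years post-injury years to model.
#' @return list with `results` (one row per fitted model: `model_id`,
#'   `metric`, `year`, `stratum`, `coefficient`, `ci_low`, `ci_high`,
#'   `p_value`, `n`), `fits` (the model objects), `anova` and `rcs_fits`.
#' @export
cohort_models <- function(cohort, game_records, years = c(1L, 2L)) {
  perf <- cohort_performance(cohort, game_records)
  metrics <- c("minutes_total", "points_total", "rebounds_total")
  entries <- cohort$entries
  results <- list()
  fits <- list()
  rcs_fits <- list()

  pairs_for <- function(stratum, yr) {
    keep <- if (stratum == "overall") rep(TRUE, nrow(entries)) else
      entries$body_region == stratum
    pids <- entries$player_id[keep]
    pre <- perf[perf$slot == "pre" & perf$player_id %in% pids, , drop = FALSE]
    post <- perf[perf$slot == paste0("post", yr) & perf$player_id %in% pids &
                   !is.na(perf$games_played), , drop = FALSE]
    idx <- match(post$player_id, pre$player_id)
    list(pre = pre[idx, , drop = FALSE], post = post)
  }
  push <- function(id, reg, stratum) {
    if (is.null(reg)) return()
    fits[[id]] <<- reg
    results[[length(results) + 1L]] <<- data.frame(
      model_id = reg$model_id, metric = reg$metric, year = reg$year,
      stratum = stratum, coefficient = reg$coefficient, ci_low = reg$ci_low,
      ci_high = reg$ci_high, p_value = reg$p_value, n = reg$n,
      stringsAsFactors = FALSE)
  }
  try_fit <- function(expr) tryCatch(expr, ctb_input_error = function(e) NULL)

  for (stratum in c("overall", "knee")) {
    for (yr in years) {
      pp <- pairs_for(stratum, yr)
      for (m in metrics)
        push(paste("post_pre", stratum, m, yr, sep = "."),
             try_fit(fit_post_pre(pp$pre[[m]], pp$post[[m]], m, yr)), stratum)
      for (m in c("points_total", "rebounds_total"))
        push(paste("per_minute", stratum, m, yr, sep = "."),
             try_fit(fit_per_minute(pp$pre[[m]], pp$post[[m]],
                                    pp$post$minutes_total, metric = m, year = yr)),
             stratum)
    }
  }

  for (yr in years) {
    pp <- pairs_for("overall", yr)
    idx <- match(pp$post$player_id, entries$player_id)
    for (m in metrics) {
      d <- data.frame(pre = pp$pre[[m]], post = pp$post[[m]],
                      age = entries$age_at_injury[idx],
                      seasons = entries$seasons_played_at_injury[idx],
                      year_of_injury = entries$index_season[idx],
                      region = entries$body_region[idx],
                      position = entries$position[idx])
      push(paste("adjusted", m, yr, sep = "."),
           try_fit(fit_adjusted(d, m, yr)), "overall")
      rcs_fits[[paste("rcs", m, yr, sep = ".")]] <-
        try_fit(fit_rcs(pp$pre[[m]], pp$post[[m]]))
    }
  }

  anova_res <- try_fit(anova_return_days(entries$days_to_return,
                                         entries$body_region))

  list(results = if (length(results) > 0) do.call(rbind, results) else NULL,
       fits = fits, rcs_fits = rcs_fits, anova = anova_res)
}
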