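# Season performance aggregates, return-to-preinjury classification, and
# prevalence estimation with Wald confidence intervals.

Z_95 <- 1.959964

#' Performance metrics tracked per season
#'
#' Season totals and per-game values over a player's box-score lines: games
#' played, games started, minutes, points, rebounds and field-goal attempts.
#'
#' @return character vector of metric labels.
#' @export
performance_metrics <- function() {
  c("games_played", "games_started", "minutes_total", "minutes_per_game",
    "points_total", "points_per_game", "rebounds_total", "rebounds_per_game",
    "fga_total")
}

#' Aggregate one player-season from box-score lines
#'
#' @param game_records game-record data frame.
#' @param player_id,season_id the player-season to aggregate.
#' @return one-row data frame of season totals and per-game values (athlete
#'   game exposures equal games played), or `NULL` when the player has no
#'   game in that season (per-game values would divide by zero).
#' @examples
#' g <- data.frame(player_id = "A", season_id = "2018",
#'                 game_date = as.Date("2017-11-01") + 0:1, team_id = "T",
#'                 started = TRUE, minutes = c(30, 20), points = c(12, 8),
#'                 rebounds = c(4, 2), field_goals_attempted = c(9, 7))
#' season_aggregates(g, "A", "2018")
#' @export
season_aggregates <- function(game_records, player_id, season_id) {
  g <- game_records[game_records$player_id == player_id &
                      game_records$season_id == as.character(season_id), ,
                    drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  n <- nrow(g)
  data.frame(player_id = player_id, season_id = as.character(season_id),
             games_played = n,
             games_started = sum(g$started),
             minutes_total = sum(g$minutes),
             minutes_per_game = sum(g$minutes) / n,
             points_total = sum(g$points),
             points_per_game = sum(g$points) / n,
             rebounds_total = sum(g$rebounds),
             rebounds_per_game = sum(g$rebounds) / n,
             fga_total = sum(g$field_goals_attempted),
             athlete_game_exposures = n,
             stringsAsFactors = FALSE)
}

# bulk variant: one row per (player, season) present in the records
season_aggregates_all <- function(game_records) {
  key <- paste(game_records$player_id, game_records$season_id, sep = "\r")
  num <- rowsum(data.frame(started = as.numeric(game_records$started),
                           minutes = game_records$minutes,
                           points = game_records$points,
                           rebounds = game_records$rebounds,
                           fga = game_records$field_goals_attempted,
                           n = 1), key)
  ids <- do.call(rbind, strsplit(rownames(num), "\r", fixed = TRUE))
  data.frame(player_id = ids[, 1], season_id = ids[, 2],
             games_played = as.integer(num$n),
             games_started = as.integer(num$started),
             minutes_total = num$minutes,
             minutes_per_game = num$minutes / num$n,
             points_total = num$points,
             points_per_game = num$points / num$n,
             rebounds_total = num$rebounds,
             rebounds_per_game = num$rebounds / num$n,
             fga_total = num$fga,
             athlete_game_exposures = as.integer(num$n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Did a player return to preinjury performance on a metric?
#'
#' The default rule is meet-or-exceed: the post-injury season value must be
#' at least the pre-injury season value. A tolerance `tau` relaxes this to
#' `post >= (1 - tau) * pre`. The meet-or-exceed reading is the parameter-free
#' interpretation of "returned to the preinjury number of games"; it is a
#' package decision, configurable because the underlying construct has no
#' standard operational definition.
#'
#' @param pre,post one-row season aggregates (see [season_aggregates()]).
#' @param metric one of [performance_metrics()].
#' @param tolerance fraction of the pre-injury value the player may fall
#'   short by while still counting as returned (default 0).
#' @return logical.
#' @export
reached_preinjury <- function(pre, post, metric, tolerance = 0) {
  if (!metric %in% performance_metrics())
    stop_input(sprintf("unknown metric '%s'", metric))
  post[[metric]] >= (1 - tolerance) * pre[[metric]]
}

#' Binomial prevalence with a Wald 95% confidence interval
#'
#' `proportion = numerator / denominator`; the interval is the normal
#' approximation `p +/- z * sqrt(p (1 - p) / n)`, clipped to `[0, 1]`.
#' Reporting layers round to whole percent, half away from zero.
#'
#' @param numerator,denominator counts, `0 <= numerator <= denominator`,
#'   `denominator >= 1`.
#' @param level confidence level.
#' @param metric,year optional labels carried on the estimate.
#' @return `"ctb_prevalence"` list: `numerator`, `denominator`, `proportion`,
#'   `ci_low`, `ci_high`, `level`, plus the labels.
#' @examples
#' prevalence_ci(58, 196)   # 30% (23, 36)
#' @export
prevalence_ci <- function(numerator, denominator, level = 0.95,
                          metric = NA_character_, year = NA_integer_) {
  if (denominator < 1) stop_input("'denominator' must be at least 1")
  if (numerator < 0 || numerator > denominator)
    stop_input("'numerator' must lie in [0, denominator]")
  p <- numerator / denominator
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / denominator)
  structure(list(numerator = numerator, denominator = denominator,
                 proportion = p,
                 ci_low = max(0, p - half), ci_high = min(1, p + half),
                 level = level, metric = metric, year = year),
            class = "ctb_prevalence")
}

#' Format a prevalence estimate the way surveillance tables print it
#'
#' @param x a `"ctb_prevalence"` object.
#' @return string like `"30% (23, 36)"` (whole percent, half away from zero).
#' @export
format_prevalence <- function(x) {
  sprintf("%d%% (%d, %d)",
          round_half_away(100 * x$proportion),
          round_half_away(100 * x$ci_low),
          round_half_away(100 * x$ci_high))
}

#' @export
print.ctb_prevalence <- function(x, ...) {
  lab <- if (!is.na(x$metric)) paste0(x$metric,
                                      if (!is.na(x$year)) paste0(", year ", x$year), ": ") else ""
  cat(sprintf("%s%s  [%d/%d, Wald %.0f%% CI]\n", lab, format_prevalence(x),
              x$numerator, x$denominator, 100 * x$level))
  invisible(x)
}

# per-entry, per-slot (pre/post1/post2) season aggregates for a cohort
cohort_performance <- function(cohort, game_records) {
  entries <- cohort$entries
  agg <- season_aggregates_all(game_records)
  out <- list()
  for (slot in c("pre", "post1", "post2")) {
    s <- entries[[paste0(slot, "_season")]]
    idx <- match(paste(entries$player_id, s), paste(agg$player_id, agg$season_id))
    rows <- agg[idx, , drop = FALSE]
    rows$player_id <- entries$player_id
    rows$slot <- slot
    rows$body_region <- entries$body_region
    out[[slot]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Descriptive mean (SD) performance table by season slot
#'
#' One row per metric and season slot (pre-injury, first and second
#' post-injury seasons); the second post-injury column is computed on
#' complete cases only (players who actually played that season). SDs use the
#' sample (n - 1) convention.
#'
#' @param cohort a `"ctb_cohort"`.
#' @param game_records game-record data frame.
#' @param metrics metric labels, defaults to [performance_metrics()].
#' @return data frame: `metric`, `slot`, `n`, `mean`, `sd`.
#' @export
descriptive_table <- function(cohort, game_records, metrics = performance_metrics()) {
  if (nrow(cohort$entries) == 0) stop_input("cohort is empty")
  perf <- cohort_performance(cohort, game_records)
  out <- list()
  for (slot in c("pre", "post1", "post2")) {
    rows <- perf[perf$slot == slot & !is.na(perf$games_played), , drop = FALSE]
    for (m in metrics) {
      v <- rows[[m]]
      out[[length(out) + 1L]] <- data.frame(
        metric = m, slot = slot, n = length(v),
        mean = if (length(v) > 0) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Prevalence of return to preinjury performance, by stratum, metric and year
#'
#' One estimate per (overall plus body-region stratum) x metric x year.
#' Year-1 denominators are players with a first post-injury season; year-2
#' denominators players with a second. Empty strata yield a flagged row with
#' no estimate rather than an error.
#'
#' @inheritParams descriptive_table
#' @param years which post-injury years to tabulate.
#' @param tolerance passed to [reached_preinjury()].
#' @return data frame: `stratum`, `metric`, `year`, `numerator`,
#'   `denominator`, `proportion`, `ci_low`, `ci_high`.
#' @export
prevalence_table <- function(cohort, game_records,
                             metrics = performance_metrics(),
                             years = c(1L, 2L), tolerance = 0) {
  perf <- cohort_performance(cohort, game_records)
  strata <- cohort$strata_counts$stratum
  out <- list()
  for (st in strata) {
    keep <- if (st == "overall") rep(TRUE, nrow(cohort$entries)) else
      cohort$entries$body_region == st
    pids <- cohort$entries$player_id[keep]
    pre <- perf[perf$slot == "pre" & perf$player_id %in% pids, , drop = FALSE]
    for (yr in years) {
      slot <- paste0("post", yr)
      post <- perf[perf$slot == slot & perf$player_id %in% pids &
                     !is.na(perf$games_played), , drop = FALSE]
      idx <- match(post$player_id, pre$player_id)
      for (m in metrics) {
        denom <- nrow(post)
        if (denom == 0) {
          out[[length(out) + 1L]] <- data.frame(
            stratum = st, metric = m, year = yr, numerator = NA_integer_,
            denominator = 0L, proportion = NA_real_, ci_low = NA_real_,
            ci_high = NA_real_, stringsAsFactors = FALSE)
          next
        }
        num <- sum(post[[m]] >= (1 - tolerance) * pre[[m]][idx])
        est <- prevalence_ci(num, denom, metric = m, year = yr)
        out[[length(out) + 1L]] <- data.frame(
          stratum = st, metric = m, year = yr, numerator = num,
          denominator = denom, proportion = est$proportion,
          ci_low = est$ci_low, ci_high = est$ci_high,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
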