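test_that("season aggregates are exact sums and ratios over box-score lines", {
  sched <- toy_schedule(2)
  g <- toy_games("A", sched, 1:2, minutes = c(30, 20), points = c(12, 8))
  agg <- season_aggregates(g, "A", "2018")
  expect_identical(agg$minutes_total, 50)
  expect_identical(agg$points_per_game, 10)
  expect_identical(agg$games_played, 2L)
  expect_identical(agg$athlete_game_exposures, 2L)

  one <- season_aggregates(g[1, ], "A", "2018")
  expect_identical(one$minutes_per_game, one$minutes_total)
  expect_identical(one$points_per_game, one$points_total)

  expect_null(season_aggregates(g, "A", "1999"))
})

test_that("bulk aggregation matches a brute-force per-player re-summation", {
  lg <- generate_league(synthetic_config(n_teams = 4, games_per_team = 20,
                                         n_seasons = 2, roster_size = 5,
                                         injury_hazard = 0.02, seed = 8))
  gr <- lg$game_records
  bulk <- courtback:::season_aggregates_all(gr)
  for (i in sample(nrow(bulk), 10)) {
    rows <- gr[gr$player_id == bulk$player_id[i] &
                 gr$season_id == bulk$season_id[i], ]
    expect_equal(bulk$minutes_total[i], sum(rows$minutes))
    expect_equal(bulk$points_total[i], sum(rows$points))
    expect_identical(bulk$games_played[i], nrow(rows))
    expect_equal(bulk$rebounds_per_game[i], mean(rows$rebounds))
  }
})

test_that("return to preinjury performance is meet-or-exceed with an optional tolerance", {
  pre <- list(games_played = 65, minutes_total = 1700)
  expect_true(reached_preinjury(pre, pre, "games_played"))
  expect_true(reached_preinjury(pre, pre, "minutes_total"))
  expect_false(reached_preinjury(pre, list(games_played = 64), "games_played"))
  expect_true(reached_preinjury(pre, list(games_played = 59), "games_played",
                                tolerance = 0.10))          # 59 >= 58.5
  expect_error(reached_preinjury(pre, pre, "assists"), class = "ctb_input_error")
  # monotone in the post value at fixed pre
  hits <- vapply(60:70, function(v)
    reached_preinjury(pre, list(games_played = v), "games_played"), logical(1))
  expect_true(!is.unsorted(hits))
})

test_that("Wald prevalence intervals reproduce printed worked examples after rounding", {
  expect_identical(format_prevalence(prevalence_ci(58, 196)), "30% (23, 36)")
  expect_identical(format_prevalence(prevalence_ci(48, 130)), "37% (29, 45)")
  p0 <- prevalence_ci(0, 10)
  expect_identical(format_prevalence(p0), "0% (0, 0)")
  expect_identical(p0$ci_low, 0)
  full <- prevalence_ci(10, 10)
  expect_identical(full$ci_high, 1)                  # clipped to [0, 1]
  expect_error(prevalence_ci(5, 0), class = "ctb_input_error")
  expect_error(prevalence_ci(11, 10), class = "ctb_input_error")
})

test_that("Wald interval width shrinks as 1/sqrt(n) at fixed proportion", {
  w <- vapply(c(50, 200, 800), function(n) {
    est <- prevalence_ci(round(0.3 * n), n)
    est$ci_high - est$ci_low
  }, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 1e-12)
  expect_equal(w[2] / w[3], 2, tolerance = 1e-12)
})

# a two-player cohort with fully hand-computable seasons
hand_cohort <- function() {
  g <- list()
  for (p in c("P1", "P2")) {
    mult <- if (p == "P1") 1 else 2
    for (s in c(2016, 2017, 2018, 2019, 2020)) {
      idx <- if (s == 2018) 1:2 else 1:4
      start <- as.Date(sprintf("%d-11-01", s - 1))
      g[[paste(p, s)]] <- data.frame(
        player_id = p, season_id = as.character(s),
        game_date = start + idx - 1, team_id = "T01", started = TRUE,
        minutes = 20 * mult, points = 10 * mult, rebounds = 4 * mult,
        field_goals_attempted = 8 * mult, stringsAsFactors = FALSE)
    }
  }
  games <- do.call(rbind, g)
  ev <- rbind(
    toy_event("P1", "2017-11-03", ret = "2018-11-01", games_missed = 16,
              season = "2018", severity = "Severe", region = "knee"),
    toy_event("P2", "2017-11-03", ret = "2018-11-01", games_missed = 16,
              season = "2018", severity = "Severe", region = "ankle"))
  ev$event_id <- c("P1#1", "P2#1")
  list(cohort = build_cohort(ev, games), games = games)
}

test_that("descriptive tables report hand-computed means and sample SDs", {
  hc <- hand_cohort()
  tab <- descriptive_table(hc$cohort, hc$games)
  pre_min <- tab[tab$metric == "minutes_total" & tab$slot == "pre", ]
  # P1: 4 games x 20 = 80; P2: 4 x 40 = 160
  expect_identical(pre_min$mean, 120)
  expect_equal(pre_min$sd, sd(c(80, 160)))
  pre_ppg <- tab[tab$metric == "points_per_game" & tab$slot == "pre", ]
  expect_identical(pre_ppg$mean, 15)

  # single-player cohort: means are that player's values, sample SD undefined
  solo <- hc$cohort
  solo$entries <- solo$entries[1, , drop = FALSE]
  tab1 <- descriptive_table(solo, hc$games)
  expect_identical(tab1$mean[tab1$metric == "minutes_total" & tab1$slot == "pre"], 80)
  expect_true(is.na(tab1$sd[tab1$metric == "minutes_total" & tab1$slot == "pre"]))
})

test_that("prevalence tables count returners per stratum with cohort denominators", {
  hc <- hand_cohort()
  tab <- prevalence_table(hc$cohort, hc$games)
  ov <- tab[tab$stratum == "overall" & tab$year == 1 &
              tab$metric == "minutes_total", ]
  # both players repeat their pre-injury season exactly: prevalence 100%
  expect_identical(ov$numerator, 2L)
  expect_identical(ov$denominator, 2L)
  expect_identical(ov$proportion, 1)
  # strata denominators match the cohort strata counts
  sc <- hc$cohort$strata_counts
  for (st in sc$stratum) {
    d <- tab[tab$stratum == st & tab$year == 1 & tab$metric == "games_played", ]
    expect_identical(d$denominator, sc$n_post1[sc$stratum == st])
  }
  # empty stratum rows are flagged, not estimated
  gh <- tab[tab$stratum == "groin/hip/thigh" & tab$year == 1, ]
  expect_true(all(gh$denominator == 0))
  expect_true(all(is.na(gh$proportion)))
})

test_that("a planted minutes decrement shows up in the post-injury descriptive column", {
  lg <- generate_league(synthetic_config(n_teams = 10, games_per_team = 60,
                                         n_seasons = 3, roster_size = 10,
                                         injury_hazard = 0.012,
                                         severity_mix = c(Slight = 0.1, Minor = 0.1,
                                                          Moderate = 0.2, Severe = 0.6),
                                         decrement_y1 = 0.7, decrement_y2 = 0.85,
                                         dropout_prob = 0, seed = 71))
  ev <- classify_events(link_injury_events(lg$transactions, lg$game_records,
                                           lg$schedule)$events)
  cohort <- build_cohort(ev, lg$game_records, lg$roster)
  expect_gt(nrow(cohort$entries), 12)
  tab <- descriptive_table(cohort, lg$game_records)
  mpg <- function(slot) tab$mean[tab$metric == "minutes_per_game" & tab$slot == slot]
  expect_lt(abs(mpg("post1") / mpg("pre") - 0.7), 0.03)
  # season totals additionally lose the games the index injury spilled into year 1
  expect_lt(tab$mean[tab$metric == "minutes_total" & tab$slot == "post1"] /
              tab$mean[tab$metric == "minutes_total" & tab$slot == "pre"], 0.75)
})
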