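# convenience: one season of daily games for a hand-built player history
season_games <- function(player, season, idx = 1:10, n = 10) {
  start <- as.Date(sprintf("%d-11-01", as.integer(season) - 1L))
  data.frame(player_id = player, season_id = as.character(season),
             game_date = start + idx - 1L, team_id = "T01", started = TRUE,
             minutes = 24, points = 10, rebounds = 4,
             field_goals_attempted = 8, stringsAsFactors = FALSE)[seq_along(idx), ]
}

severe_event <- function(player, season, onset, ret, games_missed = 14) {
  toy_event(player, onset, ret = ret, games_missed = games_missed,
            season = season, severity = "Severe", region = "knee")
}

test_that("injuries spilling into the next season keep their index season", {
  games <- rbind(season_games("A", 2016), season_games("A", 2017),
                 season_games("A", 2018, idx = 1:3),
                 season_games("A", 2019), season_games("A", 2020))
  ev <- severe_event("A", "2018", "2017-11-04", "2018-11-01", games_missed = 20)
  s <- assign_seasons(ev, games)
  expect_identical(s$index_season, 2018L)
  expect_identical(s$pre_season, 2017L)
  expect_identical(s$post1_season, 2019L)   # return fell in the next season
  expect_identical(s$post2_season, 2020L)
})

test_that("a within-season return takes the next season played as year 1", {
  games <- rbind(season_games("A", 2017), season_games("A", 2018, idx = c(1:3, 20)),
                 season_games("A", 2019))
  ev <- severe_event("A", "2018", "2017-11-04", "2017-11-20", games_missed = 16)
  s <- assign_seasons(ev, games)
  expect_identical(s$index_season, 2018L)
  expect_identical(s$post1_season, 2019L)
  expect_true(is.na(s$post2_season))

  # never plays again: no post season
  games2 <- rbind(season_games("A", 2017), season_games("A", 2018, idx = 1:3))
  ev2 <- severe_event("A", "2018", "2017-11-04", NA)
  s2 <- assign_seasons(ev2, games2)
  expect_true(is.na(s2$post1_season))
  expect_null(assign_seasons(toy_event("A", "2017-11-04", games_missed = 2,
                                       severity = "Minor", region = "knee"),
                             games2))
})

test_that("eligibility rules fire on short careers, pre-season injuries and reinjuries", {
  games3 <- rbind(season_games("A", 2017), season_games("A", 2018),
                  season_games("A", 2019))
  ev <- severe_event("A", "2018", "2017-11-15", "2018-11-01")
  s <- assign_seasons(ev, rbind(games3, season_games("A", 2018, idx = 1:14)[11:14, ]))

  # two seasons only
  games2 <- rbind(season_games("A", 2018, idx = 1:5), season_games("A", 2019))
  s2 <- assign_seasons(ev, games2)
  chk <- check_eligibility(s2, ev, games2, NULL)
  expect_true("under_3_seasons" %in% chk$reasons)
  expect_true("no_prior_season_play" %in% chk$reasons)
  expect_false(chk$eligible)

  # a Moderate injury in the season before the index disqualifies
  pre_inj <- toy_event("A", "2016-11-03", ret = "2016-11-09", games_missed = 5,
                       season = "2017", severity = "Moderate", region = "other")
  chk <- check_eligibility(s, rbind(ev, pre_inj), games3, NULL)
  expect_identical(chk$reasons, "prior_season_injury_gt_minor")
  # ... but a Minor one is tolerated
  pre_inj$games_missed <- 3
  pre_inj$severity <- "Minor"
  chk <- check_eligibility(s, rbind(ev, pre_inj), games3, NULL)
  expect_true(chk$eligible)

  # reinjury within 14 days of return (day 14 inclusive)
  for (d in c(10, 14)) {
    re <- toy_event("A", as.Date("2018-11-01") + d, games_missed = 2,
                    season = "2019", severity = "Minor", region = "ankle")
    chk <- check_eligibility(s, rbind(ev, re), games3, NULL)
    expect_true("reinjury_within_14d" %in% chk$reasons, info = paste("day", d))
  }
  re15 <- toy_event("A", as.Date("2018-11-01") + 15, games_missed = 2,
                    season = "2019", severity = "Minor", region = "ankle")
  chk <- check_eligibility(s, rbind(ev, re15), games3, NULL)
  expect_false("reinjury_within_14d" %in% chk$reasons)
})

test_that("a hand-built three-player history yields the expected cohort", {
  # P1: clean severe knee injury, plays both following seasons
  g1 <- rbind(season_games("P1", 2016), season_games("P1", 2017),
              season_games("P1", 2018, idx = 1:4), season_games("P1", 2019),
              season_games("P1", 2020))
  e1 <- severe_event("P1", "2018", "2017-11-05", "2018-11-01", 20)
  e1$event_id <- "P1#1"
  # P2: severe ankle injury but reinjured 7 days after return
  g2 <- g1; g2$player_id <- "P2"
  e2 <- severe_event("P2", "2018", "2017-11-05", "2018-11-01", 20)
  e2$body_region <- "ankle"
  e2b <- toy_event("P2", "2018-11-08", games_missed = 1, season = "2019",
                   severity = "Slight", region = "ankle")
  # P3: severe knee injury, never plays again
  g3 <- rbind(season_games("P3", 2016), season_games("P3", 2017),
              season_games("P3", 2018, idx = 1:4))
  e3 <- severe_event("P3", "2018", "2017-11-05", NA, 6)
  e3$games_missed <- 14

  cohort <- build_cohort(rbind(e1, e2, e2b, e3),
                         rbind(g1, g2, g3))
  expect_identical(cohort$entries$player_id, c("P1", "P3"))
  expect_identical(cohort$entries$post1_season, c(2019L, NA_integer_))
  expect_identical(cohort$entries$post2_season, c(2020L, NA_integer_))
  expect_true("reinjury_within_14d" %in%
                cohort$exclusions$reason[cohort$exclusions$player_id == "P2"])
  expect_true("no_post_season_play" %in%
                cohort$exclusions$reason[cohort$exclusions$player_id == "P3"])
  sc <- cohort$strata_counts
  expect_identical(sc$n_severe[sc$stratum == "overall"], 2L)
  expect_identical(sc$n_post1[sc$stratum == "overall"], 1L)
  expect_identical(sc$n_post2[sc$stratum == "overall"], 1L)
  expect_identical(sc$n_severe[sc$stratum == "knee"], 2L)
  expect_identical(sc$n_severe[sc$stratum == "ankle"], 0L)
})

test_that("each player contributes exactly one index event and denominators nest", {
  lg <- generate_league(synthetic_config(n_teams = 8, games_per_team = 40,
                                         n_seasons = 4, roster_size = 10,
                                         injury_hazard = 0.01,
                                         severity_mix = c(Slight = 0.2, Minor = 0.2,
                                                          Moderate = 0.2, Severe = 0.4),
                                         seed = 61))
  ev <- classify_events(link_injury_events(lg$transactions, lg$game_records,
                                           lg$schedule)$events)
  cohort <- build_cohort(ev, lg$game_records, lg$roster)
  expect_false(anyDuplicated(cohort$entries$player_id) > 0)
  sc <- cohort$strata_counts
  expect_true(all(sc$n_post2 <= sc$n_post1))
  expect_true(all(sc$n_post1 <= sc$n_severe))
  ov <- sc[sc$stratum == "overall", ]
  expect_identical(ov$n_severe, sum(sc$n_severe[sc$stratum != "overall"]))
})

test_that("second-season attrition tracks the planted dropout probability", {
  lg <- generate_league(synthetic_config(n_teams = 20, games_per_team = 40,
                                         n_seasons = 5, roster_size = 12,
                                         injury_hazard = 0.01,
                                         severity_mix = c(Slight = 0.05, Minor = 0.05,
                                                          Moderate = 0.10, Severe = 0.80),
                                         dropout_prob = 0.33, seed = 62))
  ev <- classify_events(link_injury_events(lg$transactions, lg$game_records,
                                           lg$schedule)$events)
  cohort <- build_cohort(ev, lg$game_records, lg$roster)
  e <- cohort$entries
  # attrition is observable only where a further season of data exists
  at_risk <- e[!is.na(e$post1_season) & e$post1_season < max(e$post1_season, na.rm = TRUE), ]
  expect_gt(nrow(at_risk), 40)
  attrition <- mean(is.na(at_risk$post2_season))
  mc <- 3 * sqrt(0.33 * 0.67 / nrow(at_risk))
  expect_lt(abs(attrition - 0.33), mc + 0.02)
})
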