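# Small in-code fixture builders shared across test files.

# a one-team schedule of consecutive daily games
toy_schedule <- function(n_games, team = "T01", season = "2018",
                         start = as.Date("2017-11-01")) {
  data.frame(team_id = team, season_id = season,
             game_date = start + seq_len(n_games) - 1L,
             stringsAsFactors = FALSE)
}

toy_games <- function(player, schedule, played_idx, minutes = 24,
                      points = 10, rebounds = 4, fga = 8, started = TRUE) {
  data.frame(player_id = player,
             season_id = schedule$season_id[played_idx],
             game_date = schedule$game_date[played_idx],
             team_id = schedule$team_id[played_idx],
             started = started, minutes = minutes, points = points,
             rebounds = rebounds, field_goals_attempted = fga,
             stringsAsFactors = FALSE)
}

toy_txn <- function(date, player, kind = "deactivate", team = "T01",
                    note = "sprained left ankle") {
  data.frame(date = as.Date(date), player_id = player, team_id = team,
             event_kind = kind, note = note, stringsAsFactors = FALSE)
}

# an event table row in the shape link_injury_events() emits
toy_event <- function(player, onset, ret = NA, games_missed = 14,
                      season = "2018", note = "sprained left ankle",
                      severity = NULL, region = NULL) {
  ev <- data.frame(event_id = paste0(player, "#1"), player_id = player,
                   team_id = "T01", season_id = season,
                   onset_date = as.Date(onset),
                   return_date = if (is.na(ret)) as.Date(NA) else as.Date(ret),
                   games_missed = games_missed,
                   days_to_return = if (is.na(ret)) NA_integer_ else
                     as.integer(as.Date(ret) - as.Date(onset)),
                   note = note, stringsAsFactors = FALSE)
  if (!is.null(severity)) ev$severity <- severity
  if (!is.null(region)) ev$body_region <- region
  ev
}

# a random toy league configuration for oracle-equivalence sweeps
random_toy_config <- function(seed) {
  set.seed(seed)
  synthetic_config(
    n_teams = sample(c(2L, 4L), 1L),
    games_per_team = sample(8:20, 1L),
    n_seasons = sample(1:2, 1L),
    roster_size = sample(2:4, 1L),
    injury_hazard = stats::runif(1, 0.005, 0.05),
    severity_mix = c(Slight = 0.3, Minor = 0.3, Moderate = 0.25, Severe = 0.15),
    dropout_prob = stats::runif(1, 0, 0.5),
    seed = seed)
}
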