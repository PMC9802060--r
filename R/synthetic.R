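# Synthetic league generator: schedule, rosters, box scores, transaction log,
# and a ground-truth record of every injected injury, so that the full
# linkage -> classification -> cohort -> analysis pipeline can be exercised
# against known answers without any external data source.

SEVERITY_LEVELS <- c("Slight", "Minor", "Moderate", "Severe")
LE_REGIONS <- c("groin/hip/thigh", "knee", "ankle")
ALL_REGIONS <- c(LE_REGIONS, "other", "unknown")

# note templates; every phrase must resolve to its region under the default
# lexicon so injected events are recoverable from free text alone
NOTE_TEMPLATES <- list(
  "knee" = c("sprained right knee", "torn ACL", "meniscus tear",
             "patellar tendinitis", "bruised left knee"),
  "groin/hip/thigh" = c("strained groin", "hip flexor strain",
                        "strained left hamstring", "quad contusion",
                        "bruised right thigh"),
  "ankle" = c("sprained left ankle", "sprained right ankle",
              "Achilles tendinitis", "high ankle sprain"),
  "other" = c("sore lower back", "sprained right wrist",
              "strained shoulder", "broken finger")
)

#' Configuration for the synthetic league generator
#'
#' Bundles and validates every knob of [generate_league()]. Defaults describe
#' a 30-team league playing 82-game seasons, with player baselines anchored to
#' league-wide per-game averages of roughly 26 minutes, 11 points and 3.6
#' rebounds, a severity distribution spanning the four time-loss bands, and
#' post-injury decrement and dropout behaviour for severely injured players.
#'
#' @param n_teams number of teams; must be even (the round-robin scheduler
#'   gives every team one game per round date, which is what keeps
#'   games-per-team exact).
#' @param games_per_team regular-season games per team per season.
#' @param n_seasons number of consecutive seasons to simulate.
#' @param roster_size players per team; every rostered player appears in every
#'   team game unless injured or dropped out.
#' @param injury_hazard per player-game probability of sustaining a time-loss
#'   injury during a played game.
#' @param severity_mix named probability vector over
#'   `c("Slight","Minor","Moderate","Severe")`; must sum to 1.
#' @param severe_region_mix named probability vector over
#'   `c("groin/hip/thigh","knee","ankle")` for severe events; must sum to 1.
#'   Default follows the relative frequencies 39:111:46 observed among severe
#'   lower-extremity injuries in the professional game.
#' @param decrement_y1,decrement_y2 multiplicative factors in (0, 1.5] applied
#'   to a player's expected minutes per game after return from their first
#'   severe injury: `decrement_y1` for the remainder of the index season and
#'   the following season, `decrement_y2` thereafter. Defaults 0.72 and 0.83
#'   are the observed season-minutes ratios one and two years after severe
#'   lower-extremity injury.
#' @param dropout_prob probability, per subsequent season, that a severely
#'   injured player leaves the league (no further game records). Default 0.33
#'   matches the observed one-in-three second-season attrition.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @param anchor_year calendar year in which the first simulated season
#'   starts (season ids are keyed by end year, so the first season is
#'   `anchor_year + 1`).
#' @param mins_mean,mins_sd mean and SD of the truncated-normal (floor 0)
#'   distribution of player baseline minutes per game.
#' @param points_rate,rebounds_rate,fga_rate league-mean per-minute rates for
#'   points, rebounds and field-goal attempts.
#' @param points_cv,rebounds_cv,fga_cv coefficients of variation of the
#'   player-level gamma-distributed per-minute rates. The points and rebounds
#'   defaults reproduce the observed between-player per-game SDs (5.8 points,
#'   2.4 rebounds) once combined with the spread of baseline minutes.
#' @param concentration concentration of the per-game Beta minutes model;
#'   per-game minutes are `48 * Beta` with player-specific mean. 80 gives a
#'   within-player game-to-game SD of about 2.7 minutes.
#' @return a validated list of class `"ctb_config"`.
#' @seealso [generate_league()], [simulate_post_pre()]
#' @export
synthetic_config <- function(n_teams = 30L,
                             games_per_team = 82L,
                             n_seasons = 3L,
                             roster_size = 15L,
                             injury_hazard = 0.002,
                             severity_mix = c(Slight = 0.35, Minor = 0.30,
                                              Moderate = 0.22, Severe = 0.13),
                             severe_region_mix = c("groin/hip/thigh" = 0.20,
                                                   "knee" = 0.57,
                                                   "ankle" = 0.23),
                             decrement_y1 = 0.72,
                             decrement_y2 = 0.83,
                             dropout_prob = 0.33,
                             seed = 1L,
                             anchor_year = 2016L,
                             mins_mean = 25.8,
                             mins_sd = 8.1,
                             points_rate = 0.434,
                             rebounds_rate = 0.140,
                             fga_rate = 0.368,
                             points_cv = 0.41,
                             rebounds_cv = 0.59,
                             fga_cv = 0.35,
                             concentration = 80) {
  n_teams <- check_count(n_teams, "n_teams")
  if (n_teams %% 2L != 0L)
    stop_config("'n_teams' must be even: the round-robin schedule plays every team once per round date")
  games_per_team <- check_count(games_per_team, "games_per_team")
  n_seasons <- check_count(n_seasons, "n_seasons")
  roster_size <- check_count(roster_size, "roster_size")
  check_prob(injury_hazard, "injury_hazard")
  check_prob(dropout_prob, "dropout_prob")

  check_mix <- function(mix, levels, name) {
    if (!is.numeric(mix) || is.null(names(mix)) || !setequal(names(mix), levels))
      stop_config(sprintf("'%s' must be a named probability vector over {%s}",
                          name, paste(levels, collapse = ", ")))
    if (any(mix < 0 | mix > 1))
      stop_config(sprintf("'%s' entries must lie in [0, 1]", name))
    if (abs(sum(mix) - 1) > 1e-9)
      stop_config(sprintf("'%s' must sum to 1 (within 1e-9)", name))
    mix[levels]
  }
  severity_mix <- check_mix(severity_mix, SEVERITY_LEVELS, "severity_mix")
  severe_region_mix <- check_mix(severe_region_mix, LE_REGIONS, "severe_region_mix")

  for (nm in c("decrement_y1", "decrement_y2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1.5)
      stop_config(sprintf("'%s' must lie in (0, 1.5]", nm))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_config("'seed' must be a single integer")

  cfg <- list(n_teams = n_teams, games_per_team = games_per_team,
              n_seasons = n_seasons, roster_size = roster_size,
              injury_hazard = injury_hazard, severity_mix = severity_mix,
              severe_region_mix = severe_region_mix,
              decrement_y1 = decrement_y1, decrement_y2 = decrement_y2,
              dropout_prob = dropout_prob, seed = as.integer(seed),
              anchor_year = as.integer(anchor_year),
              mins_mean = mins_mean, mins_sd = mins_sd,
              points_rate = points_rate, rebounds_rate = rebounds_rate,
              fga_rate = fga_rate, points_cv = points_cv,
              rebounds_cv = rebounds_cv, fga_cv = fga_cv,
              concentration = concentration)
  class(cfg) <- "ctb_config"
  cfg
}

# every team plays one game on each of `games_per_team` consecutive round
# dates per season; pairings are irrelevant to any downstream statistic, so
# only the team-date grid is materialised
make_schedule <- function(config) {
  out <- vector("list", config$n_seasons)
  teams <- sprintf("T%02d", seq_len(config$n_teams))
  for (s in seq_len(config$n_seasons)) {
    start <- as.Date(sprintf("%d-10-15", config$anchor_year + s - 1L))
    dates <- start + seq_len(config$games_per_team) - 1L
    out[[s]] <- data.frame(
      team_id = rep(teams, each = config$games_per_team),
      season_id = as.character(config$anchor_year + s),
      game_date = rep(dates, times = config$n_teams),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# truncated normal via inverse-cdf, lower bound 0
rtnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

rgamma_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# per-game minutes: 48 * Beta with given mean (capped just under 48)
rminutes <- function(n, mean, concentration) {
  m <- pmin(mean, 46) / 48
  48 * stats::rbeta(n, m * concentration, (1 - m) * concentration)
}

draw_games_missed <- function(severity) {
  switch(severity,
         Slight = 1L,
         Minor = sample(2:3, 1L),
         Moderate = sample(4:13, 1L),
         Severe = 14L + stats::rnbinom(1L, size = 2, mu = 14))
}

#' Draw one or more box-score lines for a player
#'
#' Counting statistics are Poisson with expectation
#' `rate per minute x minutes x decrement`; zero minutes gives all zeros.
#'
#' @param player_baseline a list or one-row data frame with per-minute rates
#'   `points_rate`, `rebounds_rate`, `fga_rate`.
#' @param minutes_played nonnegative numeric vector of minutes, one per game.
#' @param decrement multiplicative factor (> 0) applied to the scoring rates.
#' @return data frame with integer columns `points`, `rebounds`,
#'   `field_goals_attempted`, one row per element of `minutes_played`.
#' @examples
#' b <- list(points_rate = 0.434, rebounds_rate = 0.140, fga_rate = 0.368)
#' draw_box_score(b, c(0, 25.8, 30))
#' @export
draw_box_score <- function(player_baseline, minutes_played, decrement = 1) {
  if (any(minutes_played < 0) || anyNA(minutes_played))
    stop_input("'minutes_played' must be nonnegative")
  if (!is.numeric(decrement) || decrement <= 0)
    stop_input("'decrement' must be positive")
  n <- length(minutes_played)
  data.frame(
    points = stats::rpois(n, player_baseline$points_rate * minutes_played * decrement),
    rebounds = stats::rpois(n, player_baseline$rebounds_rate * minutes_played * decrement),
    field_goals_attempted = stats::rpois(n, player_baseline$fga_rate * minutes_played * decrement)
  )
}

make_baselines <- function(config, player_ids, team_ids) {
  n <- length(player_ids)
  data.frame(
    player_id = player_ids,
    team_id = team_ids,
    mins_pg = pmin(rtnorm0(n, config$mins_mean, config$mins_sd), 46),
    points_rate = rgamma_cv(n, config$points_rate, config$points_cv),
    rebounds_rate = rgamma_cv(n, config$rebounds_rate, config$rebounds_cv),
    fga_rate = rgamma_cv(n, config$fga_rate, config$fga_cv),
    stringsAsFactors = FALSE
  )
}

make_roster_metadata <- function(config, baselines, season1_start) {
  n <- nrow(baselines)
  age0 <- stats::runif(n, 19, 34)
  height <- stats::rnorm(n, 200, 8)
  pos <- cut(height, breaks = stats::quantile(height, c(0, 1/3, 2/3, 1)),
             labels = c("guard", "forward", "center"), include.lowest = TRUE)
  data.frame(
    player_id = baselines$player_id,
    birth_date = season1_start - round(age0 * 365.25),
    height_cm = round(height, 1),
    weight_kg = round(stats::rnorm(n, 100, 10), 1),
    position = as.character(pos),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic league with known ground truth
#'
#' Simulates rosters, an 82-game-per-season schedule, per-game box scores, a
#' dated transaction log of roster deactivations/activations with free-text
#' injury notes, and roster metadata. Injuries occur only on played games
#' (with probability `injury_hazard` per player-game); the injured player then
#' misses a severity-dependent number of consecutive team games, the
#' deactivation transaction is dated at the first missed game, and the
#' activation at the return game. Severely injured players may drop out of
#' the league in any subsequent season, leaving all later absences (and, when
#' the dropout interrupts a rehabilitation, a missing return date). Ground
#' truth records every injected event with its realised games missed,
#' severity band, body region, and note text.
#'
#' @param config a [synthetic_config()] object.
#' @return an object of class `"ctb_league"`: a list with data frames
#'   `schedule` (team_id, season_id, game_date), `game_records` (one box-score
#'   line per played player-game), `transactions`, `roster`, and a
#'   `ground_truth` list (player baselines, injected `injuries`, `dropouts`,
#'   `n_hazard_draws`, and the config).
#' @examples
#' lg <- generate_league(synthetic_config(n_teams = 4, games_per_team = 10,
#'                                        n_seasons = 2, roster_size = 5,
#'                                        injury_hazard = 0.01, seed = 7))
#' lg
#' @export
generate_league <- function(config) {
  if (!inherits(config, "ctb_config")) config <- do.call(synthetic_config, config)
  set.seed(config$seed)

  schedule <- make_schedule(config)
  teams <- unique(schedule$team_id)
  # common round dates: identical for every team by construction
  team_dates <- sort(unique(schedule$game_date))
  date_season <- schedule$season_id[match(team_dates, schedule$game_date)]
  season_index <- match(date_season, sort(unique(date_season)))
  N <- length(team_dates)

  player_ids <- as.vector(vapply(seq_along(teams), function(i)
    sprintf("P%02d_%02d", i, seq_len(config$roster_size)), character(config$roster_size)))
  player_teams <- rep(teams, each = config$roster_size)
  baselines <- make_baselines(config, player_ids, player_teams)
  roster <- make_roster_metadata(config, baselines, min(team_dates))

  h <- config$injury_hazard
  games_list <- vector("list", length(player_ids))
  injury_rows <- list()
  dropout_rows <- list()
  txn_rows <- list()

  for (p in seq_along(player_ids)) {
    pid <- player_ids[p]
    played <- logical(N)
    inj <- list()
    idx <- 1L
    while (idx <= N) {
      if (h == 0) { played[idx:N] <- TRUE; break }
      gap <- stats::rgeom(1L, h)
      g <- idx + gap                      # injury occurs on played game g
      if (g >= N) { played[idx:N] <- TRUE; break }
      played[idx:g] <- TRUE
      severity <- sample(SEVERITY_LEVELS, 1L, prob = config$severity_mix)
      m <- draw_games_missed(severity)
      region <- if (severity == "Severe") {
        sample(LE_REGIONS, 1L, prob = config$severe_region_mix)
      } else {
        sample(c(LE_REGIONS, "other"), 1L, prob = c(0.22, 0.25, 0.28, 0.25))
      }
      note <- sample(NOTE_TEMPLATES[[region]], 1L)
      onset_idx <- g + 1L
      return_idx <- if (g + m + 1L <= N) g + m + 1L else NA_integer_
      inj[[length(inj) + 1L]] <- list(onset_idx = onset_idx, return_idx = return_idx,
                                      intended = m, severity_drawn = severity,
                                      region = region, note = note)
      if (is.na(return_idx)) break
      idx <- return_idx
    }

    # dropout: after the first drawn-severe injury, the player may leave the
    # league at the start of any subsequent season
    drop_from <- NA_integer_
    sev_idx <- which(vapply(inj, function(e) e$severity_drawn == "Severe", logical(1)))
    if (length(sev_idx) > 0 && config$dropout_prob > 0) {
      s0 <- season_index[inj[[sev_idx[1]]]$onset_idx]
      for (t in seq_len(config$n_seasons)) {
        if (t <= s0) next
        if (stats::runif(1L) < config$dropout_prob) { drop_from <- t; break }
      }
    }
    if (!is.na(drop_from)) {
      played[season_index >= drop_from] <- FALSE
      keep <- vapply(inj, function(e) season_index[e$onset_idx] < drop_from, logical(1))
      inj <- inj[keep]
      if (length(inj) > 0) {
        last <- inj[[length(inj)]]
        if (!is.na(last$return_idx) && season_index[last$return_idx] >= drop_from) {
          last$return_idx <- NA_integer_
          inj[[length(inj)]] <- last
        }
      }
      dropout_rows[[length(dropout_rows) + 1L]] <- data.frame(
        player_id = pid, from_season = sort(unique(date_season))[drop_from],
        stringsAsFactors = FALSE)
    }

    for (e in inj) {
      realized <- if (is.na(e$return_idx)) N - e$onset_idx + 1L else e$intended
      injury_rows[[length(injury_rows) + 1L]] <- data.frame(
        player_id = pid, team_id = player_teams[p],
        season_id = date_season[e$onset_idx],
        onset_date = team_dates[e$onset_idx],
        return_date = if (is.na(e$return_idx)) as.Date(NA) else team_dates[e$return_idx],
        games_missed = realized,
        intended_games_missed = e$intended,
        severity = as.character(classify_severity(realized)),
        intended_severity = e$severity_drawn,
        region = e$region, note = e$note,
        stringsAsFactors = FALSE)
      txn_rows[[length(txn_rows) + 1L]] <- data.frame(
        date = team_dates[e$onset_idx], player_id = pid, team_id = player_teams[p],
        event_kind = "deactivate", note = e$note, stringsAsFactors = FALSE)
      if (!is.na(e$return_idx))
        txn_rows[[length(txn_rows) + 1L]] <- data.frame(
          date = team_dates[e$return_idx], player_id = pid, team_id = player_teams[p],
          event_kind = "activate", note = "activated from injured list",
          stringsAsFactors = FALSE)
    }

    # box scores for played games, with post-severe-injury minutes decrement
    gi <- which(played)
    if (length(gi) > 0) {
      mult <- rep(1, length(gi))
      if (length(sev_idx) > 0) {
        first_sev <- inj_first_severe <- NULL
        # the first drawn-severe injury may have been truncated away by dropout;
        # decrement still keys on its onset, which is only kept when it happened
        sev_kept <- which(vapply(inj, function(e) e$severity_drawn == "Severe", logical(1)))
        if (length(sev_kept) > 0) {
          o <- inj[[sev_kept[1]]]$onset_idx
          s0 <- season_index[o]
          after <- gi > o
          mult[after & season_index[gi] <= s0 + 1L] <- config$decrement_y1
          mult[after & season_index[gi] > s0 + 1L] <- config$decrement_y2
        }
      }
      minutes <- rminutes(length(gi), baselines$mins_pg[p] * mult, config$concentration)
      box <- draw_box_score(baselines[p, ], minutes)
      p_start <- pmin(0.95, pmax(0.02, (baselines$mins_pg[p] - 12) / 24))
      games_list[[p]] <- data.frame(
        player_id = pid, season_id = date_season[gi],
        game_date = team_dates[gi], team_id = player_teams[p],
        started = stats::runif(length(gi)) < p_start * mult,
        minutes = round(minutes, 1),
        points = box$points, rebounds = box$rebounds,
        field_goals_attempted = box$field_goals_attempted,
        stringsAsFactors = FALSE)
    }
  }

  game_records <- do.call(rbind, games_list[!vapply(games_list, is.null, logical(1))])

  # benign non-injury transactions, one per team per season
  for (s in sort(unique(date_season))) {
    for (tm in teams) {
      pid <- sample(player_ids[player_teams == tm], 1L)
      txn_rows[[length(txn_rows) + 1L]] <- data.frame(
        date = sample(team_dates[date_season == s], 1L), player_id = pid,
        team_id = tm, event_kind = "other", note = "signed to 10-day contract",
        stringsAsFactors = FALSE)
    }
  }

  transactions <- if (length(txn_rows) > 0) do.call(rbind, txn_rows) else
    data.frame(date = as.Date(character()), player_id = character(),
               team_id = character(), event_kind = character(),
               note = character(), stringsAsFactors = FALSE)
  transactions <- transactions[order(transactions$date, transactions$player_id,
                                     transactions$event_kind), , drop = FALSE]
  rownames(transactions) <- NULL

  injuries <- if (length(injury_rows) > 0) do.call(rbind, injury_rows) else
    data.frame(player_id = character(), team_id = character(),
               season_id = character(), onset_date = as.Date(character()),
               return_date = as.Date(character()), games_missed = integer(),
               intended_games_missed = integer(), severity = character(),
               intended_severity = character(), region = character(),
               note = character(), stringsAsFactors = FALSE)
  dropouts <- if (length(dropout_rows) > 0) do.call(rbind, dropout_rows) else
    data.frame(player_id = character(), from_season = character(),
               stringsAsFactors = FALSE)

  out <- list(schedule = schedule, game_records = game_records,
              transactions = transactions, roster = roster,
              ground_truth = list(players = baselines, injuries = injuries,
                                  dropouts = dropouts,
                                  n_hazard_draws = nrow(game_records),
                                  config = config))
  class(out) <- "ctb_league"
  out
}

#' @export
print.ctb_league <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat("Synthetic league:", cfg$n_teams, "teams x", cfg$games_per_team,
      "games x", cfg$n_seasons, "seasons (seed", paste0(cfg$seed, ")\n"))
  cat("  players:", nrow(x$roster),
      "| box-score lines:", nrow(x$game_records),
      "| transactions:", nrow(x$transactions), "\n")
  inj <- x$ground_truth$injuries
  cat("  injected injuries:", nrow(inj))
  if (nrow(inj) > 0)
    cat(" (", paste(names(table(inj$severity)), table(inj$severity),
                    sep = ": ", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Simulate pre/post season pairs with a planted prognostic coefficient
#'
#' A focused generator for estimator-calibration studies. Pre-injury season
#' totals are drawn from the same player-baseline performance model as
#' [generate_league()]; the post-injury season is then drawn *conditionally on
#' the realised pre-injury season* with expectation `decrement x pre`, so the
#' planted decrement is exactly the population post-on-pre regression slope
#' for every metric. (In the mechanistic league generator the slope is
#' instead mildly attenuated by within-player noise, as in any
#' errors-in-variables setting.)
#'
#' @param n number of players (pairs).
#' @param decrement planted ratio of expected post-season to pre-season value.
#' @param games team games per season.
#' @param config a [synthetic_config()] supplying the baseline performance
#'   parameters (only those fields are used).
#' @return data frame with one row per player: `pre_minutes`, `post_minutes`,
#'   `pre_points`, `post_points`, `pre_rebounds`, `post_rebounds`.
#' @examples
#' set.seed(1)
#' d <- simulate_post_pre(50, decrement = 0.5)
#' coef(fit_post_pre(d$pre_minutes, d$post_minutes))
#' @export
simulate_post_pre <- function(n, decrement, games = 82L,
                              config = synthetic_config()) {
  if (!is.numeric(decrement) || decrement <= 0)
    stop_input("'decrement' must be positive")
  mu <- pmin(rtnorm0(n, config$mins_mean, config$mins_sd), 46)
  rp <- rgamma_cv(n, config$points_rate, config$points_cv)
  rr <- rgamma_cv(n, config$rebounds_rate, config$rebounds_cv)

  pre_min_pg <- matrix(rminutes(n * games, rep(mu, games), config$concentration),
                       nrow = n)
  pre_minutes <- rowSums(pre_min_pg)
  pre_points <- stats::rpois(n, rp * pre_minutes)
  pre_rebounds <- stats::rpois(n, rr * pre_minutes)

  post_mu <- pmin(decrement * pre_minutes / games, 46)
  post_min_pg <- matrix(rminutes(n * games, rep(post_mu, games), config$concentration),
                        nrow = n)
  post_minutes <- rowSums(post_min_pg)
  # counts get homoscedastic conditional noise (variance fixed at the Poisson
  # variance of the average player) so the planted slope is the estimand of a
  # correctly specified least-squares model; the league generator keeps
  # per-game Poisson counts instead
  draw_count <- function(mu) pmax(0, round(mu + stats::rnorm(n, 0, sqrt(mean(mu)))))
  post_points <- draw_count(decrement * pre_points)
  post_rebounds <- draw_count(decrement * pre_rebounds)

  data.frame(pre_minutes = pre_minutes, post_minutes = post_minutes,
             pre_points = pre_points, post_points = post_points,
             pre_rebounds = pre_rebounds, post_rebounds = post_rebounds)
}

#' Write a synthetic league to CSV files plus a ground-truth JSON
#'
#' Emits the same CSV dialects consumed by [read_transactions()],
#' [read_game_logs()] and [read_schedule()], plus `roster.csv` and
#' `ground_truth.json`.
#'
#' @param league a `"ctb_league"` object from [generate_league()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_league <- function(league, dir) {
  if (!inherits(league, "ctb_league")) stop_input("'league' must be a ctb_league")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(transactions = file.path(dir, "transactions.csv"),
             games = file.path(dir, "games.csv"),
             schedule = file.path(dir, "schedule.csv"),
             roster = file.path(dir, "roster.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_transactions(league$transactions, paths[["transactions"]])
  write_game_logs(league$game_records, paths[["games"]])
  write_schedule(league$schedule, paths[["schedule"]])
  utils::write.csv(league$roster, paths[["roster"]], row.names = FALSE)
  gt <- league$ground_truth
  gt$injuries$onset_date <- as.character(gt$injuries$onset_date)
  gt$injuries$return_date <- as.character(gt$injuries$return_date)
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
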