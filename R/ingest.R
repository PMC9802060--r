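# Reading the transaction / game-log / schedule CSV dialects, linking the two
# sources at the individual-game level into time-loss injury events, and
# computing cross-source agreement.

TXN_COLS <- c("date", "player_id", "team_id", "event_kind", "note")
GAME_COLS <- c("player_id", "season_id", "game_date", "team_id", "started",
               "minutes", "points", "rebounds", "field_goals_attempted")
SCHED_COLS <- c("team_id", "season_id", "game_date")

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing, collapse = ", ")))
  df
}

new_problems <- function() {
  data.frame(row = integer(), reason = character(), detail = character(),
             stringsAsFactors = FALSE)
}

add_problem <- function(problems, rows, reason, detail = "") {
  if (length(rows) == 0) return(problems)
  rbind(problems, data.frame(row = rows, reason = reason, detail = detail,
                             stringsAsFactors = FALSE))
}

#' Read a roster-transaction log
#'
#' Expects a comma-separated UTF-8 file with header columns `date`,
#' `player_id`, `team_id`, `event_kind`, `note`. Rows with unparseable dates
#' or unknown event kinds are excluded from the returned records but reported
#' on the error channel (the `"problems"` attribute), never silently dropped.
#'
#' @param path file path.
#' @return data frame of transactions in date order with a parsed `Date`
#'   column, carrying a `"problems"` attribute describing flagged rows.
#' @export
read_transactions <- function(path) {
  df <- read_csv_checked(path, TXN_COLS)
  problems <- new_problems()
  dates <- parse_iso_date(df$date)
  bad_date <- which(is.na(dates) & nzchar(df$date) | !nzchar(df$date))
  problems <- add_problem(problems, bad_date, "unparseable_date", df$date[bad_date])
  bad_kind <- which(!(df$event_kind %in% c("deactivate", "activate", "other")))
  problems <- add_problem(problems, bad_kind, "unknown_event_kind",
                          df$event_kind[bad_kind])
  drop <- union(bad_date, bad_kind)
  out <- df[setdiff(seq_len(nrow(df)), drop), TXN_COLS, drop = FALSE]
  out$date <- dates[setdiff(seq_len(nrow(df)), drop)]
  out <- out[order(out$date, out$player_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "problems") <- problems
  out
}

#' Read a per-player per-game box-score log
#'
#' Same dialect rules as [read_transactions()]. Duplicate
#' `(player_id, game_date)` keys are a format error (the log is defined at
#' one record per player-game); minutes outside `[0, 60]` are retained but
#' flagged on the problems attribute.
#'
#' @param path file path.
#' @return data frame of game records with parsed dates and numeric columns,
#'   plus a `"problems"` attribute.
#' @export
read_game_logs <- function(path) {
  df <- read_csv_checked(path, GAME_COLS)
  problems <- new_problems()
  dates <- parse_iso_date(df$game_date)
  bad_date <- which(is.na(dates))
  problems <- add_problem(problems, bad_date, "unparseable_date", df$game_date[bad_date])
  keep <- setdiff(seq_len(nrow(df)), bad_date)
  out <- df[keep, GAME_COLS, drop = FALSE]
  out$game_date <- dates[keep]
  key <- paste(out$player_id, out$game_date)
  if (anyDuplicated(key))
    stop_format(sprintf("duplicate (player_id, game_date) key(s): %s",
                        paste(unique(key[duplicated(key)]), collapse = "; ")))
  for (col in c("minutes", "points", "rebounds", "field_goals_attempted"))
    out[[col]] <- as.numeric(out[[col]])
  out$started <- out$started %in% c("TRUE", "true", "1", "T")
  bad_min <- which(is.na(out$minutes) | out$minutes < 0 | out$minutes > 60)
  problems <- add_problem(problems, bad_min, "minutes_out_of_range",
                          as.character(out$minutes[bad_min]))
  out <- out[order(out$player_id, out$game_date), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "problems") <- problems
  out
}

#' Read a team schedule
#'
#' @param path CSV with columns `team_id`, `season_id`, `game_date` at the
#'   team-game grain.
#' @return data frame with parsed dates.
#' @export
read_schedule <- function(path) {
  df <- read_csv_checked(path, SCHED_COLS)
  dates <- parse_iso_date(df$game_date)
  if (anyNA(dates)) stop_format("schedule contains unparseable game_date values")
  df$game_date <- dates
  df[order(df$team_id, df$game_date), , drop = FALSE]
}

#' @rdname read_transactions
#' @param transactions data frame to write.
#' @export
write_transactions <- function(transactions, path) {
  transactions$date <- as.character(transactions$date)
  utils::write.csv(transactions[, TXN_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_game_logs
#' @param game_records data frame to write.
#' @export
write_game_logs <- function(game_records, path) {
  game_records$game_date <- as.character(game_records$game_date)
  utils::write.csv(game_records[, GAME_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_schedule
#' @param schedule data frame to write.
#' @export
write_schedule <- function(schedule, path) {
  schedule$game_date <- as.character(schedule$game_date)
  utils::write.csv(schedule[, SCHED_COLS], path, row.names = FALSE)
  invisible(path)
}

#' Link transactions and game logs into time-loss injury events
#'
#' Harmonises the two sources at the individual-game level. For each player,
#' the team schedule is scanned for maximal runs of consecutively missed team
#' games; a run becomes an injury event when a deactivation transaction for
#' that player is dated inside the gap (after the last played game and before
#' the return game). The onset date is the first missed team game — not the
#' unobservable practice-injury date — and the recovery date is the first
#' game played after the gap. `games_missed` counts team games strictly
#' between the last played game and the return. Players never returning get
#' `return_date = NA`, `games_missed` equal to the remaining team games, and
#' a missing-recovery flag.
#'
#' @param transactions data frame from [read_transactions()].
#' @param game_records data frame from [read_game_logs()].
#' @param schedule team-game schedule from [read_schedule()].
#' @return list with `events` (one row per injury event: `event_id`,
#'   `player_id`, `team_id`, `season_id`, `onset_date`, `return_date`,
#'   `games_missed`, `days_to_return`, `note`) and `report`, a
#'   `"ctb_validation"` list of flag counts and excluded identifiers.
#' @examples
#' lg <- generate_league(synthetic_config(n_teams = 4, games_per_team = 12,
#'                                        n_seasons = 1, roster_size = 4,
#'                                        injury_hazard = 0.02, seed = 2))
#' link_injury_events(lg$transactions, lg$game_records, lg$schedule)$events
#' @export
link_injury_events <- function(transactions, game_records, schedule) {
  players <- sort(unique(game_records$player_id))
  not_in_games <- setdiff(unique(transactions$player_id), players)

  deact <- transactions[transactions$event_kind == "deactivate", , drop = FALSE]
  sched_by_team <- split(schedule[, c("season_id", "game_date")], schedule$team_id)
  games_by_player <- split(game_records[, c("team_id", "game_date")],
                           game_records$player_id)
  deact_by_player <- split(deact, deact$player_id)

  n_missing_recovery <- 0L
  n_deact_no_missed_game <- 0L
  n_trade_window <- 0L
  trade_players <- character()
  events <- vector("list", length(players))

  for (pi in seq_along(players)) {
    pid <- players[pi]
    pg <- games_by_player[[pid]]
    pteams <- unique(pg$team_id)
    if (length(pteams) > 1) { n_trade_window <- n_trade_window + 1L
      trade_players <- c(trade_players, pid) }
    team_sched <- unique(do.call(rbind, sched_by_team[pteams]))
    team_sched <- team_sched[order(team_sched$game_date), , drop = FALSE]
    tdates <- team_sched$game_date
    tseason <- team_sched$season_id
    played <- tdates %in% pg$game_date
    pd <- deact_by_player[[pid]]
    ddates <- if (is.null(pd)) as.Date(character()) else sort(pd$date)

    runs <- rle(played)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    used_deact <- logical(length(ddates))
    rows <- list()
    for (r in seq_along(runs$values)) {
      if (runs$values[r]) next          # a run of played games
      if (starts[r] == 1L) next         # absence before first appearance
      last_played <- tdates[starts[r] - 1L]
      has_return <- ends[r] < length(tdates)
      return_date <- if (has_return) tdates[ends[r] + 1L] else as.Date(NA)
      in_gap <- ddates > last_played &
        (if (has_return) ddates < return_date else TRUE)
      if (!any(in_gap)) next
      used_deact[in_gap] <- TRUE
      first_d <- which(in_gap)[1]
      note <- if (is.null(pd)) "" else pd$note[order(pd$date)][first_d]
      onset <- tdates[starts[r]]
      gm <- runs$lengths[r]
      if (!has_return) n_missing_recovery <- n_missing_recovery + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        player_id = pid, team_id = pteams[1], season_id = tseason[starts[r]],
        onset_date = onset, return_date = return_date, games_missed = gm,
        days_to_return = if (has_return) as.integer(return_date - onset) else NA_integer_,
        note = note, stringsAsFactors = FALSE)
    }
    n_deact_no_missed_game <- n_deact_no_missed_game + sum(!used_deact)
    if (length(rows) > 0) events[[pi]] <- do.call(rbind, rows)
  }

  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(player_id = character(), team_id = character(),
                         season_id = character(), onset_date = as.Date(character()),
                         return_date = as.Date(character()),
                         games_missed = integer(), days_to_return = integer(),
                         note = character(), stringsAsFactors = FALSE)
  events <- events[order(events$player_id, events$onset_date), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) > 0) {
    events$event_id <- paste0(events$player_id, "#",
                              stats::ave(seq_len(nrow(events)),
                                         events$player_id, FUN = seq_along))
    events <- events[, c("event_id", setdiff(names(events), "event_id"))]
  } else events$event_id <- character(0)

  # negative days to recovery cannot arise from the run construction, but the
  # internal validity check is still applied so hand-edited inputs are caught
  neg <- which(!is.na(events$days_to_return) & events$days_to_return < 0)
  excluded_ids <- events$event_id[neg]
  if (length(neg) > 0) events <- events[-neg, , drop = FALSE]

  # activations with no open deactivation, in transaction order per player
  n_act_wo_deact <- 0L
  for (pid in unique(transactions$player_id)) {
    tx <- transactions[transactions$player_id == pid, , drop = FALSE]
    tx <- tx[order(tx$date), , drop = FALSE]
    open <- FALSE
    for (k in seq_len(nrow(tx))) {
      if (tx$event_kind[k] == "deactivate") open <- TRUE
      else if (tx$event_kind[k] == "activate") {
        if (!open) n_act_wo_deact <- n_act_wo_deact + 1L
        open <- FALSE
      }
    }
  }

  report <- structure(list(
    n_events = nrow(events),
    n_missing_recovery = n_missing_recovery,
    n_negative_recovery = length(neg),
    n_deactivations_without_missed_game = n_deact_no_missed_game,
    n_activations_without_deactivation = n_act_wo_deact,
    players_not_in_game_logs = not_in_games,
    trade_window_players = trade_players,
    excluded_event_ids = excluded_ids
  ), class = "ctb_validation")

  list(events = events, report = report)
}

#' @export
print.ctb_validation <- function(x, ...) {
  cat("Injury-event linkage validation\n")
  cat("  events emitted:                 ", x$n_events, "\n")
  cat("  missing recovery (no return):   ", x$n_missing_recovery, "\n")
  cat("  negative days to recovery:      ", x$n_negative_recovery, "(excluded)\n")
  cat("  deactivations w/o missed game:  ", x$n_deactivations_without_missed_game, "\n")
  cat("  activations w/o deactivation:   ", x$n_activations_without_deactivation, "\n")
  cat("  players absent from game logs:  ", length(x$players_not_in_game_logs), "\n")
  cat("  players with multi-team seasons:", length(x$trade_window_players), "\n")
  invisible(x)
}

#' Write / read linked injury events
#'
#' @param events injury-event data frame.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  events$onset_date <- as.character(events$onset_date)
  events$return_date <- as.character(events$return_date)
  utils::write.csv(events, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  ev$onset_date <- parse_iso_date(ev$onset_date)
  ev$return_date <- parse_iso_date(ev$return_date)
  ev$games_missed <- as.integer(ev$games_missed)
  ev$days_to_return <- as.integer(ev$days_to_return)
  ev$note[is.na(ev$note)] <- ""
  ev
}

#' Agreement between two injury-event sets
#'
#' Events are paired within player by nearest onset date, up to a matching
#' tolerance; each reported percentage is matched-and-equal over matched.
#' Mirrors an external-validation exercise comparing independently collected
#' injury logs on exact date, games missed, and injury site.
#'
#' @param events_a,events_b injury-event data frames (site agreement needs a
#'   `body_region` column on both).
#' @param date_tolerance_days maximum onset-date difference for a pair.
#' @return `"ctb_agreement"` list: `pct_exact_date`, `pct_missed_games`,
#'   `pct_injury_site` (percent, in `[0, 100]`), `n_matched`,
#'   `n_unmatched_a`, `n_unmatched_b`.
#' @export
agreement <- function(events_a, events_b, date_tolerance_days = 30) {
  if (nrow(events_a) == 0 || nrow(events_b) == 0)
    stop_input("agreement is undefined for an empty event set")
  pairs <- list()
  for (pid in intersect(unique(events_a$player_id), unique(events_b$player_id))) {
    ia <- which(events_a$player_id == pid)
    ib <- which(events_b$player_id == pid)
    cand <- expand.grid(a = ia, b = ib)
    cand$d <- abs(as.numeric(events_a$onset_date[cand$a] -
                               events_b$onset_date[cand$b]))
    cand <- cand[cand$d <= date_tolerance_days, , drop = FALSE]
    cand <- cand[order(cand$d), , drop = FALSE]
    ua <- ub <- integer()
    for (k in seq_len(nrow(cand))) {
      if (cand$a[k] %in% ua || cand$b[k] %in% ub) next
      ua <- c(ua, cand$a[k]); ub <- c(ub, cand$b[k])
      pairs[[length(pairs) + 1L]] <- c(cand$a[k], cand$b[k])
    }
  }
  m <- length(pairs)
  if (m == 0) stop_input("no events could be matched within the date tolerance")
  a <- vapply(pairs, `[`, integer(1), 1)
  b <- vapply(pairs, `[`, integer(1), 2)
  site <- if (all(c("body_region" %in% names(events_a),
                    "body_region" %in% names(events_b))))
    100 * mean(events_a$body_region[a] == events_b$body_region[b]) else NA_real_
  structure(list(
    pct_exact_date = 100 * mean(events_a$onset_date[a] == events_b$onset_date[b]),
    pct_missed_games = 100 * mean(events_a$games_missed[a] == events_b$games_missed[b]),
    pct_injury_site = site,
    n_matched = m,
    n_unmatched_a = nrow(events_a) - m,
    n_unmatched_b = nrow(events_b) - m
  ), class = "ctb_agreement")
}

#' @export
print.ctb_agreement <- function(x, ...) {
  cat(sprintf("Agreement over %d matched event pairs (unmatched: %d / %d)\n",
              x$n_matched, x$n_unmatched_a, x$n_unmatched_b))
  cat(sprintf("  exact onset date: %.1f%%\n", x$pct_exact_date))
  cat(sprintf("  games missed:     %.1f%%\n", x$pct_missed_games))
  cat(sprintf("  injury site:      %s\n",
              if (is.na(x$pct_injury_site)) "NA"
              else sprintf("%.1f%%", x$pct_injury_site)))
  invisible(x)
}
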