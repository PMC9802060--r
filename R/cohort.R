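# Cohort construction: eligibility screening and index / pre / post season
# assignment around each player's primary severe lower-extremity injury.

#' Assign index, pre-injury and post-injury seasons for one player
#'
#' The index season is the season in which the first (primary) severe
#' lower-extremity injury occurred; missed games spilling into the next
#' season do not shift the index. The pre-injury season is the season
#' immediately preceding the index (NA when the player did not play it).
#' The first post-injury season is the season of the first game played after
#' return when that differs from the index season, otherwise the next season
#' the player appeared in; the second post-injury season is the next season
#' played after that.
#'
#' @param player_events classified injury events for one player (needs
#'   `severity`, `body_region`, `season_id`, `onset_date`, `return_date`).
#' @param player_games the player's game records (needs `season_id`,
#'   `game_date`).
#' @param le_regions body regions that count as lower-extremity.
#' @return `NULL` when the player has no severe lower-extremity event,
#'   otherwise a list with `index_event` (one-row data frame),
#'   `index_season`, `pre_season`, `post1_season`, `post2_season`
#'   (season end-years as integers, NA when absent).
#' @export
assign_seasons <- function(player_events, player_games, le_regions = LE_REGIONS) {
  sev <- player_events[player_events$severity == "Severe" &
                         player_events$body_region %in% le_regions, , drop = FALSE]
  if (nrow(sev) == 0) return(NULL)
  sev <- sev[order(sev$onset_date), , drop = FALSE]
  index_event <- sev[1, , drop = FALSE]
  index_s <- season_num(index_event$season_id)
  seasons_played <- sort(unique(season_num(player_games$season_id)))

  pre <- if ((index_s - 1L) %in% seasons_played) index_s - 1L else NA_integer_

  post1 <- NA_integer_
  if (!is.na(index_event$return_date)) {
    ret_row <- player_games[player_games$game_date == index_event$return_date, , drop = FALSE]
    ret_s <- if (nrow(ret_row) > 0) season_num(ret_row$season_id[1]) else NA_integer_
    if (!is.na(ret_s) && ret_s != index_s) {
      post1 <- ret_s
    } else {
      later <- seasons_played[seasons_played > index_s]
      if (length(later) > 0) post1 <- later[1]
    }
  }
  post2 <- NA_integer_
  if (!is.na(post1)) {
    later <- seasons_played[seasons_played > post1]
    if (length(later) > 0) post2 <- later[1]
  }
  list(index_event = index_event, index_season = index_s, pre_season = pre,
       post1_season = post1, post2_season = post2)
}

#' Evaluate the cohort eligibility rules for one player
#'
#' The rules: at least `min_seasons` distinct seasons played; at least
#' `min_age` years old at injury; played the season immediately before the
#' index; no worse-than-minor injury (4 or more games missed) during that
#' pre-injury season; no reinjury with onset within `reinjury_days` calendar
#' days (inclusive) after return to sport; and at least one season played
#' after return. The last rule is reported separately (`no_post_season_play`)
#' because players failing only it still belong to the severely injured
#' denominator.
#'
#' @param seasons result of [assign_seasons()] for the player.
#' @param player_events all of the player's time-loss events.
#' @param player_games the player's game records.
#' @param roster_row one roster-metadata row (may be missing fields).
#' @param min_seasons,min_age,reinjury_days,pre_disqualifying_games rule
#'   parameters; the pre-season tolerance admits Slight and Minor injuries
#'   (up to 3 games missed).
#' @return list with `eligible` (logical; entry rules only), `reasons`
#'   (character vector of reason codes), and `has_post1`.
#' @export
check_eligibility <- function(seasons, player_events, player_games, roster_row,
                              min_seasons = 3L, min_age = 18,
                              reinjury_days = 14L, pre_disqualifying_games = 4L) {
  reasons <- character()
  seasons_played <- unique(season_num(player_games$season_id))
  if (length(seasons_played) < min_seasons) reasons <- c(reasons, "under_3_seasons")

  if (!is.null(roster_row) && nrow(roster_row) == 1 &&
      !is.na(roster_row$birth_date)) {
    age <- as.numeric(seasons$index_event$onset_date - roster_row$birth_date) / 365.25
    if (age < min_age) reasons <- c(reasons, "under_18")
  }

  if (is.na(seasons$pre_season)) {
    reasons <- c(reasons, "no_prior_season_play")
  } else {
    pre_ev <- player_events[season_num(player_events$season_id) == seasons$pre_season &
                              player_events$games_missed >= pre_disqualifying_games, ,
                            drop = FALSE]
    if (nrow(pre_ev) > 0) reasons <- c(reasons, "prior_season_injury_gt_minor")
  }

  ret <- seasons$index_event$return_date
  if (!is.na(ret)) {
    gap <- as.numeric(player_events$onset_date - ret)
    if (any(gap > 0 & gap <= reinjury_days))
      reasons <- c(reasons, "reinjury_within_14d")
  }

  has_post1 <- !is.na(seasons$post1_season)
  if (!has_post1) reasons <- c(reasons, "no_post_season_play")

  list(eligible = length(setdiff(reasons, "no_post_season_play")) == 0,
       reasons = reasons, has_post1 = has_post1)
}

#' Build the severe lower-extremity injury cohort
#'
#' Applies [assign_seasons()] and [check_eligibility()] to every player with
#' a severe lower-extremity event and assembles the cohort entries, the
#' exclusion log, and the strata counts that serve as denominators for the
#' return-to-performance tables (severely injured; played a first post-injury
#' season; played a second).
#'
#' @param events classified injury events (see [classify_events()]),
#'   regular-season filtered.
#' @param game_records full game-record data frame.
#' @param roster roster metadata (`player_id`, `birth_date`, `height_cm`,
#'   `weight_kg`, `position`); missing metadata leaves covariates NA, and such
#'   players are dropped only from adjusted (complete-case) models.
#' @param cutoff_date optional extraction cutoff; events with onset after it
#'   are ignored.
#' @param le_regions body regions counted as lower-extremity.
#' @inheritParams check_eligibility
#' @return `"ctb_cohort"`: list with `entries` (one row per eligible player;
#'   `post1_season`/`post2_season` NA when not played), `exclusions`
#'   (player_id, reason), and `strata_counts` (stratum x `n_severe`,
#'   `n_post1`, `n_post2`).
#' @export
build_cohort <- function(events, game_records, roster = NULL,
                         cutoff_date = NULL, le_regions = LE_REGIONS,
                         min_seasons = 3L, min_age = 18, reinjury_days = 14L,
                         pre_disqualifying_games = 4L) {
  if (!all(c("severity", "body_region") %in% names(events)))
    stop_input("'events' must be classified first (see classify_events)")
  if (!is.null(cutoff_date))
    events <- events[events$onset_date <= as.Date(cutoff_date), , drop = FALSE]
  if (is.null(roster))
    roster <- data.frame(player_id = character(), birth_date = as.Date(character()),
                         height_cm = numeric(), weight_kg = numeric(),
                         position = character(), stringsAsFactors = FALSE)
  if (is.character(roster$birth_date)) roster$birth_date <- parse_iso_date(roster$birth_date)

  sev_players <- unique(events$player_id[events$severity == "Severe" &
                                           events$body_region %in% le_regions])
  ev_by_player <- split(events, events$player_id)
  games_by_player <- split(game_records, game_records$player_id)

  entries <- list()
  excl <- list()
  for (pid in sort(sev_players)) {
    pev <- ev_by_player[[pid]]
    pg <- games_by_player[[pid]]
    if (is.null(pg)) { excl[[length(excl) + 1L]] <-
      data.frame(player_id = pid, reason = "no_game_records"); next }
    seasons <- assign_seasons(pev, pg, le_regions)
    rr <- roster[roster$player_id == pid, , drop = FALSE]
    chk <- check_eligibility(seasons, pev, pg, rr, min_seasons, min_age,
                             reinjury_days, pre_disqualifying_games)
    for (rsn in chk$reasons)
      excl[[length(excl) + 1L]] <- data.frame(player_id = pid, reason = rsn,
                                              stringsAsFactors = FALSE)
    entry_ok <- length(setdiff(chk$reasons, "no_post_season_play")) == 0
    if (!entry_ok) next

    age <- if (nrow(rr) == 1 && !is.na(rr$birth_date))
      as.numeric(seasons$index_event$onset_date - rr$birth_date) / 365.25 else NA_real_
    bmi <- if (nrow(rr) == 1 && !is.na(rr$height_cm) && !is.na(rr$weight_kg))
      rr$weight_kg / (rr$height_cm / 100)^2 else NA_real_
    pos <- if (nrow(rr) == 1) rr$position else NA_character_
    sp_at <- sum(unique(season_num(pg$season_id)) <= seasons$index_season)

    entries[[length(entries) + 1L]] <- data.frame(
      player_id = pid,
      body_region = seasons$index_event$body_region,
      index_season = seasons$index_season,
      pre_season = seasons$pre_season,
      post1_season = seasons$post1_season,
      post2_season = seasons$post2_season,
      index_event_id = seasons$index_event$event_id %||% NA_character_,
      onset_date = seasons$index_event$onset_date,
      return_date = seasons$index_event$return_date,
      games_missed = seasons$index_event$games_missed,
      days_to_return = seasons$index_event$days_to_return %||% NA_integer_,
      age_at_injury = age,
      seasons_played_at_injury = sp_at,
      position = pos,
      bmi = bmi,
      stringsAsFactors = FALSE)
  }

  entries <- if (length(entries) > 0) do.call(rbind, entries) else
    data.frame(player_id = character(), body_region = character(),
               index_season = integer(), pre_season = integer(),
               post1_season = integer(), post2_season = integer(),
               index_event_id = character(), onset_date = as.Date(character()),
               return_date = as.Date(character()), games_missed = integer(),
               days_to_return = integer(), age_at_injury = numeric(),
               seasons_played_at_injury = integer(), position = character(),
               bmi = numeric(), stringsAsFactors = FALSE)
  exclusions <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(player_id = character(), reason = character(),
               stringsAsFactors = FALSE)

  strata <- c("overall", le_regions)
  counts <- do.call(rbind, lapply(strata, function(s) {
    e <- if (s == "overall") entries else entries[entries$body_region == s, , drop = FALSE]
    data.frame(stratum = s, n_severe = nrow(e),
               n_post1 = sum(!is.na(e$post1_season)),
               n_post2 = sum(!is.na(e$post2_season)),
               stringsAsFactors = FALSE)
  }))

  structure(list(entries = entries, exclusions = exclusions,
                 strata_counts = counts),
            class = "ctb_cohort")
}

#' @export
print.ctb_cohort <- function(x, ...) {
  sc <- x$strata_counts
  ov <- sc[sc$stratum == "overall", ]
  cat("Severe lower-extremity injury cohort\n")
  cat(sprintf("  severely injured: %d | played post-1: %d | played post-2: %d\n",
              ov$n_severe, ov$n_post1, ov$n_post2))
  if (nrow(x$exclusions) > 0) {
    tab <- table(x$exclusions$reason)
    cat("  exclusions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
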