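# Severity-band and body-region classification of time-loss injury events,
# plus the regular-season restriction.

#' The time-loss severity bands
#'
#' Games missed map to Slight (1), Minor (2-3), Moderate (4-13) and
#' Severe (14 or more); the bands partition the positive integers.
#'
#' @return a data frame with one row per band: `severity`, `min_games`,
#'   `max_games` (Inf for the open-ended Severe band).
#' @export
severity_bands <- function() {
  data.frame(severity = SEVERITY_LEVELS,
             min_games = c(1, 2, 4, 14),
             max_games = c(1, 3, 13, Inf),
             stringsAsFactors = FALSE)
}

#' Classify games missed into a severity band
#'
#' @param games_missed integer vector of games missed; every value must be at
#'   least 1 (the time-loss definition requires missing one game).
#' @return ordered factor with levels Slight < Minor < Moderate < Severe.
#' @examples
#' classify_severity(c(1, 2, 3, 4, 13, 14, 60))
#' @export
classify_severity <- function(games_missed) {
  if (anyNA(games_missed) || any(games_missed < 1) ||
      any(games_missed != floor(games_missed)))
    stop_input("'games_missed' must be integers >= 1: a time-loss injury misses at least one game")
  cut(games_missed, breaks = c(1, 2, 4, 14, Inf), right = FALSE,
      labels = SEVERITY_LEVELS, ordered_result = TRUE)
}

#' Default keyword-to-body-region lexicon
#'
#' Maps lowercase keywords found in transaction note text to a body region.
#' Achilles keywords map to ankle (the nearest analysed region for
#' Achilles-tendon injuries; edit the lexicon if a different assignment is
#' wanted). Keywords naming body parts outside the three lower-extremity
#' study regions map to `other`; notes with no keyword hit map to `unknown`.
#'
#' @return data frame with columns `keyword`, `region`.
#' @seealso [map_body_region()], [read_region_lexicon()]
#' @export
default_region_lexicon <- function() {
  rbind(
    data.frame(keyword = c("knee", "acl", "mcl", "pcl", "meniscus",
                           "patella", "patellar"),
               region = "knee", stringsAsFactors = FALSE),
    data.frame(keyword = c("groin", "hip", "thigh", "hamstring", "quad",
                           "quadriceps", "adductor"),
               region = "groin/hip/thigh", stringsAsFactors = FALSE),
    data.frame(keyword = c("ankle", "achilles"),
               region = "ankle", stringsAsFactors = FALSE),
    data.frame(keyword = c("back", "wrist", "shoulder", "hand", "finger",
                           "elbow", "neck", "head", "concussion", "calf",
                           "foot", "toe", "rib", "abdominal"),
               region = "other", stringsAsFactors = FALSE)
  )
}

#' Read a region lexicon from a two-column CSV
#'
#' @param path CSV with columns `keyword`, `region`.
#' @return validated lexicon data frame.
#' @export
read_region_lexicon <- function(path) {
  lex <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("keyword", "region") %in% names(lex)))
    stop_format("lexicon file must have columns 'keyword' and 'region'")
  lex$keyword <- tolower(trimws(lex$keyword))
  if (anyDuplicated(lex$keyword))
    stop_format("lexicon keywords must each map to exactly one region")
  if (!all(lex$region %in% ALL_REGIONS))
    stop_format(sprintf("lexicon regions must be among {%s}",
                        paste(ALL_REGIONS, collapse = ", ")))
  lex
}

#' Map free-text injury notes to a body region
#'
#' Case-insensitive whole-word keyword matching; when several keywords occur,
#' the one appearing earliest in the note wins (lexicon order breaks ties).
#' Notes with no keyword hit — including empty notes — map to `"unknown"`,
#' which is a value, not an error.
#'
#' @param note character vector of free-text notes.
#' @param lexicon keyword-to-region table, see [default_region_lexicon()].
#' @return character vector of regions.
#' @examples
#' map_body_region(c("sprained left ankle", "torn ACL", ""))
#' @export
map_body_region <- function(note, lexicon = default_region_lexicon()) {
  low <- tolower(ifelse(is.na(note), "", note))
  out <- rep("unknown", length(low))
  best <- rep(Inf, length(low))
  for (i in seq_len(nrow(lexicon))) {
    pos <- regexpr(paste0("\\b", lexicon$keyword[i], "\\b"), low, perl = TRUE)
    hit <- pos > 0 & pos < best
    out[hit] <- lexicon$region[i]
    best[hit] <- pos[hit]
  }
  out
}

#' Attach severity and body region to linked injury events
#'
#' @param events injury-event data frame from [link_injury_events()] (must
#'   carry `games_missed` and `note`).
#' @param lexicon keyword-to-region table.
#' @return `events` with added `severity` and `body_region` columns.
#' @export
classify_events <- function(events, lexicon = default_region_lexicon()) {
  events$severity <- as.character(classify_severity(events$games_missed))
  events$body_region <- map_body_region(events$note, lexicon)
  events
}

#' Data-driven regular-season windows
#'
#' First and last game date per season, taken from the schedule; used when no
#' explicit season calendar is supplied.
#'
#' @param schedule data frame with `season_id` and `game_date`.
#' @return data frame: `season_id`, `first_date`, `last_date`.
#' @export
season_windows <- function(schedule) {
  sp <- split(schedule$game_date, schedule$season_id)
  data.frame(season_id = names(sp),
             first_date = as.Date(vapply(sp, function(d) as.character(min(d)), "")),
             last_date = as.Date(vapply(sp, function(d) as.character(max(d)), "")),
             stringsAsFactors = FALSE)
}

#' Restrict events to regular-season onsets
#'
#' Keeps events whose onset date falls inside a regular-season window
#' (boundaries inclusive); everything else is excluded and counted by reason.
#'
#' @param events injury-event data frame with `onset_date`.
#' @param windows season calendar from [season_windows()] or a file.
#' @return list with `events` (the surviving subset) and `excluded`
#'   (data frame of dropped events with a `reason` column:
#'   `off_season` or `outside_known_seasons`).
#' @export
filter_regular_season <- function(events, windows) {
  if (nrow(events) == 0)
    return(list(events = events, excluded = cbind(events, reason = character(0))))
  inside <- rep(FALSE, nrow(events))
  for (i in seq_len(nrow(windows)))
    inside <- inside | (events$onset_date >= windows$first_date[i] &
                          events$onset_date <= windows$last_date[i])
  in_span <- events$onset_date >= min(windows$first_date) &
    events$onset_date <= max(windows$last_date)
  excluded <- events[!inside, , drop = FALSE]
  if (nrow(excluded) > 0)
    excluded$reason <- ifelse(in_span[!inside], "off_season", "outside_known_seasons")
  else excluded$reason <- character(0)
  list(events = events[inside, , drop = FALSE], excluded = excluded)
}
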