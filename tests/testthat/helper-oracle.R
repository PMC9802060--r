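# Independent brute-force oracle for injury-event linkage: a plain pointer
# walk over each player's team schedule (no rle, no vectorised run logic),
# kept deliberately separate from the package implementation.

brute_force_events <- function(transactions, game_records, schedule) {
  out <- list()
  for (pid in sort(unique(game_records$player_id))) {
    pg <- game_records[game_records$player_id == pid, , drop = FALSE]
    ts <- schedule[schedule$team_id %in% unique(pg$team_id), , drop = FALSE]
    ts <- ts[!duplicated(ts$game_date), , drop = FALSE]
    ts <- ts[order(ts$game_date), , drop = FALSE]
    deact <- transactions[transactions$player_id == pid &
                            transactions$event_kind == "deactivate", , drop = FALSE]
    n <- nrow(ts)
    played <- ts$game_date %in% pg$game_date
    i <- 1L
    while (i <= n && !played[i]) i <- i + 1L   # before first appearance
    while (i <= n) {
      if (played[i]) { i <- i + 1L; next }
      j <- i
      while (j <= n && !played[j]) j <- j + 1L
      last_played <- ts$game_date[i - 1L]
      ret <- if (j <= n) ts$game_date[j] else as.Date(NA)
      qualifies <- any(deact$date > last_played &
                         (if (is.na(ret)) TRUE else deact$date < ret))
      if (qualifies)
        out[[length(out) + 1L]] <- data.frame(
          player_id = pid, onset_date = ts$game_date[i], return_date = ret,
          games_missed = j - i, stringsAsFactors = FALSE)
      i <- j
    }
  }
  if (length(out) == 0)
    return(data.frame(player_id = character(), onset_date = as.Date(character()),
                      return_date = as.Date(character()), games_missed = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$player_id, res$onset_date), , drop = FALSE]
}

# canonical key for comparing event sets
event_key <- function(ev) {
  paste(ev$player_id, ev$onset_date,
        ifelse(is.na(ev$return_date), "never", as.character(ev$return_date)),
        ev$games_missed)
}
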