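# End-to-end pipeline: simulate or read inputs, link, classify, restrict to
# the regular season, build the cohort, tabulate, model, and write a
# reproducible results bundle with a run manifest.

#' Pipeline configuration
#'
#' @param simulate generate inputs with [generate_league()] instead of
#'   reading files.
#' @param sim_config a [synthetic_config()] used when `simulate = TRUE`.
#' @param transactions,games,schedule,roster input CSV paths (used when
#'   `simulate = FALSE`).
#' @param out_dir output directory for the results bundle; `NULL` writes
#'   nothing.
#' @param lexicon_path optional region-lexicon CSV; defaults to
#'   [default_region_lexicon()].
#' @param cutoff_date optional extraction cutoff date for injury onsets.
#' @param tolerance return-to-performance tolerance (see
#'   [reached_preinjury()]).
#' @param years post-injury years to analyse.
#' @return validated `"ctb_pipeline_config"` list.
#' @export
pipeline_config <- function(simulate = TRUE, sim_config = synthetic_config(),
                            transactions = NULL, games = NULL, schedule = NULL,
                            roster = NULL, out_dir = NULL, lexicon_path = NULL,
                            cutoff_date = NULL, tolerance = 0,
                            years = c(1L, 2L)) {
  if (!simulate) {
    for (p in c(transactions = transactions, games = games, schedule = schedule)) {
      if (is.null(p)) stop_config("file-based runs need 'transactions', 'games' and 'schedule' paths")
      if (!file.exists(p)) stop_input(sprintf("input file not found: %s", p))
    }
  }
  structure(list(simulate = simulate, sim_config = sim_config,
                 transactions = transactions, games = games,
                 schedule = schedule, roster = roster, out_dir = out_dir,
                 lexicon_path = lexicon_path, cutoff_date = cutoff_date,
                 tolerance = tolerance, years = years),
            class = "ctb_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: acquire inputs (simulate or read), link transactions and game logs
#' into time-loss injury events, classify severity and body region, restrict
#' to regular-season onsets, build the severe lower-extremity cohort, compute
#' demographic / descriptive / prevalence tables, fit the model battery, and
#' (when `out_dir` is set) write CSV outputs, a JSON results bundle, a
#' rendered plain-text report and a run manifest sufficient to re-run
#' bit-identically.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a `"ctb_results"` list with `events`, `validation`,
#'   `cohort`, `demographics`, `descriptive`, `prevalence`, `models`,
#'   `anova`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "ctb_pipeline_config")) stop_config("'config' must come from pipeline_config()")

  if (config$simulate) {
    league <- generate_league(config$sim_config)
    transactions <- league$transactions
    games <- league$game_records
    schedule <- league$schedule
    roster <- league$roster
  } else {
    transactions <- read_transactions(config$transactions)
    games <- read_game_logs(config$games)
    schedule <- read_schedule(config$schedule)
    roster <- if (!is.null(config$roster)) {
      r <- utils::read.csv(config$roster, stringsAsFactors = FALSE)
      r$birth_date <- parse_iso_date(r$birth_date)
      r
    } else NULL
  }

  lexicon <- if (!is.null(config$lexicon_path))
    read_region_lexicon(config$lexicon_path) else default_region_lexicon()

  linked <- link_injury_events(transactions, games, schedule)
  events <- classify_events(linked$events, lexicon)
  frs <- filter_regular_season(events, season_windows(schedule))
  cohort <- build_cohort(frs$events, games, roster,
                         cutoff_date = config$cutoff_date)

  has_cohort <- nrow(cohort$entries) > 0
  demographics <- if (has_cohort) demographics_table(cohort) else NULL
  descriptive <- if (has_cohort) descriptive_table(cohort, games) else NULL
  prevalence <- if (has_cohort)
    prevalence_table(cohort, games, years = config$years,
                     tolerance = config$tolerance) else NULL
  models <- if (has_cohort) cohort_models(cohort, games, years = config$years) else NULL

  manifest <- list(
    seed = if (config$simulate) config$sim_config$seed else NA,
    simulate = config$simulate,
    n_transactions = nrow(transactions),
    n_game_records = nrow(games),
    n_events = nrow(events),
    n_events_regular_season = nrow(frs$events),
    n_off_season_excluded = nrow(frs$excluded),
    n_severe = cohort$strata_counts$n_severe[cohort$strata_counts$stratum == "overall"],
    n_post1 = cohort$strata_counts$n_post1[cohort$strata_counts$stratum == "overall"],
    n_post2 = cohort$strata_counts$n_post2[cohort$strata_counts$stratum == "overall"],
    tolerance = config$tolerance)

  bundle <- structure(list(events = events, validation = linked$report,
                           off_season = frs$excluded, cohort = cohort,
                           demographics = demographics,
                           descriptive = descriptive, prevalence = prevalence,
                           models = models$results, anova = models$anova,
                           fits = models$fits, rcs_fits = models$rcs_fits,
                           manifest = manifest),
                      class = "ctb_results")

  if (!is.null(config$out_dir)) write_results(bundle, config, config$out_dir)
  invisible(bundle)
}

write_results <- function(bundle, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_events(bundle$events, file.path(dir, "events.csv"))
  coh <- bundle$cohort$entries
  coh$onset_date <- as.character(coh$onset_date)
  coh$return_date <- as.character(coh$return_date)
  utils::write.csv(coh, file.path(dir, "cohort.csv"), row.names = FALSE, na = "")
  utils::write.csv(bundle$cohort$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$descriptive))
    utils::write.csv(bundle$descriptive, file.path(dir, "descriptive.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$prevalence))
    utils::write.csv(bundle$prevalence, file.path(dir, "prevalence.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$models))
    utils::write.csv(bundle$models, file.path(dir, "models.csv"),
                     row.names = FALSE)

  results <- list(strata_counts = bundle$cohort$strata_counts,
                  demographics = bundle$demographics,
                  descriptive = bundle$descriptive,
                  prevalence = bundle$prevalence,
                  models = bundle$models,
                  anova = if (!is.null(bundle$anova)) unclass(bundle$anova) else NULL)
  jsonlite::write_json(results, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")

  cfg_json <- jsonlite::toJSON(list(sim_config = unclass(config$sim_config),
                                    tolerance = config$tolerance,
                                    years = config$years,
                                    cutoff_date = config$cutoff_date),
                               auto_unbox = TRUE, digits = NA, null = "null")
  cfg_path <- file.path(dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- bundle$manifest
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(render_tables(bundle), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Demographic summary of the return-to-sport cohort
#'
#' Mean (SD) of age at injury, seasons played and BMI plus position
#' percentages, overall and per body region, among players with a first
#' post-injury season.
#'
#' @param cohort a `"ctb_cohort"`.
#' @return data frame, one row per stratum and variable.
#' @export
demographics_table <- function(cohort) {
  e <- cohort$entries[!is.na(cohort$entries$post1_season), , drop = FALSE]
  strata <- cohort$strata_counts$stratum
  out <- list()
  for (st in strata) {
    d <- if (st == "overall") e else e[e$body_region == st, , drop = FALSE]
    stat <- function(v) c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
    for (vn in c("age_at_injury", "seasons_played_at_injury", "bmi")) {
      s <- stat(d[[vn]])
      out[[length(out) + 1L]] <- data.frame(stratum = st, variable = vn,
                                            n = nrow(d), mean = s[["mean"]],
                                            sd = s[["sd"]], pct = NA_real_,
                                            stringsAsFactors = FALSE)
    }
    for (pos in c("guard", "forward", "center")) {
      pct <- if (nrow(d) > 0) 100 * mean(d$position == pos, na.rm = TRUE) else NA_real_
      out[[length(out) + 1L]] <- data.frame(stratum = st,
                                            variable = paste0("position_", pos),
                                            n = nrow(d), mean = NA_real_,
                                            sd = NA_real_, pct = pct,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Render the results bundle as a plain-text report
#'
#' Pure formatting: every number comes from a record already in the bundle.
#' Means print as `"25.8 (8.1)"`, prevalences as `"30% (23, 36)"`, empty
#' cells as an em dash.
#'
#' @param bundle a `"ctb_results"` from [run_pipeline()].
#' @return character vector of report lines.
#' @export
render_tables <- function(bundle) {
  lines <- character()
  add <- function(...) lines <<- c(lines, paste0(...))
  sc <- bundle$cohort$strata_counts
  ov <- sc[sc$stratum == "overall", ]
  add("Return to sport and return to performance after severe lower-extremity injury")
  add(strrep("=", 78))
  add(sprintf("Severely injured: %d | played a first post-injury season: %d | a second: %d",
              ov$n_severe, ov$n_post1, ov$n_post2))
  add("")

  if (!is.null(bundle$demographics)) {
    add("Demographics (players with a first post-injury season); mean (SD) or %")
    for (st in unique(bundle$demographics$stratum)) {
      d <- bundle$demographics[bundle$demographics$stratum == st, ]
      pos <- d[grepl("^position_", d$variable), ]
      add(sprintf("  %-16s n=%-4d age %s  seasons %s  BMI %s  G/F/C %s/%s/%s%%",
                  st, d$n[1],
                  fmt_mean_sd(d$mean[d$variable == "age_at_injury"],
                              d$sd[d$variable == "age_at_injury"]),
                  fmt_mean_sd(d$mean[d$variable == "seasons_played_at_injury"],
                              d$sd[d$variable == "seasons_played_at_injury"]),
                  fmt_mean_sd(d$mean[d$variable == "bmi"], d$sd[d$variable == "bmi"]),
                  round_half_away(pos$pct[1]), round_half_away(pos$pct[2]),
                  round_half_away(pos$pct[3])))
    }
    add("")
  }

  if (!is.null(bundle$descriptive)) {
    add("Season performance, mean (SD)")
    add(sprintf("  %-18s %-16s %-16s %-16s", "metric", "pre-injury",
                "1 y following", "2 y following"))
    for (m in unique(bundle$descriptive$metric)) {
      d <- bundle$descriptive[bundle$descriptive$metric == m, ]
      cell <- function(slot) {
        r <- d[d$slot == slot, ]
        if (nrow(r) == 0 || r$n == 0 || is.na(r$mean)) "—"
        else fmt_mean_sd(r$mean, r$sd, if (grepl("per_game", m)) 1 else 0)
      }
      add(sprintf("  %-18s %-16s %-16s %-16s", m, cell("pre"), cell("post1"),
                  cell("post2")))
    }
    add("")
  }

  if (!is.null(bundle$prevalence)) {
    add("Prevalence of return to preinjury performance (per 100 athletes, 95% CI)")
    for (yr in sort(unique(bundle$prevalence$year))) {
      add(sprintf("  year %d following severe injury", yr))
      for (st in unique(bundle$prevalence$stratum)) {
        d <- bundle$prevalence[bundle$prevalence$stratum == st &
                                 bundle$prevalence$year == yr, ]
        cells <- vapply(seq_len(nrow(d)), function(i) {
          if (d$denominator[i] == 0 || is.na(d$proportion[i])) return("—")
          sprintf("%d%% (%d, %d)", round_half_away(100 * d$proportion[i]),
                  round_half_away(100 * d$ci_low[i]),
                  round_half_away(100 * d$ci_high[i]))
        }, character(1))
        add(sprintf("    %-18s (n=%d) %s", st, max(d$denominator),
                    paste(cells, collapse = "  ")))
      }
    }
    add("")
  }

  if (!is.null(bundle$models)) {
    add("Prognostic regressions (coefficient of pre-injury value, 95% CI)")
    d <- bundle$models
    for (i in seq_len(nrow(d)))
      add(sprintf("  %-12s %-10s %-15s y%d: %.2f (%.2f, %.2f), p=%.3g, n=%d",
                  d$model_id[i], d$stratum[i], d$metric[i], d$year[i],
                  d$coefficient[i], d$ci_low[i], d$ci_high[i], d$p_value[i],
                  d$n[i]))
    add("")
  }

  if (!is.null(bundle$anova)) {
    a <- bundle$anova
    add(sprintf("Days to return to sport by region: F(%d, %d) = %.2f, p = %.3f",
                a$df_between, a$df_within, a$f_statistic, a$p_value))
    for (i in seq_along(a$groups))
      add(sprintf("  %-18s %s", a$groups[i], fmt_mean_sd(a$means[i], a$sds[i], 0)))
  }
  lines
}

#' @export
print.ctb_results <- function(x, ...) {
  cat(render_tables(x), sep = "\n")
  invisible(x)
}
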