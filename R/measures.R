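#' Names of the behavioural measures
#'
#' The eight per-player summaries of gambling involvement used throughout
#' the package, in canonical order: `duration` (calendar days spanned,
#' inclusive), `frequency` (% of those days with at least one bet),
#' `n_bets`, `bets_per_day` (bets per *active* day), `mean_bet` (ETH),
#' `total_wagered` (ETH), `net_loss` (ETH; negative = net win) and
#' `percent_loss` (net loss as % of total wagered).
#'
#' @return Character vector of column names.
#' @export
behavioural_measures <- function() {
  c("duration", "frequency", "n_bets", "bets_per_day",
    "mean_bet", "total_wagered", "net_loss", "percent_loss")
}

#' Betting duration in calendar days
#'
#' Days elapsed between first and last bet, rounded up at midnight
#' boundaries: bets at 22:00 on one day and 09:00 the next count as a
#' duration of two days even though they are under 24 hours apart. Days
#' are UTC calendar dates.
#'
#' @param bet_times Non-empty POSIXct vector of bet placement instants.
#' @return Integer number of days (>= 1).
#' @export
duration_days <- function(bet_times) {
  if (length(bet_times) == 0) abort_domain("duration_days() needs at least one bet")
  d <- utc_date(as_utc_time(bet_times))
  as.integer(max(d) - min(d)) + 1L
}

#' Number of active betting days
#'
#' Count of distinct UTC calendar dates on which at least one bet was
#' placed.
#'
#' @inheritParams duration_days
#' @return Integer count (>= 1).
#' @export
active_days <- function(bet_times) {
  if (length(bet_times) == 0) abort_domain("active_days() needs at least one bet")
  length(unique(utc_date(as_utc_time(bet_times))))
}

check_bets <- function(bets) {
  if (nrow(bets) == 0) abort_domain("at least one matched bet is required")
  if (any(bets$stake <= 0)) abort_integrity("all stakes must be positive")
  invisible(bets)
}

#' Behavioural measures for one player
#'
#' Computes the eight behavioural measures from one address's matched
#' bets: `frequency = 100 * active_days / duration`; `bets_per_day =
#' n_bets / active_days`; `net_loss = total_wagered - total paid out`;
#' `percent_loss = 100 * net_loss / total_wagered`. Temporal measures use
#' bet placement times only.
#'
#' @param bets Matched bets of a single address (see [match_bets()]).
#' @return One-row tibble: `address`, `active_days`, then the columns of
#'   [behavioural_measures()].
#' @export
compute_measures <- function(bets) {
  check_bets(bets)
  if (length(unique(bets$address)) != 1L) {
    abort_domain("compute_measures() expects bets of a single address")
  }
  measures_table(bets, by = "address")
}

#' Behavioural measures table for a cohort
#'
#' One row of behavioural measures per group key: either per unique
#' address (bets pooled across applications and games) or per address
#' within each application-game combination, the grouping used when
#' comparing games to screen for non-human players.
#'
#' @param bets Matched bets for any number of players.
#' @param by `"address"` (unique-address mode, default) or
#'   `"address_game"` (one row per address per app-game combination; the
#'   output gains `app`, `game` and a `group` label `"app:game"`).
#' @return Tibble sorted by group key with `active_days` plus the columns
#'   of [behavioural_measures()].
#' @export
measures_table <- function(bets, by = c("address", "address_game")) {
  by <- match.arg(by)
  check_bets(bets)
  keys <- if (by == "address") "address" else c("address", "app", "game")
  tab <- bets %>%
    dplyr::mutate(.date = utc_date(.data$bet_time)) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      duration = as.integer(max(.data$.date) - min(.data$.date)) + 1L,
      active_days = dplyr::n_distinct(.data$.date),
      n_bets = dplyr::n(),
      total_wagered = sum(.data$stake),
      net_loss = sum(.data$stake) - sum(.data$payout),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      frequency = 100 * .data$active_days / .data$duration,
      bets_per_day = .data$n_bets / .data$active_days,
      mean_bet = .data$total_wagered / .data$n_bets,
      percent_loss = 100 * .data$net_loss / .data$total_wagered
    ) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  if (by == "address_game") {
    tab$group <- paste(tab$app, tab$game, sep = ":")
  }
  cols <- c(keys, if (by == "address_game") "group", "active_days",
            behavioural_measures())
  tab[, cols]
}

#' Write a behavioural measures table
#'
#' Delimited-text export, one row per player (or per player-game row).
#'
#' @param measures Measures tibble from [measures_table()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_measures <- function(measures, path) {
  readr::write_csv(measures, path, na = "")
  invisible(path)
}
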