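#' Specify a fixed-odds casino game
#'
#' A game pays `payout_multiplier` times the stake with probability
#' `win_prob` and nothing otherwise, so the expected return per unit
#' staked is `p * m` and the house edge is `e = 1 - p * m`. Provably-fair
#' dice and coin-flip contracts advertise these parameters, so players
#' can know exactly what the house takes per bet.
#'
#' @param app Application label.
#' @param game Game label.
#' @param win_prob Win probability, in (0, 1).
#' @param payout_multiplier Payout multiplier on a win, > 0.
#' @param allow_player_edge Permit `p * m > 1` (a player-favourable game);
#'   default FALSE.
#' @return A `game_spec` list with a `house_edge` field.
#' @export
game_spec <- function(app, game, win_prob, payout_multiplier,
                      allow_player_edge = FALSE) {
  if (win_prob < 0 || win_prob > 1) abort_config("`win_prob` must be in [0, 1]")
  if (payout_multiplier <= 0) abort_config("`payout_multiplier` must be > 0")
  e <- 1 - win_prob * payout_multiplier
  if (e < 0 && !allow_player_edge) {
    abort_config("game has a negative house edge; set allow_player_edge = TRUE to permit")
  }
  structure(list(app = app, game = game, win_prob = win_prob,
                 payout_multiplier = payout_multiplier, house_edge = e),
            class = "game_spec")
}

#' Long-run expected percent loss of a game
#'
#' Analytic companion to the simulator: over many bets a player's
#' realised percent loss converges to `100 * house_edge`, the amount the
#' house takes from each unit staked.
#'
#' @param game A [game_spec()].
#' @return Percent loss (on the 0-100 scale).
#' @export
expected_percent_loss <- function(game) {
  100 * game$house_edge
}

#' Human bettor profile
#'
#' Parameters of the heavy-tailed human population the generator draws
#' from. Bet counts are rounded log-normal draws (median
#' `exp(n_bets_meanlog)`). Each player has a characteristic stake level
#' drawn log-normally across players (`stake_meanlog`,
#' `stake_sdlog_between`; median stake `exp(stake_meanlog)` ETH), with
#' smaller within-player log-normal variation (`stake_sdlog_within`)
#' around it. Careers are a mixture: a point mass of single-day bettors
#' (`p_single_day`) and a log-normal long tail of multi-day spans capped
#' at `career_max_days`; within a multi-day career, bets land on a
#' Beta-distributed fraction of days, in one short session per active
#' day. Defaults give a typical player with about one active day, order
#' ten bets, and 0.1 ETH stakes, with heavily-involved tails.
#'
#' @param n_bets_meanlog,n_bets_sdlog Log-normal parameters of per-player
#'   bet counts.
#' @param stake_meanlog,stake_sdlog_between Log-normal parameters of the
#'   across-player characteristic stake (ETH).
#' @param stake_sdlog_within Within-player log-sd of stakes around the
#'   characteristic level.
#' @param p_single_day Probability a career spans a single calendar day.
#' @param career_meanlog,career_sdlog Log-normal parameters of multi-day
#'   career spans (days).
#' @param career_max_days Upper cap on career span, days.
#' @param activity_shape1,activity_shape2 Beta parameters of the fraction
#'   of career days that are active.
#' @return A `player_profile` of kind `"human"`.
#' @export
human_profile <- function(n_bets_meanlog = log(10), n_bets_sdlog = 1.2,
                          stake_meanlog = log(0.1), stake_sdlog_between = 1.5,
                          stake_sdlog_within = 0.3,
                          p_single_day = 0.55,
                          career_meanlog = log(6), career_sdlog = 1.1,
                          career_max_days = 365,
                          activity_shape1 = 1.5, activity_shape2 = 1) {
  structure(list(kind = "human", n_bets_meanlog = n_bets_meanlog,
                 n_bets_sdlog = n_bets_sdlog, stake_meanlog = stake_meanlog,
                 stake_sdlog_between = stake_sdlog_between,
                 stake_sdlog_within = stake_sdlog_within,
                 p_single_day = p_single_day, career_meanlog = career_meanlog,
                 career_sdlog = career_sdlog, career_max_days = career_max_days,
                 activity_shape1 = activity_shape1,
                 activity_shape2 = activity_shape2),
            class = "player_profile")
}

#' Algorithmic (bot) bettor profile
#'
#' The minimal mechanism producing a second, near-degenerate peak in the
#' behavioural-measure distributions: bots place a near-constant number
#' of bets of near-constant stake at exactly regular intervals over a
#' long fixed span. With the defaults every bot bets roughly daily for
#' half a year with 0.05 ETH stakes.
#'
#' @param n_bets_mean,n_bets_sd Normal parameters of per-bot bet counts
#'   (rounded, floored at 1).
#' @param stake Constant stake level, ETH.
#' @param stake_jitter Relative log-scale jitter on stakes (tiny).
#' @param career_days Fixed betting span, days.
#' @return A `player_profile` of kind `"bot"`.
#' @export
bot_profile <- function(n_bets_mean = 200, n_bets_sd = 2,
                        stake = 0.05, stake_jitter = 1e-4,
                        career_days = 180) {
  structure(list(kind = "bot", n_bets_mean = n_bets_mean,
                 n_bets_sd = n_bets_sd, stake = stake,
                 stake_jitter = stake_jitter, career_days = career_days),
            class = "player_profile")
}

#' Default application-game groups for simulation
#'
#' Six application-game combinations: five human-only groups on
#' near-even-odds games with house edges between 1% and 3%, plus one
#' coin-flip group dominated by bots (180 bots, 20 humans), emulating a
#' ledger in which one game's traffic is mostly algorithmic. The human
#' games all pay close to 2:1 so that the five human groups are
#' behaviourally exchangeable: a long-odds game (say a 1-in-12 double
#' dice) gives its players a genuinely different percent-loss
#' distribution and would rightly be detected as a distinct population
#' rather than serving as a null group.
#'
#' @return Tibble with columns `app`, `game`, `win_prob`,
#'   `payout_multiplier`, `n_human`, `n_bot`.
#' @export
default_games <- function() {
  tibble::tibble(
    app = c("dapp_a", "dapp_a", "dapp_a", "dapp_b", "dapp_b", "dapp_c"),
    game = c("coinflip", "evenroll", "hundred", "hundred", "coinflip",
             "coinflip"),
    win_prob = c(0.495, 0.4925, 0.49, 0.4875, 0.485, 0.495),
    payout_multiplier = c(2, 2, 2, 2, 2, 2),
    n_human = c(200L, 200L, 200L, 200L, 200L, 20L),
    n_bot = c(0L, 0L, 0L, 0L, 0L, 180L)
  )
}

#' Configure a synthetic bettor population
#'
#' Fixes everything the generator needs: the application-game groups with
#' their game odds and population sizes, the human and bot profiles, the
#' study window, and the master seed (mandatory; it fixes the entire
#' output stream). Per-player seeds are derived reproducibly from the
#' master seed and the group/player indices, so any single player's
#' transaction stream is reproducible in isolation.
#'
#' @param games Group table as in [default_games()].
#' @param human [human_profile()] shared by all human players.
#' @param bot [bot_profile()] shared by all bot players.
#' @param start_date First day of the study window (UTC).
#' @param window_days Length of the window human careers are placed in.
#' @param seed Master seed (integer).
#' @return A `sim_config` list.
#' @export
sim_config <- function(games = default_games(), human = human_profile(),
                       bot = bot_profile(),
                       start_date = as.Date("2019-01-01"), window_days = 400L,
                       seed = 1L) {
  if (is.null(seed) || is.na(seed)) abort_config("a master `seed` is mandatory")
  if (anyDuplicated(paste(games$app, games$game))) {
    abort_config("duplicate (app, game) labels in `games`")
  }
  if (nrow(games) < 1 || sum(games$n_human + games$n_bot) < 1) {
    abort_config("population must contain at least one player")
  }
  for (i in seq_len(nrow(games))) {
    game_spec(games$app[i], games$game[i], games$win_prob[i],
              games$payout_multiplier[i])  # validates odds and edge
  }
  if (window_days < human$career_max_days + 1) {
    abort_config("`window_days` must exceed the maximum human career span")
  }
  structure(list(games = games, human = human, bot = bot,
                 start_date = as.Date(start_date),
                 window_days = as.integer(window_days),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One player's bets as plain vectors (seconds since epoch, stakes, wins).
# All randomness comes from the caller-supplied seed.
sim_player_core <- function(profile, game, seed, start_num, window_days) {
  set.seed(seed)
  day <- 86400
  if (profile$kind == "human") {
    n <- max(1L, as.integer(round(rlnorm(1, profile$n_bets_meanlog,
                                         profile$n_bets_sdlog))))
    career <- if (runif(1) < profile$p_single_day) 1L else {
      min(profile$career_max_days,
          1L + as.integer(round(rlnorm(1, profile$career_meanlog,
                                       profile$career_sdlog))))
    }
    a_target <- max(1L, as.integer(round(
      rbeta(1, profile$activity_shape1, profile$activity_shape2) * career)))
    a <- min(n, career, a_target)
    days_active <- sort(sample.int(career, a)) - 1L
    start_day <- sample.int(window_days - career + 1L, 1L) - 1L
    # every active day gets one bet, remaining bets spread multinomially
    counts <- as.vector(rmultinom(1, n - a, rep(1 / a, a))) + 1L
    bet_day <- rep(days_active, counts)
    session_start <- runif(a, 0, day - 3700)
    secs <- rep(session_start, counts) + runif(n, 0, 3600)
    t <- start_num + (start_day + bet_day) * day + secs
    theta <- rlnorm(1, profile$stake_meanlog, profile$stake_sdlog_between)
    stakes <- theta * rlnorm(n, 0, profile$stake_sdlog_within)
  } else {
    n <- max(1L, as.integer(round(rnorm(1, profile$n_bets_mean,
                                        profile$n_bets_sd))))
    interval <- profile$career_days * day / n
    phase <- runif(1, 0, interval)
    t <- start_num + phase + (seq_len(n) - 1) * interval
    stakes <- profile$stake * exp(rnorm(n, 0, profile$stake_jitter))
  }
  ord <- order(t)
  wins <- runif(n) < game$win_prob
  list(t = round(t[ord]), stake = stakes[ord], win = wins[ord])
}

#' Simulate one player's transaction stream
#'
#' For each bet a `to_app` (stake) record is emitted; with the game's win
#' probability a `from_app` (payout) record of `stake * payout_multiplier`
#' follows a fixed small confirmation delay (30 s) later. Output is
#' time-ordered and fully determined by `seed`.
#'
#' @param profile A [human_profile()] or [bot_profile()].
#' @param game A [game_spec()].
#' @param seed Integer seed for this player.
#' @param start_date First day of the placement window.
#' @param window_days Window length in days (human careers are placed
#'   uniformly within it; bots start at the window origin).
#' @param address Player address label.
#' @return Tibble of transaction records (see [read_transactions()]).
#' @export
simulate_player <- function(profile, game, seed, start_date = as.Date("2019-01-01"),
                            window_days = 400L, address = "0xplayer") {
  start_num <- as.numeric(as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC"))
  core <- sim_player_core(profile, game, seed, start_num, window_days)
  assemble_ledger(list(core), address = address, app = game$app,
                  game = game$game, payout_multiplier = game$payout_multiplier)
}

payout_delay_s <- 30

# Bind per-player cores into one transaction tibble.
assemble_ledger <- function(cores, address, app, game, payout_multiplier) {
  n_bets <- vapply(cores, function(x) length(x$t), integer(1))
  t <- unlist(lapply(cores, `[[`, "t"))
  stake <- unlist(lapply(cores, `[[`, "stake"))
  win <- unlist(lapply(cores, `[[`, "win"))
  total <- sum(n_bets)
  addr <- rep(address, n_bets)
  app_v <- rep(app, total)
  game_v <- rep(game, total)
  mult <- rep(payout_multiplier, total)
  bet <- tibble::tibble(address = addr, app = app_v, game = game_v,
                        timestamp = t, direction = "to_app", value = stake)
  pay <- tibble::tibble(address = addr[win], app = app_v[win],
                        game = game_v[win],
                        timestamp = t[win] + payout_delay_s,
                        direction = "from_app",
                        value = stake[win] * mult[win])
  out <- dplyr::bind_rows(bet, pay)
  out <- out[order(out$timestamp, out$address, out$direction), ]
  out$tx_hash <- sprintf("0xt%08d", seq_len(nrow(out)))
  out$timestamp <- as_utc_time(out$timestamp)
  out[, c("tx_hash", "address", "app", "game", "timestamp", "direction", "value")]
}

#' Simulate a full transaction ledger
#'
#' Draws every configured group's human and bot players and emits a
#' single time-sorted transaction ledger in the exact format
#' [read_transactions()] reads. Deterministic: the same `sim_config`
#' (including seed) yields a byte-identical ledger file, and matching the
#' output always succeeds with zero orphan payouts (every payout follows
#' its stake by construction).
#'
#' @param config A [sim_config()].
#' @return Tibble of transaction records.
#' @export
simulate_population <- function(config) {
  start_num <- as.numeric(as.POSIXct(paste(config$start_date, "00:00:00"),
                                     tz = "UTC"))
  games <- config$games
  parts <- vector("list", nrow(games))
  for (i in seq_len(nrow(games))) {
    g <- game_spec(games$app[i], games$game[i], games$win_prob[i],
                   games$payout_multiplier[i])
    n_h <- games$n_human[i]
    n_b <- games$n_bot[i]
    cores <- vector("list", n_h + n_b)
    addresses <- character(n_h + n_b)
    for (j in seq_len(n_h + n_b)) {
      profile <- if (j <= n_h) config$human else config$bot
      cores[[j]] <- sim_player_core(profile, g, derive_seed(config$seed, i, j),
                                    start_num, config$window_days)
      addresses[j] <- sprintf("0x%s%02d%05d",
                              if (j <= n_h) "h" else "b", i, j)
    }
    parts[[i]] <- assemble_ledger(cores, address = addresses,
                                  app = g$app, game = g$game,
                                  payout_multiplier = g$payout_multiplier)
  }
  out <- dplyr::bind_rows(parts)
  out <- out[order(out$timestamp, out$address, out$direction), ]
  out$tx_hash <- sprintf("0xt%08d", seq_len(nrow(out)))
  out
}

#' Read / write a simulation configuration
#'
#' `sim_config` round-trips through a plain-text YAML file; the master
#' seed is mandatory in the file.
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(list(
    games = lapply(seq_len(nrow(config$games)), function(i) as.list(config$games[i, ])),
    human = unclass(config$human), bot = unclass(config$bot),
    start_date = as.character(config$start_date),
    window_days = config$window_days, seed = config$seed
  ), path, precision = 17)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) abort_config("simulation config file must set `seed`")
  games <- dplyr::bind_rows(lapply(raw$games, tibble::as_tibble))
  human <- do.call(human_profile, raw$human[setdiff(names(raw$human), "kind")])
  bot <- do.call(bot_profile, raw$bot[setdiff(names(raw$bot), "kind")])
  sim_config(games = games, human = human, bot = bot,
             start_date = as.Date(raw$start_date %||% "2019-01-01"),
             window_days = raw$window_days %||% 400L, seed = raw$seed)
}
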