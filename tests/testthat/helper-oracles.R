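# Independent brute-force oracles and fixture builders. These never call
# the implementation paths they are used to check.

utc <- function(s) as.POSIXct(s, tz = "UTC")

# ECDF-sup two-sample K-S statistic by direct evaluation at every pooled
# point.
ks2_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(fa - fb))
}

# One-sample K-S statistic against the fitted normal, by direct ECDF
# evaluation on the sorted standardised sample.
ksnorm_oracle <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  phi <- pnorm(z)
  max(seq_len(n) / n - phi, phi - (seq_len(n) - 1) / n)
}

# Spearman rho by the direct rank formula: Pearson product-moment of
# midranks, computed from sums rather than cor().
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Exhaustive earliest-first matching oracle. Enumerates every injective
# payout -> eligible-stake assignment, keeps the maximum-cardinality
# ones, and picks the lexicographically smallest stake-index sequence
# (payouts in time order; unmatched = +Inf). Returns the stake index
# matched to each payout (NA = orphan).
match_oracle <- function(stake_time, payout_time, lookahead = 0) {
  np <- length(payout_time)
  best <- NULL
  best_key <- NULL
  recurse <- function(j, used, assign) {
    if (j > np) {
      key <- ifelse(is.na(assign), Inf, assign)
      cand <- list(assign = assign, matched = sum(!is.na(assign)), key = key)
      if (is.null(best) || cand$matched > best$matched ||
          (cand$matched == best$matched &&
           isTRUE(vec_less(cand$key, best$key)))) {
        best <<- cand
      }
      return(invisible(NULL))
    }
    eligible <- which(!used & stake_time <= payout_time[j] + lookahead)
    for (s in c(eligible, NA)) {
      u <- used
      if (!is.na(s)) u[s] <- TRUE
      a <- assign
      a[j] <- s
      recurse(j + 1, u, a)
    }
  }
  vec_less <- function(a, b) {
    for (i in seq_along(a)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    FALSE
  }
  if (np == 0) return(integer(0))
  recurse(1, rep(FALSE, length(stake_time)), rep(NA_integer_, np))
  best$assign
}

# Random single-stream transaction fixture (one address/app/game),
# time-sorted, with ties possible.
random_stream <- function(n, seed) {
  set.seed(seed)
  t <- sort(sample.int(n + 2, n, replace = TRUE))
  tibble::tibble(
    tx_hash = sprintf("h%02d", seq_len(n)),
    address = "0xabc", app = "appx", game = "dice",
    timestamp = utc("2020-01-01 00:00:00") + t,
    direction = sample(c("to_app", "from_app"), n, replace = TRUE),
    value = round(runif(n, 0.01, 2), 3)
  )
}

# Matched-bet fixture builder.
make_bets <- function(address, times, stakes, payouts,
                      app = "appx", game = "dice") {
  n <- length(times)
  tibble::tibble(
    address = rep(address, length.out = n), app = app, game = game,
    bet_time = utc(times), stake = stakes, payout = payouts,
    bet_hash = sprintf("b%s%02d", substr(address[1], 3, 5), seq_len(n)),
    payout_hash = ifelse(payouts > 0, sprintf("p%02d", seq_len(n)), NA_character_)
  )
}

# Compact simulation config for structural tests (fast, still 6 groups).
small_sim_config <- function(seed, n_human = 25L, n_bot = 23L) {
  games <- betledger::default_games()
  games$n_human <- c(rep(n_human, 5), 2L)
  games$n_bot <- c(rep(0L, 5), n_bot)
  betledger::sim_config(games = games, seed = seed)
}

bot_group_label <- function() "dapp_c:coinflip"
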