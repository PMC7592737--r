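test_that("duration rounds up across midnight boundaries", {
  # 22:00 one day, 09:00 the next: under 24h apart, still two days
  expect_equal(duration_days(utc(c("2020-03-01 22:00:00", "2020-03-02 09:00:00"))), 2L)
  expect_equal(duration_days(utc("2020-03-01 13:00:00")), 1L)
  expect_equal(duration_days(utc(c("2020-03-01 00:00:01", "2020-03-06 23:59:59"))), 6L)
  expect_equal(duration_days(utc(c("2020-03-01 00:00:01", "2020-03-07 23:59:59"))), 7L)
  expect_error(duration_days(utc(character())), class = "betledger_domain_error")
})

test_that("active_days counts distinct UTC calendar dates", {
  expect_equal(active_days(utc(rep("2020-03-01 10:00:00", 3))), 1L)
  expect_equal(active_days(utc(c("2020-03-01 10:00:00", "2020-03-01 23:00:00",
                                 "2020-03-03 01:00:00"))), 2L)
  set.seed(11)
  dates <- sample(sprintf("2020-04-%02d", 1:10), 100, replace = TRUE)
  # force all 10 dates to appear
  dates[1:10] <- sprintf("2020-04-%02d", 1:10)
  times <- utc(paste(dates, sprintf("%02d:%02d:00", sample(0:23, 100, TRUE),
                                    sample(0:59, 100, TRUE))))
  expect_equal(active_days(times), length(unique(dates)))
  expect_error(active_days(utc(character())), class = "betledger_domain_error")
})

test_that("compute_measures reproduces hand-computed fixtures", {
  one_loss <- make_bets("0xaa", "2020-01-01 10:00:00", 1, 0)
  m <- compute_measures(one_loss)
  expect_equal(m$n_bets, 1L)
  expect_equal(m$total_wagered, 1)
  expect_equal(m$net_loss, 1)
  expect_equal(m$percent_loss, 100)
  expect_equal(m$frequency, 100)

  break_even <- make_bets("0xaa", "2020-01-01 10:00:00", 1, 1)
  m2 <- compute_measures(break_even)
  expect_equal(m2$net_loss, 0)
  expect_equal(m2$percent_loss, 0)

  # 6 bets on 3 calendar dates spanning 5 days; stakes 0.1 each,
  # payouts summing 0.54
  fix <- make_bets("0xaa",
                   c("2020-02-01 09:00:00", "2020-02-01 22:30:00",
                     "2020-02-03 12:00:00", "2020-02-03 12:05:00",
                     "2020-02-05 01:00:00", "2020-02-05 23:00:00"),
                   stakes = rep(0.1, 6),
                   payouts = c(0.19, 0, 0.19, 0, 0.16, 0))
  m3 <- compute_measures(fix)
  expect_equal(m3$duration, 5L)
  expect_equal(m3$frequency, 60)
  expect_equal(m3$bets_per_day, 2)
  expect_equal(m3$mean_bet, 0.1)
  expect_equal(m3$total_wagered, 0.6)
  expect_equal(m3$net_loss, 0.06)
  expect_equal(m3$percent_loss, 10)
})

test_that("compute_measures rejects empty, non-positive, and multi-address input", {
  expect_error(compute_measures(make_bets("0xaa", character(), numeric(), numeric())),
               class = "betledger_domain_error")
  expect_error(compute_measures(make_bets("0xaa", "2020-01-01 10:00:00", 0, 0)),
               class = "betledger_integrity_error")
  two <- dplyr::bind_rows(make_bets("0xaa", "2020-01-01 10:00:00", 1, 0),
                          make_bets("0xbb", "2020-01-01 11:00:00", 1, 0))
  expect_error(compute_measures(two), class = "betledger_domain_error")
})

test_that("measures_table groups per address or per address-game", {
  bets <- dplyr::bind_rows(
    make_bets("0xaa", c("2020-01-01 10:00:00", "2020-01-02 10:00:00"),
              c(1, 2), c(0, 3.8), app = "a1", game = "dice"),
    make_bets("0xaa", "2020-01-05 10:00:00", 4, 0, app = "a2", game = "flip"),
    make_bets("0xbb", "2020-01-01 12:00:00", 8, 0, app = "a1", game = "dice")
  )
  per_group <- measures_table(bets, by = "address_game")
  expect_equal(nrow(per_group), 3)
  expect_true(all(c("group", "duration", "percent_loss") %in% names(per_group)))
  unique_addr <- measures_table(bets, by = "address")
  expect_equal(nrow(unique_addr), 2)
  # pooled total wagered per address equals the sum over its groups
  pooled <- tapply(per_group$total_wagered, per_group$address, sum)
  expect_equal(as.vector(pooled[unique_addr$address]), unique_addr$total_wagered)
  # duration pools across games: 0xaa bets Jan 1 to Jan 5
  expect_equal(unique_addr$duration[unique_addr$address == "0xaa"], 5L)
  # invariants: frequency ties to active days, mean_bet to totals
  expect_equal(unique_addr$frequency,
               100 * unique_addr$active_days / unique_addr$duration)
  expect_equal(unique_addr$mean_bet * unique_addr$n_bets,
               unique_addr$total_wagered)
})

test_that("measures are scale-equivariant and time-shift invariant", {
  set.seed(21)
  bets <- make_bets("0xaa",
                    sprintf("2020-01-%02d %02d:00:00", sample(1:20, 15, TRUE),
                            sample(0:23, 15, TRUE)),
                    stakes = round(runif(15, 0.1, 2), 3),
                    payouts = round(runif(15, 0, 2), 3))
  base <- compute_measures(bets)
  c_scale <- 3.7
  scaled <- bets
  scaled$stake <- scaled$stake * c_scale
  scaled$payout <- scaled$payout * c_scale
  m_s <- compute_measures(scaled)
  for (col in c("mean_bet", "total_wagered", "net_loss")) {
    expect_equal(m_s[[col]], c_scale * base[[col]])
  }
  for (col in c("duration", "frequency", "n_bets", "bets_per_day", "percent_loss")) {
    expect_equal(m_s[[col]], base[[col]])
  }
  shifted <- bets
  shifted$bet_time <- shifted$bet_time + 17 * 86400
  m_t <- compute_measures(shifted)
  expect_equal(m_t[setdiff(names(m_t), "address")],
               base[setdiff(names(base), "address")])
})

test_that("player net losses sum to the house gross win", {
  cfg <- small_sim_config(seed = 5)
  led <- simulate_population(cfg)
  res <- match_ledger(led)
  measures <- measures_table(res$bets, by = "address")
  stakes <- sum(led$value[led$direction == "to_app"])
  payouts <- sum(led$value[led$direction == "from_app"])
  expect_equal(sum(measures$net_loss), stakes - payouts, tolerance = 1e-10)
})
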