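test_that("read_transactions parses well-formed ledgers and rejects bad rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "tx_hash,address,app,game,timestamp,direction,value",
    "h1,0xAA,app1,dice,2020-01-01T10:00:00Z,to_app,0.5",
    "h2,0xAA,app1,dice,2020-01-01T10:00:30Z,from_app,0.95",
    "h3,0xBB,app1,dice,2020-01-02T11:00:00Z,to_app,1.0"
  ), f)
  recs <- read_transactions(f)
  expect_equal(nrow(recs), 3)
  expect_equal(nrow(rejected_rows(recs)), 0)
  expect_equal(recs$address, c("0xaa", "0xaa", "0xbb"))  # lower-cased, sorted
  expect_s3_class(recs$timestamp, "POSIXct")
  expect_equal(attr(recs$timestamp, "tzone"), "UTC")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "tx_hash,address,app,game,timestamp,direction,value",
    "h1,0xaa,app1,dice,2020-01-01T10:00:00Z,to_app,0.5",
    "h2,0xaa,app1,dice,2020-01-01T10:00:30Z,to_app,-1",
    "h3,0xbb,app1,dice,2020-01-02T11:00:00Z,to_app,1.0"
  ), f2)
  recs2 <- suppressMessages(read_transactions(f2))
  expect_equal(nrow(recs2), 2)
  rej <- rejected_rows(recs2)
  expect_equal(nrow(rej), 1)
  expect_equal(rej$reason, "negative_value")
})

test_that("read_transactions flags zero-value stakes, bad rows, and schema problems", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "tx_hash,address,app,game,timestamp,direction,value",
    "h1,0xaa,app1,dice,2020-01-01T10:00:00Z,to_app,0",
    "h2,0xaa,app1,dice,not-a-time,to_app,1",
    "h3,0xaa,app1,dice,2020-01-01T10:00:00Z,sideways,1",
    "h4,0xaa,app1,dice,2020-01-01T12:00:00Z,from_app,0",
    "h5,0xaa,app1,dice,2020-01-01T11:00:00Z,to_app,1"
  ), f)
  recs <- suppressMessages(read_transactions(f))
  # zero-value payout rows are legal; zero-value stakes are not
  expect_equal(nrow(recs), 2)
  expect_setequal(rejected_rows(recs)$reason,
                  c("zero_value_stake", "bad_timestamp", "bad_direction"))

  f_bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tx_hash,address,app,game,when,direction,value"), f_bad)
  expect_error(read_transactions(f_bad), "timestamp",
               class = "betledger_schema_error")

  f_dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "tx_hash,address,app,game,timestamp,direction,value",
    "h1,0xaa,app1,dice,2020-01-01T10:00:00Z,to_app,1",
    "h1,0xaa,app1,dice,2020-01-01T11:00:00Z,to_app,1"
  ), f_dup)
  expect_error(read_transactions(f_dup), class = "betledger_integrity_error")
})

test_that("match_bets pairs payouts with the earliest prior unmatched stake", {
  s <- tibble::tibble(
    tx_hash = c("s1", "p1"), address = "0xaa", app = "a", game = "g",
    timestamp = utc("2020-01-01 00:00:00") + c(1, 2),
    direction = c("to_app", "from_app"), value = c(1, 1.9)
  )
  res <- match_bets(s)
  expect_equal(nrow(res$bets), 1)
  expect_equal(res$bets$payout, 1.9)
  expect_equal(res$bets$payout_hash, "p1")
  expect_equal(as.list(res$report),
               list(n_bets_matched = 1L, n_bets_unmatched = 0L,
                    n_orphan_payouts = 0L))

  # two stakes then two payouts: first payout to first stake, second to second
  s2 <- tibble::tibble(
    tx_hash = c("s1", "s2", "p1", "p2"), address = "0xaa", app = "a", game = "g",
    timestamp = utc("2020-01-01 00:00:00") + 1:4,
    direction = c("to_app", "to_app", "from_app", "from_app"),
    value = c(1, 2, 10, 20)
  )
  res2 <- match_bets(s2)
  expect_equal(res2$bets$payout[res2$bets$bet_hash == "s1"], 10)
  expect_equal(res2$bets$payout[res2$bets$bet_hash == "s2"], 20)

  # payout with no eligible prior stake is an orphan
  s3 <- tibble::tibble(
    tx_hash = c("p1", "s1"), address = "0xaa", app = "a", game = "g",
    timestamp = utc("2020-01-01 00:00:00") + 1:2,
    direction = c("from_app", "to_app"), value = c(5, 1)
  )
  res3 <- match_bets(s3)
  expect_equal(res3$bets$payout, 0)
  expect_equal(res3$report$n_orphan_payouts, 1L)

  # a lookahead window lets a marginally-early payout match
  res3b <- match_bets(s3, lookahead = 5)
  expect_equal(res3b$bets$payout, 5)
  expect_equal(res3b$report$n_orphan_payouts, 0L)
})

test_that("match_bets validates ordering, stream key, and empty input", {
  s <- tibble::tibble(
    tx_hash = c("s1", "s2"), address = "0xaa", app = "a", game = "g",
    timestamp = utc("2020-01-01 00:00:00") + c(10, 1),
    direction = "to_app", value = 1
  )
  expect_error(match_bets(s), class = "betledger_ordering_error")
  s$timestamp <- rev(s$timestamp)
  s$address <- c("0xaa", "0xbb")
  expect_error(match_bets(s), class = "betledger_domain_error")
  empty <- s[0, ]
  res <- match_bets(empty)
  expect_equal(nrow(res$bets), 0)
  expect_equal(sum(unlist(res$report)), 0)
})

test_that("matching conserves money and ignores input row order", {
  for (seed in 1:20) {
    stream <- random_stream(12, seed = seed)
    res <- match_ledger(stream)
    stakes_in <- sum(stream$value[stream$direction == "to_app" & stream$value > 0])
    payouts_in <- sum(stream$value[stream$direction == "from_app"])
    expect_equal(sum(res$bets$stake), stakes_in)
    expect_lte(sum(res$bets$payout), payouts_in + 1e-12)
    if (res$report$n_orphan_payouts == 0) {
      expect_equal(sum(res$bets$payout), payouts_in)
    }
    shuffled <- stream[sample(nrow(stream)), ]
    expect_equal(match_ledger(shuffled), res)
  }
})

test_that("greedy matching equals the exhaustive earliest-first oracle", {
  for (seed in 1:60) {
    n <- sample(2:8, 1)
    stream <- random_stream(n, seed = seed + 1000)
    res <- match_bets(stream)
    st <- stream[stream$direction == "to_app", ]
    pt <- stream[stream$direction == "from_app", ]
    assign <- match_oracle(as.numeric(st$timestamp), as.numeric(pt$timestamp))
    hit <- !is.na(assign)
    expected_payout <- numeric(nrow(st))
    expected_payout[assign[hit]] <- pt$value[hit]
    got <- res$bets[match(st$tx_hash, res$bets$bet_hash), ]
    expect_equal(got$payout, expected_payout)
    expect_equal(res$report$n_orphan_payouts, sum(!hit))
  }
})

test_that("matched bets round-trip losslessly through CSV", {
  bets <- make_bets("0xaa",
                    times = sprintf("2020-01-%02d 12:00:%02d", c(1, 1, 2, 3, 5, 5, 6, 7, 8, 9), 0:9),
                    stakes = seq(0.1, 1, by = 0.1),
                    payouts = c(0.19, 0, 0, 0.4, 0, 0.6, 0, 0, 0.9, 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_matched_bets(bets, f)
  back <- read_matched_bets(f)
  expect_equal(back, bets)
  # fixed point: write the read table again, files are identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_matched_bets(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("matched-bet reader forces payout to zero when the hash is absent", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "address,app,game,bet_time,stake_eth,payout_eth,bet_hash,payout_hash",
    "0xaa,a,g,2020-01-01T00:00:00Z,1,0.5,b1,",
    "0xaa,a,g,2020-01-01T00:01:00Z,1,1.9,b2,p2"
  ), f)
  back <- read_matched_bets(f)
  expect_equal(back$payout, c(0, 1.9))

  f_dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "address,app,game,bet_time,stake_eth,payout_eth,bet_hash,payout_hash",
    "0xaa,a,g,2020-01-01T00:00:00Z,1,0,b1,",
    "0xaa,a,g,2020-01-01T00:01:00Z,1,0,b1,"
  ), f_dup)
  expect_error(read_matched_bets(f_dup), class = "betledger_integrity_error")

  # empty table -> header-only file
  f_empty <- withr::local_tempfile(fileext = ".csv")
  write_matched_bets(make_bets("0xaa", character(), numeric(), numeric()), f_empty)
  expect_equal(length(readLines(f_empty)), 1)
  expect_equal(nrow(read_matched_bets(f_empty)), 0)
})
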