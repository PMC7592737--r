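#' Column mapping for raw transaction ledgers
#'
#' A ledger CSV has one row per on-chain transfer to or from an application
#' contract. `transaction_schema()` names the columns the reader expects;
#' override any entry to point at differently-named columns in your file.
#'
#' @param tx_hash,address,app,game,timestamp,direction,value Column names in
#'   the file holding, respectively: the unique transaction identifier, the
#'   player address, the application label, the game label, the UTC
#'   timestamp, the transfer direction (`"to_app"` for stakes, `"from_app"`
#'   for payouts), and the transferred amount in ETH.
#' @return Named character vector mapping canonical field names to file
#'   column names.
#' @export
transaction_schema <- function(tx_hash = "tx_hash", address = "address",
                               app = "app", game = "game",
                               timestamp = "timestamp",
                               direction = "direction", value = "value") {
  c(tx_hash = tx_hash, address = address, app = app, game = game,
    timestamp = timestamp, direction = direction, value = value)
}

#' Read a raw transaction ledger
#'
#' Reads a delimited-text ledger, maps its columns through `schema`,
#' validates each row, and returns the clean records sorted by
#' (address, timestamp, tx_hash). Malformed rows are never silently
#' dropped: they are collected into a rejects table (see
#' [rejected_rows()]) with one reason per row, and a message reports the
#' count. Zero-value stake rows cannot be bets and are rejected with
#' reason `"zero_value_stake"`; addresses are lower-cased (hex-address
#' convention).
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Mapping from canonical names to file columns, as built by
#'   [transaction_schema()].
#' @return A tibble of transaction records with columns `tx_hash`,
#'   `address`, `app`, `game`, `timestamp` (POSIXct, UTC), `direction`,
#'   `value`, carrying the rejects table as attribute `"rejects"`.
#' @export
read_transactions <- function(path, schema = transaction_schema()) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing) > 0) {
    abort_schema(sprintf("ledger is missing mapped column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  df <- tibble::tibble(
    tx_hash = raw[[schema[["tx_hash"]]]],
    address = tolower(raw[[schema[["address"]]]]),
    app = raw[[schema[["app"]]]],
    game = raw[[schema[["game"]]]],
    timestamp = suppressWarnings(readr::parse_datetime(raw[[schema[["timestamp"]]]])),
    direction = raw[[schema[["direction"]]]],
    value = suppressWarnings(as.numeric(raw[[schema[["value"]]]]))
  )
  df$timestamp <- as_utc_time(df$timestamp)

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$timestamp)] <- "bad_timestamp"
  reason[is.na(reason) & is.na(df$value)] <- "bad_value"
  reason[is.na(reason) & df$value < 0] <- "negative_value"
  reason[is.na(reason) & !(df$direction %in% c("to_app", "from_app"))] <- "bad_direction"
  reason[is.na(reason) & df$direction == "to_app" & df$value == 0] <- "zero_value_stake"

  rejects <- df[!is.na(reason), ]
  rejects$reason <- reason[!is.na(reason)]
  records <- df[is.na(reason), ]

  if (anyDuplicated(records$tx_hash)) {
    abort_integrity("duplicate tx_hash values in ledger")
  }
  records <- dplyr::arrange(records, .data$address, .data$timestamp, .data$tx_hash)
  if (nrow(rejects) > 0) {
    message(sprintf("read_transactions: rejected %d malformed row(s); see rejected_rows()",
                    nrow(rejects)))
  }
  attr(records, "rejects") <- rejects
  records
}

#' Rows rejected while reading a ledger
#'
#' @param records A transaction table returned by [read_transactions()].
#' @return Tibble of rejected rows with a `reason` column (empty if none).
#' @export
rejected_rows <- function(records) {
  attr(records, "rejects") %||% tibble::tibble()
}

# Greedy earliest-first queue matching on one time-sorted stream.
# stake_time / payout_time are numeric seconds; returns the stake index
# matched to each payout (NA = orphan payout with no eligible prior stake).
match_stream <- function(stake_time, payout_time, lookahead = 0) {
  ns <- length(stake_time)
  match_idx <- rep(NA_integer_, length(payout_time))
  head_i <- 1L
  for (j in seq_along(payout_time)) {
    if (head_i <= ns && stake_time[head_i] <= payout_time[j] + lookahead) {
      match_idx[j] <- head_i
      head_i <- head_i + 1L
    }
  }
  match_idx
}

matched_bet_cols <- c("address", "app", "game", "bet_time", "stake", "payout",
                      "bet_hash", "payout_hash")

#' Pair payouts with stakes in a single player-game stream
#'
#' Implements the chronological matching rule for contract ledgers: an
#' outgoing (payout) transaction is taken to be the payout of the earliest
#' previously placed, still-unmatched bet from the same address. Stakes
#' never receive more than one payout; stakes left unmatched are losing
#' bets (payout 0); payouts with no eligible prior stake are reported as
#' orphans.
#'
#' @param records Transaction records of one (address, app, game) stream,
#'   sorted by timestamp.
#' @param lookahead Seconds by which a payout may precede its stake and
#'   still match, for ledgers where one transaction is recorded marginally
#'   ahead of another. Default 0 (strict chronology).
#' @return A list with `bets` (tibble of matched bets: `address`, `app`,
#'   `game`, `bet_time`, `stake`, `payout`, `bet_hash`, `payout_hash`) and
#'   `report` (one-row tibble: `n_bets_matched`, `n_bets_unmatched`,
#'   `n_orphan_payouts`).
#' @export
match_bets <- function(records, lookahead = 0) {
  if (nrow(records) == 0) {
    return(list(
      bets = empty_matched_bets(),
      report = tibble::tibble(n_bets_matched = 0L, n_bets_unmatched = 0L,
                              n_orphan_payouts = 0L)
    ))
  }
  key <- unique(records[, c("address", "app", "game")])
  if (nrow(key) != 1L) {
    abort_domain("match_bets() expects records of a single (address, app, game) stream; use match_ledger() for full ledgers")
  }
  if (is.unsorted(as.numeric(records$timestamp))) {
    abort_ordering("records must be sorted by timestamp")
  }
  res <- match_stream_records(records, lookahead)
  res$bets <- dplyr::arrange(res$bets, .data$bet_time, .data$bet_hash)
  res
}

empty_matched_bets <- function() {
  tibble::tibble(address = character(), app = character(), game = character(),
                 bet_time = as_utc_time(numeric()), stake = numeric(),
                 payout = numeric(), bet_hash = character(),
                 payout_hash = character())
}

# Core matcher over pre-sorted stream index groups. Works on plain
# vectors so large ledgers with many small streams stay cheap.
match_indexed <- function(records, groups, lookahead) {
  dir <- records$direction
  val <- records$value
  ts <- as.numeric(records$timestamp)
  n_orphans <- 0L
  stake_idx <- vector("list", length(groups))
  pay_value <- vector("list", length(groups))
  pay_hash <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    ii <- groups[[k]]
    si <- ii[dir[ii] == "to_app" & val[ii] > 0]
    pi <- ii[dir[ii] == "from_app"]
    idx <- match_stream(ts[si], ts[pi], lookahead)
    hit <- !is.na(idx)
    pv <- numeric(length(si))
    ph <- rep(NA_character_, length(si))
    pv[idx[hit]] <- val[pi][hit]
    ph[idx[hit]] <- records$tx_hash[pi][hit]
    stake_idx[[k]] <- si
    pay_value[[k]] <- pv
    pay_hash[[k]] <- ph
    n_orphans <- n_orphans + sum(!hit)
  }
  si <- unlist(stake_idx)
  payout <- unlist(pay_value)
  payout_hash <- unlist(pay_hash) %||% character()
  bets <- tibble::tibble(
    address = records$address[si], app = records$app[si],
    game = records$game[si], bet_time = records$timestamp[si],
    stake = val[si], payout = payout %||% numeric(),
    bet_hash = records$tx_hash[si],
    payout_hash = payout_hash
  )
  n_matched <- sum(!is.na(payout_hash))
  list(bets = bets,
       report = tibble::tibble(
         n_bets_matched = n_matched,
         n_bets_unmatched = nrow(bets) - n_matched,
         n_orphan_payouts = n_orphans
       ))
}

match_stream_records <- function(records, lookahead) {
  match_indexed(records, list(seq_len(nrow(records))), lookahead)
}

#' Match a full multi-player ledger
#'
#' Splits a transaction table into (address, app, game) streams, applies
#' the matching rule of [match_bets()] to each, and combines the results.
#' Input need not be pre-sorted; streams are time-sorted internally, so
#' the result is invariant to row order of the input.
#'
#' @inheritParams match_bets
#' @param records Transaction records for any number of players and games.
#' @return As [match_bets()]; the report aggregates all streams.
#' @export
match_ledger <- function(records, lookahead = 0) {
  if (nrow(records) == 0) return(match_bets(records, lookahead))
  ord <- order(records$address, records$app, records$game,
               records$timestamp, records$tx_hash)
  records <- records[ord, ]
  key <- paste(records$address, records$app, records$game, sep = "\r")
  groups <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  res <- match_indexed(records, groups, lookahead)
  res$bets <- dplyr::arrange(res$bets, .data$address, .data$app, .data$game,
                             .data$bet_time, .data$bet_hash)
  res
}

#' Write / read matched-bet tables
#'
#' Matched bets are stored as CSV with the stable column set `address,
#' app, game, bet_time, stake_eth, payout_eth, bet_hash, payout_hash`
#' (bet_time ISO-8601 UTC), mirroring deposited matched-bet data layouts
#' that carry the hashes of both the bet placement and the payout
#' transaction. The round trip is lossless. On read, a missing
#' `payout_hash` cell marks a losing bet and forces `payout` to 0.
#'
#' @param bets Matched-bet tibble as produced by [match_bets()].
#' @param path File path.
#' @return `write_matched_bets()` returns `path` invisibly;
#'   `read_matched_bets()` returns a matched-bet tibble.
#' @export
write_matched_bets <- function(bets, path) {
  out <- tibble::tibble(
    address = bets$address, app = bets$app, game = bets$game,
    bet_time = format_utc(bets$bet_time),
    stake_eth = bets$stake, payout_eth = bets$payout,
    bet_hash = bets$bet_hash, payout_hash = bets$payout_hash
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_matched_bets
#' @export
read_matched_bets <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      address = readr::col_character(), app = readr::col_character(),
      game = readr::col_character(), bet_time = readr::col_datetime(),
      stake_eth = readr::col_double(), payout_eth = readr::col_double(),
      bet_hash = readr::col_character(), payout_hash = readr::col_character()
    ),
    progress = FALSE
  )
  if (anyDuplicated(raw$bet_hash)) abort_integrity("duplicate bet_hash values in matched-bet file")
  bets <- tibble::tibble(
    address = tolower(raw$address), app = raw$app, game = raw$game,
    bet_time = as_utc_time(raw$bet_time), stake = raw$stake_eth,
    payout = ifelse(is.na(raw$payout_hash), 0, raw$payout_eth),
    bet_hash = raw$bet_hash, payout_hash = raw$payout_hash
  )
  bets
}

#' Write a raw transaction ledger
#'
#' Emits the same CSV layout [read_transactions()] reads with the default
#' schema, with ISO-8601 UTC timestamps.
#'
#' @param records Transaction records tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(records, path) {
  out <- tibble::tibble(
    tx_hash = records$tx_hash, address = records$address,
    app = records$app, game = records$game,
    timestamp = format_utc(records$timestamp),
    direction = records$direction, value = records$value
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
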