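#' Screen a transaction ledger for bot-dominated groups
#'
#' Convenience composition of the screening stage: match the ledger,
#' compute per-group behavioural measures (one row per address within
#' each application-game combination), build the pairwise K-S matrix and
#' apply the flag rule.
#'
#' @param records Transaction records (see [read_transactions()] /
#'   [simulate_population()]).
#' @inheritParams flag_nonhuman
#' @inheritParams match_bets
#' @return A list with `flags` (a `flag_report`), `ks` (the `ks_matrix`),
#'   `measures` (the per-group measures table) and `bets`/`match_report`.
#' @export
screen_ledger <- function(records, theta = 0.35, alpha = 0.01, phi = 0.75,
                          p_adjust = "none", lookahead = 0) {
  matched <- match_ledger(records, lookahead = lookahead)
  per_group <- measures_table(matched$bets, by = "address_game")
  km <- pairwise_ks_matrix(per_group)
  flags <- flag_nonhuman(km, theta = theta, alpha = alpha, phi = phi,
                         p_adjust = p_adjust)
  list(flags = flags, ks = km, measures = per_group,
       bets = matched$bets, match_report = matched$report)
}

#' Configure an end-to-end pipeline run
#'
#' Exactly one input source must be given: a raw transaction ledger CSV
#' (`transactions`), a pre-matched bet CSV (`matched_bets`), or a
#' simulation (`simulate`).
#'
#' @param transactions Path to a raw ledger CSV, or NULL.
#' @param matched_bets Path to a matched-bet CSV, or NULL.
#' @param simulate A [sim_config()], or NULL.
#' @param out_dir Output directory (created if absent).
#' @param theta,alpha,phi,p_adjust Bot-screen thresholds, see
#'   [flag_nonhuman()].
#' @param q Heavy-involvement split quantile, see [heavy_split()].
#' @param lookahead Matching lookahead window in seconds.
#' @param fiat_rate Optional ETH-to-fiat rate; when set, financial
#'   columns are additionally reported in fiat in the run report (the
#'   stored measures stay in ETH).
#' @param schema Ledger column mapping for `transactions` input.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(transactions = NULL, matched_bets = NULL,
                            simulate = NULL, out_dir = tempfile("betledger_run_"),
                            theta = 0.35, alpha = 0.01, phi = 0.75,
                            p_adjust = "none", q = 0.95, lookahead = 0,
                            fiat_rate = NULL, schema = transaction_schema()) {
  n_sources <- sum(!is.null(transactions), !is.null(matched_bets), !is.null(simulate))
  if (n_sources != 1L) {
    abort_config("exactly one input source is required: `transactions`, `matched_bets`, or `simulate`")
  }
  check_fraction(theta, "theta"); check_fraction(alpha, "alpha")
  check_fraction(phi, "phi")
  if (q <= 0 || q >= 1) abort_config("`q` must be strictly between 0 and 1")
  structure(list(transactions = transactions, matched_bets = matched_bets,
                 simulate = simulate, out_dir = out_dir, theta = theta,
                 alpha = alpha, phi = phi, p_adjust = p_adjust, q = q,
                 lookahead = lookahead, fiat_rate = fiat_rate, schema = schema),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest (or simulation), stake/payout matching, per-group
#' behavioural measures, the pairwise K-S bot screen, wholesale removal
#' of flagged groups at the transaction level, and the cohort analytics
#' on the retained unique-address measures table: non-parametric
#' descriptives, the Spearman matrix, and the heavy-involvement split.
#' Writes all stage outputs as CSV plus a YAML run report into
#' `config$out_dir`; runs are fully deterministic given the inputs and
#' the simulation seed.
#'
#' Output files: `matched_bets.csv`, `measures_by_group.csv`,
#' `measures.csv`, `ks_matrix.csv` (long format), `ks_<measure>.csv`
#' (square tables), `cohort_summary.csv`, `spearman_rho.csv`,
#' `spearman_p.csv`, `heavy_split_top.csv`, `heavy_split_rest.csv`,
#' `run_report.yaml`.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list (stage counts, flagged groups, thresholds,
#'   file inventory, config echo), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort_config("`config` must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character()

  n_rejected <- 0L
  if (!is.null(config$simulate)) {
    records <- simulate_population(config$simulate)
  } else if (!is.null(config$transactions)) {
    records <- read_transactions(config$transactions, schema = config$schema)
    n_rejected <- nrow(rejected_rows(records))
  } else {
    records <- NULL
  }

  if (!is.null(records)) {
    matched <- match_ledger(records, lookahead = config$lookahead)
    bets <- matched$bets
    match_report <- matched$report
    n_raw <- nrow(records)
  } else {
    bets <- read_matched_bets(config$matched_bets)
    match_report <- tibble::tibble(n_bets_matched = sum(!is.na(bets$payout_hash)),
                                   n_bets_unmatched = sum(is.na(bets$payout_hash)),
                                   n_orphan_payouts = NA_integer_)
    n_raw <- NA_integer_
  }
  if (isTRUE(match_report$n_orphan_payouts > 0)) {
    warning(sprintf("%d orphan payout(s) had no eligible prior stake",
                    match_report$n_orphan_payouts))
  }
  write_matched_bets(bets, out("matched_bets.csv"))
  files <- c(files, "matched_bets.csv")

  per_group <- measures_table(bets, by = "address_game")
  write_measures(per_group, out("measures_by_group.csv"))
  files <- c(files, "measures_by_group.csv")

  groups <- sort(unique(per_group$group))
  flags <- NULL
  km <- NULL
  if (length(groups) >= 2) {
    km <- pairwise_ks_matrix(per_group)
    flags <- flag_nonhuman(km, theta = config$theta, alpha = config$alpha,
                           phi = config$phi, p_adjust = config$p_adjust)
    readr::write_csv(ks_long(km), out("ks_matrix.csv"))
    files <- c(files, "ks_matrix.csv")
    for (msr in km$measures) {
      f <- sprintf("ks_%s.csv", msr)
      readr::write_csv(as_tibble(as.data.frame(ks_table(km, msr)),
                                 rownames = "group"), out(f))
      files <- c(files, f)
    }
  }
  flagged <- if (is.null(flags)) character() else flags$flagged
  if (length(flagged) >= length(groups) && length(groups) > 0) {
    abort_domain("all groups were flagged as non-human; no players retained")
  }

  key <- paste(bets$app, bets$game, sep = ":")
  retained_bets <- bets[!(key %in% flagged), ]
  measures <- measures_table(retained_bets, by = "address")
  write_measures(measures, out("measures.csv"))
  files <- c(files, "measures.csv")

  summary_tbl <- describe_measures(measures)
  write_cohort(summary_tbl, out("cohort_summary.csv"))
  files <- c(files, "cohort_summary.csv")

  sp <- spearman_matrix(measures)
  write_cohort(sp, out("spearman.csv"))
  files <- c(files, "spearman_rho.csv", "spearman_p.csv")

  hs <- heavy_split(measures, q = config$q)
  write_cohort(hs, out("heavy_split.csv"))
  files <- c(files, "heavy_split_top.csv",
             if (!is.null(hs$rest_summary)) "heavy_split_rest.csv")

  report <- structure(list(
    n_raw_transactions = n_raw,
    n_rejected_rows = n_rejected,
    n_matched_bets = nrow(bets),
    match_report = match_report,
    n_groups = length(groups),
    flagged_groups = flagged,
    thresholds = list(theta = config$theta, alpha = config$alpha,
                      phi = config$phi, p_adjust = config$p_adjust,
                      q = config$q, lookahead = config$lookahead),
    n_players_total = length(unique(bets$address)),
    n_players_retained = nrow(measures),
    fiat_rate = config$fiat_rate,
    median_total_wagered_fiat = if (!is.null(config$fiat_rate))
      config$fiat_rate * stats::median(measures$total_wagered) else NULL,
    files = files,
    out_dir = config$out_dir,
    version = as.character(utils::packageVersion("betledger"))
  ), class = "run_report")
  yaml::write_yaml(lapply(unclass(report), function(x) {
    if (inherits(x, "data.frame")) as.list(x) else x
  }), out("run_report.yaml"))
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("betledger pipeline run\n")
  cat(sprintf("  raw transactions : %s\n", format(x$n_raw_transactions)))
  cat(sprintf("  rejected rows    : %d\n", x$n_rejected_rows))
  cat(sprintf("  matched bets     : %d (unmatched stakes: %d, orphan payouts: %s)\n",
              x$n_matched_bets, x$match_report$n_bets_unmatched,
              format(x$match_report$n_orphan_payouts)))
  cat(sprintf("  groups           : %d, flagged: %s\n", x$n_groups,
              if (length(x$flagged_groups) == 0) "none" else
                paste(x$flagged_groups, collapse = ", ")))
  cat(sprintf("  players          : %d total, %d retained\n",
              x$n_players_total, x$n_players_retained))
  cat(sprintf("  outputs in       : %s\n", x$out_dir))
  invisible(x)
}
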