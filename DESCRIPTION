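Package: betledger
Title: Behavioural Analysis of Decentralised Casino Betting Ledgers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for player-behaviour-tracking research on blockchain
    gambling transaction ledgers. Reads per-transaction CSV ledgers from
    decentralised casino applications, pairs payout transactions with the
    stakes that triggered them, computes the eight classical per-player
    behavioural measures (duration, frequency, number of bets, bets per
    active day, mean bet size, total wagered, net loss, percent loss),
    screens application-game groups for likely non-human (bot) players via
    a pairwise two-sample Kolmogorov-Smirnov matrix across measures, and
    produces cohort analytics: non-parametric descriptives with normality
    statistics, Spearman rank correlations, and a 95:5 heavy-involvement
    split by total wagered. Includes a seeded agent-based generator of
    synthetic transaction ledgers (heavy-tailed human bettors, fixed
    house-edge games, near-degenerate bot populations) so the full
    pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
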