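# betledger

Player-behaviour-tracking analytics for decentralised casino transaction
ledgers.

Decentralised gambling applications are casino-style games (dice rolls,
coin flips) implemented as smart contracts on a public blockchain. Every
stake is a transfer *to* the contract and every winning payout a transfer
*from* it, so a complete, pre-anonymised record of each player's betting
career is publicly available — an unusually rich data source for gambling
epidemiology. `betledger` turns such per-transaction ledgers into the
classical behavioural-measure analyses used in player behaviour tracking
research, for researchers studying spending patterns, heavy involvement,
and data-quality hazards (notably algorithmic, non-human bettors) in this
domain.

## What it computes

**Bet/payout matching.** Within each (address, application, game) stream,
an outgoing transaction chronologically following an incoming one is
taken as the payout of the earliest still-unmatched prior bet; unmatched
stakes are losses (payout 0), payouts with no eligible prior stake are
reported as orphans.

**Behavioural measures.** For each player with bets at times
t<sub>1</sub> … t<sub>n</sub>, stakes s<sub>i</sub>, payouts
p<sub>i</sub>:

- duration `d` — calendar days from first to last bet, inclusive (a
  22:00 bet and a 09:00 bet the next day span 2 days);
- frequency — `100 · a / d`, where `a` is the number of distinct days
  with at least one bet;
- number of bets `n`; bets per active day — `n / a`;
- mean bet size — `W / n`, total wagered — `W = Σ sᵢ` (ETH);
- net loss — `L = Σ sᵢ − Σ pᵢ`; percent loss — `100 · L / W`.

**Bot screening.** Per-game measure distributions are compared pairwise
with the two-sample Kolmogorov–Smirnov statistic
`D = sup_x |F̂₁(x) − F̂₂(x)|`, giving a G × G × M coefficient array. A
group whose distribution stands out against almost all others (default:
`D ≥ 0.35` with `p < 0.01` against at least 75% of other groups, on any
measure) is flagged as likely non-human — algorithmic bettors driven by
few parameters produce near-degenerate behavioural distributions.

**Cohort analytics.** On the retained players: mean/STD/median/IQR with
one-sample K-S normality coefficients per measure; Spearman rank
correlations between measures; and the empirical 95:5 heavy-involvement
split by total wagered (top `⌈0.05 n⌉` players).

**Synthetic ledgers.** A seeded agent-based generator (heavy-tailed
human bettors on fixed house-edge games, plus near-degenerate bot
populations) emits ledgers in the exact input format, so the entire
pipeline is testable end to end without any external data.

## Worked example

```r
library(betledger)

cfg    <- sim_config(seed = 42)          # 5 human groups + 1 bot-dominated group
ledger <- simulate_population(cfg)       # 83,752 transaction records
scr    <- screen_ledger(ledger)
scr$flags
#> Non-human group screen (theta = 0.35, alpha = 0.01, phi = 0.75, p_adjust = none)
#> Flagged groups: dapp_c:coinflip
#> Strongest evidence (fraction of other groups exceeded):
#>            group       measure frac_exceeding
#>  dapp_c:coinflip      duration              1
#>  dapp_c:coinflip        n_bets              1
#>  dapp_c:coinflip  bets_per_day              1
#>  dapp_c:coinflip      mean_bet              1
#>  dapp_c:coinflip total_wagered              1
```

The screen flags exactly the bot-dominated coin-flip group: its players'
durations, bet counts and stakes separate from every human group. Drop
the flagged group and describe the retained cohort:

```r
retained <- scr$bets[!(paste(scr$bets$app, scr$bets$game, sep = ":")
                       %in% scr$flags$flagged), ]
players  <- measures_table(retained, by = "address")
describe_measures(players)
#> # A tibble: 8 × 8
#>   measure         mean    std   median    iqr   ks_D      ks_p     n
#> 1 duration       4.9   10.4     1       4     0.353  0          1000
#> 2 frequency     88.5   22.3   100      12.5   0.436  0          1000
#> 3 n_bets        19.6   28.6    10      18     0.257  0          1000
#> 4 bets_per_day  13.5   20.9     6      13     0.276  0          1000
#> 5 mean_bet       0.296  0.603   0.116   0.258 0.312  0          1000
#> 6 total_wagered  5.30  15.7     1.07    3.54  0.368  0          1000
#> 7 net_loss       0.302  2.81    0.0209  0.473 0.278  0          1000
#> 8 percent_loss   3.12  44.4     3.56   42.0   0.0775 0.0000122  1000
```

The typical synthetic player bets on a single day (median duration 1,
frequency 100%), places ~10 bets of ~0.1 ETH, and loses a few percent of
the total wagered; every measure is heavily non-normal (large K-S
coefficients), which is why medians, IQRs and rank correlations carry the
description. The heavy-involvement split:

```r
heavy_split(players)
#> Heavy-involvement split at q = 0.95: top 50, rest 950 players (threshold 20.31 ETH wagered)
#> Top cohort:    median n_bets 45, median total wagered 34.6 ETH, ...
#> Remaining:     median n_bets  9, median total wagered 0.97 ETH, ...
```

The top 5% wager ~35× the majority's median — the concentration of
spending that makes this split the standard lens for heavy involvement.

`run_pipeline(pipeline_config(simulate = cfg, out_dir = "out"))` runs all
stages and writes every table (matched bets, per-group and per-player
measures, the K-S matrix in long and square form, cohort summary,
Spearman matrices, split summaries) as CSV plus a YAML run report. Real
ledgers enter through `pipeline_config(transactions = "ledger.csv")` or
pre-matched bets through `matched_bets =`. A thin command-line wrapper
with `simulate` / `match` / `measures` / `screen` / `run` subcommands is
installed at `inst/scripts/betledger-cli.R`.

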