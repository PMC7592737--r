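---
title: "Methods: behavioural measures, bot screening, and the synthetic bettor population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural measures, bot screening, and the synthetic bettor population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`betledger` analyses transaction ledgers of decentralised gambling
applications: smart-contract casinos where each stake is an on-chain
transfer to the contract and each winning payout a transfer back. This
vignette documents the statistical procedures, the design choices made
where the problem left them open, and exactly what the synthetic
population does and does not emulate.

## Bet/payout matching

A contract ledger records transfers, not bets. The matching rule treats
an outgoing (`from_app`) transaction as the payout of a previously
placed bet from the same address: within each (address, application,
game) stream, time-sorted, each payout is assigned to the **earliest
unmatched stake** with stake time ≤ payout time. Unmatched stakes are
losing bets (dice-style contracts pay winners only), so their payout is
0; payouts with no eligible prior stake are counted as orphans and
reported, never silently dropped.

Choices worth knowing:

* **Strictness.** By default no reordering tolerance is applied: a
  payout recorded even one second before its stake does not match. An
  optional `lookahead` window (seconds) relaxes this for ledgers where
  one transaction can be recorded marginally ahead of another; the
  strict default is preferred because it is exactly reproducible.
* **Ambiguity is harmless for aggregates.** When a player has several
  unresolved stakes, earliest-first assignment may pair a payout with a
  different stake than the game engine did. All eight behavioural
  measures are per-player aggregates (sums and time spans), which are
  invariant to which eligible stake a payout is attached to. Analyses
  that need true bet-level pairing (e.g. loss-chasing) are out of scope.
* **Hygiene.** Zero-value stakes cannot be bets and are rejected with a
  logged reason, as are rows with unparseable timestamps or values.
  Addresses are compared case-insensitively and stored lower-case.
  Timestamps are UTC throughout (block timestamps are UTC).

Greedy earliest-first matching is verified in the test suite against an
exhaustive oracle that enumerates every maximum-cardinality assignment
on streams of up to 8 transactions.

## The eight behavioural measures

For a player with bets at UTC instants $t_1,\dots,t_n$, stakes $s_i$ and
payouts $p_i$:

| measure | definition | unit |
|---|---|---|
| duration | calendar days spanned, inclusive | days |
| frequency | $100 \cdot a/d$, $a$ = distinct betting days | % |
| n_bets | $n$ | count |
| bets_per_day | $n / a$ (per *active* day) | count/day |
| mean_bet | $W/n$ | ETH |
| total_wagered | $W = \sum s_i$ | ETH |
| net_loss | $L = W - \sum p_i$ (negative = net win) | ETH |
| percent_loss | $100 \cdot L/W$ | % |

Duration rounds up at midnight boundaries: bets at 22:00 and 09:00 the
next day span two days despite being under 24 h apart, so a single-day
bettor always has frequency 100%. "Days" are UTC midnights. Temporal
measures use bet-placement times only; payout timestamps never enter.
Fiat conversion, when wanted, is a presentation-layer multiplication by
one configured rate and is never stored in the measures table.

## Screening for non-human players

Public contracts attract algorithmic bettors (bots) — to inflate
perceived popularity or chase jackpot conditions — and their transactions
would contaminate any epidemiological description of *human* play. Bots
driven by few parameters produce near-degenerate measure distributions,
so a game whose player-measure distributions separate from *almost all*
other games is a bot candidate.

The screen computes, for every pair of application-game groups and every
measure, the two-sample Kolmogorov–Smirnov statistic (the ECDF sup
distance, evaluated at all pooled points with right-continuous steps,
ties included) with the asymptotic p-value at effective size
$n_1 n_2/(n_1+n_2)$, yielding a G×G×M array. P-values are deliberately
reported uncorrected — at G×G×M scale their individual descriptive power
is limited either way, and the coefficient magnitudes carry the signal;
a Bonferroni/BH switch is available for the decision rule.

The flag rule quantifies "stands out against almost all others": group
$g$ is flagged iff for some measure the fraction of other groups $h$
with $D_{gh} \ge \theta$ and $p_{gh} < \alpha$ reaches $\phi$. Defaults
$\theta = 0.35$, $\alpha = 0.01$, $\phi = 0.75$ follow the common
reporting convention of highlighting K-S coefficients above 0.35 at
p < 0.01, and requiring "almost all" (≥ 75%) other groups keeps a single
anomalous pairing from flagging anyone. The report always carries the
full per-measure evidence, so a second-most-extreme group can be
inspected without being auto-removed; removal is wholesale at the
transaction level and only ever of flagged groups.

## Cohort analytics

All measures are heavily right-skewed, so the descriptives lead with
medians and IQRs. Conventions:

* Percentiles use linear interpolation (`quantile` type 7), so IQRs are
  reproducible elsewhere; STD is the sample (n−1) version.
* The normality coefficient is the one-sample K-S statistic of the
  sample standardised by **its own** mean and SD against the standard
  normal. Estimating parameters from the same sample biases the
  p-values anti-conservative (the Lilliefors caveat); the statistic is
  used as the conventional descriptive coefficient, and with the
  D ≈ 0.2–0.9 magnitudes these measures produce, the verdict does not
  hinge on the correction.
* Spearman correlations use midranks for ties (rho is the Pearson
  correlation of ranks) with asymptotic t p-values; a constant column
  has undefined rank correlation and is reported as missing, never 0.
* The heavy-involvement split ranks players by total wagered and takes
  the top $\lceil (1-q)\,n \rceil$ (default q = 0.95; e.g. 518 of a
  10,357-player cohort). Ties are broken by address so the partition is
  deterministic; the ceiling is guarded against floating-point excess
  (0.05 × 800 must give 40, not 41).

Cohort analytics run on the unique-address measures table computed
*after* flagged-group removal, so one address betting in several
retained games is a single player with pooled bets.

## The synthetic population

The generator exists so the full pipeline — ingest, matching, measures,
screen, cohort stats — can be exercised end to end, with known ground
truth, without downloading anything. It emulates the statistical
structure the analysis assumes:

* **Games** have fixed win probability $p$ and payout multiplier $m$,
  house edge $e = 1 - pm$; a winning bet pays $s\,m$ one confirmation
  delay (30 s) after the stake. The five default human games are
  near-even-odds (edges 1–3%).
* **Human bettors** are heavy-tailed: bet counts are rounded log-normal
  (median 10); each player has a characteristic stake level, log-normal
  across players (median 0.1 ETH, log-sd 1.5) with smaller within-player
  variation (log-sd 0.3) around it — players keep a typical stake but
  vary it bet to bet; careers mix a 55% point mass of single-day players
  with a log-normal tail of multi-day spans (capped at one year), a
  Beta-distributed fraction of career days active, and one short betting
  session per active day. The resulting typical player — median one
  active day, frequency 100%, ~10 bets of ~0.1 ETH — matches the shape
  reported for real decentralised-casino cohorts, without claiming to
  reproduce any table exactly.
* **Bots** are the minimal near-degenerate mechanism: a near-constant
  number of bets (200 ± 2) of near-constant stake (0.05 ETH) at exactly
  regular intervals over a fixed 180-day span. The default population
  has five human groups of 200 and one group of 180 bots + 20 humans —
  one game dominated by algorithmic traffic.
* **Determinism.** The master seed is mandatory; per-player seeds are
  derived from it and the group/player indices, so a config file
  reproduces the ledger byte-for-byte (YAML numerics are written at
  precision 17 for this reason), and any single player's stream can be
  regenerated in isolation.

Design notes. The human groups share one profile and near-identical
odds deliberately: they are the screen's null population, and groups
must be exchangeable for "flagged exactly the bot group" to be the
correct answer. A long-odds game (say a 1-in-12 double-dice at 11.7×)
gives its players a *genuinely* different percent-loss distribution —
~40% of ten-bet players lose exactly 100% — and the screen rightly
reports it as a distinct population; that is a property of the method,
not a defect, but it makes such games unsuitable as null groups. The
within-player stake variation puts a small (≈ 4–7%) upward bias on
mean-of-stakes relative to the stake median — the price of realism, and
well inside the 10% recovery band checked in the tests.

What the generator does **not** emulate: within-day session clustering
beyond a single session window, gas fees, jackpot mechanics,
exchange-rate dynamics, addresses shared by several humans, or bots
with adaptive strategies. Passing tests therefore demonstrate that the
pipeline recovers the structure this generator plants — not that real
ledgers contain no subtler non-human behaviour.

## Problem sizes and numerical tolerances

The test suite and acceptance script use desk-scale sizes chosen to make
the statistics decisive: 100 seeded populations (~1,200 players,
~80,000 transactions each) for the screen's power and 50 bot-free
populations for its size; 25 players × 10⁴ bets for house-edge recovery
(binomial SE gives a ±3 SE ≈ ±2.85 percentage-point band around the 5%
edge); 30 replicate populations of 500 humans for stake-median recovery
(a single cohort median has ~8% sampling SE, so replication — not a
larger cohort — supplies the power). Money conservation is exact up to
floating-point summation (~10⁻¹³ ETH on 10⁵ transactions). Oracle
comparisons (K-S, matching, Spearman) are exact equalities at default
numerical tolerance.

## Known limitations

* The matching rule cannot resolve true bet-payout pairings under
  concurrency; only aggregate-safe analyses should rely on it.
* The uncorrected pairwise K-S matrix is a screening device, not an
  inference procedure; with very many groups the flag rule's α is
  nominal only.
* One-sample K-S p-values are Lilliefors-biased as documented above.
* Measures assume one address = one player; address clustering and
  cross-application identity are out of scope.
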