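#' One-sample K-S statistic against a fitted normal
#'
#' Standardises the sample by its own mean and standard deviation and
#' computes the supremum distance between the empirical CDF and the
#' standard normal CDF, with the asymptotic p-value. Because the normal
#' parameters are estimated from the same sample the p-values carry the
#' usual Lilliefors bias (anti-conservative); the statistic is reported as
#' the conventional descriptive normality coefficient for heavily skewed
#' behavioural measures, not as a calibrated test.
#'
#' @param sample Numeric vector, n >= 3, non-constant.
#' @return List with `D` and `p`.
#' @export
ks_normality <- function(sample) {
  sample <- sample[!is.na(sample)]
  if (length(sample) < 3) abort_domain("ks_normality() needs at least 3 values")
  s <- stats::sd(sample)
  if (!is.finite(s) || s == 0) abort_domain("ks_normality() is undefined for a constant sample")
  z <- (sample - mean(sample)) / s
  ht <- suppressWarnings(stats::ks.test(z, "pnorm", exact = FALSE))
  list(D = unname(ht$statistic), p = unname(ht$p.value))
}

#' Non-parametric cohort descriptives
#'
#' Per measure: mean, sample standard deviation (n - 1), median,
#' inter-quartile range (75th minus 25th percentile, linear
#' interpolation), and the one-sample K-S normality coefficient with its
#' p-value. Degenerate columns (constant, or fewer than 3 values) get
#' `NA` K-S entries; a single-row cohort reports STD 0.
#'
#' @param measures Measures table (one row per player).
#' @param measure_names Columns to summarise; defaults to the eight
#'   behavioural measures present in the table.
#' @return A tibble (`cohort_summary`) with one row per measure and
#'   columns `measure`, `mean`, `std`, `median`, `iqr`, `ks_D`, `ks_p`,
#'   `n`.
#' @export
describe_measures <- function(measures,
                              measure_names = intersect(behavioural_measures(),
                                                        names(measures))) {
  if (nrow(measures) == 0) abort_domain("describe_measures() needs at least one row")
  missing <- setdiff(measure_names, names(measures))
  if (length(missing) > 0) {
    abort_schema(sprintf("measures table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  n <- nrow(measures)
  rows <- lapply(measure_names, function(col) {
    x <- measures[[col]]
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    ks <- tryCatch(ks_normality(x),
                   betledger_domain_error = function(e) list(D = NA_real_, p = NA_real_))
    tibble::tibble(
      measure = col,
      mean = mean(x),
      std = if (n == 1) 0 else stats::sd(x),
      median = stats::median(x),
      iqr = q[2] - q[1],
      ks_D = ks$D,
      ks_p = ks$p,
      n = n
    )
  })
  dplyr::bind_rows(rows)
}

#' Spearman rank-order correlation matrix
#'
#' Rank correlations (midranks for ties; rho is the Pearson correlation
#' of the ranks) between all pairs of behavioural measures, preferred
#' over parametric correlations because the measures are heavily
#' non-normal. P-values use the asymptotic t approximation. A constant
#' column has no ranks to correlate: its entries are reported as missing
#' (`NA`), never as 0.
#'
#' @inheritParams describe_measures
#' @return A `cor_matrix`: list with `measures`, `rho` and `p` (M x M
#'   matrices) and `n`.
#' @export
spearman_matrix <- function(measures,
                            measure_names = intersect(behavioural_measures(),
                                                      names(measures))) {
  n <- nrow(measures)
  if (n < 3) abort_domain("spearman_matrix() needs at least 3 rows")
  M <- length(measure_names)
  rho <- matrix(NA_real_, M, M, dimnames = list(measure_names, measure_names))
  p <- matrix(NA_real_, M, M, dimnames = list(measure_names, measure_names))
  constant <- vapply(measure_names, function(col) {
    x <- measures[[col]]
    all(x == x[1])
  }, logical(1))
  for (i in seq_len(M)) {
    if (!constant[i]) {
      rho[i, i] <- 1
      p[i, i] <- 0
    }
    if (i == M) next
    for (j in seq(i + 1, M)) {
      if (constant[i] || constant[j]) next
      x <- measures[[measure_names[i]]]
      y <- measures[[measure_names[j]]]
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(measures = measure_names, rho = rho, p = p, n = n),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman rank-order correlations (n = %d)\n", x$n))
  print(round(x$rho, digits))
  invisible(x)
}

#' Split a cohort into heavy and non-heavy bettors
#'
#' The empirically determined involvement split: players are ranked by
#' total amount wagered and the top `100 * (1 - q)` percent (by default
#' the top 5%) form the heavily-involved cohort, the remainder the
#' majority cohort. The top cohort has exactly `ceiling((1 - q) * n)`
#' players; ties in total wagered are broken by address so the partition
#' is deterministic.
#'
#' @param measures Unique-address measures table with `total_wagered` and
#'   `address` columns.
#' @param q Split quantile in (0, 1); default 0.95 (a 95:5 split).
#' @return A `heavy_split`: list with `top` and `rest` (player rows),
#'   `threshold_wagered` (smallest total wagered in the top cohort), `q`,
#'   and `top_summary` / `rest_summary` from [describe_measures()].
#' @export
heavy_split <- function(measures, q = 0.95) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    abort_config("`q` must be a single number strictly between 0 and 1")
  }
  if (nrow(measures) < 1) abort_domain("heavy_split() needs at least one row")
  ord <- order(-measures$total_wagered, measures$address)
  sorted <- measures[ord, ]
  n <- nrow(sorted)
  # ceiling((1 - q) * n), guarded against floating-point excess
  # (0.05 * 800 must give 40, not ceiling(40.000000000000004) = 41)
  k <- max(1L, as.integer(ceiling((1 - q) * n - sqrt(.Machine$double.eps))))
  top <- sorted[seq_len(k), ]
  rest <- sorted[setdiff(seq_len(n), seq_len(k)), ]
  structure(list(
    top = top, rest = rest,
    threshold_wagered = min(top$total_wagered),
    q = q,
    top_summary = describe_measures(top),
    rest_summary = if (nrow(rest) > 0) describe_measures(rest) else NULL
  ), class = "heavy_split")
}

#' @export
print.heavy_split <- function(x, ...) {
  cat(sprintf("Heavy-involvement split at q = %.2f: top %d, rest %d players (threshold %.4g ETH wagered)\n",
              x$q, nrow(x$top), nrow(x$rest), x$threshold_wagered))
  cat("\nTop cohort:\n")
  print(as.data.frame(x$top_summary), row.names = FALSE, digits = 3)
  if (!is.null(x$rest_summary)) {
    cat("\nRemaining cohort:\n")
    print(as.data.frame(x$rest_summary), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write cohort outputs as delimited text
#'
#' @param x A `cohort_summary` tibble, `cor_matrix`, or `heavy_split`.
#' @param path File path (for `cor_matrix` two files are written, with
#'   `_rho` and `_p` suffixes before the extension).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  if (inherits(x, "cor_matrix")) {
    stem <- sub("\\.csv$", "", path)
    readr::write_csv(as_tibble(as.data.frame(x$rho), rownames = "measure"),
                     paste0(stem, "_rho.csv"))
    readr::write_csv(as_tibble(as.data.frame(x$p), rownames = "measure"),
                     paste0(stem, "_p.csv"))
  } else if (inherits(x, "heavy_split")) {
    stem <- sub("\\.csv$", "", path)
    readr::write_csv(x$top_summary, paste0(stem, "_top.csv"))
    if (!is.null(x$rest_summary)) {
      readr::write_csv(x$rest_summary, paste0(stem, "_rest.csv"))
    }
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}
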