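#' Two-sample Kolmogorov-Smirnov test
#'
#' The K-S II statistic: the supremum over the pooled sample points of the
#' absolute difference between the two empirical CDFs, with the p-value
#' from the asymptotic Kolmogorov distribution at effective sample size
#' `n_a * n_b / (n_a + n_b)`. Small D or high p means the two samples
#' cannot be distinguished; pairwise large-D comparisons across game
#' groups are the basis of the non-human-player screen.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `D` (statistic in \[0, 1\]) and `p`.
#' @export
ks2 <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort_domain("ks2() requires two non-empty samples")
  }
  ht <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(ht$statistic), p = unname(ht$p.value))
}

#' Pairwise K-S matrix across player groups
#'
#' For every pair of application-game groups and every behavioural
#' measure, runs [ks2()] between the two groups' per-player measure
#' distributions, producing a G x G x M array of coefficients (and one of
#' p-values). Group and measure axes are ordered deterministically
#' (groups sorted lexicographically); the matrix is symmetric with a zero
#' diagonal. P-values are reported uncorrected: run this many tests and
#' the individual p-values lose descriptive power, but the coefficient
#' magnitudes still broadly rank distributional differences (a correction
#' can be applied in [flag_nonhuman()]).
#'
#' @param measures Per-group measures table from
#'   `measures_table(bets, by = "address_game")`, or any data frame with a
#'   group column and the measure columns.
#' @param measure_names Measures to compare; default all eight.
#' @param group_col Name of the group-label column. Default `"group"`.
#' @return A `ks_matrix` object: list with `groups`, `measures`, and
#'   arrays `D` and `p` (dimensions group x group x measure).
#' @export
pairwise_ks_matrix <- function(measures, measure_names = behavioural_measures(),
                               group_col = "group") {
  if (!group_col %in% names(measures)) {
    abort_schema(sprintf("measures table has no `%s` column", group_col))
  }
  missing <- setdiff(measure_names, names(measures))
  if (length(missing) > 0) {
    abort_schema(sprintf("measures table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  groups <- sort(unique(measures[[group_col]]))
  if (length(groups) < 2) abort_domain("need at least two groups to compare")
  G <- length(groups)
  M <- length(measure_names)
  samples <- lapply(groups, function(g) measures[measures[[group_col]] == g, , drop = FALSE])
  D <- array(0, dim = c(G, G, M), dimnames = list(groups, groups, measure_names))
  p <- array(1, dim = c(G, G, M), dimnames = list(groups, groups, measure_names))
  for (m in seq_len(M)) {
    col <- measure_names[m]
    for (i in seq_len(G - 1)) {
      xi <- samples[[i]][[col]]
      for (j in seq(i + 1, G)) {
        kt <- ks2(xi, samples[[j]][[col]])
        D[i, j, m] <- D[j, i, m] <- kt$D
        p[i, j, m] <- p[j, i, m] <- kt$p
      }
    }
  }
  structure(list(groups = groups, measures = measure_names, D = D, p = p),
            class = "ks_matrix")
}

#' @export
print.ks_matrix <- function(x, ...) {
  cat(sprintf("Pairwise two-sample K-S matrix: %d x %d x %d (group x group x measure)\n",
              length(x$groups), length(x$groups), length(x$measures)))
  cat("groups:  ", paste(x$groups, collapse = ", "), "\n")
  cat("measures:", paste(x$measures, collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of a K-S matrix
#'
#' One row per unordered group pair per measure.
#'
#' @param m A `ks_matrix` from [pairwise_ks_matrix()].
#' @return Tibble with `group_a`, `group_b`, `measure`, `D`, `p`.
#' @export
ks_long <- function(m) {
  G <- length(m$groups)
  pairs <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
  out <- lapply(seq_along(m$measures), function(k) {
    tibble::tibble(
      group_a = m$groups[pairs[, 1]],
      group_b = m$groups[pairs[, 2]],
      measure = m$measures[k],
      D = m$D[cbind(pairs, k)],
      p = m$p[cbind(pairs, k)]
    )
  })
  dplyr::bind_rows(out)
}

#' One measure's slice of a K-S matrix as a square table
#'
#' @param m A `ks_matrix`.
#' @param measure Measure name.
#' @return Symmetric numeric matrix of D statistics with group dimnames.
#' @export
ks_table <- function(m, measure) {
  if (!measure %in% m$measures) abort_config(sprintf("unknown measure: %s", measure))
  m$D[, , measure]
}

#' Flag likely non-human (bot) player groups
#'
#' A group whose players' behavioural distributions stand out against
#' almost all other groups is a bot candidate: algorithmic bettors driven
#' by few parameters produce near-degenerate measure distributions that
#' separate cleanly from the human bulk. The rule: group g is flagged iff
#' for some measure, the fraction of other groups h with `D[g,h] >= theta`
#' and `p[g,h] < alpha` is at least `phi`. The defaults follow the
#' reporting convention of highlighting coefficients above 0.35 at
#' p < 0.01.
#'
#' @param m A `ks_matrix` from [pairwise_ks_matrix()].
#' @param theta K-S coefficient magnitude threshold, in \[0, 1\]. Default 0.35.
#' @param alpha Significance level, in \[0, 1\]. Default 0.01.
#' @param phi Minimum fraction of other groups exceeded, in \[0, 1\].
#'   Default 0.75.
#' @param p_adjust Multiple-testing correction applied to the pairwise
#'   p-values before thresholding (flag rule only; the matrix itself stays
#'   uncorrected): `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return A `flag_report`: list with `flagged` (character vector of group
#'   labels), `evidence` (tibble: `group`, `measure`, `frac_exceeding`) and
#'   `thresholds`.
#' @export
flag_nonhuman <- function(m, theta = 0.35, alpha = 0.01, phi = 0.75,
                          p_adjust = c("none", "bonferroni", "BH")) {
  check_fraction(theta, "theta")
  check_fraction(alpha, "alpha")
  check_fraction(phi, "phi")
  p_adjust <- match.arg(p_adjust)
  G <- length(m$groups)
  M <- length(m$measures)
  padj <- m$p
  if (p_adjust != "none") {
    ut <- which(upper.tri(matrix(0, G, G)), arr.ind = TRUE)
    flat_idx <- do.call(rbind, lapply(seq_len(M), function(k) cbind(ut, k)))
    adj <- stats::p.adjust(m$p[flat_idx], method = p_adjust)
    padj[flat_idx] <- adj
    padj[flat_idx[, c(2, 1, 3), drop = FALSE]] <- adj
  }
  evidence <- tidyr::expand_grid(group = m$groups, measure = m$measures)
  evidence$frac_exceeding <- mapply(function(g, mm) {
    others <- setdiff(m$groups, g)
    mean(m$D[g, others, mm] >= theta & padj[g, others, mm] < alpha)
  }, evidence$group, evidence$measure)
  flagged <- evidence %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(flag = any(.data$frac_exceeding >= phi), .groups = "drop")
  structure(list(
    flagged = flagged$group[flagged$flag],
    evidence = evidence,
    thresholds = list(theta = theta, alpha = alpha, phi = phi, p_adjust = p_adjust)
  ), class = "flag_report")
}

#' @export
print.flag_report <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("Non-human group screen (theta = %.2f, alpha = %.2g, phi = %.2f, p_adjust = %s)\n",
              th$theta, th$alpha, th$phi, th$p_adjust))
  if (length(x$flagged) == 0) {
    cat("No groups flagged.\n")
  } else {
    cat("Flagged groups:", paste(x$flagged, collapse = ", "), "\n")
  }
  top <- x$evidence %>% dplyr::arrange(dplyr::desc(.data$frac_exceeding)) %>% utils::head(5)
  cat("Strongest evidence (fraction of other groups exceeded):\n")
  print(as.data.frame(top), row.names = FALSE)
  invisible(x)
}
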