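#' Cross-tabulate haplogroup calls by cohort grouping
#'
#' Counts samples per group x haplogroup at the requested reporting level,
#' with unassigned samples tallied in an `"NA"` column, and per-group
#' percentages that sum to 100 within rounding — the layout of published
#' regional and period tables.
#'
#' @param calls hg-call data.frame from [classify_cohort()] (needs
#'   `sample_id` plus the level columns).
#' @param meta cohort metadata (`sample_id`, `birth_year`, `region`, `metro`).
#' @param grouping one of `"region"`, `"period"`, `"area"`, `"year"`.
#' @param level reporting level passed to [label_at_level()].
#' @param periods for `grouping = "period"`: list of inclusive year ranges,
#'   e.g. `list(c(1981, 1986), c(2000, 2005))`; samples outside every period
#'   are dropped.
#' @param collapse optional label-collapse mapping (see [label_at_level()]).
#' @return An `hg_crosstab`: list with `counts` (groups x haplogroups integer
#'   matrix, `"NA"` column last) and `percent` (same shape, rows summing to
#'   100).
#' @export
crosstab <- function(calls, meta,
                     grouping = c("region", "period", "area", "year"),
                     level = c("hg", "macro", "subhg"),
                     periods = list(c(1981, 1986), c(2000, 2005)),
                     collapse = NULL) {
  grouping <- match.arg(grouping)
  level <- match.arg(level)
  i <- match(calls$sample_id, meta$sample_id)
  if (anyNA(i)) {
    stop("sample(s) without metadata: ",
         paste(utils::head(calls$sample_id[is.na(i)], 5L), collapse = ", "))
  }
  meta <- meta[i, , drop = FALSE]
  grp <- switch(grouping,
    region = meta$region,
    year = as.character(meta$birth_year),
    area = ifelse(meta$metro, "metropolitan", "rural"),
    period = {
      g <- rep(NA_character_, nrow(meta))
      for (p in periods) {
        tag <- paste0(p[1L], "-", p[2L])
        g[meta$birth_year >= p[1L] & meta$birth_year <= p[2L]] <- tag
      }
      g
    })
  keep <- !is.na(grp)
  lab <- label_at_level(calls, level, collapse)[keep]
  grp <- grp[keep]
  lab[is.na(lab)] <- "NA"
  if (!length(grp)) {
    return(structure(list(counts = matrix(0L, 0L, 0L),
                          percent = matrix(numeric(), 0L, 0L)),
                     class = "hg_crosstab"))
  }
  hg_levels <- c(sort(setdiff(unique(lab), "NA")), intersect("NA", unique(lab)))
  counts <- table(factor(grp, levels = sort(unique(grp))),
                  factor(lab, levels = hg_levels))
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  percent <- 100 * counts / rowSums(counts)
  structure(list(counts = counts, percent = percent), class = "hg_crosstab")
}

#' @export
print.hg_crosstab <- function(x, digits = 1, ...) {
  cat("hg_crosstab:", nrow(x$counts), "groups x", ncol(x$counts),
      "haplogroup bins\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the point-probability (minimum-likelihood)
#' convention: with margins fixed, the hypergeometric probabilities of all
#' tables no more probable than the observed one are summed. No sampling is
#' involved.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise: the observed
#'   table is `rbind(c(a, b), c(c, d))`.
#' @return The p-value in \[0, 1\].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n == 0) stop("all-zero table: the test is undefined")
  m1 <- a + b   # row 1 total
  k1 <- a + c   # column 1 total
  lo <- max(0L, k1 - (c + d))
  hi <- min(m1, k1)
  support <- lo:hi
  probs <- stats::dhyper(support, m1, c + d, k1)
  p_obs <- stats::dhyper(a, m1, c + d, k1)
  # relative tolerance as in standard exact-test implementations
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# log point probability of an r x c table under fixed margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Permutation (Monte Carlo) Fisher test for r x c tables
#'
#' The test statistic is the table's point probability under fixed margins;
#' the p-value is the add-one estimator
#' `(1 + #permuted tables at most as probable) / (n_perm + 1)`. Null tables
#' are drawn with [stats::r2dtable()]. For 2x2 input the exact routine is
#' used instead (no sampling needed).
#'
#' @param tab integer matrix of counts (>= 2 rows and columns, positive
#'   margins).
#' @param n_perm number of Monte Carlo replicates (>= 1000).
#' @param seed integer seed for the replicate stream.
#' @return list with `p_value`, `method` (`"exact"` or `"monte_carlo"`),
#'   `n_perm` and `seed` (the latter two NA for the exact path).
#' @export
permutation_fisher <- function(tab, n_perm = 10000L, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margins: every row and column needs a positive total")
  }
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    return(list(p_value = fisher_exact_2x2(tab[1, 1], tab[1, 2],
                                           tab[2, 1], tab[2, 2]),
                method = "exact", n_perm = NA_integer_, seed = NA_integer_))
  }
  stopifnot(n_perm >= 1000L)
  set.seed(seed)
  lp_obs <- log_table_prob(tab)
  sims <- stats::r2dtable(n_perm, rowSums(tab), colSums(tab))
  lp_sim <- vapply(sims, log_table_prob, 0)
  p <- (1 + sum(lp_sim <= lp_obs + 1e-7)) / (n_perm + 1)
  list(p_value = p, method = "monte_carlo", n_perm = as.integer(n_perm),
       seed = as.integer(seed))
}

#' Bonferroni decisions for a set of frequency comparisons
#'
#' @param results data.frame with a `p_value` column (e.g. from
#'   [period_comparison()]).
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of simultaneous comparisons; defaults to 14 (13 haplogroup
#'   rows plus the NA row of published tables), overridable.
#' @return `results` with columns `significant` (p <= alpha/m), `alpha` and
#'   `m` appended.
#' @export
bonferroni <- function(results, alpha = 0.05, m = 14L) {
  stopifnot(is.data.frame(results), "p_value" %in% names(results),
            alpha > 0, m >= 1)
  if (m < nrow(results)) {
    warning("m (", m, ") is smaller than the number of comparisons (",
            nrow(results), ")")
  }
  results$significant <- results$p_value <= alpha / m
  results$alpha <- alpha
  results$m <- as.integer(m)
  results
}

#' Compare haplogroup frequencies between two groups, hg by hg
#'
#' For every haplogroup column of a 2-row contingency table, collapses to the
#' 2x2 table (focal haplogroup vs all others) and applies the exact Fisher
#' test, then annotates Bonferroni decisions. This reproduces the layout of
#' published period- and region-comparison tables (percent, count, p).
#'
#' @param xt an `hg_crosstab` with exactly 2 rows, or a 2-row count matrix.
#' @param alpha,m passed to [bonferroni()].
#' @return data.frame: `hg`, per-group percent and count, `p_value`,
#'   `significant`, `alpha`, `m`.
#' @export
period_comparison <- function(xt, alpha = 0.05, m = 14L) {
  counts <- if (inherits(xt, "hg_crosstab")) xt$counts else as.matrix(xt)
  if (nrow(counts) != 2L) stop("need exactly two groups to compare")
  tot <- rowSums(counts)
  res <- data.frame(
    hg = colnames(counts),
    group1_pct = 100 * counts[1L, ] / tot[1L],
    group1_n = counts[1L, ],
    group2_pct = 100 * counts[2L, ] / tot[2L],
    group2_n = counts[2L, ],
    p_value = vapply(seq_len(ncol(counts)), function(j) {
      fisher_exact_2x2(counts[1L, j], tot[1L] - counts[1L, j],
                       counts[2L, j], tot[2L] - counts[2L, j])
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  bonferroni(res, alpha = alpha, m = m)
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Yearly haplogroup proportion series with Wilson intervals
#'
#' Per calendar year and focal haplogroup: count, denominator, proportion and
#' Wilson 95% interval. The denominator is all samples with the needed labels,
#' optionally restricted to one macro-hg (e.g. hg U out of macro-hg R rather
#' than out of the whole cohort).
#'
#' @param calls hg-call data.frame.
#' @param meta cohort metadata with `sample_id` and `birth_year`.
#' @param hg_set character vector of focal haplogroup labels (after collapse).
#' @param level reporting level for the focal labels.
#' @param collapse optional label-collapse mapping.
#' @param macro_denominator optional macro-hg label restricting the
#'   denominator to samples of that macro-hg.
#' @param conf confidence level of the Wilson interval (default 0.95).
#' @return data.frame: `year`, `hg`, `count`, `denominator`, `proportion`,
#'   `lower`, `upper`.
#' @export
yearly_trend <- function(calls, meta, hg_set, level = "hg", collapse = NULL,
                         macro_denominator = NULL, conf = 0.95) {
  i <- match(calls$sample_id, meta$sample_id)
  if (anyNA(i)) stop("sample(s) without metadata")
  year <- meta$birth_year[i]
  if (length(unique(year)) < 2L) stop("need at least two distinct birth years")
  lab <- label_at_level(calls, level, collapse)
  in_denom <- if (is.null(macro_denominator)) {
    rep(TRUE, nrow(calls))
  } else {
    !is.na(calls$macro_hg) & calls$macro_hg == macro_denominator
  }
  years <- sort(unique(year))
  rows <- list()
  for (hg in hg_set) {
    for (y in years) {
      d <- sum(in_denom & year == y)
      x <- sum(in_denom & year == y & !is.na(lab) & lab == hg)
      ci <- if (d > 0) wilson_ci(x, d, conf) else c(lower = NA_real_, upper = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, hg = hg, count = x, denominator = d,
        proportion = if (d > 0) x / d else NA_real_,
        lower = ci[["lower"]], upper = ci[["upper"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Least-squares slope of a yearly proportion series
#'
#' Convenience wrapper for trend recovery checks: fits
#' `proportion ~ year` by ordinary least squares for one haplogroup's series
#' and returns the slope with its standard error.
#'
#' @param series output of [yearly_trend()] filtered to one haplogroup (or
#'   with `hg` constant).
#' @return Named numeric vector `c(slope, se)`.
#' @export
trend_slope <- function(series) {
  stopifnot(length(unique(series$hg)) == 1L)
  fit <- stats::lm(proportion ~ year, data = series)
  s <- summary(fit)$coefficients
  c(slope = unname(s["year", "Estimate"]), se = unname(s["year", "Std. Error"]))
}
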