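test_that("crosstab reproduces published percentage arithmetic and table layout", {
  # macro-level: 26 L0 among 24,216 haplotyped is 0.1%
  mc <- published_macro_counts()
  pct <- 100 * mc$n / sum(mc$n)
  expect_equal(round(pct[mc$macro_hg == "L0"], 1), 0.1)
  expect_equal(round(pct[mc$macro_hg == "R"], 1), 90.6)

  # hg level within macro R: 10,912 H among 21,836 is 50.0%
  expect_equal(round(100 * 10912 / 21836, 1), 50.0)

  # crosstab on synthetic calls: counts, NA column, rows sum to 100
  calls <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    macro_hg = c("R", "R", "R", "L3", NA, "R", "M", "R"),
    hg = c("H", "H", "U", NA, NA, NA, NA, "U"),
    sub_hg = NA_character_, status = "partial", stringsAsFactors = FALSE)
  meta <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    birth_year = c(1981, 1982, 2001, 2002, 1981, 2003, 2004, 1983),
    region = "Capital", metro = TRUE, stringsAsFactors = FALSE)
  xt <- crosstab(calls, meta, grouping = "period", level = "hg",
                 collapse = c(L3 = "L"))
  expect_identical(rownames(xt$counts), c("1981-1986", "2000-2005"))
  expect_identical(colnames(xt$counts)[ncol(xt$counts)], "NA")
  expect_identical(sum(xt$counts), 8L)
  expect_identical(xt$counts["1981-1986", "H"], 2L)
  expect_identical(xt$counts["2000-2005", "L"], 1L)
  expect_identical(xt$counts["1981-1986", "NA"], 1L)
  expect_equal(unname(rowSums(xt$percent)), c(100, 100), tolerance = 1e-9)

  # sample without metadata is an input error naming it
  expect_error(crosstab(calls, meta[-3L, ], grouping = "period"), "s3")

  # empty input gives an empty table
  xt0 <- crosstab(calls[0L, ], meta, grouping = "region")
  expect_identical(dim(xt0$counts), c(0L, 0L))
})

test_that("exact 2x2 Fisher test reproduces printed p-values and the enumeration oracle", {
  # published period comparisons at printed precision
  expect_equal(fisher_exact_2x2(8, 4562, 67, 5468), 1.14e-10, tolerance = 0.005)
  expect_equal(fisher_exact_2x2(44, 4526, 131, 5404), 3.73e-08, tolerance = 0.005)
  expect_equal(fisher_exact_2x2(2162, 2408, 2454, 3081), 2.98e-03, tolerance = 0.005)
  expect_equal(fisher_exact_2x2(405, 4165, 511, 5024), 0.53, tolerance = 0.01)

  # identical proportions give p = 1
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)

  # all-zero table is undefined
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "undefined")

  # brute-force enumeration oracle for all tables with n <= 30
  brute <- function(a, b, c, d) {
    n <- a + b + c + d; r1 <- a + b; c1 <- a + c
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- vapply(ks, function(k) {
      choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1)
    }, 0)
    p_obs <- probs[ks == a]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(60)
  for (i in 1:50) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    if (sum(cells) == 0) next
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                 brute(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }

  # symmetry under row swap and column swap
  expect_equal(fisher_exact_2x2(8, 4562, 67, 5468),
               fisher_exact_2x2(67, 5468, 8, 4562), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(8, 4562, 67, 5468),
               fisher_exact_2x2(4562, 8, 5468, 67), tolerance = 1e-12)

  # agreement with the standard exact-test implementation
  expect_equal(fisher_exact_2x2(12, 5, 3, 14),
               stats::fisher.test(rbind(c(12, 5), c(3, 14)))$p.value,
               tolerance = 1e-9)
})

test_that("permutation Fisher delegates 2x2, is seeded, and converges to the exact p", {
  tab22 <- rbind(c(12, 5), c(3, 14))
  res <- permutation_fisher(tab22, n_perm = 1000L, seed = 3)
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, fisher_exact_2x2(12, 5, 3, 14))

  # 3x2 null-by-construction: p near 1
  tab_null <- rbind(c(60, 60), c(90, 90), c(120, 120))
  r_null <- permutation_fisher(tab_null, n_perm = 10000L, seed = 4)
  expect_identical(r_null$method, "monte_carlo")
  expect_gt(r_null$p_value, 0.5)

  # determinism in the seed
  r1 <- permutation_fisher(tab_null, n_perm = 2000L, seed = 9)
  r2 <- permutation_fisher(tab_null, n_perm = 2000L, seed = 9)
  expect_identical(r1$p_value, r2$p_value)

  # Monte Carlo converges to the exact value for a 2x2 forced through the
  # r x c path by duplicating a row of zeros-free structure as 2x2 blocks
  a <- 20L; b <- 30L; c <- 35L; d <- 15L
  p_exact <- fisher_exact_2x2(a, b, c, d)
  # force the Monte Carlo machinery on the same 2x2 by calling the internal
  # statistic path via a 2x2 passed through r2dtable manually
  set.seed(11)
  n_perm <- 20000L
  lp_obs <- mitocline:::log_table_prob(rbind(c(a, b), c(c, d)))
  sims <- stats::r2dtable(n_perm, c(a + b, c + d), c(a + c, b + d))
  lp_sim <- vapply(sims, mitocline:::log_table_prob, 0)
  p_mc <- (1 + sum(lp_sim <= lp_obs + 1e-7)) / (n_perm + 1)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_mc - p_exact), 3 * se)

  # degenerate margins error
  expect_error(permutation_fisher(rbind(c(0, 0), c(1, 2))), "margins")
})

test_that("Bonferroni decisions use alpha/m and are monotone in p", {
  res <- data.frame(hg = c("L", "U", "X"),
                    p_value = c(1.14e-10, 0.02, 0.5))
  out <- bonferroni(res, alpha = 0.05, m = 14L)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))  # 0.02 > 0.05/14
  expect_identical(out$m[1L], 14L)

  # m = 1 reduces to the raw alpha test (m override below the comparison
  # count is allowed but flagged)
  out1 <- suppressWarnings(bonferroni(res, alpha = 0.05, m = 1L))
  expect_identical(out1$significant, c(TRUE, TRUE, FALSE))

  # monotone: sorted p gives a significance vector that never re-enables
  set.seed(61)
  ps <- sort(runif(20))
  dec <- bonferroni(data.frame(p_value = ps), alpha = 0.05, m = 20L)$significant
  expect_true(all(diff(as.integer(dec)) <= 0))

  # m smaller than the number of comparisons is flagged
  expect_warning(bonferroni(data.frame(p_value = ps), alpha = 0.05, m = 5L),
                 "smaller")
})

test_that("period comparison reproduces the published two-period table", {
  pc <- published_period_counts()
  counts <- t(as.matrix(pc[, c("period_1981_1986", "period_2000_2005")]))
  colnames(counts) <- pc$hg
  res <- period_comparison(counts, alpha = 0.05, m = 14L)
  expect_equal(res$p_value[res$hg == "L"], 1.14e-10, tolerance = 0.005)
  expect_equal(res$p_value[res$hg == "M"], 3.73e-08, tolerance = 0.005)
  expect_true(all(res$significant[res$hg %in% c("L", "M")]))
  expect_false(res$significant[res$hg == "U"])  # p ~ 0.02 > 0.05/14
  expect_equal(res$group1_pct[res$hg == "H"], 47.3, tolerance = 0.05)
  expect_equal(res$group2_pct[res$hg == "H"], 44.3, tolerance = 0.05)
})

test_that("yearly trend series recover configured slopes and support macro denominators", {
  tr <- toy_tree()
  panel <- toy_panel(tr)
  m <- toy_model(c("H", "M"), c(0.99, 0.01), trend = c(M = 0.0005))
  co <- simulate_cohort(m, tr, 40000, seed = 62)
  calls <- data.frame(sample_id = co$sample_id,
                      macro_hg = vapply(co$true_hg, function(h) tree_path(tr, h)[2L], ""),
                      hg = NA_character_, sub_hg = NA_character_,
                      status = "partial", stringsAsFactors = FALSE)
  yt <- yearly_trend(calls, co, "M", level = "macro")
  sl <- trend_slope(yt)
  expect_lt(abs(sl[["slope"]] - 0.0005), 3 * sl[["se"]])
  expect_gt(sl[["slope"]], 0)
  # Wilson intervals bracket the proportion
  expect_true(all(yt$lower <= yt$proportion & yt$proportion <= yt$upper))

  # constant-frequency haplogroup (trend-free model): slope within 3 SE of 0
  m0 <- toy_model(c("H", "M"), c(0.8, 0.2))
  co0 <- simulate_cohort(m0, tr, 40000, seed = 64)
  calls0 <- data.frame(sample_id = co0$sample_id,
                       macro_hg = vapply(co0$true_hg, function(h) tree_path(tr, h)[2L], ""),
                       hg = NA_character_, sub_hg = NA_character_,
                       status = "partial", stringsAsFactors = FALSE)
  sl_h <- trend_slope(yearly_trend(calls0, co0, "M", level = "macro"))
  expect_lt(abs(sl_h[["slope"]]), 3 * sl_h[["se"]])

  # macro-restricted denominator: counts divided by that macro's totals
  m2 <- toy_model(c("H", "U", "M"), c(0.5, 0.3, 0.2))
  co2 <- simulate_cohort(m2, tr, 5000, seed = 63)
  calls2 <- data.frame(sample_id = co2$sample_id,
                       macro_hg = vapply(co2$true_hg, function(h) tree_path(tr, h)[2L], ""),
                       hg = ifelse(co2$true_hg %in% c("H", "U"), co2$true_hg, NA),
                       sub_hg = NA_character_, status = "partial",
                       stringsAsFactors = FALSE)
  yt_r <- yearly_trend(calls2, co2, "U", macro_denominator = "R")
  yt_all <- yearly_trend(calls2, co2, "U")
  expect_true(all(yt_r$denominator <= yt_all$denominator))
  y1 <- yt_r$year[1L]
  expect_identical(yt_r$denominator[1L],
                   sum(calls2$macro_hg == "R" & co2$birth_year == y1))
})
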