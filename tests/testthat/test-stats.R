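test_that("median_min_max reports the middle order statistic and extremes", {
  expect_equal(median_min_max(rep(3.5, 7)),
               c(median = 3.5, min = 3.5, max = 3.5))
  expect_equal(median_min_max(1), c(median = 1, min = 1, max = 1))
  expect_error(median_min_max(numeric(0)), "empty")

  set.seed(31)
  x <- runif(101)
  s <- sort(x)
  expect_equal(median_min_max(x),
               c(median = s[51], min = s[1], max = s[101]))
  y <- runif(10)                                 # even n: mean of middles
  sy <- sort(y)
  expect_equal(median_min_max(y)[["median"]], mean(sy[5:6]))
})

test_that("percent change follows 100 * (value - baseline) / baseline", {
  expect_equal(percent_change(100, 110), 10)
  expect_equal(percent_change(0.4, 0.4), 0)
  expect_equal(percent_change(0.381, 0.677), 100 * (0.677 - 0.381) / 0.381)
  expect_error(percent_change(0, 1), "zero baseline")
  # antisymmetry holds in the numerator only, not in the value
  expect_false(isTRUE(all.equal(percent_change(0.381, 0.677),
                                -percent_change(0.677, 0.381))))
})

test_that("seven uniformly signed distinct pairs give the minimal exact p", {
  base <- rep(0.381, 7)
  cond <- base * (1 + c(10.6, 14.2, 19.9, 23.1, 27.7, 35.0, 43.5) / 100)
  res <- wilcoxon_exact(base, cond)
  expect_identical(res$p_value, 2 / 2^7)           # 0.015625
  expect_equal(round(res$p_value, 2), 0.02)        # as printed in reports
  expect_equal(res$statistic, 28)
  # the same bound holds for any n with distinct magnitudes, one sign
  for (n in c(3, 5, 9)) {
    p <- wilcoxon_exact(rep(0, n), seq_len(n))$p_value
    expect_identical(p, 2 / 2^n)
  }
})

test_that("all-zero paired differences are degenerate with p = 1", {
  res <- wilcoxon_exact(rep(232, 7), rep(232, 7))
  expect_identical(res$p_value, 1)
  expect_identical(res$statistic, 0)
  res2 <- wilcoxon_exact(rep(232, 7), rep(232, 7), zero_policy = "pratt")
  expect_identical(res2$p_value, 1)
})

test_that("exact p agrees with explicit 2^n enumeration", {
  d <- c(1, -2, 3)
  got <- wilcoxon_exact(rep(0, 3), d)
  ref <- oracle_wilcoxon(d)
  expect_identical(got$p_value, ref$p)
  expect_equal(got$statistic, ref$W)

  set.seed(2024)
  for (rep_i in 1:60) {
    n <- sample(2:10, 1)
    d <- sample(c(-3, -2, -1, 0, 1, 2, 3), n, replace = TRUE) +
      round(rnorm(n), 1) * sample(c(0, 1), n, replace = TRUE)
    for (zp in c("drop", "pratt")) {
      for (alt in c("two_sided", "greater", "less")) {
        got <- wilcoxon_exact(rep(0, n), d, zero_policy = zp,
                              alternative = alt)
        ref <- oracle_wilcoxon(d, alternative = alt, zero_policy = zp)
        expect_equal(got$p_value, ref$p, tolerance = 1e-12)
      }
    }
  }
})

test_that("two-sided p is invariant under swapping baseline and condition", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    p1 <- wilcoxon_exact(a, b)$p_value
    p2 <- wilcoxon_exact(b, a)$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("exact path agrees with the classical test on tie-free data", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:15, 1)
    a <- rnorm(n); b <- a + rnorm(n)
    got <- wilcoxon_exact(a, b)$p_value
    ref <- stats::wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("large samples switch to a continuity-corrected normal tail", {
  set.seed(88)
  a <- rnorm(40); b <- a + 0.4 + rnorm(40)
  got <- wilcoxon_exact(a, b)
  expect_match(got$method, "normal approximation")
  ref <- stats::wilcox.test(b, a, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-9)
})

test_that("cohort summary matches a spreadsheet-style recomputation", {
  set.seed(404)
  subjects <- sprintf("s%d", 1:7)
  phases <- c("baseline", "medium", "high")
  vals <- matrix(abs(rnorm(21, 0.4, 0.1)), nrow = 7,
                 dimnames = list(subjects, phases))
  vals[, "medium"] <- vals[, "baseline"] * runif(7, 1.1, 1.4)
  vals[, "high"] <- vals[, "baseline"] * runif(7, 1.4, 3)
  metrics <- data.frame(subject = rep(subjects, 3),
                        metric = "rms_oxy",
                        phase = rep(phases, each = 7),
                        value = c(vals))
  cs <- summarize_cohort(metrics, baseline = "baseline", phases = phases)

  for (ph in phases) {
    row <- cs[cs$metric == "rms_oxy" & cs$phase == ph, ]
    expect_equal(row$median, median(vals[, ph]))
    expect_equal(row$min, min(vals[, ph]))
    expect_equal(row$max, max(vals[, ph]))
    if (ph == "baseline") expect_true(is.na(row$p))
    else {
      expect_equal(row$p,
                   oracle_wilcoxon(vals[, ph] - vals[, "baseline"])$p)
      expect_true(row$significant)   # all increases: minimal p = 0.0156
    }
  }
  # derived percent-change metric: per-subject change, then summarized
  drow <- cs[cs$metric == "drms_oxy_pct" & cs$phase == "medium", ]
  dvals <- 100 * (vals[, "medium"] - vals[, "baseline"]) / vals[, "baseline"]
  expect_equal(drow$median, median(dvals))
  expect_equal(drow$p, oracle_wilcoxon(dvals)$p)
})

test_that("cohort summary handles single subjects and missing subjects", {
  one <- data.frame(subject = "s1", metric = "rms_oxy",
                    phase = c("baseline", "medium"), value = c(0.3, 0.4))
  cs <- summarize_cohort(one, phases = c("baseline", "medium"))
  expect_true(all(is.na(cs$p)))
  expect_equal(cs$median[cs$phase == "medium" & cs$metric == "rms_oxy"], 0.4)

  # a subject missing at one timepoint: cell computed on available pairs
  m <- data.frame(subject = c("s1", "s2", "s3", "s1", "s2"),
                  metric = "rms_oxy",
                  phase = c(rep("baseline", 3), rep("medium", 2)),
                  value = c(0.3, 0.31, 0.29, 0.4, 0.42))
  cs2 <- summarize_cohort(m, phases = c("baseline", "medium"))
  row <- cs2[cs2$phase == "medium" & cs2$metric == "rms_oxy", ]
  expect_identical(row$n, 2L)
})
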