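test_that("ratio t-test reproduces published under-replication p-values", {
  r <- ratio_t_test(1.66, 0.050, 3)
  expect_equal(r$df, 2)
  expect_equal(round(r$p, 3), 0.021)
  r <- ratio_t_test(1.81, 0.016, 3)
  expect_equal(round(r$p, 3), 0.007)
  r <- ratio_t_test(2.0, 0.04, 3)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(ratio_t_test(1.9, 0, 3), "positive")
  expect_error(ratio_t_test(1.9, 0.1, 1), "n >= 2")
})

test_that("df = 2 Student tail matches its closed form", {
  for (t in c(0.1, 0.5, 1, 2.46, 6.8, 11.875, 40)) {
    p_pkg <- ratio_t_test(2 - t * 0.01, 0.01, 3)$p
    expect_equal(p_pkg, 1 - t / sqrt(2 + t^2), tolerance = 1e-6)
  }
})

test_that("composition chi-square matches brute force and aligns levels", {
  r <- composition_chisq(c(10, 20, 30), c(10, 20, 30))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  r <- composition_chisq(c(90, 10), c(50, 50))
  expect_equal(r$chi2, 38.095, tolerance = 1e-3)
  expect_equal(r$df, 1)

  # brute-force oracle on random tables (all expected counts >= 1)
  set.seed(404)
  for (i in 1:20) {
    L <- sample(2:6, 1)
    a <- rpois(L, 40) + 5
    b <- rpois(L, 40) + 5
    r <- composition_chisq(a, b)
    m <- rbind(a, b)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(r$chi2, sum((m - e)^2 / e), tolerance = 1e-9)
    expect_equal(r$df, L - 1)
    expect_equal(r$p, pchisq(r$chi2, L - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # named alignment pads absent levels with zero, pooling merges them
  r <- composition_chisq(c("2" = 10, "4" = 10, "8" = 10),
                         c("2" = 10, "4" = 10, "8" = 10, "16" = 0))
  expect_lte(ncol(r$table), 4L)
  expect_true(is.finite(r$chi2))
  expect_error(composition_chisq(c(0, 0), c(1, 2)), "non-zero")
})

test_that("one-way ANOVA with LSD letters behaves on raw data", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- anova_lsd(g)
  expect_equal(r$F, 0)
  expect_identical(unname(r$letters), c("a", "a"))

  # degenerate: all values identical
  r <- anova_lsd(list(x = c(2, 2), y = c(2, 2)))
  expect_equal(r$F, 0)
  expect_identical(unname(r$letters), c("a", "a"))

  # one far-outlying group gets an exclusive letter
  r <- anova_lsd(list(lo = c(0.99, 1.00, 1.01), mid = c(1.00, 1.01, 1.02),
                      hi = c(4.99, 5.00, 5.01)))
  expect_identical(unname(r$letters), c("a", "a", "b"))

  # cross-check F and p against stats::aov
  set.seed(11)
  g <- lapply(1:4, function(i) rnorm(5, mean = i * 0.5))
  names(g) <- paste0("g", 1:4)
  r <- anova_lsd(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), each = 5))
  ref <- summary(stats::aov(y ~ grp, df))[[1]]
  expect_equal(r$F, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(r$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
})

test_that("summary-statistic ANOVA equals the raw-data ANOVA it implies", {
  set.seed(77)
  for (i in 1:15) {
    k <- sample(3:6, 1)
    means <- runif(k, 0.3, 0.6)
    ses <- runif(k, 0.002, 0.05)
    raw <- Map(raw_triple, means, ses)
    names(raw) <- paste0("g", seq_len(k))
    a_raw <- anova_lsd(raw)
    a_sum <- anova_from_summary(means, ses, rep(3L, k), labels = names(raw))
    expect_equal(a_sum$F, a_raw$F, tolerance = 1e-9)
    expect_equal(a_sum$p, a_raw$p, tolerance = 1e-9)
    expect_identical(unname(a_sum$letters), unname(a_raw$letters))
  }
  expect_error(anova_from_summary(c(1, 2), c(0.1, 0.1, 0.1), c(3, 3)),
               "equal length")
})

test_that("LSD letters are a valid cover of the pairwise decisions", {
  set.seed(303)
  for (i in 1:25) {
    k <- sample(3:7, 1)
    means <- sort(runif(k))
    ses <- runif(k, 0.01, 0.2)
    ns <- sample(2:5, k, replace = TRUE)
    r <- anova_from_summary(means, ses, ns)
    if (r$ms_within == 0) next
    tcrit <- qt(0.975, r$df_within)
    share <- function(i, j) {
      li <- strsplit(r$letters[i], "")[[1]]
      lj <- strsplit(r$letters[j], "")[[1]]
      length(intersect(li, lj)) > 0
    }
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
      lsd <- tcrit * sqrt(r$ms_within * (1 / ns[a] + 1 / ns[b]))
      expect_identical(share(a, b), abs(means[a] - means[b]) < lsd)
    }
  }
})

test_that("pooled two-sample t from summaries matches raw t.test", {
  r <- two_sample_t(10, 1, 3, 10, 1, 3)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r <- two_sample_t(394, 2.42, 6, 430, 1.78, 5)
  expect_equal(r$df, 9)
  expect_equal(r$t, -11.53, tolerance = 1e-2)

  # construction oracle: raw samples realising the summaries exactly
  set.seed(5)
  for (i in 1:10) {
    m <- runif(2, 0, 10)
    s <- runif(2, 0.1, 1)
    x <- m[1] + s[1] * sqrt(3) * c(-1, 0, 1)
    y <- m[2] + s[2] * sqrt(4) * scale(rnorm(4))[, 1] / sqrt(4 / 3)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    r <- two_sample_t(mean(x), sd(x) / sqrt(3), 3, mean(y), sd(y) / 2, 4)
    expect_equal(r$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(r$p, ref$p.value, tolerance = 1e-9)
  }
})
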