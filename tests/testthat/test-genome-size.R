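test_that("C-value estimation follows the reference-ratio formula", {
  expect_equal(estimate_c_value(100, 100, 0.18), 0.18)
  expect_equal(estimate_c_value(223.89, 100, 0.18), 0.403, tolerance = 1e-3)
  # gain invariance and linearity in the reference C-value
  expect_equal(estimate_c_value(120, 80), estimate_c_value(1200, 800))
  expect_equal(estimate_c_value(120, 80, 0.36),
               2 * estimate_c_value(120, 80, 0.18))
  expect_error(estimate_c_value(-1, 100), "positive")
  expect_error(estimate_c_value(100, 0), "positive")
})

test_that("pg-to-Mb conversion uses 978 Mb per pg", {
  expect_equal(round(pg_to_mb(0.403)), 394)
  expect_equal(round(pg_to_mb(0.440)), 430)
  expect_equal(pg_to_mb(0), 0)
  expect_equal(pg_to_mb(1), 978)
  expect_error(pg_to_mb(-0.1), "non-negative")
})

test_that("replicate aggregation computes mean, SE and CV range", {
  est <- aggregate_replicates(c(0.4, 0.4, 0.4))
  expect_equal(est$mean_pg, 0.4)
  expect_equal(est$se_pg, 0)

  est <- aggregate_replicates(c(0.39, 0.40, 0.42),
                              per_replicate_cv_pct = c(3.69, 5.0, 6.73))
  expect_equal(est$mean_pg, 0.40333, tolerance = 1e-4)
  expect_equal(est$se_pg, sd(c(0.39, 0.40, 0.42)) / sqrt(3))
  expect_equal(est$se_mb, 8.63, tolerance = 1e-2)
  expect_equal(est$cv_range_pct, c(3.69, 6.73))
  expect_equal(est$mean_mb, est$mean_pg * 978, tolerance = 1e-9)
  expect_equal(est$n, length(est$per_replicate_pg))

  expect_error(aggregate_replicates(0.4), "at least 2")
  expect_output(print(est), "Genome size")
})

test_that("pipeline recovery: calibrated C-value tracks the true ratio", {
  # sample at rho x reference base must come back at rho x 0.18 pg
  ref_tpl <- simple_template(proportions = c(0.888, 0.083, 0.028) / 0.999,
                             base = 100, ratios = c(1.94, 1.66), cv = 0.04)
  for (rho in c(2.239, 2.444)) {
    smp_tpl <- simple_template(base = 100 * rho, cv = 0.05)
    for (s in 1:2) {
      ref <- ploidy_fit(generate_sample(ref_tpl, 20000, seed = 100 + s))
      smp <- ploidy_fit(generate_sample(smp_tpl, 20000, seed = 200 + s))
      cv <- estimate_c_value(coef(smp)[["2Cx"]], coef(ref)[["2Cx"]])
      expect_lt(abs(cv / (rho * 0.18) - 1), 0.015)
    }
  }
})
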