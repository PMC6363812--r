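test_that("empty and invalid requests are handled", {
  tpl <- simple_template()
  ev <- generate_sample(tpl, 0, seed = 1)
  expect_s3_class(ev, "event_table")
  expect_equal(nrow(ev), 0L)
  expect_named(ev, c("fl3", "ssc", "true_label"))
  expect_error(generate_sample(tpl, -1, seed = 1), "non-negative")
})

test_that("identical (template, n, seed) give bit-identical tables", {
  tpl <- template_library()$harm_midgut
  a <- generate_sample(tpl, 5000, seed = 42)
  b <- generate_sample(tpl, 5000, seed = 42)
  expect_identical(a, b)
  c <- generate_sample(tpl, 5000, seed = 43)
  expect_false(identical(a$fl3, c$fl3))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(generate_sample(simple_template(), 1000, seed = 7))
  expect_identical(runif(3), before)
})

test_that("reference-head label fractions match the configured composition", {
  # 88.8 / 8.3 / 2.8% template at n = 50000: within ~2 binomial SD
  tpl <- template_library()$dmel_adult_head
  tpl0 <- template_without_interference(tpl, drop_debris = TRUE)
  ev <- generate_sample(tpl0, 50000, seed = 7)
  obs <- as.vector(table(ev$true_label)[paste0(c(2, 4, 8), "Cx")]) / nrow(ev)
  expect_true(all(abs(obs - tpl0$class_proportions) < 0.006))
})

test_that("per-component fractions stay within 4 binomial SD", {
  for (tpl in template_library()[c("harm_midgut", "harm_male_gonad",
                                   "harm_salivary_gland")]) {
    n <- 20000
    ev <- generate_sample(tpl, n, seed = 31)
    scale <- 1 - tpl$debris_fraction - tpl$chain_fraction
    probs <- c(setNames(tpl$class_proportions * scale,
                        paste0(tpl$class_levels, "Cx")),
               debris = tpl$debris_fraction, chain = tpl$chain_fraction)
    probs <- probs[probs > 0]
    obs <- table(factor(ev$true_label, levels = names(probs))) / n
    tol <- 4 * sqrt(probs * (1 - probs) / n)
    expect_true(all(abs(as.vector(obs) - probs) < tol))
  }
})

test_that("per-class log-fluorescence means match the log-normal moments", {
  # centre is the log-normal median: E[log FL] = log(centre)
  tpl <- simple_template(ratios = c(2, 2), cv = 0.05)
  ev <- generate_sample(tpl, 100000, seed = 12)
  sdlog <- sqrt(log(1 + tpl$peak_cv^2))
  for (i in seq_along(tpl$class_levels)) {
    lf <- log(ev$fl3[ev$true_label == paste0(tpl$class_levels[i], "Cx")])
    se <- sdlog / sqrt(length(lf))
    expect_lt(abs(mean(lf) - log(tpl$class_centres[i])), 3 * se)
    expect_lt(abs(sd(lf) - sdlog), 4 * se)
  }
})

test_that("empirical class medians recover the under-replication ladder", {
  tpl <- simple_template(proportions = c(0.4, 0.35, 0.25),
                         ratios = c(1.8, 2.1), cv = 0.08)
  ev <- generate_sample(tpl, 100000, seed = 5)
  med <- vapply(paste0(tpl$class_levels, "Cx"), function(lab)
    median(ev$fl3[ev$true_label == lab]), numeric(1))
  recovered <- med[-1L] / med[-length(med)]
  expect_true(all(abs(recovered / tpl$under_replication - 1) < 0.02))
})

test_that("interference skews the affected classes the right way", {
  base <- simple_template(cv = 0.04)
  up <- simple_template(cv = 0.04, interference = "strengthening")
  down <- simple_template(cv = 0.04, interference = "weakening")
  ev0 <- generate_sample(base, 30000, seed = 8)
  evs <- generate_sample(up, 30000, seed = 8)
  evw <- generate_sample(down, 30000, seed = 8)
  m <- function(ev, lab) mean(log(ev$fl3[ev$true_label == lab]))
  expect_gt(m(evs, "2Cx"), m(ev0, "2Cx"))     # strengthening: shifted up
  expect_lt(m(evw, "8Cx"), m(ev0, "8Cx"))     # weakening: >2Cx shifted down
  expect_equal(m(evw, "2Cx"), m(ev0, "2Cx"), tolerance = 1e-2)
})

test_that("event_table enforces positivity and finiteness", {
  expect_error(event_table(c(1, -1), c(1, 1)), "positive")
  expect_error(event_table(c(1, Inf), c(1, 1)), "finite")
  expect_error(event_table(1, -2), "non-negative")
  expect_silent(event_table(c(1, 2), c(0, 5)))
})
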