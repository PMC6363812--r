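# Debris gating, histogramming, peak detection, ladder assignment,
# cluster statistics and chain detection.

test_that("debris gate removes close to the true debris load", {
  clean <- simple_template()
  g0 <- gate_debris(generate_sample(clean, 20000, seed = 4))
  expect_lt(g0$gated_fraction, 0.01)

  dirty <- simple_template(debris = 0.10)
  g1 <- gate_debris(generate_sample(dirty, 20000, seed = 4))
  expect_lt(abs(g1$gated_fraction - 0.10), 0.03)

  expect_error(gate_debris(event_table()), "empty")
})

test_that("identical events are never gated and the cap is enforced", {
  same <- event_table(rep(100, 500), rep(50, 500))
  expect_equal(gate_debris(same)$gated_fraction, 0)

  set.seed(61)
  overload <- event_table(
    fl3 = c(rlnorm(7800, log(100), 0.04),
            exp(runif(2200, log(300), log(5000)))),
    ssc = c(rlnorm(7800, log(100), 0.1), rlnorm(2200, log(600), 0.1)))
  expect_warning(g <- gate_debris(overload, max_gate_fraction = 0.1),
                 "relaxed")
  expect_equal(g$gated_fraction, 0.1, tolerance = 1e-4)
})

test_that("histogram bins conserve events and cover degenerate input", {
  one <- event_table(100, 10)
  h <- build_histogram(one, n_bins = 64)
  expect_equal(sum(h$counts), 1L)
  expect_equal(sum(h$counts > 0), 1L)

  ev <- event_table(exp(runif(5000, 0, 1)), rep(1, 5000))
  h <- build_histogram(ev, n_bins = 10, scale = "log")
  expect_equal(sum(h$counts), 5000L)
  # uniform log-fluorescence: each of 10 bins within 4 multinomial SD
  expect_true(all(abs(h$counts - 500) < 4 * sqrt(5000 * 0.1 * 0.9)))
  expect_true(all(diff(h$bin_edges) > 0))
})

test_that("a single log-normal population yields one peak at its centre", {
  ev <- single_class_events(20000, centre = 150, cv = 0.05, seed = 9)
  pk <- detect_peaks(ev)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$position / 150 - 1), 0.02)
})

test_that("the three reference-head classes give exactly three peaks", {
  tpl <- template_without_interference(template_library()$dmel_adult_head,
                                       drop_debris = TRUE)
  pk <- detect_peaks(generate_sample(tpl, 20000, seed = 21))
  expect_equal(nrow(pk), 3L)
  expect_true(all(abs(pk$position / tpl$class_centres - 1) < 0.02))
})

test_that("featureless input raises a no-peak error", {
  flat <- event_table(exp(runif(20000, 0, 3)), rep(1, 20000))
  expect_error(detect_peaks(flat), "no peak")
  expect_error(detect_peaks(event_table()), "empty")
})

test_that("ladder assignment anchors 2Cx and walks both directions", {
  pk <- function(pos, mass) data.frame(position = pos, mass = mass,
                                       prominence = 1, sd_log = 0.05,
                                       height = 1, lo = pos * 0.9,
                                       hi = pos * 1.1)
  # downward trend: most populous first
  lad <- assign_ploidy(pk(c(100, 194, 375), c(0.5, 0.3, 0.2)))
  expect_equal(lad$peaks$level, c(2, 4, 8))
  # haploid flag: tiny low peak at half the anchor position becomes 1Cx
  lad <- assign_ploidy(pk(c(50, 108, 204), c(0.1, 0.6, 0.3)),
                       expect_haploid = TRUE)
  expect_equal(lad$peaks$level, c(1, 2, 4))
  expect_equal(lad$anchor_level, 1)
  # without the flag the lowest chained peak is 2Cx
  lad <- assign_ploidy(pk(c(50, 108, 204), c(0.1, 0.6, 0.3)))
  expect_equal(lad$peaks$level, c(2, 4, 8))
  # upward composition (hemolymph-like): lowest chained peak still 2Cx
  lad <- assign_ploidy(pk(c(100, 199, 380), c(0.2, 0.33, 0.47)))
  expect_equal(lad$peaks$level, c(2, 4, 8))
  # single peak: anchor-only profile
  lad <- assign_ploidy(pk(100, 1))
  expect_equal(lad$peaks$level, 2)
  # off-ladder peak left unclassified
  lad <- assign_ploidy(pk(c(100, 194, 290), c(0.5, 0.3, 0.2)))
  expect_equal(lad$peaks$level, c(2, 4))
  expect_equal(nrow(lad$unassigned), 1L)
})

test_that("near-equal anchor candidates off the ladder are ambiguous", {
  pk <- data.frame(position = c(100, 300), mass = c(0.5, 0.49),
                   prominence = 1, sd_log = 0.05, height = 1,
                   lo = c(90, 270), hi = c(110, 330))
  expect_error(assign_ploidy(pk), "ambiguous")
  # equal masses reconciled by the ladder are fine
  pk$position <- c(100, 195)
  expect_silent(assign_ploidy(pk))
})

test_that("cluster statistics recover the generator truth", {
  tpl <- simple_template(cv = 0.05)
  ev <- generate_sample(tpl, 20000, seed = 14)
  fit <- ploidy_fit(ev)
  clu <- fit$clusters
  truth <- table(ev$true_label)[paste0(tpl$class_levels, "Cx")]
  expect_equal(clu$level, tpl$class_levels)
  expect_true(all(abs(clu$count / as.vector(truth) - 1) < 0.02))
  expect_lt(abs(clu$mean_fi[clu$level == 2] / 100 - 1), 0.01)
  # single class: fraction 1
  f1 <- ploidy_fit(single_class_events(5000, seed = 2))
  expect_equal(f1$clusters$fraction, 1)
})

test_that("event attribution agrees with generating labels", {
  tpl <- simple_template(cv = 0.06)
  ev <- generate_sample(tpl, 20000, seed = 23)
  fit <- ploidy_fit(ev, gate = FALSE)
  pred <- as.character(predict(fit, ev))
  scored <- pred != "unclassified"
  expect_lt(mean(pred[scored] != ev$true_label[scored]), 0.02)
})

test_that("profiles are monotone and conserve events", {
  lib <- template_library()
  for (nm in c("harm_head", "harm_male_gonad", "harm_salivary_gland")) {
    fit <- ploidy_fit(generate_sample(lib[[nm]], 15000, seed = 6),
                      expect_haploid = 1 %in% lib[[nm]]$class_levels)
    expect_true(all(diff(fit$clusters$mean_fi) > 0))
    n_post <- fit$n_events - fit$n_gated
    expect_equal(sum(fit$clusters$count) +
                   round(fit$unclassified_fraction * n_post), n_post)
    expect_equal(sum(fit$clusters$fraction), 1, tolerance = 1e-9)
  }
})

test_that("chain detection flags the salivary phenotype only", {
  lib <- template_library()
  fit <- ploidy_fit(generate_sample(lib$harm_salivary_gland, 20000, seed = 3))
  expect_true(fit$chain_detected)
  clean <- template_without_interference(lib$harm_salivary_gland)
  fitc <- ploidy_fit(generate_sample(clean, 20000, seed = 3))
  expect_true(fitc$chain_detected)
  expect_lt(abs(fitc$chain_mass - 0.15), 0.05)
  fit0 <- ploidy_fit(generate_sample(lib$harm_midgut, 20000, seed = 3))
  expect_false(fit0$chain_detected)
})

test_that("fit methods behave like a classed model object", {
  fit <- ploidy_fit(generate_sample(template_library()$dmel_adult_head,
                                    10000, seed = 1))
  expect_named(coef(fit), c("2Cx", "4Cx", "8Cx"))
  expect_output(print(fit), "anchor 2Cx")
  expect_output(print(summary(fit)), "Ploidy profile")
  r <- residuals(fit)
  expect_length(r, fit$n_events - fit$n_gated)
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.02)
  sim <- simulate(fit, seed = 4, n_events = 2000)
  expect_s3_class(sim, "event_table")
  expect_equal(nrow(sim), 2000L)
  # simulated composition mirrors the fitted fractions
  f2 <- table(sim$true_label)[["2Cx"]] / 2000
  expect_lt(abs(f2 - fit$clusters$fraction[1]), 0.05)
  df <- as.data.frame(fit)
  expect_named(df, c("level", "mean_fi", "sd_fi", "count", "fraction", "cv"))
  p <- withr::local_tempfile(fileext = ".png")
  grDevices::png(p); plot(fit); grDevices::dev.off()
  expect_true(file.exists(p))
})
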