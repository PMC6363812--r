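test_that("template library contains the eight study phenotypes", {
  lib <- template_library()
  expect_length(lib, 8L)
  expect_setequal(names(lib), c(
    "dmel_adult_head", "harm_head", "harm_hemolymph",
    "harm_salivary_gland", "harm_male_gonad", "harm_midgut",
    "harm_malpighian_tubules", "hass_head"))
  expect_true(all(vapply(lib, inherits, logical(1), "tissue_template")))

  # male gonad carries a haploid class; salivary gland carries a chain
  expect_true(1 %in% lib$harm_male_gonad$class_levels)
  expect_gt(lib$harm_salivary_gland$chain_fraction, 0)

  # composition trends: midgut peaks at 16Cx then drops at 32Cx,
  # gonad peaks at 4Cx, hemolymph rises 2Cx -> 8Cx, heads fall 2Cx -> top
  mg <- lib$harm_midgut
  expect_equal(mg$class_levels[which.max(mg$class_proportions)], 16)
  expect_lt(mg$class_proportions[mg$class_levels == 32],
            mg$class_proportions[mg$class_levels == 16])
  gon <- lib$harm_male_gonad
  expect_equal(gon$class_levels[which.max(gon$class_proportions)], 4)
  hem <- lib$harm_hemolymph
  expect_true(all(diff(hem$class_proportions) > 0))
  for (nm in c("dmel_adult_head", "harm_head", "hass_head"))
    expect_true(all(diff(lib[[nm]]$class_proportions) < 0))
})

test_that("class centres follow the under-replication ladder", {
  lib <- template_library()
  for (tpl in lib) {
    expect_equal(sum(tpl$class_proportions), 1, tolerance = 1e-9)
    expect_true(all(tpl$class_proportions >= 0))
    expect_true(all(diff(tpl$class_centres) > 0))
    # oracle: centre of level k = 2Cx base times the product of step ratios
    i2 <- match(2, tpl$class_levels)
    manual <- tpl$base_2cx_intensity *
      cumprod(c(1, tpl$under_replication))[seq_along(tpl$class_levels)] /
      cumprod(c(1, tpl$under_replication))[i2]
    expect_equal(unname(tpl$class_centres), manual, tolerance = 1e-12)
    expect_lte(tpl$debris_fraction + tpl$chain_fraction, 1)
  }
})

test_that("template construction rejects invalid parameters", {
  expect_error(simple_template(proportions = c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(simple_template(base = -5), "positive")
  expect_error(simple_template(ratios = c(1.9)), "one factor per")
  expect_error(simple_template(debris = 0.6, chain = 0.5), "\\[0, 1\\]")
  expect_error(simple_template(levels = c(2, 4, 7)), "double")
  expect_error(simple_template(levels = c(4, 8, 16)), "2Cx")
  expect_error(
    tissue_template("c", c(2, 4), c(0.5, 0.5), 100, 1.9, chain_fraction = 0.1),
    "8Cx")
})

test_that("template_without_interference strips only what it promises", {
  tpl <- template_library()$harm_midgut
  clean <- template_without_interference(tpl)
  expect_identical(clean$interference, "none")
  expect_identical(clean$class_proportions, tpl$class_proportions)
  expect_identical(clean$debris_fraction, tpl$debris_fraction)
  bare <- template_without_interference(tpl, drop_debris = TRUE)
  expect_identical(bare$debris_fraction, 0)
})
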