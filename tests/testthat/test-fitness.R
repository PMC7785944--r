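plant_row <- function(...) {
  base <- list(plant_id = "p1", population = "barra-like",
               flowers_total = 10, flowers_hermaphrodite = 10,
               fruits_total = 4,
               fruit1_ripe = NA, fruit1_aborted = NA,
               fruit2_ripe = NA, fruit2_aborted = NA,
               fruit3_ripe = NA, fruit3_aborted = NA,
               percent_corolla_predated = 0, ovaries_predated = 0)
  mod <- list(...)
  base[names(mod)] <- mod
  as.data.frame(base, stringsAsFactors = FALSE)
}

test_that("female components: hand-checked arithmetic", {
  # one fruit with 30 ripe, 10 aborted
  f <- female_fitness_components(plant_row(fruit1_ripe = 30, fruit1_aborted = 10,
                                           fruits_total = 4))
  expect_equal(f$ovules_per_flower, 40)
  expect_equal(f$seed_set, 0.75)
  expect_equal(f$seeds_per_fruit, 30)
  expect_equal(f$seeds_per_plant, 120)
  expect_equal(f$fruit_set, 0.4)

  # three fruits: (10/10, 20/0, 30/30)
  f3 <- female_fitness_components(plant_row(
    fruit1_ripe = 10, fruit1_aborted = 10,
    fruit2_ripe = 20, fruit2_aborted = 0,
    fruit3_ripe = 30, fruit3_aborted = 30))
  expect_equal(f3$seeds_per_fruit, 20)
  expect_equal(f3$seed_set, mean(c(0.5, 1, 0.5)))

  # no fruits at all: zero fitness, not missing
  f0 <- female_fitness_components(plant_row(fruits_total = 0))
  expect_equal(f0$fruit_set, 0)
  expect_equal(f0$seeds_per_plant, 0)
})

test_that("fruits with zero ovules are excluded from means, with a message", {
  expect_message(
    f <- female_fitness_components(plant_row(
      fruit1_ripe = 0, fruit1_aborted = 0,
      fruit2_ripe = 10, fruit2_aborted = 10)),
    "zero ovules")
  expect_equal(f$seeds_per_fruit, 10)
  expect_equal(f$seed_set, 0.5)
})

assay_row <- function(counts, anthers = 1) {
  out <- data.frame(plant_id = "p1", anthers_counted = anthers,
                    suspension_volume_ul = 1500, subsample_volume_ul = 10,
                    stringsAsFactors = FALSE)
  for (i in seq_along(counts)) out[[paste0("subsample_", i)]] <- counts[i]
  out
}

test_that("male components: volume arithmetic and clamping", {
  plants <- plant_row(flowers_hermaphrodite = 12)
  # mean 10 grains per 10 ul subsample, 1.5 ml suspension, 1 anther:
  # 10 x 150 grains in the anther sample, x10 anthers -> 15,000 per flower
  m <- male_fitness_components(plants, assay_row(rep(10, 10)), 21711.33)
  expect_equal(m$undispersed_per_flower, 15000)
  expect_equal(m$dispersed_per_flower, 21711.33 - 15000)
  expect_equal(m$dispersed_per_plant, (21711.33 - 15000) * 12)
  expect_false(m$dispersal_clamped)

  # empty anthers: full dispersal
  m0 <- male_fitness_components(plants, assay_row(rep(0, 10)), 21711.33)
  expect_equal(m0$dispersed_per_flower, 21711.33)

  # two anthers counted halve the per-anther scaling
  m2 <- male_fitness_components(plants, assay_row(rep(10, 10), anthers = 2),
                                21711.33)
  expect_equal(m2$undispersed_per_flower, 7500)

  # undispersed above the population mean is clamped and flagged
  mc <- male_fitness_components(plants, assay_row(rep(200, 10)), 21711.33)
  expect_equal(mc$dispersed_per_flower, 0)
  expect_true(mc$dispersal_clamped)

  expect_error(male_fitness_components(plants, assay_row(rep(1, 10), anthers = 3),
                                       21711.33), "anthers_counted")
  bad <- assay_row(rep(1, 10)); bad$subsample_volume_ul <- 0
  expect_error(male_fitness_components(plants, bad, 21711.33), "volume")
})

test_that("population-level dispersal matches the published linearity", {
  # an assay whose scaled-up undispersed count is 3,855.23 grains/flower
  # must yield 17,856.10 dispersed grains/flower under a production mean of
  # 21,711.33 (mean dispersed = production - mean undispersed, by linearity)
  m <- male_fitness_components(plant_row(),
                               assay_row(rep(3855.23 / 1500, 10)), 21711.33)
  expect_equal(m$undispersed_per_flower, 3855.23, tolerance = 1e-9)
  expect_equal(m$dispersed_per_flower, 17856.10, tolerance = 1e-9)
})

test_that("herbivory proportion and its guards", {
  expect_equal(herbivory_components(plant_row(
    ovaries_predated = 0))$proportion_ovaries_predated, 0)
  h <- herbivory_components(plant_row(flowers_total = 21, ovaries_predated = 13))
  expect_equal(h$proportion_ovaries_predated, 13 / 21, tolerance = 1e-12)
  expect_lt(h$proportion_ovaries_predated, 0.62 + 1e-9)
  expect_error(herbivory_components(plant_row(flowers_total = 5,
                                              ovaries_predated = 6)),
               "exceeds")
})

test_that("product identities hold on every simulated record", {
  pr <- population_preset("barra-like")
  tab <- simulate_population(pr, 200, seed = 31)
  assay <- simulate_pollen_assay(pr, tab, seed = 32)
  fc <- fitness_components(tab, assay, pr$pollen_production[["mean"]])
  ok <- !is.na(fc$seeds_per_fruit) & tab$fruits_total > 0
  expect_equal(fc$seeds_per_plant[ok],
               fc$seeds_per_fruit[ok] * tab$fruits_total[ok],
               tolerance = 1e-12)
  expect_equal(fc$dispersed_per_plant,
               fc$dispersed_per_flower * tab$flowers_hermaphrodite,
               tolerance = 1e-12)
  expect_true(all(fc$fruit_set >= 0 & fc$fruit_set <= 1, na.rm = TRUE))
  expect_true(all(fc$seed_set >= 0 & fc$seed_set <= 1, na.rm = TRUE))
  expect_true(all(fc$proportion_ovaries_predated >= 0 &
                    fc$proportion_ovaries_predated <= 1, na.rm = TRUE))
})

test_that("male fitness scales with hermaphrodite flowers only", {
  plants <- rbind(plant_row(), plant_row())
  plants$plant_id <- c("p1", "p2")
  plants$flowers_total <- c(20, 20)
  plants$flowers_hermaphrodite <- c(20, 10)
  assay <- rbind(assay_row(rep(5, 10)), assay_row(rep(5, 10)))
  assay$plant_id <- c("p1", "p2")
  m <- male_fitness_components(plants, assay, 20000)
  expect_equal(m$dispersed_per_plant[1], 2 * m$dispersed_per_plant[2])
})
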