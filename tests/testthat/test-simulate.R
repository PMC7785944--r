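test_that("the generator is deterministic given a seed", {
  pr <- population_preset("barra-like")
  expect_identical(simulate_population(pr, 100, seed = 7),
                   simulate_population(pr, 100, seed = 7))
  t1 <- simulate_population(pr, 100, seed = 7)
  t2 <- simulate_population(pr, 100, seed = 8)
  expect_false(identical(t1, t2))

  a1 <- simulate_pollen_assay(pr, t1, seed = 11)
  a2 <- simulate_pollen_assay(pr, t1, seed = 11)
  expect_identical(a1, a2)
})

test_that("generator rejects invalid sizes and non-finite presets", {
  pr <- population_preset("barra-like")
  expect_error(simulate_population(pr, 2, seed = 1))
  bad <- pr
  bad$path_coefficients[1] <- NaN
  expect_error(simulate_population(bad, 10, seed = 1), "non-finite")
})

test_that("plant-table invariants: counts, ids, ratios", {
  tab <- simulate_population(population_preset("melide-like"), 400, seed = 2)
  expect_false(anyDuplicated(tab$plant_id) > 0)
  for (col in c("flowers_total", "fruits_total", "ovaries_predated",
                "seeds_per_plant", "floral_display"))
    expect_true(all(tab[[col]] >= 0 & tab[[col]] == round(tab[[col]])))
  expect_true(all(tab$corolla_color > 1))
  expect_true(all(tab$flowers_hermaphrodite <= tab$flowers_total))
  expect_true(all(tab$fruits_total <= tab$flowers_total))
  expect_true(all(tab$ovaries_predated <= tab$flowers_total))
})

test_that("observed moments recover the preset targets at n = 5000", {
  for (nm in c("barra-like", "melide-like")) {
    pr <- population_preset(nm)
    tab <- simulate_population(pr, 5000, seed = 41)
    for (v in c(sem_vars, "floral_display")) {
      tgt <- pr$trait_moments[[v]]
      se_mean <- tgt[["sd"]] / sqrt(5000)
      se_sd <- tgt[["sd"]] / sqrt(2 * 5000)
      expect_lt(abs(mean(tab[[v]]) - tgt[["mean"]]), 3 * se_mean)
      expect_lt(abs(sd(tab[[v]]) - tgt[["sd"]]), 3 * se_sd)
    }
  }
})

test_that("flowers mean and corolla-to-flowers coefficient recover at n = 10000", {
  pr <- population_preset("barra-like")
  tab <- simulate_population(pr, 10000, seed = 1)
  expect_lt(abs(mean(tab$flowers_total) / 17.41 - 1), 0.02)
  z <- scale(tab[c("corolla_color", "flowers_total")])
  b <- coef(lm(z[, 2] ~ z[, 1]))[2]
  expect_lt(abs(b - 0.30), 0.04)
})

test_that("zero residual noise gives a deterministic corolla-flower map", {
  pr <- population_preset("barra-like")
  pr$latent$resid_sd[c("calyx_color", "flowers_total", "ovaries_predated",
                       "seeds_per_plant")] <- 0
  tab <- simulate_population(pr, 2000, seed = 5)
  # rounding to integer counts leaves a sliver below perfect correlation:
  # uniform rounding noise has variance 1/12 against a latent variance of
  # ~22, bounding the correlation near sqrt(1 - (1/12)/22) ~ 0.998
  expect_gt(abs(cor(tab$corolla_color, tab$flowers_total)), 0.995)
  expect_gt(abs(cor(tab$corolla_color, tab$calyx_color)), 1 - 1e-9)
})

test_that("pollen assay closure: forced dispersal fractions", {
  pr <- population_preset("barra-like")
  tab <- simulate_population(pr, 300, seed = 9)

  a0 <- simulate_pollen_assay(pr, tab, seed = 10, force_fraction = 0)
  m0 <- male_fitness_components(tab, a0, pr$pollen_production[["mean"]])
  # nothing dispersed: estimates recover full production within Poisson error
  expect_lt(abs(mean(m0$undispersed_per_flower) /
                  pr$pollen_production[["mean"]] - 1), 0.01)
  # per-plant dispersed estimates are pure clamped Poisson noise
  expect_lt(mean(m0$dispersed_per_flower),
            0.05 * pr$pollen_production[["mean"]])

  a1 <- simulate_pollen_assay(pr, tab, seed = 10, force_fraction = 1)
  counts <- as.matrix(a1[grep("^subsample_[0-9]+$", names(a1))])
  expect_true(all(counts == 0))
})

test_that("assay round-trip recovers the mean dispersed pollen per flower", {
  pr <- population_preset("barra-like")
  tab <- simulate_population(pr, 500, seed = 21)
  assay <- simulate_pollen_assay(pr, tab, seed = 22)
  male <- male_fitness_components(tab, assay, pr$pollen_production[["mean"]])
  truth <- mean(assay$dispersal_fraction) * pr$pollen_production[["mean"]]
  expect_lt(abs(mean(male$dispersed_per_flower) / truth - 1), 0.03)
  # and the Beta draw hits the preset fraction moments
  expect_lt(abs(mean(assay$dispersal_fraction) -
                  pr$dispersal_fraction_moments[["mean"]]), 0.035)
})

test_that("simulated colour patches hit the target ratio", {
  expect_equal(rg_ratio(simulate_color_patch(1.0, 64)), 1.0)
  expect_equal(rg_ratio(simulate_color_patch(1.68, 64)), 1.68)
  noisy <- simulate_color_patch(1.3, 256, noise_sd = 0.01, seed = 3)
  expect_lt(abs(rg_ratio(noisy) - 1.3), 0.005)
  expect_identical(simulate_color_patch(1.2, 32, 0.05, seed = 4),
                   simulate_color_patch(1.2, 32, 0.05, seed = 4))
  expect_error(simulate_color_patch(-1, 64), "target_ratio")
  expect_error(simulate_color_patch(1.3, 64, noise_sd = -0.1), "noise_sd")
})
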