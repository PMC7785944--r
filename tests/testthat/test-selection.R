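test_that("relativization: arithmetic and the mean-1 identity", {
  expect_equal(relativize_fitness(c(2, 2, 2)), c(1, 1, 1))
  w <- relativize_fitness(c(0, 2))
  expect_equal(w, c(0, 2))
  expect_equal(var(w), 2)
  set.seed(10)
  for (i in 1:10) {
    v <- rexp(sample(5:50, 1))
    expect_equal(mean(relativize_fitness(v)), 1, tolerance = 1e-12)
  }
  expect_error(relativize_fitness(c(0, 0, 0)), "positive")
  expect_error(relativize_fitness(c(1, NA)), ">= 2")
})

test_that("trait standardization: zero mean, unit sample SD, per population", {
  d <- data.frame(x = c(1, 2, 3))
  expect_equal(standardize_traits(d, "x")$x, c(-1, 0, 1))
  set.seed(11)
  d2 <- data.frame(x = rnorm(30, 5, 3), pop = rep(c("a", "b"), 15))
  d2$x[d2$pop == "b"] <- d2$x[d2$pop == "b"] + 10
  joint <- standardize_traits(d2, "x")
  sep <- standardize_traits(d2, "x", population = "pop")
  for (p in c("a", "b")) {
    expect_lt(abs(mean(sep$x[sep$pop == p])), 1e-12)
    expect_equal(sd(sep$x[sep$pop == p]), 1, tolerance = 1e-12)
  }
  # shifted means make pooled and within-population scaling differ
  expect_false(isTRUE(all.equal(joint$x, sep$x)))
  expect_error(standardize_traits(data.frame(x = rep(1, 5)), "x"), "constant")
})

test_that("selection opportunity is the variance of relative fitness", {
  expect_equal(selection_opportunity(c(1, 1, 1)), 0)
  expect_equal(selection_opportunity(c(0, 2)), 2)
  expect_error(selection_opportunity(3), ">= 2")
})

test_that("differentials equal the brute-force covariance", {
  # fitness unrelated to the trait
  z <- data.frame(z1 = c(-1, 0, 1))
  expect_equal(selection_differentials(z, c(1, 1, 1))$S, 0)
  expect_equal(selection_differentials(z, c(0.5, 1, 1.5))$S, 0.5)

  set.seed(12)
  Z <- as.data.frame(matrix(rnorm(250), 50, 5))
  w <- relativize_fitness(rexp(50))
  S <- selection_differentials(Z, w)$S
  brute <- vapply(Z, function(zj)
    sum((zj - mean(zj)) * (w - mean(w))) / (50 - 1), 0)
  expect_equal(S, unname(brute), tolerance = 1e-12)
})

test_that("gradients: regression identities against differentials", {
  set.seed(13)
  # single standardized trait: beta' = S'
  z1 <- scale(rnorm(40))[, 1]
  z1 <- (z1 - mean(z1)) / sd(z1)
  w <- relativize_fitness(exp(0.4 * z1 + rnorm(40, 0, 0.3)))
  d <- data.frame(z1 = z1)
  expect_equal(selection_gradients(d, w)$beta,
               selection_differentials(d, w)$S, tolerance = 1e-12)

  # exactly orthogonal standardized predictors: beta' = S' for all traits
  q <- qr.Q(qr(cbind(1, matrix(rnorm(60 * 3), 60, 3))))[, -1]
  Z <- as.data.frame(apply(q, 2, function(x) (x - mean(x)) / sd(x)))
  names(Z) <- paste0("t", 1:3)
  stopifnot(max(abs(cov(as.matrix(Z))[upper.tri(diag(3))])) < 1e-10)
  w2 <- relativize_fitness(exp(0.3 * Z$t1 - 0.2 * Z$t3 + rnorm(60, 0, 0.2)))
  expect_equal(selection_gradients(Z, w2)$beta,
               selection_differentials(Z, w2)$S, tolerance = 1e-10)
})

test_that("rank-deficient designs are reported with the offending column", {
  set.seed(14)
  Z <- data.frame(a = rnorm(20))
  Z$b <- 2 * Z$a
  expect_error(selection_gradients(Z, rexp(20)), "b")
  expect_error(selection_gradients(data.frame(a = rnorm(4), b = rnorm(4),
                                              c = rnorm(4)), rexp(4)),
               "complete cases")
})

test_that("selection analysis on synthetic data: flower number dominates", {
  pr <- population_preset("barra-like")
  tab <- simulate_population(pr, 5000, seed = 15)
  fit <- selection_analysis(tab,
    traits = c("corolla_color", "calyx_color", "corolla_area", "calyx_length",
               "ovules_per_flower", "floral_display", "flowers_total"),
    components = "seeds_per_plant")
  tabc <- coef(fit)
  bfl <- tabc$beta[tabc$trait == "flowers_total"]
  expect_gt(bfl, 0)
  expect_true(all(bfl > tabc$beta[tabc$trait != "flowers_total"]))

  # opportunity near the analytic variance of relative seed production
  I <- tabc$opportunity[1]
  tm <- pr$trait_moments$seeds_per_plant
  expect_lt(abs(I / (tm[["sd"]] / tm[["mean"]])^2 - 1), 0.15)
})

test_that("selection table writer emits one starred row per trait", {
  tab <- simulate_population(population_preset("melide-like"), 120, seed = 16)
  fit <- selection_analysis(tab, traits = c("corolla_color", "flowers_total"),
                            components = c("seeds_per_plant", "fruits_total"),
                            population = "population")
  path <- tempfile(fileext = ".tsv")
  out <- write_selection_table(fit, path)
  expect_equal(nrow(out), 2)
  expect_true(all(c("seeds_per_plant_S", "fruits_total_beta") %in% names(out)))
  expect_true(file.exists(path))
  unlink(path)
})
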