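test_that("saturated model: T ~ 0 and implied covariance equals the sample", {
  dag <- demo_dag()
  d <- simulate_dag(400, dag$edges, dag$coefs, dag$resid_sd, dag$vars,
                    seed = 19)
  sat_edges <- unlist(lapply(1:4, function(i)
    paste0(dag$vars[i], "->", dag$vars[(i + 1):5])))
  m <- path_model(dag$vars, "a", sat_edges)
  expect_equal(m$df, 0)
  fit <- fit_path(m, d)
  expect_lt(fit$T, 1e-6)
  expect_equal(fit$implied, cov(d[dag$vars]), tolerance = 1e-5)
})

test_that("numerical ML equals per-equation OLS for recursive models", {
  dag <- demo_dag()
  d <- simulate_dag(300, dag$edges, dag$coefs, dag$resid_sd, dag$vars,
                    seed = 20)
  m <- path_model(dag$vars, "a", paste0(dag$edges$from, "->", dag$edges$to))
  ml <- fit_path(m, d, engine = "ml")
  ols <- fit_path(m, d, engine = "ols")
  expect_lt(max(abs(ml$coef - ols$coef)), 1e-6)
  expect_lt(abs(ml$T - ols$T), 1e-6)
  # the OLS route is itself checked against lm() on the raw data
  ref <- coef(lm(d$d ~ d$b + d$c))[-1]
  expect_equal(unname(ols$coef[c("b->d", "c->d")]), unname(ref),
               tolerance = 1e-10)
})

test_that("fitting from a covariance matrix equals fitting raw data", {
  dag <- demo_dag()
  d <- simulate_dag(250, dag$edges, dag$coefs, dag$resid_sd, dag$vars,
                    seed = 21)
  m <- path_model(dag$vars, "a", paste0(dag$edges$from, "->", dag$edges$to))
  raw <- fit_path(m, d)
  cv <- fit_path(m, sample_cov = cov(d[dag$vars]), N = nrow(d))
  expect_lt(max(abs(raw$coef - cv$coef)), 1e-8)
  expect_lt(abs(raw$T - cv$T), 1e-8)
})

test_that("models with residual covariances fit by ML", {
  # x -> y1, x -> y2 with y1 ~~ y2 is saturated: T = 0, implied = S
  set.seed(22)
  n <- 500
  x <- rnorm(n); u <- rnorm(n)
  y1 <- 0.6 * x + u + rnorm(n, 0, 0.5)
  y2 <- -0.4 * x + u + rnorm(n, 0, 0.5)
  d <- data.frame(x, y1, y2)
  m <- path_model(c("x", "y1", "y2"), "x", c("x->y1", "x->y2"),
                  residual_cov = "y1~~y2")
  expect_equal(m$df, 0)
  fit <- fit_path(m, d)
  expect_lt(fit$T, 1e-6)
  expect_equal(fit$implied, cov(d), tolerance = 1e-4)
  expect_error(fit_path(m, d, engine = "ols"), "residual covariances")
  # the fitted residual covariance is positive (shared confounder)
  expect_gt(fit$Psi["y1", "y2"], 0.5)
})

test_that("standardized solution: correlation identity and scale invariance", {
  set.seed(23)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  d <- data.frame(x = x, y = y)
  m <- path_model(c("x", "y"), "x", "x->y")
  fit <- fit_path(m, d)
  std <- standardized_solution(fit)
  expect_equal(std$std, cor(x, y), tolerance = 1e-9)

  # rescaling any column leaves all standardized coefficients unchanged
  # (up to optimizer convergence noise)
  d2 <- data.frame(x = 1000 * x, y = y / 50)
  std2 <- standardized_solution(fit_path(m, d2))
  expect_equal(std2$std, std$std, tolerance = 1e-6)

  dag <- demo_dag()
  d5 <- simulate_dag(400, dag$edges, dag$coefs, dag$resid_sd, dag$vars,
                     seed = 24)
  m5 <- path_model(dag$vars, "a", paste0(dag$edges$from, "->", dag$edges$to))
  s1 <- standardized_solution(fit_path(m5, d5))
  d5s <- d5
  for (v in dag$vars) d5s[[v]] <- d5s[[v]] * runif(1, 0.1, 10)
  s2 <- standardized_solution(fit_path(m5, d5s))
  expect_equal(s2$std, s1$std, tolerance = 1e-6)
})

test_that("information criteria: saturated value and the nested identity", {
  vars <- paste0("v", 1:6)
  set.seed(25)
  d <- as.data.frame(matrix(rnorm(6 * 200), 200, 6))
  names(d) <- vars
  sat_edges <- unlist(lapply(1:5, function(i)
    paste0(vars[i], "->", vars[(i + 1):6])))
  sat <- fit_path(path_model(vars, "v1", sat_edges), d)
  ic <- information_criteria(sat)
  expect_equal(unname(ic["AIC"]), 2 * 21, tolerance = 1e-6)

  restr <- fit_path(path_model(vars, "v1", sat_edges[-(1:2)]), d)
  cmp <- compare_nested(sat, restr)
  # AIC_restricted - AIC_full = delta-chi-square - 2 * delta-df
  expect_equal(restr$AIC - sat$AIC, cmp$delta_chisq - 2 * cmp$delta_df,
               tolerance = 1e-6)
  expect_equal(cmp$delta_df, 2)
})

test_that("nested comparisons: self-test is zero, T is monotone", {
  dag <- demo_dag()
  m_full <- path_model(dag$vars, "a", paste0(dag$edges$from, "->", dag$edges$to))
  set.seed(26)
  for (i in 1:5) {
    d <- simulate_dag(150, dag$edges, dag$coefs, dag$resid_sd, dag$vars,
                      seed = 260 + i)
    full <- fit_path(m_full, d)
    self <- compare_nested(full, full)
    expect_equal(self$delta_chisq, 0)
    expect_equal(self$delta_df, 0)
    # drop one edge at random: restricted T never beats the full model
    k <- sample(nrow(dag$edges), 1)
    restr <- fit_path(path_model(dag$vars, "a",
      paste0(dag$edges$from[-k], "->", dag$edges$to[-k])), d)
    expect_gte(restr$T, full$T - 1e-8)
  }
  # non-nested pair is refused
  ma <- fit_path(path_model(c("a", "b", "c"), "a", c("a->b", "b->c")),
                 d[c("a", "b", "c")])
  mb <- fit_path(path_model(c("a", "b", "c"), "a", c("a->c", "c->b")),
                 d[c("a", "b", "c")])
  expect_error(compare_nested(ma, mb), "not nested")
})

test_that("path tracing: implied covariances decompose over tracing paths", {
  # for the chain + direct edge x -> m -> y, x -> y:
  # cov(x, y) = var(x) * (b_xy + b_xm * b_my)
  m <- path_model(c("x", "m", "y"), "x", c("x->m", "m->y", "x->y"))
  Sig <- implied_covariance(m,
    coef = c("x->m" = 0.8, "m->y" = 0.5, "x->y" = -0.3),
    var = c(x = 2, m = 1, y = 1))
  expect_equal(Sig["x", "y"], 2 * (-0.3 + 0.8 * 0.5), tolerance = 1e-12)
  expect_equal(Sig["m", "y"], 0.5 * Sig["m", "m"] - 0.3 * Sig["x", "m"],
               tolerance = 1e-12)
})

test_that("fit guards: sample size, positive definiteness, missing columns", {
  m <- chain_model()
  d <- data.frame(x = rnorm(4), m = rnorm(4), y = rnorm(4))
  expect_error(fit_path(m, d[1:4, ]), "complete cases")
  expect_error(fit_path(m, data.frame(x = rnorm(10))), "lacks variable")
  d2 <- data.frame(x = rnorm(30))
  d2$m <- 2 * d2$x   # singular sample covariance
  d2$y <- rnorm(30)
  expect_error(fit_path(m, d2), "positive definite")
})

test_that("simulate() round-trips the implied covariance", {
  set.seed(27)
  d <- data.frame(x = rnorm(300))
  d$m <- 0.7 * d$x + rnorm(300)
  d$y <- 0.5 * d$m + rnorm(300)
  fit <- fit_path(chain_model(), d)
  sim <- simulate(fit, nsim = 20000, seed = 28)
  expect_lt(max(abs(cov(sim) - fit$implied)), 0.08)
  expect_identical(simulate(fit, 10, seed = 1), simulate(fit, 10, seed = 1))
})
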