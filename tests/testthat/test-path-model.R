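test_that("parameter counting and df arithmetic", {
  vars <- paste0("v", 1:6)
  sat_edges <- unlist(lapply(1:5, function(i)
    paste0(vars[i], "->", vars[(i + 1):6])))
  m <- path_model(vars, exogenous = "v1", edges = sat_edges)
  expect_equal(length(sat_edges), 15)
  expect_equal(m$t, 21)   # p(p+1)/2 moments, all free
  expect_equal(m$df, 0)
  m2 <- path_model(vars, "v1", sat_edges[-(1:2)])
  expect_equal(m2$df, 2)
})

test_that("model validation rejects malformed specifications", {
  expect_error(path_model(c("A", "B"), character(0), c("A->B", "B->A")),
               "cycle")
  expect_error(path_model(c("A", "B", "C"), "A", c("A->B", "B->C", "C->B")),
               "cycle")
  expect_error(path_model(c("A", "B"), "A", "A->C"), "unknown variable")
  expect_error(path_model(c("A", "B"), "A", c("A->B", "A->B")), "duplicate")
  expect_error(path_model(c("A", "B"), "A", "B->A"), "exogenous")
  expect_error(path_model(c("A", "A"), "A", character(0)), "duplicated")
  expect_error(path_model(c("A", "B", "C"), "A", "A->B",
                          residual_cov = "B~~B"), "itself")
})

test_that("implied covariance: diagonal, chain and simulation oracle", {
  m0 <- path_model(c("a", "b"), c("a", "b"), character(0))
  S0 <- implied_covariance(m0, coef = numeric(0), var = c(a = 2, b = 3),
                           cov = c("a~~b" = 0.5))
  expect_equal(S0, matrix(c(2, 0.5, 0.5, 3), 2,
                          dimnames = list(c("a", "b"), c("a", "b"))))

  # chain x -> m -> y with unit residual variances: cov(x, y) = a * b
  ch <- chain_model()
  Sc <- implied_covariance(ch, coef = c("x->m" = 0.7, "m->y" = -0.4),
                           var = c(x = 1, m = 1, y = 1))
  expect_equal(Sc["x", "y"], 0.7 * -0.4, tolerance = 1e-12)
  expect_equal(Sc["m", "m"], 1 + 0.7^2, tolerance = 1e-12)

  # five-variable DAG against a large simulation
  dag <- demo_dag()
  m <- path_model(dag$vars, "a", paste0(dag$edges$from, "->", dag$edges$to))
  Sig <- implied_covariance(m, coef = dag$coefs, var = dag$resid_sd^2)
  d <- simulate_dag(2e5, dag$edges, dag$coefs, dag$resid_sd, dag$vars,
                    seed = 17)
  expect_lt(max(abs(Sig - cov(d))), 4 / sqrt(2e5) * max(diag(Sig)))
  expect_equal(Sig, t(Sig))
})

test_that("d-separation: chain, fork, collider", {
  m <- path_model(c("x", "z", "y", "w"), "x",
                  c("x->z", "z->y", "x->w", "y->w"))
  expect_false(d_separated(m, "x", "y"))
  expect_true(d_separated(m, "x", "y", "z"))         # chain blocked
  m2 <- path_model(c("a", "b", "c"), "a", c("a->b", "a->c"))
  expect_false(d_separated(m2, "b", "c"))
  expect_true(d_separated(m2, "b", "c", "a"))        # fork blocked
  m3 <- path_model(c("a", "b", "c"), c("a", "b"), c("a->c", "b->c"))
  expect_true(d_separated(m3, "a", "b"))             # collider open only when
  expect_false(d_separated(m3, "a", "b", "c"))       # conditioned on
})

test_that("enumeration: saturated class, contract df, small-case oracle", {
  sat <- enumerate_near_saturated(c("x", "y", "z"), "x", df_set = 0)
  expect_length(sat, 1)
  expect_equal(sat[[1]]$df, 0)

  cands <- enumerate_near_saturated(c("x", "y", "z"), "x", df_set = 1)
  expect_true(all(vapply(cands, function(m) m$df, 0) == 1))
  # exhaustive oracle: fit every raw (ordering, removed-edge) candidate on a
  # random covariance and count distinct implied matrices
  set.seed(18)
  A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(3)
  dimnames(S) <- list(c("x", "y", "z"), c("x", "y", "z"))
  fits <- list()
  for (ord in list(c("x", "y", "z"), c("x", "z", "y"))) {
    edges <- data.frame(from = ord[c(1, 1, 2)], to = ord[c(2, 3, 3)],
                        stringsAsFactors = FALSE)
    for (drop in 1:3) {
      keep <- edges[-drop, ]
      m <- path_model(ord, "x", paste0(keep$from, "->", keep$to))
      f <- fit_path(m, sample_cov = S, N = 100, engine = "ols")
      fits[[length(fits) + 1]] <- round(f$implied[c("x", "y", "z"),
                                                  c("x", "y", "z")], 8)
    }
  }
  n_distinct <- length(unique(vapply(fits, function(M)
    paste(M, collapse = ","), "")))
  expect_equal(length(cands), n_distinct)

  expect_error(enumerate_near_saturated(paste0("v", 1:9), "v1"), "8 variables")
  expect_error(enumerate_near_saturated(c("x", "y"), "x", df_set = 5),
               "df_set")
})

test_that("equivalence classes carry provenance and deduplicate correctly", {
  cands <- enumerate_near_saturated(c("x", "y", "z", "w"), "x", df_set = 1:2)
  # every class: df in the requested set, provenance present
  for (m in cands) {
    expect_true(m$df %in% 1:2)
    expect_false(is.null(attr(m, "ordering")))
    expect_false(is.null(attr(m, "removed")))
  }
  # total raw candidates = orderings x removals; classes must not exceed it
  expect_lte(length(cands), factorial(3) * (6 + choose(6, 2)))
  # class sizes account for all raw candidates
  expect_equal(sum(vapply(cands, function(m) attr(m, "class_size"), 0L)),
               factorial(3) * (6 + choose(6, 2)))
})
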