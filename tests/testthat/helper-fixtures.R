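# Shared fixtures: model builders and small oracles used across test files.

sem_vars <- c("corolla_color", "calyx_color", "flowers_total",
              "ovaries_predated", "seeds_per_plant")

generating_edges <- c("corolla_color->calyx_color",
                      "corolla_color->flowers_total",
                      "flowers_total->ovaries_predated",
                      "ovaries_predated->seeds_per_plant",
                      "flowers_total->seeds_per_plant")

generating_model <- function() path_model(sem_vars, "corolla_color",
                                          generating_edges)

chain_model <- function() path_model(c("x", "m", "y"), "x",
                                     c("x->m", "m->y"))

# Simulate raw data from a parameterized recursive DAG (unit-variance
# exogenous, Gaussian residuals) - an oracle independent of the package's
# implied_covariance algebra.
simulate_dag <- function(n, edges, coefs, resid_sd, order, seed) {
  set.seed(seed)
  d <- list()
  for (v in order) {
    pa <- edges$from[edges$to == v]
    mu <- 0
    for (p in pa) mu <- mu + coefs[[paste0(p, "->", v)]] * d[[p]]
    d[[v]] <- mu + rnorm(n, 0, resid_sd[[v]])
  }
  as.data.frame(d)
}

# A fixed 5-variable random-ish DAG used by several oracle tests.
demo_dag <- function() {
  vars <- c("a", "b", "c", "d", "e")
  edges <- parse_pairs_test(c("a->b", "a->c", "b->d", "c->d", "d->e", "b->e"))
  coefs <- c("a->b" = 0.8, "a->c" = -0.5, "b->d" = 0.6, "c->d" = 0.7,
             "d->e" = -0.4, "b->e" = 0.3)
  resid_sd <- c(a = 1, b = 0.9, c = 1.1, d = 0.8, e = 1.2)
  list(vars = vars, edges = edges, coefs = coefs, resid_sd = resid_sd)
}

parse_pairs_test <- function(x) {
  parts <- strsplit(x, "->", fixed = TRUE)
  data.frame(from = vapply(parts, `[`, "", 1),
             to = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
}
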