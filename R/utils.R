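# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a locally seeded RNG
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulation functions are deterministic without clobbering
#' the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok)
    stop(sprintf("'%s' must be a single finite number %s %s", name,
                 if (strict) ">" else ">=", format(lower)), call. = FALSE)
  invisible(x)
}

# Moments of Y = max(0, X), X ~ N(mu, sigma) (censoring at zero).
censored_moments <- function(mu, sigma) {
  z <- mu / sigma
  p <- stats::pnorm(z)
  lam <- stats::dnorm(z)
  m1 <- mu * p + sigma * lam
  m2 <- (mu^2 + sigma^2) * p + mu * sigma * lam
  c(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

# Moments of X | X > a, X ~ N(mu, sigma) (lower truncation).
truncated_moments <- function(mu, sigma, a) {
  al <- (a - mu) / sigma
  lam <- stats::dnorm(al) / (1 - stats::pnorm(al))
  c(mean = mu + sigma * lam,
    sd = sigma * sqrt(pmax(1 + al * lam - lam^2, 0)))
}

# Solve for latent (mu, sigma) whose censored/truncated moments hit a target.
match_censored <- function(mean, sd) {
  obj <- function(par) {
    m <- censored_moments(par[1], exp(par[2]))
    sum((m - c(mean, sd))^2)
  }
  o <- stats::optim(c(mean, log(sd)), obj,
                    control = list(reltol = 1e-14, maxit = 5000))
  c(mu = o$par[1], sigma = exp(o$par[2]))
}

match_truncated <- function(mean, sd, a) {
  obj <- function(par) {
    m <- truncated_moments(par[1], exp(par[2]), a)
    sum((m - c(mean, sd))^2)
  }
  o <- stats::optim(c(mean, log(sd)), obj,
                    control = list(reltol = 1e-14, maxit = 5000))
  c(mu = o$par[1], sigma = exp(o$par[2]))
}

# Lower-truncated normal draws by inverse-CDF.
rnorm_trunc <- function(n, mu, sigma, a) {
  u <- stats::runif(n, stats::pnorm((a - mu) / sigma), 1)
  mu + sigma * stats::qnorm(u)
}

# Round to integer-valued double, clamped below.
round_count <- function(x, lower = 0) pmax(lower, round(x))
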