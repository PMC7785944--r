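#' Fit a path model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy
#' `F(theta) = log|Sigma(theta)| - log|S| + tr(S Sigma(theta)^-1) - p`
#' between the sample covariance `S` and the model-implied covariance.
#' Residual and exogenous variances are parameterized on the log scale to
#' enforce positivity; the optimizer is quasi-Newton (BFGS) warm-started
#' from per-equation OLS. The chi-square statistic is `T = (N - 1) F` at
#' the optimum (Joreskog-Sorbom multiplier convention; within-run model
#' comparisons do not depend on the choice).
#'
#' For recursive models without residual covariances, per-equation OLS is
#' itself the exact ML solution; `engine = "ols"` uses that closed form
#' directly (and is what the bootstrap and model-enumeration helpers use
#' for speed). The default `engine = "ml"` always runs the numerical
#' optimizer.
#'
#' @param model a [path_model()].
#' @param data a data.frame containing the model variables (complete cases
#'   are used), or `NULL` when `sample_cov` is given.
#' @param sample_cov optional sample covariance matrix (with `N`), used
#'   instead of raw data.
#' @param N number of observations when fitting from a covariance matrix.
#' @param engine `"ml"` (numerical optimizer) or `"ols"` (closed form; only
#'   for recursive models without residual covariances).
#' @param rescale named vector of scale factors applied to columns before
#'   fitting, e.g. `c(seeds_per_plant = 1e-3)` to divide total female
#'   fitness by 1,000 and reduce its dominant variance.
#' @return An object of class `"path_fit"`; see [summary.path_fit()].
#' @examples
#' tab <- simulate_population(population_preset("barra-like"), 500, seed = 1)
#' m <- path_model(c("corolla_color", "flowers_total", "seeds_per_plant"),
#'                 exogenous = "corolla_color",
#'                 edges = c("corolla_color->flowers_total",
#'                           "flowers_total->seeds_per_plant"))
#' fit <- fit_path(m, tab, rescale = c(seeds_per_plant = 1e-3))
#' coef(fit)
#' @export
fit_path <- function(model, data = NULL, sample_cov = NULL, N = NULL,
                     engine = c("ml", "ols"), rescale = NULL) {
  stopifnot(inherits(model, "path_model"))
  engine <- match.arg(engine)
  vars <- model$variables

  if (is.null(sample_cov)) {
    if (is.null(data)) stop("supply 'data' or 'sample_cov'", call. = FALSE)
    missing_cols <- setdiff(vars, names(data))
    if (length(missing_cols))
      stop("data lacks variable(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
    N <- nrow(d)
    if (!is.null(rescale))
      for (v in names(rescale)) d[[v]] <- d[[v]] * rescale[[v]]
    S <- stats::cov(d)
  } else {
    if (is.null(N)) stop("'N' is required with 'sample_cov'", call. = FALSE)
    S <- as.matrix(sample_cov)[vars, vars]
    if (!is.null(rescale)) {
      sc <- stats::setNames(rep(1, length(vars)), vars)
      sc[names(rescale)] <- rescale
      S <- diag(sc) %*% S %*% diag(sc)
      dimnames(S) <- list(vars, vars)
    }
  }
  if (N <= model$p + 2)
    stop("need more complete cases than variables + 2", call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("sample covariance is not positive definite", call. = FALSE)

  fit <- if (engine == "ols") fit_path_ols(model, S, N)
         else fit_path_ml(model, S, N)
  fit$model <- model
  fit$S <- S
  fit$N <- N
  fit$engine <- engine
  fit$rescale <- rescale
  fit <- finish_path_fit(fit)
  class(fit) <- "path_fit"
  fit
}

# ---- closed form (recursive, no residual covariances) ----
fit_path_ols <- function(model, S, N) {
  if (nrow(model$residual_cov))
    stop("engine 'ols' requires a model without residual covariances",
         call. = FALSE)
  vars <- model$variables
  sol <- recursive_ols_cov(model$order, model$exogenous, model$edges, S)
  sol$implied <- sol$implied[vars, vars]
  sol$Psi <- sol$Psi[vars, vars]
  sol$psi <- sol$psi[vars]
  ekey <- paste0(model$edges$from, "->", model$edges$to)
  coefs <- stats::setNames(
    vapply(seq_along(ekey), function(i)
      sol$B[model$edges$to[i], model$edges$from[i]], 0), ekey)
  # classical OLS standard errors from covariance algebra
  se <- stats::setNames(rep(NA_real_, length(ekey)), ekey)
  for (v in unique(model$edges$to)) {
    pa <- parents_of(model, v)
    cv <- sol$psi[v] / (N - 1) * solve(S[pa, pa, drop = FALSE])
    se[paste0(pa, "->", v)] <- sqrt(diag(as.matrix(cv)))
  }
  list(coef = coefs, coef_se = se, psi = sol$psi,
       Psi = sol$Psi, implied = sol$implied,
       convergence = list(converged = TRUE, method = "closed form"))
}

# ---- numerical ML ----
fit_path_ml <- function(model, S, N) {
  par <- pack_parameters(model, S)
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  p <- model$p

  objective <- function(theta) {
    Sigma <- build_sigma(model, theta, par)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    val <- logdet - logdetS + tr - p
    if (!is.finite(val)) 1e10 else as.numeric(val)
  }

  opt <- stats::optim(par$init, objective, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  # polish once more from the optimum
  opt <- stats::optim(opt$par, objective, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  theta <- opt$par

  grad <- numeric_gradient(objective, theta)
  converged <- opt$convergence == 0 || sqrt(sum(grad^2)) < 1e-6
  if (!converged)
    warning(sprintf("ML fit did not converge (gradient norm %.2e)",
                    sqrt(sum(grad^2))), call. = FALSE)

  H <- stats::optimHess(theta, objective)
  theta_cov <- tryCatch(2 / (N - 1) * solve(H), error = function(e) NULL)

  unpacked <- unpack_parameters(model, theta, par)
  coef_se <- stats::setNames(rep(NA_real_, length(par$coef_idx)),
                             names(par$init)[par$coef_idx])
  if (!is.null(theta_cov)) {
    d <- diag(theta_cov)[par$coef_idx]
    coef_se[] <- sqrt(pmax(d, 0))
  }
  list(coef = unpacked$coef, coef_se = coef_se, psi = unpacked$psi,
       Psi = unpacked$Psi, implied = unpacked$Sigma,
       theta = theta, theta_cov = theta_cov, F_min = opt$value,
       convergence = list(converged = converged,
                          gradient_norm = sqrt(sum(grad^2)),
                          F_min = opt$value, method = "BFGS"))
}

numeric_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# Parameter packing: edge coefficients, log variances (residual +
# exogenous), then free covariances (residual + exogenous pairs).
pack_parameters <- function(model, S) {
  ekey <- paste0(model$edges$from, "->", model$edges$to)
  ols <- recursive_ols_cov(model$order, model$exogenous, model$edges, S)
  coef_init <- vapply(seq_along(ekey), function(i)
    ols$B[model$edges$to[i], model$edges$from[i]], 0)
  var_names <- model$variables
  var_init <- log(pmax(ols$psi[var_names], 1e-8))

  cov_keys <- character(0); cov_init <- numeric(0)
  if (nrow(model$residual_cov)) {
    cov_keys <- paste0(model$residual_cov$a, "~~", model$residual_cov$b)
    cov_init <- rep(0, length(cov_keys))
  }
  ne <- length(model$exogenous)
  if (ne > 1) {
    pairs <- utils::combn(model$exogenous, 2)
    exo_keys <- paste0(pairs[1, ], "~~", pairs[2, ])
    cov_keys <- c(cov_keys, exo_keys)
    cov_init <- c(cov_init, apply(pairs, 2, function(ab) S[ab[1], ab[2]]))
  }

  init <- c(coef_init, var_init, cov_init)
  names(init) <- c(ekey, paste0("logvar:", var_names),
                   if (length(cov_keys)) paste0("cov:", cov_keys))
  list(init = init,
       coef_idx = seq_along(ekey),
       var_idx = length(ekey) + seq_along(var_names),
       cov_idx = if (length(cov_keys))
         length(ekey) + length(var_names) + seq_along(cov_keys) else integer(0),
       cov_keys = cov_keys)
}

unpack_parameters <- function(model, theta, par) {
  ekey <- paste0(model$edges$from, "->", model$edges$to)
  coef <- stats::setNames(theta[par$coef_idx], ekey)
  var <- stats::setNames(exp(theta[par$var_idx]), model$variables)
  cov <- if (length(par$cov_idx))
    stats::setNames(theta[par$cov_idx], par$cov_keys) else NULL
  Sigma <- implied_covariance(model, coef, var, cov)
  # rebuild Psi for residual-variance reporting
  p <- model$p
  Psi <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  diag(Psi) <- var
  if (!is.null(cov))
    for (nm in names(cov)) {
      ab <- strsplit(nm, "~~", fixed = TRUE)[[1]]
      Psi[ab[1], ab[2]] <- Psi[ab[2], ab[1]] <- cov[[nm]]
    }
  list(coef = coef, psi = var, Psi = Psi, Sigma = Sigma)
}

build_sigma <- function(model, theta, par) {
  u <- unpack_parameters(model, theta, par)
  u$Sigma
}

# Common fit statistics.
finish_path_fit <- function(fit) {
  model <- fit$model; S <- fit$S; N <- fit$N
  p <- model$p
  ch <- chol(fit$implied)
  logdet <- 2 * sum(log(diag(ch)))
  logdetS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  Fmin <- logdet - logdetS + sum(diag(chol2inv(ch) %*% S)) - p
  Fmin <- max(Fmin, 0)
  fit$F_min <- Fmin
  fit$T <- (N - 1) * Fmin
  fit$df <- model$df
  fit$p_value <- if (model$df > 0)
    stats::pchisq(fit$T, model$df, lower.tail = FALSE) else NA_real_
  fit$AIC <- fit$T + 2 * model$t
  fit$BIC <- fit$T + model$t * log(N)
  fit$logLik <- -((N - 1) / 2) * (logdet + sum(diag(chol2inv(ch) %*% S)))
  r2 <- vapply(model$endogenous, function(v)
    1 - fit$psi[[v]] / fit$implied[v, v], 0)
  fit$R2 <- r2
  fit
}

#' Standardized path coefficients
#'
#' Rescales each unstandardized coefficient by `sd(cause) / sd(effect)`,
#' using the model-implied SDs. Standardized coefficients can exceed 1 in
#' magnitude when predictors are correlated.
#'
#' @param fit a [fit_path()] result.
#' @return A `data.frame`: `from`, `to`, `est` (unstandardized), `std`.
#' @export
standardized_solution <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  sds <- sqrt(diag(fit$implied))
  if (any(sds == 0)) stop("zero implied SD", call. = FALSE)
  E <- fit$model$edges
  est <- unname(fit$coef)
  data.frame(from = E$from, to = E$to, est = est,
             std = est * sds[E$from] / sds[E$to],
             stringsAsFactors = FALSE)
}

#' Chi-square-scale information criteria
#'
#' `AIC = T + 2t` and `BIC = T + t log(N)`, with `T` the model chi-square
#' and `t` the free-parameter count. This chi-square-plus-penalty scale is
#' rank-equivalent, for fixed data, to the likelihood-based criteria;
#' absolute values are engine-convention dependent and only orderings are
#' meaningful.
#'
#' @param fit a [fit_path()] result.
#' @return Named vector `c(AIC =, BIC =)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  c(AIC = fit$AIC, BIC = fit$BIC)
}

#' Chi-square difference test for nested path models
#'
#' Nesting is checked structurally: the restricted model's edges and
#' residual covariances must be subsets of the full model's, over the same
#' variables.
#'
#' @param full,restricted [fit_path()] results on the same data.
#' @return A list with `delta_chisq`, `delta_df`, `p`.
#' @export
compare_nested <- function(full, restricted) {
  stopifnot(inherits(full, "path_fit"), inherits(restricted, "path_fit"))
  if (!setequal(full$model$variables, restricted$model$variables))
    stop("models are defined on different variables", call. = FALSE)
  key <- function(E, sep) paste0(E[[1]], sep, E[[2]])
  if (!all(key(restricted$model$edges, "->") %in% key(full$model$edges, "->")) ||
      !all(key(restricted$model$residual_cov, "~~") %in%
           key(full$model$residual_cov, "~~")))
    stop("models are not nested", call. = FALSE)
  d <- restricted$T - full$T
  if (d < -1e-6)
    warning("restricted model fits better than the full model; ",
            "check convergence", call. = FALSE)
  d <- max(d, 0)
  ddf <- restricted$df - full$df
  list(delta_chisq = d, delta_df = ddf,
       p = if (ddf > 0) stats::pchisq(d, ddf, lower.tail = FALSE) else NA_real_)
}

# ---- methods ----

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Path model fit (%s): %d variables, N = %d\n",
              x$engine, x$model$p, x$N))
  cat(sprintf("  chi-square T = %.4f, df = %d%s\n", x$T, x$df,
              if (!is.na(x$p_value)) sprintf(", p = %.4g", x$p_value) else ""))
  cat(sprintf("  AIC = %.2f, BIC = %.2f\n", x$AIC, x$BIC))
  invisible(x)
}

#' Summary of a fitted path model
#'
#' @param object a [fit_path()] result.
#' @param ... unused.
#' @return A `summary.path_fit` object: the coefficient table
#'   (unstandardized and standardized estimates, SEs, z, p), residual
#'   variances, R-squared per endogenous variable and fit statistics.
#' @export
summary.path_fit <- function(object, ...) {
  std <- standardized_solution(object)
  se <- object$coef_se
  z <- object$coef / se
  tab <- data.frame(from = std$from, to = std$to, est = std$est,
                    se = unname(se), z = unname(z),
                    p = unname(2 * stats::pnorm(-abs(z))), std = std$std,
                    stringsAsFactors = FALSE)
  structure(list(coefficients = tab, R2 = object$R2, psi = object$psi,
                 T = object$T, df = object$df, p_value = object$p_value,
                 AIC = object$AIC, BIC = object$BIC, N = object$N,
                 engine = object$engine,
                 convergence = object$convergence),
            class = "summary.path_fit")
}

#' @export
print.summary.path_fit <- function(x, ...) {
  cat(sprintf("Path model fit (N = %d, engine %s)\n", x$N, x$engine))
  cat(sprintf("chi-square T = %.4f, df = %d%s; AIC = %.2f, BIC = %.2f\n\n",
              x$T, x$df,
              if (!is.na(x$p_value)) sprintf(", p = %.4g", x$p_value) else "",
              x$AIC, x$BIC))
  tab <- x$coefficients
  tab$est <- round(tab$est, 4); tab$se <- round(tab$se, 4)
  tab$z <- round(tab$z, 3); tab$p <- signif(tab$p, 3)
  tab$std <- round(tab$std, 3)
  print(tab, row.names = FALSE)
  cat("\nR-squared of endogenous variables:\n")
  print(round(x$R2, 3))
  invisible(x)
}

#' @export
coef.path_fit <- function(object, ...) object$coef

#' @export
fitted.path_fit <- function(object, ...) object$implied

#' @export
residuals.path_fit <- function(object, ...) object$S - object$implied

#' @export
logLik.path_fit <- function(object, ...) {
  structure(object$logLik, df = object$model$t, nobs = object$N,
            class = "logLik")
}

#' @export
vcov.path_fit <- function(object, ...) {
  se <- object$coef_se
  if (!is.null(object$theta_cov)) {
    idx <- seq_along(object$coef)
    v <- object$theta_cov[idx, idx, drop = FALSE]
    dimnames(v) <- list(names(object$coef), names(object$coef))
    return(v)
  }
  diag(se^2, length(se)) -> v
  dimnames(v) <- list(names(se), names(se))
  v
}

#' Simulate data from a fitted path model
#'
#' Draws multivariate-normal samples with the model-implied covariance
#' (means zero: the fit is covariance-structure only).
#'
#' @param object a [fit_path()] result.
#' @param nsim number of rows to draw.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A `data.frame` with one column per model variable.
#' @export
simulate.path_fit <- function(object, nsim = object$N, seed = NULL, ...) {
  draw <- function() {
    L <- chol(object$implied)
    Z <- matrix(stats::rnorm(nsim * object$model$p), nsim)
    out <- as.data.frame(Z %*% L)
    names(out) <- object$model$variables
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
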