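#' Nonparametric bootstrap inference for a path model
#'
#' Resamples plants (rows) with replacement, refits the model on each
#' replicate, and summarizes the replicate coefficient estimates:
#' bootstrap SEs, percentile confidence intervals, and normal-approximation
#' `Z = estimate / SE` with two-sided p-values. Replicates whose fit fails
#' (e.g. a singular resampled covariance) are dropped and counted.
#'
#' @param model a [path_model()].
#' @param data data.frame with the model variables.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed RNG seed; the same seed yields identical inference.
#' @param engine fitting engine passed to [fit_path()]; default uses the
#'   closed form when the model admits it.
#' @param rescale passed to [fit_path()].
#' @param level confidence level for the percentile intervals.
#' @return An object of class `"path_boot"`: per-parameter table
#'   (`est`, `se`, `z`, `p`, `ci_lower`, `ci_upper`), the replicate matrix,
#'   `B`, `seed` and the failed-replicate count.
#' @export
bootstrap_path <- function(model, data, B = 1000, seed, engine = NULL,
                           rescale = NULL, level = 0.95) {
  stopifnot(inherits(model, "path_model"))
  if (B < 100) stop("B must be >= 100 for reported bootstrap SEs", call. = FALSE)
  if (is.null(engine))
    engine <- if (nrow(model$residual_cov)) "ml" else "ols"
  d <- data[stats::complete.cases(data[model$variables]),
            model$variables, drop = FALSE]
  n <- nrow(d)
  fit0 <- fit_path(model, d, engine = engine, rescale = rescale)

  idx <- with_seed(seed, matrix(sample.int(n, n * B, replace = TRUE), n, B))
  reps <- matrix(NA_real_, B, length(fit0$coef),
                 dimnames = list(NULL, names(fit0$coef)))
  failed <- 0L
  for (b in seq_len(B)) {
    est <- tryCatch(
      fit_path(model, d[idx[, b], , drop = FALSE],
               engine = engine, rescale = rescale)$coef,
      error = function(e) NULL)
    if (is.null(est)) failed <- failed + 1L else reps[b, ] <- est
  }
  if (failed > B / 2)
    stop("more than half of the bootstrap replicates failed", call. = FALSE)
  if (failed > 0.05 * B)
    warning(sprintf("%d of %d bootstrap replicates failed", failed, B),
            call. = FALSE)

  ok <- stats::complete.cases(reps)
  se <- apply(reps[ok, , drop = FALSE], 2, stats::sd)
  al <- (1 - level) / 2
  ci <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(al, 1 - al))
  z <- fit0$coef / se
  structure(list(
    table = data.frame(parameter = names(fit0$coef), est = unname(fit0$coef),
                       se = unname(se), z = unname(z),
                       p = unname(2 * stats::pnorm(-abs(z))),
                       ci_lower = unname(ci[1, ]), ci_upper = unname(ci[2, ]),
                       stringsAsFactors = FALSE),
    replicates = reps[ok, , drop = FALSE], fit = fit0,
    B = B, seed = seed, failed = failed, level = level),
    class = "path_boot")
}

#' @export
print.path_boot <- function(x, ...) {
  cat(sprintf("Bootstrap inference: B = %d (%d failed), seed = %s\n",
              x$B, x$failed, format(x$seed)))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Indirect and total effects along directed paths
#'
#' Enumerates every directed path from `source` to `target` in the fitted
#' DAG and multiplies the unstandardized coefficients along each. The total
#' indirect effect is the sum over all paths excluding the direct edge; the
#' total effect adds the direct coefficient. When a [bootstrap_path()]
#' result is supplied, the same products are computed per replicate to give
#' bootstrap SEs, normal-approximation Z and p, and percentile intervals.
#'
#' @param fit a [fit_path()] result.
#' @param source,target variable names; `source` must precede `target`.
#' @param boot optional [bootstrap_path()] result for the same model.
#' @return A list with `paths` (per-path products), `direct`, `indirect`,
#'   `total`, and (with `boot`) an `inference` table.
#' @export
indirect_effects <- function(fit, source, target, boot = NULL) {
  stopifnot(inherits(fit, "path_fit"))
  E <- fit$model$edges
  stopifnot(source %in% fit$model$variables, target %in% fit$model$variables)

  find_paths <- function(v, acc) {
    if (v == target) return(list(acc))
    nxt <- E$to[E$from == v]
    out <- list()
    for (w in nxt) out <- c(out, find_paths(w, c(acc, w)))
    out
  }
  paths <- find_paths(source, source)
  if (length(paths) == 0) {
    message("no directed path from ", source, " to ", target)
    return(list(paths = list(), direct = 0, indirect = 0, total = 0))
  }
  prod_along <- function(coefs, path)
    prod(coefs[paste0(path[-length(path)], "->", path[-1])])

  products <- vapply(paths, prod_along, 0, coefs = fit$coef)
  is_direct <- lengths(paths) == 2
  direct <- if (any(is_direct)) sum(products[is_direct]) else 0
  indirect <- sum(products[!is_direct])
  out <- list(paths = stats::setNames(as.list(products),
                vapply(paths, paste, "", collapse = " -> ")),
              direct = direct, indirect = indirect,
              total = direct + indirect)

  if (!is.null(boot)) {
    stopifnot(inherits(boot, "path_boot"))
    reps <- boot$replicates
    rep_ind <- apply(reps, 1, function(cf) {
      pr <- vapply(paths, prod_along, 0, coefs = cf)
      c(indirect = sum(pr[!is_direct]), total = sum(pr))
    })
    est <- c(indirect = indirect, total = out$total)
    se <- apply(rep_ind, 1, stats::sd)
    z <- est / se
    al <- (1 - boot$level) / 2
    ci <- apply(rep_ind, 1, stats::quantile, probs = c(al, 1 - al))
    out$inference <- data.frame(
      effect = names(est), est = unname(est), se = unname(se), z = unname(z),
      p = unname(2 * stats::pnorm(-abs(z))),
      ci_lower = ci[1, ], ci_upper = ci[2, ],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Backward trimming of a path model
#'
#' Starting from a baseline model, iteratively removes the non-significant
#' path with the smallest absolute standardized coefficient, refits, and
#' records the chi-square difference test of the reduced model against the
#' baseline. Trimming stops when every remaining path is significant at
#' `alpha` or when a removal is rejected by the difference test at `alpha`.
#' The returned model is the visited model with the lowest AIC (ties broken
#' by BIC).
#'
#' @param data data.frame with the model variables.
#' @param baseline a [path_model()] with at least one edge.
#' @param alpha significance level for path retention and difference tests.
#' @param engine,rescale passed to [fit_path()].
#' @return A list with `model` (selected spec), `fit`, and `steps` (the
#'   comparison table; one row per visited model, df strictly increasing).
#' @export
trim_model <- function(data, baseline, alpha = 0.05, engine = "ml",
                       rescale = NULL) {
  stopifnot(inherits(baseline, "path_model"))
  if (nrow(baseline$edges) == 0)
    stop("baseline model has no removable path", call. = FALSE)
  base_fit <- fit_path(baseline, data, engine = engine, rescale = rescale)

  visited <- list(list(model = baseline, fit = base_fit, removed = NA))
  current <- baseline; current_fit <- base_fit
  repeat {
    sm <- summary(current_fit)$coefficients
    nonsig <- sm[!is.na(sm$p) & sm$p >= alpha, , drop = FALSE]
    if (nrow(nonsig) == 0 || nrow(current$edges) == 1) break
    drop_row <- nonsig[which.min(abs(nonsig$std)), ]
    keep <- !(current$edges$from == drop_row$from &
                current$edges$to == drop_row$to)
    reduced <- path_model(current$variables, current$exogenous,
                          current$edges[keep, , drop = FALSE],
                          if (nrow(current$residual_cov))
                            current$residual_cov else NULL)
    red_fit <- fit_path(reduced, data, engine = engine, rescale = rescale)
    cmp <- compare_nested(base_fit, red_fit)
    visited[[length(visited) + 1]] <- list(
      model = reduced, fit = red_fit,
      removed = paste0(drop_row$from, "->", drop_row$to),
      delta_chisq = cmp$delta_chisq, delta_df = cmp$delta_df, p = cmp$p)
    if (!is.na(cmp$p) && cmp$p < alpha) break  # removal rejected
    current <- reduced; current_fit <- red_fit
  }

  steps <- do.call(rbind, lapply(visited, function(v) data.frame(
    removed = if (is.character(v$removed)) v$removed else "(baseline)",
    T = v$fit$T, df = v$fit$df, AIC = v$fit$AIC, BIC = v$fit$BIC,
    delta_chisq = v$delta_chisq %||% NA_real_,
    delta_df = v$delta_df %||% NA_real_, p = v$p %||% NA_real_,
    stringsAsFactors = FALSE)))
  aic <- vapply(visited, function(v) v$fit$AIC, 0)
  bic <- vapply(visited, function(v) v$fit$BIC, 0)
  best <- order(round(aic, 10), round(bic, 10))[1]
  list(model = visited[[best]]$model, fit = visited[[best]]$fit, steps = steps)
}

#' Rank enumerated candidate models by information criteria
#'
#' Fast scorer for [enumerate_near_saturated()] candidates (recursive
#' models without residual covariances). Uses the per-equation
#' factorization of the ML discrepancy -- each equation's contribution
#' depends only on (effect, parent set), which is memoised across
#' candidates -- and is exactly equivalent to fitting each candidate with
#' [fit_path()].
#'
#' @param models list of [path_model()] candidates from the enumerator.
#' @param data data.frame, or `NULL` when `sample_cov`/`N` given.
#' @param sample_cov,N optional sample covariance and size.
#' @param rescale passed through as in [fit_path()].
#' @return A `data.frame` with one row per candidate: `T`, `df`, `AIC`,
#'   `BIC`, ordered as `models`.
#' @export
rank_candidates <- function(models, data = NULL, sample_cov = NULL, N = NULL,
                            rescale = NULL) {
  stopifnot(length(models) > 0)
  vars <- models[[1]]$variables
  if (is.null(sample_cov)) {
    d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
    N <- nrow(d)
    if (!is.null(rescale))
      for (v in names(rescale)) d[[v]] <- d[[v]] * rescale[[v]]
    S <- stats::cov(d)
  } else {
    S <- as.matrix(sample_cov)[vars, vars]
  }
  cache <- new.env(parent = emptyenv())
  log_resid <- function(v, pa) {
    key <- paste(v, paste(sort(pa), collapse = ","), sep = "|")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    val <- if (length(pa) == 0) log(S[v, v]) else {
      b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
      log(S[v, v] - drop(S[v, pa, drop = FALSE] %*% b))
    }
    assign(key, val, envir = cache)
    val
  }
  rows <- lapply(models, function(m) {
    if (nrow(m$residual_cov))
      stop("rank_candidates requires models without residual covariances",
           call. = FALSE)
    ord <- attr(m, "ordering") %||% m$order
    Fm <- 0
    for (j in seq_along(ord)) {
      v <- ord[j]
      if (v %in% m$exogenous) next
      pred <- ord[seq_len(j - 1)]
      pa <- parents_of(m, v)
      if (length(pa) == length(pred)) next
      Fm <- Fm + log_resid(v, pa) - log_resid(v, pred)
    }
    T <- max((N - 1) * Fm, 0)
    data.frame(T = T, df = m$df, AIC = T + 2 * m$t, BIC = T + m$t * log(N))
  })
  do.call(rbind, rows)
}
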