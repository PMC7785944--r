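#' Relative fitness
#'
#' Divides each plant's absolute fitness by the population mean, so the
#' returned vector has mean 1 over the non-missing entries.
#'
#' @param values absolute fitness values (>= 2 non-missing, positive mean).
#' @return Numeric vector of relative fitness `w` (NAs preserved).
#' @export
relativize_fitness <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need >= 2 non-missing fitness values", call. = FALSE)
  m <- mean(v)
  if (m <= 0) stop("mean fitness must be positive", call. = FALSE)
  values / m
}

#' Standardize traits to zero mean and unit variance
#'
#' Standardizes each trait column to mean 0 and sample SD 1 (`n - 1`
#' denominator), within population when a grouping is supplied -- traits are
#' never pooled across populations before standardization.
#'
#' @param data a data.frame of plants.
#' @param traits character vector of trait column names.
#' @param population optional name of the population column; when given,
#'   standardization is done separately within each population.
#' @return `data` with the trait columns replaced by their standardized
#'   values.
#' @export
standardize_traits <- function(data, traits, population = NULL) {
  stopifnot(is.data.frame(data), all(traits %in% names(data)))
  zs <- function(x) {
    v <- x[!is.na(x)]
    if (length(unique(v)) < 2) stop("constant trait column", call. = FALSE)
    (x - mean(v)) / stats::sd(v)
  }
  groups <- if (is.null(population)) list(seq_len(nrow(data)))
            else split(seq_len(nrow(data)), data[[population]])
  for (tr in traits)
    for (idx in groups)
      data[idx, tr] <- zs(data[[tr]][idx])
  data
}

#' Opportunity for selection
#'
#' The sample variance of relative fitness: the upper bound on the strength
#' of selection imposed by fitness variability.
#'
#' @param w relative fitness (from [relativize_fitness()]).
#' @return A single number, `I`.
#' @export
selection_opportunity <- function(w) {
  w <- w[!is.na(w)]
  if (length(w) < 2) stop("need >= 2 values", call. = FALSE)
  stats::var(w)
}

#' Standardized selection differentials
#'
#' For each trait, `S' = cov(z, w)`, the sample covariance between the
#' standardized trait and relative fitness: total (direct plus indirect)
#' selection on the trait. The p-value comes from the univariate regression
#' of `w` on the trait (two-sided t).
#'
#' @param z data.frame or matrix of standardized traits.
#' @param w relative fitness, same length as `nrow(z)`.
#' @return A `data.frame` with one row per trait: `trait`, `S`, `se`, `p`,
#'   `n` (pairwise-complete cases).
#' @export
selection_differentials <- function(z, w) {
  z <- as.data.frame(z)
  stopifnot(nrow(z) == length(w))
  rows <- lapply(names(z), function(tr) {
    ok <- stats::complete.cases(z[[tr]], w)
    if (sum(ok) < 3) stop("fewer than 3 complete cases for trait ", tr,
                          call. = FALSE)
    zj <- z[[tr]][ok]; wj <- w[ok]
    S <- stats::cov(zj, wj)
    if (stats::var(wj) == 0) {
      # constant fitness: no selection, no sampling variance to test
      se <- 0; p <- NA_real_
    } else {
      # degenerate exact fits (zero residual) are legitimate here
      fit <- suppressWarnings(summary(stats::lm(wj ~ zj))$coefficients)
      se <- fit[2, 2]; p <- fit[2, 4]
    }
    data.frame(trait = tr, S = S, se = se, p = p, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standardized selection gradients
#'
#' Ordinary least squares of relative fitness on all standardized traits
#' jointly (with intercept). The partial-regression coefficients are the
#' standardized linear selection gradients `beta'`: the force and direction
#' of selection acting directly on each trait, holding the others constant.
#'
#' @inheritParams selection_differentials
#' @return A `data.frame` with one row per trait: `trait`, `beta`, `se`,
#'   `p`, plus the listwise-complete `n` as an attribute.
#' @export
selection_gradients <- function(z, w) {
  z <- as.data.frame(z)
  stopifnot(nrow(z) == length(w))
  ok <- stats::complete.cases(z, w)
  n <- sum(ok)
  k <- ncol(z)
  if (n <= k + 1) stop("need more complete cases than traits + 1", call. = FALSE)
  X <- as.matrix(z[ok, , drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < k + 1) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1, k + 1)] - 1
    stop("rank-deficient design; offending trait(s): ",
         paste(colnames(X)[drop_idx], collapse = ", "), call. = FALSE)
  }
  fit <- summary(stats::lm(w[ok] ~ X))$coefficients
  out <- data.frame(trait = colnames(z), beta = fit[-1, 1], se = fit[-1, 2],
                    p = fit[-1, 4], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- n
  out
}

#' Phenotypic selection analysis over populations and fitness components
#'
#' For every population and fitness component: relativizes absolute fitness
#' within the population, standardizes traits within the population, and
#' computes the opportunity for selection `I`, standardized selection
#' differentials `S'` and standardized selection gradients `beta'` with
#' classical SEs and p-values. Complete cases are determined per analysis,
#' so sample sizes vary across traits and components.
#'
#' @param data plant-level data.frame holding trait columns and absolute
#'   fitness columns.
#' @param traits character vector of trait column names.
#' @param components character vector of absolute fitness column names.
#' @param population name of the population column, or `NULL` for a single
#'   population.
#' @return An object of class `"selection_fit"` with `print()`,
#'   `summary()` and `coef()` methods.
#' @examples
#' tab <- simulate_population(population_preset("barra-like"), 200, seed = 1)
#' fit <- selection_analysis(tab,
#'   traits = c("corolla_color", "flowers_total"),
#'   components = "seeds_per_plant")
#' coef(fit)
#' @export
selection_analysis <- function(data, traits, components, population = NULL) {
  stopifnot(is.data.frame(data), all(traits %in% names(data)),
            all(components %in% names(data)))
  pops <- if (is.null(population)) list(all = seq_len(nrow(data)))
          else split(seq_len(nrow(data)), data[[population]])

  res <- list()
  for (pop in names(pops)) {
    idx <- pops[[pop]]
    sub <- data[idx, , drop = FALSE]
    zsub <- standardize_traits(sub, traits)
    for (comp in components) {
      w <- relativize_fitness(sub[[comp]])
      S <- selection_differentials(zsub[traits], w)
      B <- selection_gradients(zsub[traits], w)
      res[[paste(pop, comp, sep = ".")]] <- list(
        population = pop, component = comp,
        opportunity = selection_opportunity(w),
        n = sum(!is.na(w)),
        differentials = S, gradients = B)
    }
  }
  structure(list(results = res, traits = traits, components = components,
                 populations = names(pops)), class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("Phenotypic selection analysis\n")
  cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  cat("  fitness components:", paste(x$components, collapse = ", "), "\n")
  cat("  traits:", paste(x$traits, collapse = ", "), "\n\n")
  for (r in x$results)
    cat(sprintf("  %s / %s: I = %.3f (n = %d)\n", r$population, r$component,
                r$opportunity, r$n))
  invisible(x)
}

#' @export
summary.selection_fit <- function(object, ...) {
  tab <- coef(object)
  structure(list(table = tab, fit = object), class = "summary.selection_fit")
}

#' @export
print.summary.selection_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  tab <- x$table
  tab$S <- sprintf("%6.3f%s", tab$S, sig_stars(tab$S_p))
  tab$beta <- sprintf("%6.3f%s (%.3f)", tab$beta, sig_stars(tab$beta_p), tab$beta_se)
  print(tab[, c("population", "component", "trait", "S", "beta")],
        row.names = FALSE)
  cat("---\nstars: * p<0.05, ** p<0.01, *** p<0.001\n")
  invisible(x)
}

sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
coef.selection_fit <- function(object, ...) {
  rows <- lapply(object$results, function(r) {
    data.frame(population = r$population, component = r$component,
               trait = r$differentials$trait,
               S = r$differentials$S, S_p = r$differentials$p,
               S_n = r$differentials$n,
               beta = r$gradients$beta, beta_se = r$gradients$se,
               beta_p = r$gradients$p,
               opportunity = r$opportunity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a selection-coefficient table as TSV
#'
#' One row per population x trait; per fitness component, columns `S'` and
#' `beta' (SE)` with significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param fit a [selection_analysis()] result.
#' @param path output TSV path.
#' @return The written data.frame, invisibly.
#' @export
write_selection_table <- function(fit, path) {
  stopifnot(inherits(fit, "selection_fit"))
  long <- coef(fit)
  out <- NULL
  for (pop in unique(long$population)) {
    sub <- long[long$population == pop, ]
    wide <- data.frame(population = pop, trait = unique(sub$trait),
                       stringsAsFactors = FALSE)
    for (comp in unique(sub$component)) {
      sc <- sub[sub$component == comp, ]
      i <- match(wide$trait, sc$trait)
      wide[[paste0(comp, "_S")]] <- sprintf("%.2f%s", sc$S[i], sig_stars(sc$S_p[i]))
      wide[[paste0(comp, "_beta")]] <-
        sprintf("%.2f%s (%.2f)", sc$beta[i], sig_stars(sc$beta_p[i]), sc$beta_se[i])
    }
    out <- rbind(out, wide)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
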