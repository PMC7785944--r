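#' Welch's two-sample t test, from raw samples or printed summaries
#'
#' Computes `t = (m1 - m2) / sqrt(SE1^2 + SE2^2)` with Welch-Satterthwaite
#' degrees of freedom `(SE1^2 + SE2^2)^2 / (SE1^4/(n1-1) + SE2^4/(n2-1))`
#' and a two-sided p-value. Inputs can be raw numeric vectors or summary
#' descriptions (named vector/list with `mean`, `n`, and either `se` or
#' `sd`), so statistics quoted from published summaries are reproducible
#' without the raw data.
#'
#' @param x,y numeric vectors, or summaries: `c(mean =, sd =, n =)` or
#'   `c(mean =, se =, n =)`.
#' @return A list with `t`, `df`, `p`, and the per-group means and SEs.
#' @examples
#' welch_t(c(mean = 21711.33, se = 620.28, n = 30),
#'         c(mean = 18192.3, se = 561.4, n = 42))
#' @export
welch_t <- function(x, y) {
  sx <- as_summary(x); sy <- as_summary(y)
  if (sx$n < 2 || sy$n < 2) stop("each group needs n >= 2", call. = FALSE)
  pooled <- sx$se^2 + sy$se^2
  if (pooled <= 0) stop("zero pooled standard error", call. = FALSE)
  t <- (sx$mean - sy$mean) / sqrt(pooled)
  df <- pooled^2 / (sx$se^4 / (sx$n - 1) + sy$se^4 / (sy$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean = c(sx$mean, sy$mean), se = c(sx$se, sy$se), n = c(sx$n, sy$n))
}

as_summary <- function(x) {
  if (is.numeric(x) && is.null(names(x)) && length(x) > 1) {
    x <- x[!is.na(x)]
    return(list(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
                n = length(x)))
  }
  x <- as.list(x)
  if (is.null(x$mean) || is.null(x$n) || (is.null(x$se) && is.null(x$sd)))
    stop("summary input needs 'mean', 'n', and 'se' or 'sd'", call. = FALSE)
  se <- if (!is.null(x$se)) x$se else x$sd / sqrt(x$n)
  if (se <= 0) stop("dispersion must be positive", call. = FALSE)
  list(mean = x$mean, se = se, n = x$n)
}

#' Brown-Forsythe / Levene test for homogeneity of variances
#'
#' One-way ANOVA F test on absolute deviations from the group centre:
#' the median (Brown-Forsythe, robust, the default) or the mean (classical
#' Levene).
#'
#' @param groups a list of numeric vectors (>= 2 groups, each with >= 2
#'   values), or a single numeric vector with `g` giving group labels.
#' @param center `"median"` or `"mean"`.
#' @param g optional grouping factor when `groups` is a vector.
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
brown_forsythe_test <- function(groups, center = c("median", "mean"), g = NULL) {
  center <- match.arg(center)
  if (!is.null(g)) groups <- split(groups, g)
  groups <- lapply(groups, function(x) x[!is.na(x)])
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("every group needs at least two values", call. = FALSE)
  centre_fun <- if (center == "median") stats::median else mean
  dev <- lapply(groups, function(x) abs(x - centre_fun(x)))
  d <- unlist(dev)
  lab <- factor(rep(seq_along(dev), lengths(dev)))
  fit <- stats::anova(stats::lm(d ~ lab))
  list(F = fit[["F value"]][1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit[["Pr(>F)"]][1])
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic `W` = sum of the (midrank-tied) ranks of `x` in the
#' pooled sample. For combined sample sizes up to `exact_limit` the
#' two-sided p-value is computed by exhaustive enumeration of all
#' assignments of the pooled ranks to the two groups (valid under ties);
#' otherwise the normal approximation with the tie-corrected variance is
#' used.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_limit largest combined n for which exact enumeration is
#'   used; default 12.
#' @return A list with `W`, `p`, and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty", call. = FALSE)
  n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])

  if (n <= exact_limit) {
    splits <- utils::combn(n, nx)
    ws <- colSums(matrix(r[splits], nrow = nx))
    EW <- nx * (n + 1) / 2
    # two-sided: double the smaller tail, capped at 1
    p <- min(1, 2 * min(mean(ws <= W + 1e-9), mean(ws >= W - 1e-9)))
    return(list(W = W, p = p, method = "exact enumeration"))
  }
  EW <- nx * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  VW <- nx * ny / 12 * ((n + 1) - tie_term)
  z <- (W - EW) / sqrt(VW)
  list(W = W, p = 2 * stats::pnorm(-abs(z)),
       method = "normal approximation with tie correction")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs, both
#'   non-constant).
#' @return A list with `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input", call. = FALSE)
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, df = n - 2, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Coefficient of variation, in percent
#'
#' @param mean,sd trait mean (non-zero) and SD (>= 0).
#' @return `100 * sd / |mean|`.
#' @examples
#' cv_percent(272.69, 251.55)  # seeds per plant
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean == 0)) stop("zero mean", call. = FALSE)
  if (any(sd < 0)) stop("negative sd", call. = FALSE)
  100 * sd / abs(mean)
}
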