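#' Specify a recursive linear path model
#'
#' Defines a path-analysis (structural equation) model over observed
#' variables: a set of exogenous variables, directed edges (cause to
#' effect), and optional residual covariances between endogenous variables
#' -- the double-headed arrows representing unresolved (non-causal)
#' associations. Directed edges must form a DAG. The model is covariance-
#' structure only: means are saturated and ignored.
#'
#' The free-parameter count is `t` = #edges + #endogenous residual
#' variances + #residual covariances + #exogenous variances +
#' #exogenous covariances, and the degrees of freedom are
#' `df = p(p+1)/2 - t` where `p` is the number of variables.
#'
#' @param variables character vector of variable names (unique).
#' @param exogenous subset of `variables` with no incoming edges.
#' @param edges directed edges: a 2-column matrix/data.frame `(from, to)` or
#'   a character vector of `"from->to"` strings.
#' @param residual_cov optional residual covariances between endogenous
#'   variables: 2-column matrix/data.frame or `"a~~b"` strings.
#' @return An object of class `"path_model"`.
#' @examples
#' m <- path_model(c("x", "m", "y"), exogenous = "x",
#'                 edges = c("x->m", "m->y"))
#' m$df
#' @export
path_model <- function(variables, exogenous, edges, residual_cov = NULL) {
  if (anyDuplicated(variables)) stop("duplicated variable names", call. = FALSE)
  if (!all(exogenous %in% variables))
    stop("exogenous names not among variables", call. = FALSE)
  E <- parse_pairs(edges, "->")
  R <- if (is.null(residual_cov) || NROW(residual_cov) == 0) {
    data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  } else {
    rc <- parse_pairs(residual_cov, "~~")
    names(rc) <- c("a", "b")
    rc
  }
  unknown <- setdiff(c(E$from, E$to, R$a, R$b), variables)
  if (length(unknown))
    stop("unknown variable(s) in edges: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(paste(E$from, E$to)))
    stop("duplicate edge", call. = FALSE)
  if (any(E$to %in% exogenous))
    stop("exogenous variable(s) cannot receive edges: ",
         paste(intersect(E$to, exogenous), collapse = ", "), call. = FALSE)
  endo <- setdiff(variables, exogenous)
  if (nrow(R)) {
    if (any(R$a == R$b)) stop("residual covariance of a variable with itself",
                              call. = FALSE)
    if (!all(c(R$a, R$b) %in% endo))
      stop("residual covariances are defined between endogenous variables",
           call. = FALSE)
    key <- apply(R, 1, function(r) paste(sort(r), collapse = "~~"))
    if (anyDuplicated(key)) stop("duplicate residual covariance", call. = FALSE)
  }

  ord <- topological_order(variables, E)
  if (is.null(ord))
    stop("directed edges contain a cycle", call. = FALSE)

  p <- length(variables)
  ne <- length(exogenous)
  t <- nrow(E) + length(endo) + nrow(R) + ne + choose(ne, 2)
  df <- p * (p + 1) / 2 - t
  if (df < 0) stop("negative degrees of freedom (over-parameterized model)",
                   call. = FALSE)

  structure(list(variables = variables, exogenous = exogenous,
                 endogenous = endo, edges = E, residual_cov = R,
                 order = ord, t = t, df = df, p = p),
            class = "path_model")
}

parse_pairs <- function(x, sep) {
  if (is.character(x)) {
    parts <- strsplit(x, sep, fixed = TRUE)
    if (any(lengths(parts) != 2))
      stop("malformed specification: ", paste(x[lengths(parts) != 2],
                                              collapse = ", "), call. = FALSE)
    out <- data.frame(from = trimws(vapply(parts, `[`, "", 1)),
                      to = trimws(vapply(parts, `[`, "", 2)),
                      stringsAsFactors = FALSE)
  } else {
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (ncol(x) != 2) stop("edge table must have two columns", call. = FALSE)
    out <- data.frame(from = as.character(x[[1]]), to = as.character(x[[2]]),
                      stringsAsFactors = FALSE)
  }
  out
}

# Kahn topological sort; NULL if cyclic.
topological_order <- function(variables, edges) {
  indeg <- stats::setNames(integer(length(variables)), variables)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  queue <- names(indeg)[indeg == 0]
  ord <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    out <- edges$to[edges$from == v]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) == length(variables)) ord else NULL
}

parents_of <- function(model, v) model$edges$from[model$edges$to == v]

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("Path model: %d variables, %d edges, %d residual covariance(s)\n",
              x$p, nrow(x$edges), nrow(x$residual_cov)))
  cat("  exogenous:", paste(x$exogenous, collapse = ", "), "\n")
  if (nrow(x$edges))
    cat("  edges:", paste(paste0(x$edges$from, "->", x$edges$to),
                          collapse = ", "), "\n")
  if (nrow(x$residual_cov))
    cat("  residual covariances:",
        paste(paste0(x$residual_cov$a, "~~", x$residual_cov$b), collapse = ", "),
        "\n")
  cat(sprintf("  free parameters t = %d, df = %d\n", x$t, x$df))
  invisible(x)
}

#' Model-implied covariance matrix
#'
#' For the recursive linear system `y = B y + e`, the implied covariance is
#' `Sigma = (I - B)^-1 Psi (I - B)^-T`, with `B` holding the path
#' coefficients and `Psi` the residual/exogenous (co)variances.
#'
#' @param model a [path_model()].
#' @param coef named path coefficients, names `"from->to"` (or in edge-table
#'   order).
#' @param var named variances: residual variances of endogenous variables
#'   and variances of exogenous variables.
#' @param cov optional named covariances, names `"a~~b"`: residual
#'   covariances and exogenous covariances.
#' @return The implied covariance matrix (symmetric), with dimnames.
#' @export
implied_covariance <- function(model, coef, var, cov = NULL) {
  stopifnot(inherits(model, "path_model"))
  vars <- model$variables
  p <- model$p
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  ekey <- paste0(model$edges$from, "->", model$edges$to)
  if (!is.null(names(coef))) {
    missing <- setdiff(ekey, names(coef))
    if (length(missing)) stop("missing coefficients: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    coef <- coef[ekey]
  } else stopifnot(length(coef) == nrow(model$edges))
  for (i in seq_len(nrow(model$edges)))
    B[model$edges$to[i], model$edges$from[i]] <- coef[i]

  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  diag(Psi) <- var[vars]
  if (any(is.na(diag(Psi)))) stop("missing variances", call. = FALSE)
  add_cov <- function(a, b, value) {
    Psi[a, b] <<- value; Psi[b, a] <<- value
  }
  if (!is.null(cov) && length(cov)) {
    for (nm in names(cov)) {
      ab <- strsplit(nm, "~~", fixed = TRUE)[[1]]
      add_cov(ab[1], ab[2], cov[[nm]])
    }
  }
  IB <- diag(p) - B
  # (I - B) is unit lower-triangular under the topological order: invertible
  Sigma <- solve(IB, t(solve(IB, t(Psi))))
  (Sigma + t(Sigma)) / 2
}

#' Enumerate near-saturated recursive candidate models
#'
#' Generates, over all topological orderings consistent with the exogenous
#' set, the saturated recursive model and every model obtained by removing
#' edges until the degrees of freedom fall in `df_set`, then deduplicates
#' candidates that are covariance-equivalent (different orderings of
#' unconnected variables can imply the same covariance structure).
#' Equivalence is detected numerically: two candidates are merged when
#' their fitted implied covariances coincide on a fixed set of random
#' probe covariance matrices.
#'
#' @param variables,exogenous as in [path_model()] (at most 8 variables).
#' @param df_set target degrees of freedom, e.g. `1:2`; each removed edge
#'   adds one df.
#' @param n_probe number of random probe matrices used for the
#'   equivalence signature.
#' @return A list of [path_model()] objects, one per equivalence class,
#'   each carrying attributes `ordering`, `removed` (the deleted edges) and
#'   `class_size` (how many raw candidates mapped to this class).
#' @export
enumerate_near_saturated <- function(variables, exogenous, df_set = 1:2,
                                     n_probe = 2) {
  p <- length(variables)
  if (p > 8) stop("enumeration is guarded to at most 8 variables", call. = FALSE)
  endo <- setdiff(variables, exogenous)
  n_sat_edges <- choose(p, 2) - choose(length(exogenous), 2)
  if (any(df_set > n_sat_edges))
    stop("df_set exceeds the saturated edge count", call. = FALSE)

  probes <- with_seed(760411, lapply(seq_len(n_probe), function(i) {
    A <- matrix(stats::rnorm(p * p), p)
    S <- crossprod(A) / p + diag(p)
    dimnames(S) <- list(variables, variables)
    S
  }))

  perms <- permutations_of(endo)
  classes <- new.env(parent = emptyenv())
  order_keys <- character(0)

  for (perm in perms) {
    ord <- c(exogenous, perm)
    sat <- saturated_edges(ord, exogenous)
    ids <- seq_len(nrow(sat))
    removal_sets <- list()
    for (k in unique(sort(df_set))) {
      removal_sets <- c(removal_sets,
        if (k == 0) list(integer(0)) else
          utils::combn(ids, k, simplify = FALSE))
    }
    for (rem in removal_sets) {
      keep <- sat[setdiff(ids, rem), , drop = FALSE]
      sig <- candidate_signature(ord, exogenous, keep, probes)
      hit <- get0(sig, envir = classes, inherits = FALSE)
      if (is.null(hit)) {
        m <- path_model(ord, exogenous,
                        if (nrow(keep)) paste0(keep$from, "->", keep$to)
                        else character(0))
        attr(m, "ordering") <- ord
        attr(m, "removed") <- sat[rem, , drop = FALSE]
        attr(m, "class_size") <- 1L
        assign(sig, m, envir = classes)
        order_keys <- c(order_keys, sig)
      } else {
        attr(hit, "class_size") <- attr(hit, "class_size") + 1L
        assign(sig, hit, envir = classes)
      }
    }
  }
  lapply(order_keys, get, envir = classes)
}

saturated_edges <- function(ord, exogenous) {
  from <- character(0); to <- character(0)
  p <- length(ord)
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    if (ord[i] %in% exogenous && ord[j] %in% exogenous) next
    from <- c(from, ord[i]); to <- c(to, ord[j])
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1]] <- c(x[i], rest)
  out
}

# Numeric covariance-equivalence signature: the fitted implied covariance
# of a recursive model is a deterministic function of its equivalence class,
# for any probe covariance.
candidate_signature <- function(ord, exogenous, edges, probes) {
  canon <- sort(ord)
  parts <- vapply(probes, function(S) {
    fit <- recursive_ols_cov(ord, exogenous, edges, S)
    M <- fit$implied[canon, canon]
    paste(sprintf("%.6f", M[upper.tri(M, diag = TRUE)]), collapse = ",")
  }, "")
  paste(parts, collapse = "|")
}

# Per-equation OLS on a covariance matrix: the exact ML solution for
# recursive models without residual covariances.
recursive_ols_cov <- function(ord, exogenous, edges, S) {
  p <- length(ord)
  B <- matrix(0, p, p, dimnames = list(ord, ord))
  psi <- stats::setNames(numeric(p), ord)
  for (v in ord) {
    if (v %in% exogenous) { psi[v] <- S[v, v]; next }
    pa <- edges$from[edges$to == v]
    if (length(pa) == 0) { psi[v] <- S[v, v]; next }
    b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
    B[v, pa] <- b
    psi[v] <- S[v, v] - drop(S[v, pa, drop = FALSE] %*% b)
  }
  Psi <- diag(psi, p)
  dimnames(Psi) <- list(ord, ord)
  if (length(exogenous) > 1)
    Psi[exogenous, exogenous] <- S[exogenous, exogenous]
  IB <- diag(p) - B
  Sigma <- solve(IB, t(solve(IB, t(Psi))))
  list(B = B, psi = psi, Psi = Psi, implied = (Sigma + t(Sigma)) / 2)
}

#' d-separation in a DAG
#'
#' Tests whether `x` and `y` are d-separated given the conditioning set
#' `given` in the directed acyclic graph of a [path_model()] (residual
#' covariances are ignored). Under the model's Gaussian assumptions,
#' d-separation corresponds to a vanishing partial correlation.
#'
#' @param model a [path_model()].
#' @param x,y variable names.
#' @param given character vector of conditioning variables (possibly empty).
#' @return `TRUE` if d-separated.
#' @export
d_separated <- function(model, x, y, given = character(0)) {
  stopifnot(inherits(model, "path_model"))
  vars <- model$variables
  stopifnot(x %in% vars, y %in% vars, all(given %in% vars))
  E <- model$edges
  # ancestral set of {x, y} union given
  anc <- unique(c(x, y, given))
  repeat {
    more <- unique(E$from[E$to %in% anc])
    if (all(more %in% anc)) break
    anc <- unique(c(anc, more))
  }
  Ea <- E[E$from %in% anc & E$to %in% anc, , drop = FALSE]
  # moralize: undirected adjacency + marry parents of common children
  adj <- matrix(FALSE, length(anc), length(anc), dimnames = list(anc, anc))
  for (i in seq_len(nrow(Ea))) {
    adj[Ea$from[i], Ea$to[i]] <- TRUE; adj[Ea$to[i], Ea$from[i]] <- TRUE
  }
  for (v in anc) {
    pa <- Ea$from[Ea$to == v]
    if (length(pa) > 1)
      for (a in pa) for (b in pa) if (a != b) adj[a, b] <- TRUE
  }
  keep <- setdiff(anc, given)
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  adj <- adj[keep, keep, drop = FALSE]
  # connectivity search from x
  seen <- x
  frontier <- x
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(v) keep[adj[v, ]])))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  !(y %in% seen)
}
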