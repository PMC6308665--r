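# coerce the (values, groups) / named-list input shapes to a named list
as_group_list <- function(values, groups = NULL, min_n = 2L) {
  gl <- if (is.list(values) && is.null(groups)) {
    values
  } else {
    if (is.null(groups)) stop("supply either a named list or values + groups",
                              call. = FALSE)
    split(as.numeric(values), groups)
  }
  gl <- lapply(gl, function(v) as.numeric(v[!is.na(v)]))
  if (length(gl) < 2) stop("at least two groups are required", call. = FALSE)
  ns <- lengths(gl)
  if (any(ns < min_n))
    stop("each group needs at least ", min_n, " observations", call. = FALSE)
  if (is.null(names(gl)) || any(!nzchar(names(gl))))
    names(gl) <- paste0("group", seq_along(gl))
  gl
}

#' Levene's test for homogeneity of variance
#'
#' Classic Levene test on absolute deviations from the group means (not the
#' Brown-Forsythe median variant): the one-way ANOVA F statistic of
#' \eqn{z_{ij} = |x_{ij} - \bar{x}_i|} with `k - 1` and `N - k` degrees of
#' freedom. Location shifts of any group leave the statistic unchanged. Used
#' to decide whether sensor comparisons may assume equal variances before
#' moving to heteroscedastic procedures.
#'
#' @param values Either a named list of numeric vectors (one per group) or a
#'   numeric vector accompanied by `groups`.
#' @param groups Optional grouping factor/vector parallel to `values`.
#' @return An object of class `htest`.
#' @export
levene_test <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  z <- lapply(gl, function(v) abs(v - mean(v)))
  k <- length(z)
  ns <- lengths(z)
  N <- sum(ns)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  ss_between <- sum(ns * (zbar_i - zbar)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_i[i])^2),
                          numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ss_within == 0) {
    stat <- if (ss_between == 0) 0 else Inf
  } else {
    stat <- (ss_between / df1) / (ss_within / df2)
  }
  p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
  structure(list(statistic = c(F = stat),
                 parameter = c(df1 = df1, df2 = df2),
                 p.value = p,
                 method = "Levene's test for homogeneity of variance (mean-centered)",
                 data.name = deparse(substitute(values))),
            class = "htest")
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Welch's F* statistic for comparing k group means without assuming equal
#' variances: with weights \eqn{w_i = n_i / s_i^2},
#' \eqn{\bar{x}_w = \sum w_i \bar{x}_i / \sum w_i},
#' \deqn{F^* = \frac{\sum_i w_i(\bar{x}_i - \bar{x}_w)^2 / (k-1)}
#'                  {1 + \frac{2(k-2)}{k^2-1}\Lambda}, \quad
#'       \Lambda = \sum_i \frac{(1 - w_i/\sum w)^2}{n_i - 1},}
#' referred to an F distribution with `k - 1` and
#' \eqn{(k^2 - 1) / (3\Lambda)} degrees of freedom. With two groups it
#' reduces to the squared Welch t statistic.
#'
#' @inheritParams levene_test
#' @return An object of class `htest`.
#' @export
welch_anova <- function(values, groups = NULL) {
  gl <- as_group_list(values, groups)
  k <- length(gl)
  ns <- lengths(gl)
  m <- vapply(gl, mean, numeric(1))
  v <- vapply(gl, stats::var, numeric(1))
  if (any(v == 0))
    stop("numeric guard: zero variance in a group", call. = FALSE)
  w <- ns / v
  sw <- sum(w)
  mw <- sum(w * m) / sw
  lambda <- sum((1 - w / sw)^2 / (ns - 1))
  stat <- sum(w * (m - mw)^2) / (k - 1) /
    (1 + 2 * (k - 2) / (k^2 - 1) * lambda)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  p <- stats::pf(stat, df1, df2, lower.tail = FALSE)
  structure(list(statistic = c(F = stat),
                 parameter = c(df1 = df1, df2 = df2),
                 p.value = p,
                 method = "Welch heteroscedastic one-way ANOVA",
                 data.name = deparse(substitute(values))),
            class = "htest")
}

#' Games-Howell pairwise post hoc comparisons
#'
#' All pairwise comparisons of group means under unequal variances and group
#' sizes. For each pair (i, j):
#' \deqn{t = \frac{|\bar{x}_i - \bar{x}_j|}{\sqrt{s_i^2/n_i + s_j^2/n_j}},}
#' with Welch-Satterthwaite degrees of freedom, and the p-value from the
#' studentized-range distribution with `k` groups evaluated at
#' \eqn{q = t\sqrt{2}} — the standard Games-Howell formulation, which keeps
#' the familywise error across all k(k-1)/2 comparisons. The reported `t` is
#' the absolute value.
#'
#' @inheritParams levene_test
#' @param conf.level Significance threshold used for the `significant` flag
#'   (default flags p < 0.05).
#' @return A data frame of class `games_howell` with one row per pair:
#'   `group1`, `group2`, `diff` (mean difference), `t`, `df`, `p`,
#'   `significant`.
#' @export
games_howell <- function(values, groups = NULL, conf.level = 0.95) {
  gl <- as_group_list(values, groups)
  k <- length(gl)
  ns <- lengths(gl)
  m <- vapply(gl, mean, numeric(1))
  v <- vapply(gl, stats::var, numeric(1))
  if (any(v == 0))
    stop("numeric guard: zero variance in a group", call. = FALSE)
  pairs <- utils::combn(k, 2)
  res <- vapply(seq_len(ncol(pairs)), function(col) {
    ij <- pairs[, col]
    i <- ij[1]; j <- ij[2]
    se2 <- v[i] / ns[i] + v[j] / ns[j]
    tval <- abs(m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / ns[i])^2 / (ns[i] - 1) +
                     (v[j] / ns[j])^2 / (ns[j] - 1))
    p <- stats::ptukey(tval * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    c(diff = m[i] - m[j], t = tval, df = df, p = p)
  }, c(diff = 0, t = 0, df = 0, p = 0))
  out <- data.frame(group1 = names(gl)[pairs[1, ]],
                    group2 = names(gl)[pairs[2, ]],
                    diff = res["diff", ], t = res["t", ], df = res["df", ],
                    p = res["p", ],
                    significant = res["p", ] < (1 - conf.level),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("games_howell", class(out))
  out
}

#' @export
print.games_howell <- function(x, digits = 4, ...) {
  cat("Games-Howell pairwise comparisons (studentized range, q = t*sqrt(2))\n")
  df <- as.data.frame(x)
  df$t <- round(df$t, 3)
  df$df <- round(df$df, 3)
  df$p <- signif(df$p, digits)
  df$significant <- ifelse(df$significant, "*", "")
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Summarise the distribution of signed size-estimation errors
#'
#' Signed errors `estimates - truth` summarised by their mean (bias), sample
#' SD, moment skewness and a binned histogram — the shape used to judge
#' whether per-object measurement errors are approximately Gaussian so that
#' averaging over many objects can compensate for them.
#'
#' @param estimates Numeric vector of size estimates (mm).
#' @param truth True size (mm), a single value or a vector parallel to
#'   `estimates`.
#' @param breaks Passed to [graphics::hist()] (default `"Sturges"`).
#' @return An `error_distribution`: list with `errors`, `mean`, `sd`, `skew`,
#'   `n` and `histogram` (a `histogram` object).
#' @export
error_distribution <- function(estimates, truth, breaks = "Sturges") {
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0)
    stop("'estimates' must be non-empty", call. = FALSE)
  errors <- estimates - truth
  n <- length(errors)
  m2 <- mean((errors - mean(errors))^2)
  skew <- if (n >= 3 && m2 > 0)
    mean((errors - mean(errors))^3) / m2^1.5 else NA_real_
  structure(list(errors = errors,
                 mean = mean(errors),
                 sd = if (n >= 2) stats::sd(errors) else NA_real_,
                 skew = skew,
                 n = n,
                 histogram = graphics::hist(errors, breaks = breaks,
                                            plot = FALSE)),
            class = "error_distribution")
}

#' @export
print.error_distribution <- function(x, ...) {
  cat(sprintf(
    "error distribution: n=%d, bias=%.3f mm, sd=%.3f mm, skew=%.3f\n",
    x$n, x$mean, x$sd, x$skew))
  invisible(x)
}

#' @export
plot.error_distribution <- function(x, main = "Signed error distribution",
                                    xlab = "error (mm)", ...) {
  plot(x$histogram, main = main, xlab = xlab, ...)
  graphics::abline(v = x$mean, lty = 2)
  invisible(x)
}
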