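#' Cliff's delta with consistent-variance confidence interval
#'
#' The dominance statistic
#' \deqn{\delta = \Pr(X > Y) - \Pr(X < Y)}
#' estimated by the pairwise sign average
#' \eqn{\hat\delta = \sum_{ij} \mathrm{sign}(x_i - y_j) / (n_x n_y)} (ties
#' contribute 0). Its variance uses Cliff's consistent estimator built from
#' the row and column dominance means, floored at
#' \eqn{(1-\hat\delta^2)/(n_x n_y - 1)} in degenerate cases such as complete
#' separation; the confidence interval is the normal-approximation interval
#' truncated to \eqn{[-1, 1]} and the p-value a two-sided z-test of
#' \eqn{\delta = 0}.
#'
#' Orientation: `x` is the reference group; \eqn{\delta < 0} means `y` tends
#' to exceed `x`. To match tables that list the ASD group first and report
#' negative \eqn{\delta} when ASD values run higher, pass the ASD sample as
#' `y`.
#'
#' @param x,y Numeric samples (non-empty); `NA`s dropped.
#' @param conf.level Confidence level for the interval.
#' @return One-row tibble: `delta`, `se`, `ci_low`, `ci_high`, `p`,
#'   `n_x`, `n_y`.
#' @examples
#' cliffs_delta(c(1, 2, 3), c(4, 5, 6))   # complete separation: -1
#' @export
cliffs_delta <- function(x, y, conf.level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty", call. = FALSE)
  d_ij <- sign(outer(x, y, "-"))
  d <- mean(d_ij)
  di <- rowMeans(d_ij)
  dj <- colMeans(d_ij)
  if (nx > 1 && ny > 1) {
    s2 <- (ny^2 * sum((di - d)^2) + nx^2 * sum((dj - d)^2) -
             sum((d_ij - d)^2)) / (nx * ny * (nx - 1) * (ny - 1))
  } else s2 <- 0
  s2 <- max(s2, (1 - d^2) / (nx * ny - 1))
  se <- sqrt(s2)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  p <- if (se > 0) 2 * stats::pnorm(-abs(d) / se) else as.numeric(d == 0)
  tibble::tibble(delta = d, se = se,
                 ci_low = max(-1, d - z * se),
                 ci_high = min(1, d + z * se),
                 p = p, n_x = nx, n_y = ny)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks (ties shared), with the two-sided
#' p-value from the usual `t = rho * sqrt((n-2)/(1-rho^2))` approximation on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors; pairs with `NA` are dropped.
#' @return One-row tibble: `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Zou's confidence interval for the difference of two independent correlations
#'
#' Modified-asymptotic interval for \eqn{r_1 - r_2} from two independent
#' samples: each correlation gets its own Fisher-z interval
#' \eqn{\tanh(\mathrm{atanh}(r) \pm z_{\alpha/2}/\sqrt{n-3})}, and the bounds
#' are combined as
#' \deqn{L = r_1 - r_2 - \sqrt{(r_1-l_1)^2 + (u_2-r_2)^2},\quad
#'       U = r_1 - r_2 + \sqrt{(u_1-r_1)^2 + (r_2-l_2)^2}.}
#'
#' @param r1,r2 Sample correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @param conf.level Confidence level.
#' @return One-row tibble: `delta_r`, `ci_low`, `ci_high`.
#' @export
zou_diff <- function(r1, n1, r2, n2, conf.level = 0.95) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each group", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci_r <- function(r, n) tanh(atanh(r) + c(-1, 1) * z / sqrt(n - 3))
  b1 <- ci_r(r1, n1); b2 <- ci_r(r2, n2)
  d <- r1 - r2
  tibble::tibble(
    delta_r = d,
    ci_low = d - sqrt((r1 - b1[1])^2 + (b2[2] - r2)^2),
    ci_high = d + sqrt((b1[2] - r1)^2 + (r2 - b2[1])^2))
}

#' Pearson chi-square test for a 2x2 table, without continuity correction
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @return One-row tibble: `chi2`, `df`, `p`.
#' @export
chisq_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}

#' Intraclass correlation ICC(3,k): two-way mixed, consistency, average measures
#'
#' From the two-way ANOVA decomposition of an n-target by k-rater matrix,
#' \deqn{ICC(3,k) = \frac{MS_B - MS_E}{MS_B}}
#' where \eqn{MS_B} is the between-target mean square and \eqn{MS_E} the
#' residual after removing the rater effect. The confidence interval follows
#' from the F ratio \eqn{MS_B/MS_E} with (n-1) and (n-1)(k-1) degrees of
#' freedom. Used here to check that the four block thresholds of a session
#' are consistent enough to justify pooling them.
#'
#' @param mat Numeric matrix, n targets (rows) x k raters (columns), no
#'   missing cells, n >= 2 and k >= 2.
#' @param conf.level Confidence level.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `n`, `k`.
#' @export
icc_consistency <- function(mat, conf.level = 0.95) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 rows and 2 columns", call. = FALSE)
  if (anyNA(mat)) stop("matrix must have no missing cells", call. = FALSE)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((mat - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  icc <- (bms - ems) / bms
  alpha <- 1 - conf.level
  fobs <- bms / ems
  fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  tibble::tibble(icc = icc, ci_low = 1 - 1 / fl, ci_high = 1 - 1 / fu,
                 n = n, k = k)
}

#' Group comparison table of continuous variables by Cliff's delta
#'
#' Builds a descriptive/comparison table: per variable, group means and SDs,
#' Cliff's delta (reference group first argument; the comparison group listed
#' in `other` is `y`), its confidence interval and p-value. P-values are
#' reported unadjusted.
#'
#' @param data Data frame of participant-level records.
#' @param vars Character vector of numeric column names to compare.
#' @param group Name of the grouping column (two levels used).
#' @param ref Level of `group` treated as the reference sample `x` (e.g. the
#'   neurotypical group, so that a higher-scoring comparison group yields
#'   negative delta).
#' @param conf.level Confidence level for the delta intervals.
#' @return Tibble with one row per variable: ns, means, SDs, `delta`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
compare_groups <- function(data, vars, group = "diagnosis", ref = "NT",
                           conf.level = 0.95) {
  levels <- unique(data[[group]])
  if (!ref %in% levels) stop("reference level not found in ", group, call. = FALSE)
  other <- setdiff(levels, ref)
  if (length(other) != 1) stop("need exactly two group levels", call. = FALSE)
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]][data[[group]] == ref]
    y <- data[[v]][data[[group]] == other]
    cd <- cliffs_delta(x, y, conf.level)
    tibble::tibble(
      variable = v, n_ref = sum(!is.na(x)), n_other = sum(!is.na(y)),
      mean_ref = mean(x, na.rm = TRUE), sd_ref = stats::sd(x, na.rm = TRUE),
      mean_other = mean(y, na.rm = TRUE), sd_other = stats::sd(y, na.rm = TRUE),
      delta = cd$delta, ci_low = cd$ci_low, ci_high = cd$ci_high, p = cd$p)
  })
}
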