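#' Cumulative probability model for continuous outcomes
#'
#' Fits a proportional-odds (cumulative logit) regression treating every
#' distinct outcome value as an ordered category — the cumulative probability
#' model, a semi-parametric regression that generalises the
#' Wilcoxon-Mann-Whitney test to multiple predictors and is rank-invariant in
#' the outcome. The model is
#' \deqn{\Pr(Y \ge y_j \mid X) = \mathrm{logit}^{-1}(\alpha_j + X\beta)}
#' with one intercept per distinct outcome value (beyond the first) and
#' positive slopes meaning larger outcomes. Ties in the outcome share a
#' category.
#'
#' The likelihood is maximised by Newton-Raphson with analytic gradient and
#' Hessian and step-halving, from the empirical-margin start (the exact null
#' MLE); the problem is convex. Convergence: gradient max-norm below `tol`.
#'
#' @param formula Model formula, continuous (or ordinal) response on the left.
#' @param data Data frame; rows with missing values in used variables are an
#'   error (resolve missingness explicitly first).
#' @param tol Convergence tolerance on the gradient max-norm.
#' @param maxit Maximum Newton iterations.
#' @return A `vf_cpm` object: slope `coefficients`, `alpha` intercepts,
#'   `vcov` (slope block), `loglik`, `loglik_null`, `n`, `bic` (slope
#'   parameters only count towards the penalty), `converged`, and bookkeeping
#'   for methods. Use [tidy()][generics::tidy] and
#'   [glance()][generics::glance] to extract inference tables.
#' @examples
#' d <- data.frame(y = rexp(60), g = rep(c("a", "b"), 30))
#' fit <- cpm(y ~ g, d)
#' tidy(fit)
#' @export
cpm <- function(formula, data, tol = 1e-8, maxit = 50) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y)
  tt <- stats::terms(mf)
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  fit <- cpm_fit_core(y, X, tol = tol, maxit = maxit)
  fit$formula <- formula
  fit$terms <- tt
  fit$call <- match.call()
  fit
}

cpm_fit_core <- function(y, X, tol = 1e-8, maxit = 50) {
  n <- length(y)
  p <- ncol(X)
  levels <- sort(unique(y))
  J <- length(levels)
  if (J < 2) stop("outcome is constant; CPM undefined", call. = FALSE)
  if (n < p + 2) stop("need n >= number of slopes + 2", call. = FALSE)
  j <- match(y, levels)
  nj <- tabulate(j, J)
  loglik_null <- sum(nj * log(nj / n))
  # empirical exceedance probabilities S_j = P(Y >= level_j), j = 2..J
  S <- rev(cumsum(rev(nj)))[-1] / n
  a <- stats::qlogis(S)                       # start = exact null MLE
  if (p == 0) {
    return(new_vf_cpm(coefficients = stats::setNames(numeric(0), character(0)),
                      alpha = a, levels = levels, vcov = matrix(0, 0, 0),
                      loglik = loglik_null, loglik_null = loglik_null,
                      n = n, converged = TRUE, iter = 0L))
  }
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  b <- numeric(p)
  ju <- j - 1L                                 # alpha index for the >= y_j bound
  has_u <- j > 1L
  has_v <- j < J
  loglik_at <- function(a, b) {
    eta <- drop(Xc %*% b)
    Fu <- ifelse(has_u, stats::plogis(a[pmax(ju, 1L)] + eta), 1)
    Fv <- ifelse(has_v, stats::plogis(a[pmin(j, J - 1L)] + eta), 0)
    pr <- Fu - Fv
    if (any(pr <= 0)) return(-Inf)
    sum(log(pr))
  }
  ll <- loglik_at(a, b)
  converged <- FALSE
  iter <- 0L
  S <- NULL                                   # slope-block Schur complement
  acc_alpha <- function(vals, idx) {          # sum vals into length J-1 slots
    out <- numeric(J - 1)
    if (length(idx)) {
      rs <- rowsum(vals, idx)
      out[as.integer(rownames(rs))] <- rs
    }
    out
  }
  for (it in seq_len(maxit)) {
    iter <- it
    eta <- drop(Xc %*% b)
    u <- ifelse(has_u, a[pmax(ju, 1L)] + eta, Inf)
    v <- ifelse(has_v, a[pmin(j, J - 1L)] + eta, -Inf)
    Fu <- ifelse(has_u, stats::plogis(u), 1)
    Fv <- ifelse(has_v, stats::plogis(v), 0)
    fu <- ifelse(has_u, Fu * (1 - Fu), 0)
    fv <- ifelse(has_v, Fv * (1 - Fv), 0)
    fpu <- fu * (1 - 2 * Fu)                  # d f / d u (0 where u = Inf)
    fpv <- fv * (1 - 2 * Fv)
    pr <- Fu - Fv
    gu <- fu / pr
    gv <- -fv / pr
    huu <- fpu / pr - gu^2
    hvv <- -fpv / pr - gv^2
    huv <- -gu * gv
    grad_a <- acc_alpha(gu[has_u], ju[has_u]) + acc_alpha(gv[has_v], j[has_v])
    grad_b <- drop(crossprod(Xc, gu + gv))
    diag_a <- acc_alpha(huu[has_u], ju[has_u]) +
      acc_alpha(hvv[has_v], j[has_v])
    mid <- has_u & has_v
    off <- acc_alpha(huv[mid], ju[mid])[-(J - 1)]  # couples alpha_{j-1}, alpha_j
    # intercept block is tridiagonal: Schur-complement Newton step
    A <- if (J > 2) {
      Matrix::bandSparse(J - 1, J - 1, k = c(-1, 0, 1),
                         diagonals = list(off, diag_a, off), symmetric = FALSE)
    } else Matrix::Matrix(diag_a, 1, 1)
    wu <- ifelse(has_u, huu + ifelse(has_v, huv, 0), 0)
    wv <- ifelse(has_v, hvv + ifelse(has_u, huv, 0), 0)
    B <- matrix(0, J - 1, p)
    if (any(has_u)) {
      rs <- rowsum((wu * Xc)[has_u, , drop = FALSE], ju[has_u])
      B[as.integer(rownames(rs)), ] <- B[as.integer(rownames(rs)), ] + rs
    }
    if (any(has_v)) {
      rs <- rowsum((wv * Xc)[has_v, , drop = FALSE], j[has_v])
      B[as.integer(rownames(rs)), ] <- B[as.integer(rownames(rs)), ] + rs
    }
    wbb <- huu + 2 * huv + hvv
    C <- crossprod(Xc * wbb, Xc)
    sol <- tryCatch({
      AinvB <- as.matrix(Matrix::solve(A, B))
      Ainvg <- as.vector(Matrix::solve(A, grad_a))
      S <- C - crossprod(B, AinvB)
      step_b <- solve(S, grad_b - drop(crossprod(B, Ainvg)))
      step_a <- Ainvg - drop(AinvB %*% step_b)
      list(a = step_a, b = step_b)
    }, error = function(e) NULL)
    if (max(abs(c(grad_a, grad_b))) < tol) { converged <- TRUE; break }
    if (is.null(sol)) {                       # non-PD fallback: ridge both blocks
      lam_r <- 1e-6 * max(abs(diag_a), abs(diag(C)), 1)
      A2 <- A - lam_r * Matrix::Diagonal(J - 1)
      AinvB <- as.matrix(Matrix::solve(A2, B))
      Ainvg <- as.vector(Matrix::solve(A2, grad_a))
      S <- C - lam_r * diag(p) - crossprod(B, AinvB)
      step_b <- solve(S, grad_b - drop(crossprod(B, Ainvg)))
      sol <- list(a = Ainvg - drop(AinvB %*% step_b), b = step_b)
    }
    halve <- 0
    repeat {
      a_new <- a - sol$a
      b_new <- b - sol$b
      ll_new <- loglik_at(a_new, b_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      sol$a <- sol$a / 2; sol$b <- sol$b / 2
      halve <- halve + 1
      if (halve > 40) break
    }
    if (halve > 40) break
    a <- a_new; b <- b_new; ll <- ll_new
  }
  # slope covariance from the Schur complement at the optimum:
  # (-H)^{-1} restricted to the slope block equals (-S)^{-1}
  vcov_b <- if (is.null(S)) matrix(NA_real_, p, p) else
    tryCatch(solve(-S), error = function(e) {
      solve(-(S - 1e-8 * max(abs(diag(S)), 1) * diag(p)))
    })
  dimnames(vcov_b) <- list(colnames(X), colnames(X))
  new_vf_cpm(
    coefficients = stats::setNames(b, colnames(X)),
    alpha = a - drop(xbar %*% b),             # uncenter intercepts
    levels = levels, vcov = vcov_b,
    loglik = ll, loglik_null = loglik_null,
    n = n, converged = converged, iter = iter)
}

new_vf_cpm <- function(coefficients, alpha, levels, vcov, loglik,
                       loglik_null, n, converged, iter) {
  structure(list(
    coefficients = coefficients, alpha = alpha, levels = levels,
    vcov = vcov, loglik = loglik, loglik_null = loglik_null, n = n,
    df_slopes = length(coefficients),
    bic = -2 * loglik + length(coefficients) * log(n),
    converged = converged, iter = iter), class = "vf_cpm")
}

#' @export
print.vf_cpm <- function(x, ...) {
  cat("Cumulative probability model (proportional odds, logit link)\n")
  cat(sprintf("n = %d, %d distinct outcome values, logLik = %.3f%s\n",
              x$n, length(x$levels), x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$coefficients)) {
    print(tidy(x), n = Inf)
  } else {
    cat("(intercept-only model)\n")
  }
  invisible(x)
}

#' @export
logLik.vf_cpm <- function(object, ...) {
  structure(object$loglik, df = object$df_slopes + length(object$alpha),
            class = "logLik")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the slope coefficients of a CPM fit
#'
#' One row per slope: log-odds estimate, standard error, Wald chi-square
#' statistic `(b/se)^2` with its 1-df p-value, and the adjusted odds ratio
#' `exp(b)` with its Wald confidence interval.
#'
#' @param x A `vf_cpm` fit.
#' @param conf.level Confidence level for the odds-ratio interval.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `statistic`
#'   (Wald chi-square), `p.value`, `aOR`, `conf.low`, `conf.high`.
#' @export
tidy.vf_cpm <- function(x, conf.level = 0.95, ...) {
  b <- x$coefficients
  if (length(b) == 0) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric(), aOR = numeric(),
                          conf.low = numeric(), conf.high = numeric()))
  }
  se <- sqrt(diag(x$vcov))
  if (any(!is.finite(se)) || any(se <= 0))
    stop("singular coefficient covariance; Wald summary unavailable",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  chi2 <- (b / se)^2
  tibble::tibble(
    term = names(b), estimate = unname(b), std.error = unname(se),
    statistic = unname(chi2),
    p.value = stats::pchisq(unname(chi2), df = 1, lower.tail = FALSE),
    aOR = exp(unname(b)),
    conf.low = exp(unname(b) - z * unname(se)),
    conf.high = exp(unname(b) + z * unname(se)))
}

#' One-row model-level summary of a CPM fit
#'
#' @param x A `vf_cpm` fit.
#' @param ... Unused.
#' @return Tibble with `n`, `logLik`, `logLik_null`, `lr_chi2`, `df`,
#'   `p.value` (likelihood-ratio test against the intercept-only model),
#'   `r2_nagelkerke`, `bic`, `converged`.
#' @export
glance.vf_cpm <- function(x, ...) {
  lr <- lr_test(x)
  tibble::tibble(n = x$n, logLik = x$loglik, logLik_null = x$loglik_null,
                 lr_chi2 = lr$chi2, df = lr$df, p.value = lr$p,
                 r2_nagelkerke = nagelkerke_r2(x), bic = x$bic,
                 converged = x$converged)
}

#' Likelihood-ratio test between nested CPM fits
#'
#' With a single argument, tests the fit against its intercept-only null
#' (whose log-likelihood has closed form). With two, tests `fit` against the
#' nested `null_fit`; both must be fitted to the same outcome.
#'
#' @param fit A `vf_cpm` fit.
#' @param null_fit Optional nested `vf_cpm` fit on the same data.
#' @return One-row tibble: `chi2`, `df`, `p`.
#' @export
lr_test <- function(fit, null_fit = NULL) {
  if (is.null(null_fit)) {
    ll0 <- fit$loglik_null; df <- fit$df_slopes
  } else {
    if (!identical(fit$levels, null_fit$levels) || fit$n != null_fit$n)
      stop("fits are not on identical data", call. = FALSE)
    if (null_fit$df_slopes > fit$df_slopes ||
        !all(names(null_fit$coefficients) %in% names(fit$coefficients)))
      stop("models are not nested", call. = FALSE)
    ll0 <- null_fit$loglik; df <- fit$df_slopes - null_fit$df_slopes
  }
  chi2 <- max(0, 2 * (fit$loglik - ll0))
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else 1
  tibble::tibble(chi2 = chi2, df = df, p = p)
}

#' Nagelkerke pseudo-R2 of a CPM fit
#'
#' \deqn{R^2 = \frac{1 - \exp\{-\tfrac{2}{n}(\ell - \ell_0)\}}
#'                  {1 - \exp\{\tfrac{2}{n}\ell_0\}}}
#'
#' @param fit A `vf_cpm` fit.
#' @return Scalar in \[0, 1).
#' @export
nagelkerke_r2 <- function(fit) {
  n <- fit$n
  num <- 1 - exp(-(2 / n) * (fit$loglik - fit$loglik_null))
  den <- 1 - exp((2 / n) * fit$loglik_null)
  num / den
}

#' Best-subset CPM selection by BIC
#'
#' Fits the cumulative probability model for every subset of the candidate
#' predictors added to the baseline predictors (the baseline terms are forced
#' into every model by default), ranks the fits by BIC, and reports BIC
#' weights \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} and the
#' approximate Bayes factor of the best model over the baseline-only model,
#' \eqn{BF_{10} = \exp\{(BIC_{base} - BIC_{best})/2\}}. Only slope parameters
#' count towards the BIC penalty: all candidate models share the same outcome
#' and hence the same intercept set, so intercept terms cancel in BIC
#' differences.
#'
#' @param data Data frame of complete cases for all variables involved.
#' @param outcome Name of the outcome column.
#' @param base Character vector of baseline predictor terms (may be empty).
#' @param candidates Character vector of candidate terms (<= 15; interaction
#'   terms like `"diagnosis:age_years"` are allowed).
#' @param force_base Keep the baseline terms in every candidate model
#'   (default). If `FALSE`, subsets are taken over `c(base, candidates)`
#'   jointly.
#' @return A `vf_cpm_search`: list with `models` (tibble of subsets: `terms`
#'   list-column, `k`, `bic`, `delta_bic`, `weight`), `best_fit`,
#'   `baseline_fit` (both `vf_cpm`), `bf10`.
#' @export
best_subset_cpm <- function(data, outcome, base, candidates,
                            force_base = TRUE) {
  if (!force_base) { candidates <- union(base, candidates); base <- character(0) }
  if (length(candidates) > 15)
    stop("more than 15 candidate predictors: exhaustive search refused",
         call. = FALSE)
  subsets <- purrr::map(0:length(candidates), function(k)
    utils::combn(candidates, k, simplify = FALSE))
  subsets <- purrr::flatten(subsets)
  fml <- function(terms) {
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    stats::as.formula(paste(outcome, "~", rhs))
  }
  fits <- purrr::map(subsets, function(s) cpm(fml(c(base, s)), data))
  bics <- purrr::map_dbl(fits, "bic")
  delta <- bics - min(bics)
  w <- exp(-delta / 2); w <- w / sum(w)
  best <- which.min(bics)
  baseline_idx <- which(purrr::map_int(subsets, length) == 0)
  models <- tibble::tibble(
    terms = purrr::map(subsets, ~ c(base, .x)),
    added = subsets,
    k = purrr::map_int(subsets, length),
    bic = bics, delta_bic = delta, weight = w) |>
    dplyr::arrange(.data$bic)
  structure(list(models = models,
                 best_terms = c(base, subsets[[best]]),
                 best_added = subsets[[best]],
                 best_fit = fits[[best]],
                 baseline_fit = fits[[baseline_idx]],
                 bf10 = exp((bics[baseline_idx] - bics[best]) / 2)),
            class = "vf_cpm_search")
}

#' @export
print.vf_cpm_search <- function(x, ...) {
  cat("Best-subset CPM search over", nrow(x$models), "models\n")
  cat("Best model adds: ",
      if (length(x$best_added)) paste(x$best_added, collapse = ", ")
      else "(nothing: baseline)", "\n", sep = "")
  cat(sprintf("BIC weight of best model = %.3f; BF10 vs baseline = %.4g\n",
              x$models$weight[1], x$bf10))
  invisible(x)
}

failed_mechanism_row <- function(n) {
  tibble::tibble(
    n = n, p_diag_base = NA_real_, aor_diag_base = NA_real_,
    diag_sig_base = NA, c_selected = NA, p_diag_with_c = NA_real_,
    aor_diag_with_c = NA_real_, diag_sig_with_c = NA, wald_c = NA_real_,
    aor_c = NA_real_, c_largest_wald = NA, r2_base = NA_real_,
    r2_with_c = NA_real_, bf10 = NA_real_, bic_weight_best = NA_real_)
}

#' Criterion-vs-sensitivity mechanism analysis of one cohort dataset
#'
#' Runs the two-step regression logic on a scored participant dataset: (1) a
#' baseline CPM of threshold on diagnosis, age, sex, and counterbalance
#' order; (2) a best-subset search adding signal-detection candidates
#' (default Az and c); (3) the baseline-plus-criterion model. It reports
#' whether diagnosis is significant in the baseline model, whether the
#' response criterion is selected by BIC, whether diagnosis loses
#' significance once c is in the model, and whether c carries the largest
#' Wald chi-square — the qualitative signature of a criterion-driven (rather
#' than sensitivity-driven) group difference in thresholds.
#'
#' @param data Participant-level data with columns `threshold_g`,
#'   `diagnosis` (`"NT"`/`"ASD"`), `age_years`, `sex` (`"F"`/`"M"`),
#'   `counterbalance`, `az`, `c`. Rows with missing thresholds (excluded
#'   sessions) are dropped.
#' @param candidates Candidate predictors for the best-subset step.
#' @param alpha Significance level used for the qualitative calls.
#' @return One-row tibble: `n`, `p_diag_base`, `aor_diag_base`,
#'   `diag_sig_base`, `c_selected`, `p_diag_with_c`, `aor_diag_with_c`,
#'   `diag_sig_with_c`, `wald_c`, `aor_c`, `c_largest_wald`,
#'   `r2_base`, `r2_with_c`, `bf10`, `bic_weight_best`.
#' @export

mechanism_scenario <- function(data, candidates = c("az", "c"),
                               alpha = 0.05) {
  data <- data[!is.na(data$threshold_g), , drop = FALSE]
  data$diagnosis <- factor(data$diagnosis, levels = c("NT", "ASD"))
  data$sex <- factor(data$sex, levels = c("F", "M"))
  data$counterbalance <- factor(data$counterbalance,
                                levels = c("ascending_first",
                                           "descending_first"))
  base <- c("diagnosis", "age_years", "sex", "counterbalance")
  base_fit <- cpm(threshold_g ~ diagnosis + age_years + sex + counterbalance,
                  data)
  with_c <- cpm(threshold_g ~ diagnosis + age_years + sex + counterbalance + c,
                data)
  search <- best_subset_cpm(data, "threshold_g", base, candidates)
  tb <- tidy(base_fit); tc <- tidy(with_c)
  row_diag_b <- tb[tb$term == "diagnosisASD", ]
  row_diag_c <- tc[tc$term == "diagnosisASD", ]
  row_c <- tc[tc$term == "c", ]
  tibble::tibble(
    n = nrow(data),
    p_diag_base = row_diag_b$p.value,
    aor_diag_base = row_diag_b$aOR,
    diag_sig_base = row_diag_b$p.value < alpha,
    c_selected = "c" %in% search$best_added,
    p_diag_with_c = row_diag_c$p.value,
    aor_diag_with_c = row_diag_c$aOR,
    diag_sig_with_c = row_diag_c$p.value < alpha,
    wald_c = row_c$statistic,
    aor_c = row_c$aOR,
    c_largest_wald = row_c$statistic == max(tc$statistic),
    r2_base = nagelkerke_r2(base_fit),
    r2_with_c = nagelkerke_r2(with_c),
    bf10 = search$bf10,
    bic_weight_best = search$models$weight[1])
}
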