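#' Corrected hit rate
#'
#' Converts a hit count into a hit proportion strictly inside (0, 1) so that
#' the normal quantile transform stays finite. A perfect score
#' (`n_hits == n_stim`) is replaced by `(n_hits + 0.5) / (n_stim + 1)`; a zero
#' score is replaced by the mirrored `0.5 / (n_stim + 1)`. All other counts
#' are returned as the plain proportion `n_hits / n_stim`.
#'
#' @param n_hits Integer vector, number of "yes" responses on stimulus trials.
#' @param n_stim Integer vector, number of stimulus trials (>= 1).
#' @return Numeric vector of corrected hit proportions in (0, 1).
#' @seealso [corrected_fa_rate()], [sdt_az()], [sdt_c()]
#' @examples
#' corrected_hit_rate(15, 20)        # 0.75, no correction
#' corrected_hit_rate(20, 20)        # 20.5/21
#' @export
corrected_hit_rate <- function(n_hits, n_stim) {
  check_counts(n_hits, n_stim, "n_hits", "n_stim")
  k <- max(length(n_hits), length(n_stim))
  n_hits <- rep_len(n_hits, k); n_stim <- rep_len(n_stim, k)
  out <- n_hits / n_stim
  out[n_hits == n_stim] <- ((n_hits + 0.5) / (n_stim + 1))[n_hits == n_stim]
  out[n_hits == 0] <- (0.5 / (n_stim + 1))[n_hits == 0]
  out
}

#' Corrected false-alarm rate
#'
#' Converts a false-alarm count on catch trials into a proportion strictly
#' inside (0, 1). A zero count is replaced by `0.5 / (n_catch + 1)`; a count
#' equal to `n_catch` is replaced by the mirrored
#' `(n_fa + 0.5) / (n_catch + 1)`.
#'
#' @param n_fa Integer vector, number of "yes" responses on catch trials.
#' @param n_catch Integer vector, number of catch trials (>= 1).
#' @return Numeric vector of corrected false-alarm proportions in (0, 1).
#' @examples
#' corrected_fa_rate(2, 20)          # 0.1
#' corrected_fa_rate(0, 20)          # 0.5/21
#' @export
corrected_fa_rate <- function(n_fa, n_catch) {
  check_counts(n_fa, n_catch, "n_fa", "n_catch")
  k <- max(length(n_fa), length(n_catch))
  n_fa <- rep_len(n_fa, k); n_catch <- rep_len(n_catch, k)
  out <- n_fa / n_catch
  out[n_fa == 0] <- (0.5 / (n_catch + 1))[n_fa == 0]
  out[n_fa == n_catch] <- ((n_fa + 0.5) / (n_catch + 1))[n_fa == n_catch]
  out
}

check_counts <- function(num, den, num_name, den_name) {
  if (any(!is.finite(num)) || any(!is.finite(den)))
    stop("counts must be finite", call. = FALSE)
  if (any(den < 1))
    stop(den_name, " must be >= 1", call. = FALSE)
  if (any(num < 0) || any(num > den))
    stop(num_name, " must lie in [0, ", den_name, "]", call. = FALSE)
  invisible(NULL)
}

check_rates <- function(h, f) {
  if (any(h <= 0 | h >= 1) || any(f <= 0 | f >= 1))
    stop("H and F must lie strictly in (0, 1); correct the rates first",
         call. = FALSE)
  invisible(NULL)
}

#' Parametric sensitivity index Az
#'
#' Area under the equal-variance Gaussian ROC through a single (false alarm,
#' hit) pair:
#' \deqn{A_z = \Phi\!\left(\frac{\Phi^{-1}(H) - \Phi^{-1}(F)}{2}\right)}
#' where \eqn{\Phi} is the standard normal cumulative distribution function.
#' Az is a monotone transform of d-prime; 0.5 is chance and 1 perfect
#' discrimination.
#'
#' @param h Hit proportion(s), strictly in (0, 1).
#' @param f False-alarm proportion(s), strictly in (0, 1).
#' @return Numeric vector of sensitivities in (0, 1).
#' @examples
#' sdt_az(0.9, 0.1)
#' sdt_az(0.5, 0.5)   # chance
#' @export
sdt_az <- function(h, f) {
  check_rates(h, f)
  stats::pnorm((stats::qnorm(h) - stats::qnorm(f)) / 2)
}

#' Response criterion c
#'
#' Location of the decision criterion relative to the zero-bias point, in
#' standard-deviation units of the latent evidence distributions:
#' \deqn{c = -\frac{\Phi^{-1}(H) + \Phi^{-1}(F)}{2}}
#' Positive values indicate a conservative strategy (favouring "no" when
#' unsure, minimising false alarms); negative values a liberal one.
#'
#' @inheritParams sdt_az
#' @return Numeric vector of criterion values (unbounded, finite).
#' @examples
#' sdt_c(0.9, 0.1)    # 0: symmetric, unbiased
#' sdt_c(0.6, 0.01)   # conservative observer
#' @export
sdt_c <- function(h, f) {
  check_rates(h, f)
  -(stats::qnorm(h) + stats::qnorm(f)) / 2
}

#' Signal-detection metrics from raw trial counts
#'
#' Applies the extreme-proportion corrections and computes the sensitivity
#' index Az and response criterion c for each row of counts. This is the
#' scoring step applied to each participant's session: hits over all stimulus
#' trials, false alarms over all catch trials.
#'
#' @param data Optional data frame holding the four count columns; if omitted
#'   the counts are taken from the remaining arguments directly.
#' @param n_hits,n_stim,n_fa,n_catch Count columns (unquoted when `data` is
#'   supplied, vectors otherwise).
#' @return A tibble with one row per input row: the four counts, corrected
#'   rates `h` and `f`, flags `h_corrected`/`f_corrected`, and `az`, `c`.
#' @examples
#' sdt_metrics(n_hits = 19, n_stim = 20, n_fa = 1, n_catch = 20)
#' @export
sdt_metrics <- function(data = NULL, n_hits = NULL, n_stim = NULL,
                        n_fa = NULL, n_catch = NULL) {
  if (!is.null(data)) {
    n_hits <- data$n_hits; n_stim <- data$n_stim
    n_fa <- data$n_fa; n_catch <- data$n_catch
  }
  h <- corrected_hit_rate(n_hits, n_stim)
  f <- corrected_fa_rate(n_fa, n_catch)
  tibble::tibble(
    n_hits = n_hits, n_stim = n_stim, n_fa = n_fa, n_catch = n_catch,
    h = h, f = f,
    h_corrected = n_hits == n_stim | n_hits == 0,
    f_corrected = n_fa == 0 | n_fa == n_catch,
    az = sdt_az(h, f),
    c = sdt_c(h, f)
  )
}
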