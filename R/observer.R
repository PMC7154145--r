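#' Internal signal strength of a simulated observer
#'
#' The generative psychometric function of the simulated observer: the mean of
#' the latent evidence distribution, in SD units above the noise distribution,
#' elicited by a filament of a given force. It is linear in log10-force with
#' slope `beta`, anchored so that the strength is exactly 1 at `alpha` grams,
#' and hard-clipped at zero:
#' \deqn{d(f) = \max\{0,\; \beta(\log_{10} f - \log_{10}\alpha) + 1\}}
#' Catch trials (no stimulus) have strength 0 by definition.
#'
#' @param force Stimulus force in grams (> 0); vectorised.
#' @param alpha Force in grams at which signal strength reaches 1 SD.
#' @param beta Slope of signal strength per log10-gram (> 0).
#' @return Numeric vector of signal strengths (SD units, >= 0).
#' @examples
#' signal_strength(0.1, alpha = 0.1, beta = 2)   # 1 by construction
#' signal_strength(1.0, alpha = 0.1, beta = 2)   # 3
#' @export
signal_strength <- function(force, alpha, beta) {
  if (any(force <= 0)) stop("force must be positive", call. = FALSE)
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be positive", call. = FALSE)
  pmax(0, beta * (log10(force) - log10(alpha)) + 1)
}

#' Simulate yes/no responses of an equal-variance SDT observer
#'
#' Draws one response per element of `d`. With probability `lapse` the
#' response is uniform at random; otherwise evidence X ~ Normal(d, 1) is
#' drawn and the observer answers "yes" iff X exceeds the internal criterion
#' `lam`. This is exactly the generative model under which the Az and c
#' estimators are unbiased. Uses the session RNG: set a seed beforehand for
#' reproducibility.
#'
#' @param d Signal strength per trial (0 for catch trials); vectorised.
#' @param lam Internal decision criterion on the evidence axis (SD units).
#' @param lapse Per-trial probability of a random response, in \[0, 0.05\].
#' @return Logical vector, `TRUE` for "yes".
#' @export
respond <- function(d, lam, lapse = 0) {
  n <- length(d)
  if (any(lapse < 0 | lapse > 0.05))
    stop("lapse must lie in [0, 0.05]", call. = FALSE)
  yes <- stats::rnorm(n, mean = d, sd = 1) > lam
  if (any(lapse > 0)) {
    lapsed <- stats::runif(n) < lapse
    yes[lapsed] <- stats::runif(sum(lapsed)) < 0.5
  }
  yes
}

group_spec <- function(n, alpha = c(0.010, 0.002), beta = c(1.5, 0.25),
                       lam = c(1.7, 0.25), lapse = c(0.02, 0.01),
                       age = c(10, 3), age_range = c(7, 17),
                       prop_male = 0.75, fsiq = c(108, 16),
                       viq = c(106, 16), piq = c(108, 17),
                       srs = c(45, 6), srs_lam_cor = 0.3) {
  list(n = n, alpha = alpha, beta = beta, lam = lam, lapse = lapse,
       age = age, age_range = age_range, prop_male = prop_male,
       fsiq = fsiq, viq = viq, piq = piq, srs = srs,
       srs_lam_cor = srs_lam_cor)
}

#' Default cohort specification
#'
#' A four-group cohort (diagnosis ASD/NT crossed with child/adult age band)
#' whose generating parameters emulate the covariate structure of a light-touch
#' detection study of autistic and neurotypical participants: group sizes,
#' ages, sex ratios, IQ and SRS-2 T-score distributions, and — crucially — a
#' criterion gap confined to the child band (ASD children hold a markedly more
#' conservative internal criterion than NT children, while the two adult
#' groups are similar) with equal sensitivity parameters within the child
#' band. Adults differ mildly in `alpha` instead (lower sensitivity in the
#' ASD group). Each group entry gives (mean, SD) pairs for the observer
#' parameters and covariates; values are drawn from truncated normals.
#'
#' The latent criterion means were calibrated by simulation so that the
#' *estimated* group summaries of the default protocol (mean criterion c,
#' mean threshold in grams, false-alarm and exclusion rates) land on the
#' scale such a study reports; the latent evidence-axis criterion is a
#' different quantity from the estimated statistic c and sits roughly 1 SD
#' higher.
#'
#' @param bands Character vector, subset of `c("child", "adult")`.
#' @param lam_gap_child Difference between ASD-child and NT-child mean
#'   internal criterion (evidence-axis SD units). Default 0.41; set 0 for a
#'   null cohort.
#' @param srs_lam_cor Correlation between the SRS T-score draw and the
#'   internal criterion draw within each group.
#' @return A `vf_cohort_spec`: a named list of group specifications.
#' @examples
#' spec <- default_cohort_spec(bands = "child")
#' names(spec)
#' @export
default_cohort_spec <- function(bands = c("child", "adult"),
                                lam_gap_child = 0.41, srs_lam_cor = 0.3) {
  bands <- match.arg(bands, c("child", "adult"), several.ok = TRUE)
  groups <- list()
  if ("child" %in% bands) {
    groups$child_NT <- group_spec(
      n = 35, lam = c(1.63, 0.19), age = c(9.49, 2.61), age_range = c(7, 17),
      prop_male = 26 / 35, fsiq = c(114.3, 15.5), viq = c(111.3, 12.8),
      piq = c(112.9, 18.2), srs = c(43.7, 6.0), srs_lam_cor = srs_lam_cor)
    groups$child_ASD <- group_spec(
      n = 55, lam = c(1.63 + lam_gap_child, 0.27), age = c(10.91, 3.35),
      age_range = c(7, 17), prop_male = 46 / 55, fsiq = c(103.5, 16.3),
      viq = c(100.5, 17.9), piq = c(105.1, 15.3), srs = c(73.9, 9.9),
      srs_lam_cor = srs_lam_cor)
  }
  if ("adult" %in% bands) {
    groups$adult_NT <- group_spec(
      n = 24, lam = c(1.93, 0.25),
      age = c(28.46, 4.77), age_range = c(18, 54), prop_male = 14 / 24,
      fsiq = c(107.7, 15.9), viq = c(107.5, 16.1), piq = c(107.5, 15.9),
      srs = c(45.1, 6.4), srs_lam_cor = srs_lam_cor)
    groups$adult_ASD <- group_spec(
      n = 33, alpha = c(0.014, 0.003), lam = c(1.93, 0.29),
      age = c(28.21, 8.92), age_range = c(18, 54), prop_male = 21 / 33,
      fsiq = c(106.4, 15.4), viq = c(103.1, 13.5), piq = c(105.7, 20.6),
      srs = c(71.4, 11.1), srs_lam_cor = srs_lam_cor)
  }
  structure(groups, class = "vf_cohort_spec")
}

#' Read a cohort specification from a YAML or JSON file
#'
#' The file holds one mapping per group; each group provides `n` and any of
#' the `group_spec` fields as `[mean, sd]` pairs (scalars allowed for `n`,
#' `prop_male`, `srs_lam_cor`, `age_range`). Unstated fields fall back to the
#' defaults of the matching group in [default_cohort_spec()] when the group
#' name matches, else to generic defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `vf_cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- default_cohort_spec()
  groups <- purrr::imap(raw, function(fields, name) {
    base <- if (name %in% names(defaults)) defaults[[name]] else group_spec(n = 1)
    for (f in names(fields)) base[[f]] <- unlist(fields[[f]])
    base
  })
  structure(groups, class = "vf_cohort_spec")
}

# truncated-normal draw by rejection, cap 1000 attempts per value
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (lower > upper) stop("impossible truncation bounds", call. = FALSE)
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("impossible truncation bounds", call. = FALSE)
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  attempts <- 0L
  while (length(bad) > 0) {
    attempts <- attempts + 1L
    if (attempts > 1000L)
      stop("truncation rejection cap exceeded; check bounds", call. = FALSE)
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Simulate a participant cohort
#'
#' Draws one participant record per row from a cohort specification:
#' diagnosis and age-band labels, demographic and questionnaire covariates,
#' and the true (latent) observer parameters `alpha`, `beta`, `lam`, `lapse`
#' that will drive the simulated detection sessions. SRS T-scores are
#' generated with a configurable correlation to the internal criterion so
#' that symptom-criterion correlation analyses can be exercised.
#' Counterbalance order (ascending- vs descending-first) is assigned by
#' [counterbalance_assign()].
#'
#' @param spec A `vf_cohort_spec`, e.g. from [default_cohort_spec()].
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @return A tibble with one row per participant: `id`, `group`, `band`,
#'   `diagnosis`, `age_years`, `sex`, `fsiq`, `viq`, `piq`, `srs_t`,
#'   `alpha`, `beta`, `lam`, `lapse`, `counterbalance`.
#' @examples
#' cohort <- simulate_cohort(default_cohort_spec(bands = "child"), seed = 1)
#' dplyr::count(cohort, group)
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "vf_cohort_spec"))
  set.seed(as.integer(seed))
  rows <- purrr::imap(unclass(spec), function(g, name) {
    n <- g$n
    if (n < 1) return(NULL)
    z_lam <- stats::rnorm(n)
    lam <- g$lam[1] + g$lam[2] * z_lam
    rho <- g$srs_lam_cor
    srs <- g$srs[1] + g$srs[2] * (rho * z_lam + sqrt(1 - rho^2) * stats::rnorm(n))
    band <- sub("_.*$", "", name)
    tibble::tibble(
      group = name,
      band = band,
      diagnosis = sub("^.*_", "", name),
      age_years = rtruncnorm(n, g$age[1], g$age[2],
                             g$age_range[1], g$age_range[2]),
      sex = ifelse(stats::runif(n) < g$prop_male, "M", "F"),
      fsiq = round(rtruncnorm(n, g$fsiq[1], g$fsiq[2], 70, 160)),
      viq = round(rtruncnorm(n, g$viq[1], g$viq[2], 60, 160)),
      piq = round(rtruncnorm(n, g$piq[1], g$piq[2], 60, 160)),
      srs_t = round(pmin(pmax(srs, 30), 100)),
      alpha = rtruncnorm(n, g$alpha[1], g$alpha[2], 0.008, 2.0),
      beta = rtruncnorm(n, g$beta[1], g$beta[2], 0.5, Inf),
      lam = lam,
      lapse = rtruncnorm(n, g$lapse[1], g$lapse[2], 0, 0.05)
    )
  })
  cohort <- dplyr::bind_rows(rows)
  cohort <- dplyr::mutate(cohort, id = sprintf("P%03d", dplyr::row_number()),
                          .before = 1)
  counterbalance_assign(cohort, seed = as.integer(seed) + 1L)
}

#' Assign counterbalance order across participants
#'
#' Alternates ascending-first / descending-first assignment over a seeded
#' random permutation of the participants, so the two orders are balanced to
#' within one participant overall.
#'
#' @param participants Data frame with one row per participant.
#' @param seed Integer seed for the permutation.
#' @return The input tibble with a `counterbalance` column
#'   (`"ascending_first"` / `"descending_first"`).
#' @export
counterbalance_assign <- function(participants, seed = 1L) {
  n <- nrow(participants)
  if (n < 1) stop("need at least one participant", call. = FALSE)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  cb <- character(n)
  cb[ord] <- rep(c("ascending_first", "descending_first"), length.out = n)
  participants$counterbalance <- cb
  tibble::as_tibble(participants)
}
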