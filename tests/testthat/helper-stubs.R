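# deterministic stub responders and small fixtures used across test files

# answers "yes" iff the force is at least `cut`; always "no" on catch trials
stub_threshold <- function(cut) {
  function(force) ifelse(is.na(force), FALSE, force >= cut)
}

stub_always <- function(answer) function(force) rep(answer, length(force))

# a round-number ladder convenient for hand-tracing
trace_ladder <- c(0.008, 0.02, 0.04, 0.07, 0.1, 0.2, 0.4, 0.6, 1.0, 2.0)
trace_opts <- function(...) protocol_options(ladder = trace_ladder, ...)

# literal transcription of the printed sensitivity / criterion equations,
# used as the independent oracle for the sdt module
oracle_az <- function(h, f) pnorm((qnorm(h) - qnorm(f)) / 2)
oracle_c <- function(h, f) -(qnorm(h) + qnorm(f)) / 2
oracle_hit <- function(k, n) if (k == n || k == 0) (k + 0.5) / (n + 1) else k / n
oracle_fa <- function(k, n) if (k == 0 || k == n) (k + 0.5) / (n + 1) else k / n

# brute-force Cliff's delta by full pairwise enumeration
oracle_cliff <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# one-participant tibble with known observer parameters
one_participant <- function(alpha = 0.08, beta = 1.5, lam = 0.6, lapse = 0,
                            counterbalance = "ascending_first") {
  tibble::tibble(id = "P001", alpha = alpha, beta = beta, lam = lam,
                 lapse = lapse, counterbalance = counterbalance)
}
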