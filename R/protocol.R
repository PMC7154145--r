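#' Default von Frey filament ladder
#'
#' Ten forces log-spaced between the lightest (0.008 g) and heaviest (2.0 g)
#' filament. Forces in grams; the ladder is strictly increasing with exact
#' endpoints.
#'
#' @param n Number of filaments.
#' @param min,max Endpoint forces in grams.
#' @return Numeric vector of forces, strictly increasing.
#' @export
filament_ladder <- function(n = 10, min = 0.008, max = 2.0) {
  if (n < 2 || min <= 0 || max <= min)
    stop("invalid filament ladder", call. = FALSE)
  forces <- 10^seq(log10(min), log10(max), length.out = n)
  forces[1] <- min; forces[n] <- max
  forces
}

#' Protocol options for the method-of-limits task
#'
#' Bundles the configurable pieces of the staircase protocol: the filament
#' ladder, catch-trial quotas per block direction, the threshold averaging
#' rule, and the catch-trial exclusion rule.
#'
#' @param ladder Stimulus forces in grams, strictly increasing.
#' @param catch_ascending,catch_descending Catch trials per ascending /
#'   descending block. Defaults 3 and 7: descending runs invite more "yes"
#'   bias, so more catches are spent there.
#' @param threshold_rule `"first"` (default): a block threshold averages the
#'   force last responded to before the first terminating response with the
#'   force of that first terminating response. `"pair"`: bracket the whole
#'   terminating pair (force before the first and force of the second).
#' @param exclusion_rule `"window"` (default): a session is excluded when any
#'   contiguous 10-trial window within a block holds more than
#'   `max_fa_per_window` catch trials answered "yes". `"block"`: the count is
#'   taken over the whole block instead.
#' @param max_fa_per_window Strict exclusion bound (exclusion requires
#'   strictly more).
#' @param window Window width in trials for the `"window"` rule.
#' @return A `vf_protocol` list.
#' @export
protocol_options <- function(ladder = filament_ladder(),
                             catch_ascending = 3, catch_descending = 7,
                             threshold_rule = c("first", "pair"),
                             exclusion_rule = c("window", "block"),
                             max_fa_per_window = 3, window = 10) {
  if (any(diff(ladder) <= 0)) stop("ladder must be strictly increasing", call. = FALSE)
  if (catch_ascending < 0 || catch_descending < 0)
    stop("catch quotas must be non-negative", call. = FALSE)
  structure(list(ladder = ladder,
                 catch_ascending = catch_ascending,
                 catch_descending = catch_descending,
                 threshold_rule = match.arg(threshold_rule),
                 exclusion_rule = match.arg(exclusion_rule),
                 max_fa_per_window = max_fa_per_window,
                 window = window),
            class = "vf_protocol")
}

sdt_responder <- function(alpha, beta, lam, lapse) {
  function(force) {
    d <- ifelse(is.na(force), 0, signal_strength(pmax(force, 1e-12), alpha, beta))
    respond(d, lam, lapse)
  }
}

#' Run one method-of-limits block
#'
#' Presents the filament ladder from its extreme in the given direction, one
#' filament per stimulus trial, until the direction's two-consecutive-response
#' rule fires (two "no" in a row for descending, two "yes" for ascending).
#' Catch-trial responses never affect termination. The block's catch quota is
#' interleaved at seeded-random positions among the realized stimulus trials
#' (never after the final stimulus trial); a "yes" on a catch trial is logged
#' as receiving false-positive feedback. If the ladder is exhausted without
#' termination the block is flagged as non-terminated.
#'
#' @param direction `"ascending"` or `"descending"`.
#' @param respond_fn Vectorised function taking forces in grams (`NA` for a
#'   catch trial) and returning logical "yes" responses; build one from
#'   observer parameters with the internal SDT rule or pass a deterministic
#'   stub.
#' @param opts A [protocol_options()] object.
#' @return A tibble of trials in presentation order: `position`, `kind`
#'   (`"stimulus"`/`"catch"`), `force_g` (`NA` on catch trials), `response`,
#'   `feedback` (TRUE on catch trials answered "yes"), plus constant columns
#'   `direction` and `terminated`.
#' @examples
#' set.seed(1)
#' stub <- function(force) ifelse(is.na(force), FALSE, force >= 0.4)
#' run_block("descending", stub, protocol_options())
#' @export
run_block <- function(direction = c("ascending", "descending"),
                      respond_fn, opts = protocol_options()) {
  direction <- match.arg(direction)
  b <- run_block_core(direction, respond_fn, opts)
  tibble::tibble(position = seq_len(b$n), kind = b$kind, force_g = b$force_g,
                 response = b$response, feedback = b$feedback,
                 direction = direction, terminated = b$terminated)
}

run_block_core <- function(direction, respond_fn, opts) {
  ladder <- opts$ladder
  forces <- if (direction == "descending") rev(ladder) else ladder
  yes <- respond_fn(forces)
  target <- if (direction == "descending") !yes else yes
  pair <- which(target[-1] & target[-length(target)])  # index of first of pair
  if (length(pair) > 0) {
    m <- pair[1] + 1L
    terminated <- TRUE
  } else {
    m <- length(forces)
    terminated <- FALSE
  }
  kind <- rep("stimulus", m)
  force <- forces[seq_len(m)]
  resp <- yes[seq_len(m)]
  quota <- if (direction == "descending") opts$catch_descending else opts$catch_ascending
  if (quota > 0) {
    catch_resp <- respond_fn(rep(NA_real_, quota))
    gap <- sample.int(m, quota, replace = TRUE)  # catch precedes stimulus trial `gap`
    ord <- order(c(seq_len(m), gap - 0.5))
    kind <- c(kind, rep("catch", quota))[ord]
    force <- c(force, rep(NA_real_, quota))[ord]
    resp <- c(resp, catch_resp)[ord]
  }
  list(kind = kind, force_g = force, response = resp,
       feedback = kind == "catch" & resp, terminated = terminated,
       n = length(kind))
}

#' Simulate full sessions for a cohort of participants
#'
#' Runs the four-block protocol (two ascending, two descending, alternating,
#' starting direction per the participant's counterbalance assignment) for
#' every row of `participants`, using each participant's latent observer
#' parameters `alpha`, `beta`, `lam`, `lapse`.
#'
#' @param participants Tibble from [simulate_cohort()] (needs columns `id`,
#'   `alpha`, `beta`, `lam`, `lapse`, `counterbalance`).
#' @param opts A [protocol_options()] object.
#' @param seed Integer seed; the full trial log is reproducible given the
#'   seed and cohort.
#' @return A tidy trial log: one row per trial with `id`, `block` (1..4),
#'   `direction`, `position`, `kind`, `force_g`, `response`, `feedback`,
#'   `terminated`.
#' @export
simulate_sessions <- function(participants, opts = protocol_options(), seed = 1L) {
  set.seed(as.integer(seed))
  needed <- c("id", "alpha", "beta", "lam", "lapse", "counterbalance")
  missing <- setdiff(needed, names(participants))
  if (length(missing) > 0)
    stop("participants lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  n <- nrow(participants)
  nb <- 4L * n
  acc <- vector("list", nb)
  who <- integer(nb); blk <- integer(nb); dir <- character(nb)
  for (i in seq_len(n)) {
    fn <- sdt_responder(participants$alpha[i], participants$beta[i],
                        participants$lam[i], participants$lapse[i])
    first_asc <- identical(participants$counterbalance[i], "ascending_first")
    dirs <- if (first_asc) c("ascending", "descending", "ascending", "descending")
            else c("descending", "ascending", "descending", "ascending")
    for (b in 1:4) {
      k <- (i - 1L) * 4L + b
      acc[[k]] <- run_block_core(dirs[b], fn, opts)
      who[k] <- i; blk[k] <- b; dir[k] <- dirs[b]
    }
  }
  lens <- vapply(acc, `[[`, integer(1), "n")
  idx <- rep.int(seq_len(nb), lens)
  tibble::tibble(
    id = participants$id[who][idx],
    block = blk[idx],
    direction = dir[idx],
    position = unlist(lapply(lens, seq_len)),
    kind = unlist(lapply(acc, `[[`, "kind")),
    force_g = unlist(lapply(acc, `[[`, "force_g")),
    response = unlist(lapply(acc, `[[`, "response")),
    feedback = unlist(lapply(acc, `[[`, "feedback")),
    terminated = rep.int(vapply(acc, `[[`, logical(1), "terminated"), lens)
  )
}

# terminating-run location within one block's stimulus trials:
# returns index (within stimulus trials) of the first of the two consecutive
# terminating responses, or NA if the block never terminated
terminal_pair_start <- function(response, direction) {
  target <- if (direction == "descending") !response else response
  pair <- which(target[-1] & target[-length(target)])
  if (length(pair) > 0) pair[1] else NA_integer_
}

block_threshold_one <- function(force, response, direction, opts) {
  k <- terminal_pair_start(response, direction)
  if (is.na(k)) {
    # ladder exhausted: threshold pinned at the extreme the travel reached
    return(list(threshold = force[length(force)], terminated = FALSE,
                terminal_pair_index = NA_integer_))
  }
  second <- switch(opts$threshold_rule, first = force[k], pair = force[k + 1])
  before <- if (k >= 2) force[k - 1] else force[k]
  list(threshold = mean(c(before, second)), terminated = TRUE,
       terminal_pair_index = k)
}

#' Per-block summaries of a trial log
#'
#' Computes, for every (participant, block), the block threshold under the
#' configured averaging rule, termination status, and catch-trial counts.
#'
#' @param trials Trial log from [simulate_sessions()].
#' @param opts A [protocol_options()] object (must match the one used to
#'   generate the log for the threshold rule to be meaningful).
#' @return Tibble with one row per participant-block: `id`, `block`,
#'   `direction`, `n_stim`, `n_hits`, `n_catch`, `n_fa`, `terminated`,
#'   `terminal_pair_index`, `threshold_g`.
#' @export
block_summaries <- function(trials, opts = protocol_options()) {
  key <- paste(trials$id, trials$block, sep = "\r")
  groups <- split(seq_len(nrow(trials)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(ix) {
    kind <- trials$kind[ix]
    s <- ix[kind == "stimulus"]
    bt <- block_threshold_one(trials$force_g[s], trials$response[s],
                              trials$direction[s[1]], opts)
    list(id = trials$id[ix[1]], block = trials$block[ix[1]],
         direction = trials$direction[s[1]],
         n_stim = length(s), n_hits = sum(trials$response[s]),
         n_catch = sum(kind == "catch"),
         n_fa = sum(kind == "catch" & trials$response[ix]),
         terminated = bt$terminated,
         terminal_pair_index = bt$terminal_pair_index,
         threshold_g = bt$threshold)
  })
  grab <- function(f, mode) vapply(rows, `[[`, mode, f, USE.NAMES = FALSE)
  tibble::tibble(
    id = grab("id", character(1)), block = grab("block", integer(1)),
    direction = grab("direction", character(1)),
    n_stim = grab("n_stim", integer(1)), n_hits = grab("n_hits", integer(1)),
    n_catch = grab("n_catch", integer(1)), n_fa = grab("n_fa", integer(1)),
    terminated = grab("terminated", logical(1)),
    terminal_pair_index = grab("terminal_pair_index", integer(1)),
    threshold_g = grab("threshold_g", numeric(1)))
}

exclusion_one <- function(is_fa, opts) {
  n <- length(is_fa)
  if (opts$exclusion_rule == "block") return(sum(is_fa) > opts$max_fa_per_window)
  w <- min(opts$window, n)
  if (w == 0) return(FALSE)
  cs <- cumsum(c(0, is_fa))
  any(cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)] > opts$max_fa_per_window)
}

#' Score simulated or recorded sessions
#'
#' Collapses a tidy trial log into one row per participant: the session
#' threshold (mean of the four block thresholds), pooled signal-detection
#' counts and metrics (hits over all stimulus trials, false alarms over all
#' catch trials, corrected rates, Az and c), the catch-trial exclusion flag,
#' and a flag for any non-terminated block. Excluded sessions carry `NA`
#' thresholds.
#'
#' @inheritParams block_summaries
#' @return Tibble with one row per participant: `id`, `threshold_g`,
#'   `n_hits`, `n_stim`, `n_fa`, `n_catch`, `h`, `f`, `az`, `c`, `excluded`,
#'   `any_nonterminated`.
#' @export
score_sessions <- function(trials, opts = protocol_options()) {
  blocks <- block_summaries(trials, opts)
  key <- paste(trials$id, trials$block, sep = "\r")
  groups <- split(seq_len(nrow(trials)), factor(key, levels = unique(key)))
  is_fa_all <- trials$kind == "catch" & trials$response
  bexcl <- vapply(groups, function(ix) exclusion_one(is_fa_all[ix], opts),
                  logical(1))
  bid <- vapply(groups, function(ix) trials$id[ix[1]], character(1))
  excl <- tibble::tibble(id = bid, excl = bexcl) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(excluded = any(.data$excl), .groups = "drop")
  out <- blocks |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      threshold_g = mean(.data$threshold_g),
      n_hits = sum(.data$n_hits), n_stim = sum(.data$n_stim),
      n_fa = sum(.data$n_fa), n_catch = sum(.data$n_catch),
      any_nonterminated = any(!.data$terminated),
      .groups = "drop") |>
    dplyr::left_join(excl, by = "id")
  m <- sdt_metrics(n_hits = out$n_hits, n_stim = out$n_stim,
                   n_fa = out$n_fa, n_catch = out$n_catch)
  out$h <- m$h; out$f <- m$f; out$az <- m$az; out$c <- m$c
  out$threshold_g[out$excluded] <- NA_real_
  dplyr::select(out, "id", "threshold_g", "n_hits", "n_stim", "n_fa",
                "n_catch", "h", "f", "az", "c", "excluded",
                "any_nonterminated")
}
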