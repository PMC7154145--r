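test_that("the default ladder has 10 rungs spanning 0.008-2.0 g", {
  l <- filament_ladder()
  expect_length(l, 10)
  expect_equal(l[1], 0.008)
  expect_equal(l[10], 2.0)
  expect_true(all(diff(l) > 0))
  expect_error(filament_ladder(n = 1), "invalid")
})

test_that("descending blocks walk down from 2.0 g and stop on two consecutive noes", {
  set.seed(1)
  b <- run_block("descending", stub_threshold(0.5), trace_opts())
  stim <- b[b$kind == "stimulus", ]
  expect_equal(stim$force_g[1], 2.0)
  expect_true(all(diff(stim$force_g) < 0))
  # yes at 2.0, 1.0, 0.6; first no at 0.4, second at 0.2 ends the block
  expect_equal(stim$response, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_true(all(b$terminated))
  expect_equal(sum(b$kind == "catch"), 7)
})

test_that("ascending blocks walk up from 0.008 g and stop on two consecutive yeses", {
  set.seed(1)
  b <- run_block("ascending", stub_threshold(0.05), trace_opts())
  stim <- b[b$kind == "stimulus", ]
  expect_equal(stim$force_g[1], 0.008)
  # no at 0.008, 0.02, 0.04; yes at 0.07 and 0.1 ends the block
  expect_equal(stim$response, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(sum(b$kind == "catch"), 3)
})

test_that("an unresponsive observer exhausts the ladder and is flagged", {
  set.seed(1)
  b <- run_block("ascending", stub_always(FALSE), trace_opts())
  expect_false(any(b$terminated))
  expect_equal(sum(b$kind == "stimulus"), 10)
  s <- block_summaries(dplyr::mutate(b, id = "x", block = 1L), trace_opts())
  expect_false(s$terminated)
  expect_true(is.na(s$terminal_pair_index))
  expect_equal(s$threshold_g, 2.0)   # pinned at the extreme reached
})

test_that("block thresholds average the forces around the first terminating response", {
  set.seed(1)
  bd <- run_block("descending", stub_threshold(0.5), trace_opts())
  sd_ <- block_summaries(dplyr::mutate(bd, id = "x", block = 1L), trace_opts())
  expect_equal(sd_$threshold_g, (0.6 + 0.4) / 2)   # last yes 0.6, first no 0.4
  set.seed(1)
  ba <- run_block("ascending", stub_threshold(0.05), trace_opts())
  sa <- block_summaries(dplyr::mutate(ba, id = "x", block = 1L), trace_opts())
  expect_equal(sa$threshold_g, (0.04 + 0.07) / 2)  # last no 0.04, first yes 0.07
})

test_that("the bracketing rule averages across the whole terminating pair", {
  opts <- trace_opts(threshold_rule = "pair")
  set.seed(1)
  bd <- run_block("descending", stub_threshold(0.5), opts)
  s <- block_summaries(dplyr::mutate(bd, id = "x", block = 1L), opts)
  expect_equal(s$threshold_g, (0.6 + 0.2) / 2)     # before first no, second no
})

test_that("feedback is logged exactly on catch trials answered yes", {
  set.seed(4)
  b <- run_block("descending", stub_always(TRUE), trace_opts())
  expect_true(all(b$feedback[b$kind == "catch"]))
  expect_false(any(b$feedback[b$kind == "stimulus"]))
})

test_that("sessions hold 4 alternating blocks with the 3/7 catch quotas", {
  set.seed(21)
  p <- one_participant(counterbalance = "descending_first")
  tr <- simulate_sessions(p, seed = 21)
  expect_equal(sort(unique(tr$block)), 1:4)
  dirs <- tr |> dplyr::distinct(block, direction) |> dplyr::arrange(block)
  expect_equal(dirs$direction,
               c("descending", "ascending", "descending", "ascending"))
  catch <- tr |> dplyr::filter(kind == "catch") |> dplyr::count(block)
  expect_equal(catch$n, c(7, 3, 7, 3))
  sess <- score_sessions(tr)
  expect_equal(sess$n_catch, 20)
})

test_that("session threshold is the mean of the four block thresholds", {
  set.seed(2)
  p <- one_participant(counterbalance = "ascending_first")
  tr <- simulate_sessions(p, trace_opts(), seed = 2)
  blocks <- block_summaries(tr, trace_opts())
  sess <- score_sessions(tr, trace_opts())
  expect_equal(sess$threshold_g, mean(blocks$threshold_g))
  expect_equal(mean(c(0.5, 0.5, 0.055, 0.055)), 0.2775)  # averaging rule itself
})

test_that("session SDT counts pool all stimulus and catch trials", {
  set.seed(3)
  p <- one_participant()
  tr <- simulate_sessions(p, trace_opts(), seed = 3)
  sess <- score_sessions(tr, trace_opts())
  expect_equal(sess$n_stim, sum(tr$kind == "stimulus"))
  expect_equal(sess$n_hits, sum(tr$kind == "stimulus" & tr$response))
  expect_equal(sess$n_fa, sum(tr$kind == "catch" & tr$response))
  expect_equal(sess$n_catch, 20)
})

test_that("a deterministic always-yes observer is excluded; exactly 3 window FAs are not", {
  # always-yes: every catch is a false alarm; 7 in one descending block
  ay <- purrr::map_dfr(1:4, function(b) {
    set.seed(b)
    dplyr::mutate(run_block(if (b %% 2) "descending" else "ascending",
                            stub_always(TRUE), trace_opts()),
                  id = "yes", block = b)
  })
  s <- score_sessions(ay, trace_opts())
  expect_true(s$excluded)
  expect_true(is.na(s$threshold_g))
  # zero false alarms: never excluded
  nf <- purrr::map_dfr(1:4, function(b) {
    set.seed(b)
    dplyr::mutate(run_block(if (b %% 2) "descending" else "ascending",
                            stub_threshold(0.5), trace_opts()),
                  id = "no", block = b)
  })
  expect_false(score_sessions(nf, trace_opts())$excluded)
  # hand-built block: exactly 3 catch-yes within a 10-trial window -> kept
  mk <- function(n_fa_yes) tibble::tibble(
    id = "h", block = 1L, direction = "descending",
    position = 1:10,
    kind = c(rep("catch", 4), rep("stimulus", 6)),
    force_g = c(rep(NA, 4), 2.0, 1.0, 0.6, 0.4, 0.2, 0.1),
    response = c(rep(TRUE, n_fa_yes), rep(FALSE, 4 - n_fa_yes),
                 TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    feedback = FALSE, terminated = TRUE)
  expect_false(score_sessions(mk(3), trace_opts())$excluded)
  expect_true(score_sessions(mk(4), trace_opts())$excluded)
})

test_that("per-block exclusion rule counts the whole block instead of windows", {
  opts_blk <- trace_opts(exclusion_rule = "block")
  long <- tibble::tibble(
    id = "w", block = 1L, direction = "descending", position = 1:20,
    kind = rep(c("catch", "stimulus"), 10),
    force_g = ifelse(rep(c(TRUE, FALSE), 10), NA, 0.5),
    response = c(rep(c(TRUE, TRUE), 4), rep(FALSE, 12)),
    feedback = FALSE, terminated = TRUE)
  # 4 catch-yes at positions 1, 9, 11, 19: > 3 per block, max 2 per 10-window
  long$response[long$kind == "catch"] <- c(TRUE, FALSE, FALSE, FALSE, TRUE,
                                           TRUE, FALSE, FALSE, FALSE, TRUE)
  expect_true(score_sessions(long, opts_blk)$excluded)
  expect_false(score_sessions(long, trace_opts())$excluded)
})

test_that("thresholds stay on the ladder or at midpoints of adjacent rungs", {
  spec <- default_cohort_spec(bands = "child")
  spec$child_NT$n <- 30; spec$child_ASD$n <- 0
  co <- simulate_cohort(spec, seed = 17)
  tr <- simulate_sessions(co, seed = 18)
  blocks <- block_summaries(tr)
  l <- filament_ladder()
  valid <- sort(unique(c(l, (l[-1] + l[-10]) / 2)))
  expect_true(all(vapply(blocks$threshold_g,
                         function(t) any(abs(valid - t) < 1e-12), logical(1))))
})

test_that("trial logs survive a CSV round trip and rescore identically", {
  co <- simulate_cohort(default_cohort_spec("child"), seed = 31)
  co <- co[1:5, ]
  tr <- simulate_sessions(co, seed = 32)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tr, path, row.names = FALSE)
  tr2 <- tibble::as_tibble(utils::read.csv(path))
  expect_equal(score_sessions(tr2), score_sessions(tr))
})
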