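test_that("cognitive load follows DAC/(DAC+FT) with its boundary cases", {
  expect_equal(cognitive_load(0.3, 2.0), 0.3 / 2.3)
  expect_equal(round(100 * cognitive_load(0.3, 2.0)), 13)
  expect_equal(cognitive_load(0.5, 0), 1)
  expect_error(cognitive_load(0, 0), "undefined")
  expect_error(cognitive_load(-1, 1), "non-negative")

  # the published 3 x 5 duration grid collapses to 12 distinct loads
  cl <- cognitive_load(rep(c(0.3, 0.5, 0.7), each = 5),
                       rep(c(0, 0.1, 0.6, 1.2, 2.0), times = 3))
  expect_length(unique(round(cl, 10)), 12)
})

test_that("timelines have the right event structure and contiguity", {
  cfg <- trial_config(list_length = 5, nd = 2, dac = 0.5, ft = 0.6, seed = 1)
  tl <- build_timeline(cfg)
  expect_equal(as.integer(table(tl$kind)[c("encode", "distractor",
                                           "free_time")]),
               c(5L, 10L, 15L))
  expect_equal(sum(tl$kind == "recall"), 5L)
  # contiguous, non-overlapping, strictly increasing onsets
  expect_equal(tl$onset, cumsum(dplyr::lag(tl$duration, default = 0)))
  expect_true(all(diff(tl$onset) > 0))
  expect_equal(max(tl$onset + tl$duration), sum(tl$duration))

  # no distracting task: encodings, free time, recall only
  tl0 <- build_timeline(trial_config(list_length = 3, nd = 0, ft = 1, seed = 1))
  expect_setequal(unique(tl0$kind), c("encode", "free_time", "recall"))

  # ft = 0 produces no free-time events at all
  tlf <- build_timeline(trial_config(list_length = 3, nd = 1, ft = 0, seed = 1))
  expect_false("free_time" %in% tlf$kind)
})

test_that("repeated distractors after the first of a burst are captured briefly", {
  p <- det_params(repeated_capture = 0.05)
  cfg <- trial_config(list_length = 3, nd = 3, dac = 0.7, ft = 0.1,
                      hod = "identical", params = p, seed = 2)
  tl <- dplyr::filter(build_timeline(cfg), kind == "distractor")
  first_of_burst <- !duplicated(tl$position)
  expect_equal(tl$duration[first_of_burst], rep(0.7, 3))
  expect_equal(tl$duration[!first_of_burst], rep(0.05, 6))

  # distinct distractors are never shortened
  cfg2 <- trial_config(list_length = 3, nd = 3, dac = 0.7, ft = 0.1,
                       hod = "distinct", params = p, seed = 2)
  tl2 <- dplyr::filter(build_timeline(cfg2), kind == "distractor")
  expect_equal(tl2$duration, rep(0.7, 9))
})

test_that("free time runs the cumulative refreshing schedule within budget", {
  lex <- generate_lexicon(stimulus_spec(), seed = 3)
  st <- wm_state(lex, position_code(), det_params())
  st <- encode(st, 1, 1, 0.5, rate = 6)

  expect_identical(run_free_time(st, 0), st)

  # deterministic step duration 0.08: a 2 s budget fits ~25 steps (one may
  # be lost to accumulated floating-point in the budget bookkeeping)
  out <- run_free_time(st, 2.0)
  expect_true(out$refresh_steps %in% c(24L, 25L))
  expect_equal(out$clock, st$clock + 2.0)

  # refreshing disabled: the interval is pure decay
  st_off <- wm_state(lex, position_code(), det_params(refresh_enabled = FALSE))
  st_off <- encode(st_off, 1, 1, 0.5, rate = 6)
  dec <- run_free_time(st_off, 1.0)
  expect_equal(dec$weights, st_off$weights * exp(-0.5))
  expect_identical(dec$refresh_steps, 0L)
})

test_that("trials with no forgetting channel are recalled perfectly", {
  # single item, no distractors, no noise, no time to decay
  p <- model_params(sigma = 0, theta = 0)
  tr <- run_trial(trial_config(1, nd = 0, ft = 0, params = p, seed = 5))
  expect_equal(tr$proportion_correct, 1)

  # both forgetting channels closed: decay off, zero overlap, no noise
  p2 <- model_params(sigma = 0, decay_enabled = FALSE)
  tr2 <- run_trial(trial_config(4, nd = 4, dac = 0.7, ft = 0.1, mdo = 0,
                                params = p2, seed = 6))
  expect_equal(tr2$proportion_correct, 1)
})

test_that("zero overlap keeps working-memory copies bit-identical to engrams", {
  cfg <- trial_config(4, nd = 2, dac = 0.5, ft = 0.6, mdo = 0, mdd = 2,
                      seed = 8)
  tr <- run_trial(cfg, keep_state = TRUE)
  st <- tr$state
  mem_rows <- which(st$presented & !st$lexicon$is_distractor)
  for (i in mem_rows) {
    v <- st$lexicon$values[i, ]
    v[is.na(v)] <- 0
    expect_identical(st$wm_values[i, ], v)
  }
})

test_that("decay during recall penalises later output positions", {
  lex <- generate_lexicon(stimulus_spec(), seed = 9)
  st <- wm_state(lex, position_code(), det_params())
  # equalise bindings across three positions, then walk the recall sequence
  for (i in 1:3) st$weights[i, st$positions$sets[[i]]] <- 0.9 / 16
  st$presented[1:3] <- TRUE
  acts <- numeric(3)
  for (p in 1:3) {
    res <- retrieve(st, p)
    acts[p] <- res$activation
    st <- decay(st, 1 / 6)
  }
  expect_true(all(diff(acts) < 0))
  expect_equal(acts[2] / acts[1], exp(-0.5 / 6))
})

test_that("recall degrades with distractor count and capture, improves with free time", {
  g <- run_grid(grid_spec(nd = c(0, 4, 8), dac = c(0.3, 0.7), ft = c(0, 2.0),
                          mdo = 0, mdd = 0, hod = "distinct",
                          list_length = c(3, 6), runs_per_case = 30, seed = 12))
  pc <- g$cases |>
    dplyr::summarise(pc = mean(.data$mean_pc), .by = c("nd", "dac", "ft"))
  wide_nd <- tidyr::pivot_wider(pc, names_from = "nd", values_from = "pc")
  expect_true(all(wide_nd$`0` >= wide_nd$`4` - 0.02))
  expect_true(all(wide_nd$`4` >= wide_nd$`8` - 0.02))
  busy <- dplyr::filter(pc, .data$nd > 0)
  wide_dac <- tidyr::pivot_wider(busy, names_from = "dac", values_from = "pc")
  expect_true(all(wide_dac$`0.3` >= wide_dac$`0.7` - 0.02))
  wide_ft <- tidyr::pivot_wider(busy, names_from = "ft", values_from = "pc")
  expect_true(all(wide_ft$`2` >= wide_ft$`0` - 0.02))
})

test_that("trial results are reproducible and serialise to JSON lines", {
  cfg <- trial_config(4, nd = 2, seed = 33)
  t1 <- run_trial(cfg)
  t2 <- run_trial(cfg)
  expect_identical(t1$recalled, t2$recalled)
  expect_identical(t1$timeline$duration, t2$timeline$duration)

  path1 <- withr::local_tempfile(fileext = ".jsonl")
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_trial_json(t1, path1)
  write_trial_json(t2, path2)
  expect_identical(readLines(path1), readLines(path2))
  expect_length(readLines(path1), 5)  # 4 positions + summary
  last <- jsonlite::fromJSON(utils::tail(readLines(path1), 1))
  expect_equal(last$seed, 33)
  expect_equal(last$factors$nd, 2)
})
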