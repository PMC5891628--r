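make_state <- function(params = det_params(), lex = tiny_lexicon(),
                       positions = position_code(n_positions = 4,
                                                 units_per_position = 6,
                                                 overlap_adjacent = 1 / 3)) {
  wm_state(lex, positions, params)
}

test_that("position code realises the prescribed adjacent overlap and no more", {
  pc <- position_code(n_positions = 9, units_per_position = 16,
                      overlap_adjacent = 0.3)
  for (i in 1:8) {
    expect_length(intersect(pc$sets[[i]], pc$sets[[i + 1]]), round(0.3 * 16))
  }
  for (i in 1:7) for (j in (i + 2):9) {
    expect_length(intersect(pc$sets[[i]], pc$sets[[j]]), 0)
  }
  expect_true(all(lengths(pc$sets) == 16))
})

test_that("encoding follows the saturating-exponential law", {
  st <- make_state()
  units <- st$positions$sets[[1]]

  # zero-duration identity
  st0 <- encode(st, 1, 1, duration = 0, rate = 6)
  expect_equal(st0$weights, st$weights)

  # closed form from w = 0: 1 - exp(-rate * duration)
  st1 <- encode(st, 1, 1, duration = 0.5, rate = 6)
  expect_equal(unique(st1$weights[1, units]), 1 - exp(-3), tolerance = 1e-12)
  expect_equal(st1$clock, 0.5)

  # distractor asymptote: strength bounds the weight at any duration
  st2 <- encode(st, 7, 1, duration = 50, rate = 6, strength = 0.5)
  expect_equal(unique(st2$weights[7, units]), 0.5, tolerance = 1e-9)

  # monotone nondecreasing in duration
  w_at <- function(d) encode(make_state(model_params(D = 0)), 1, 1,
                             duration = d, rate = 6)$weights[1, units[1]]
  ws <- vapply(c(0, 0.05, 0.2, 0.5, 1, 3), w_at, numeric(1))
  expect_true(all(diff(ws) > 0))
  expect_true(all(ws >= 0 & ws <= 1))

  expect_error(encode(st, 1, 1, duration = -1), "negative")
})

test_that("decay is exponential, ablatable, and a semigroup", {
  st <- make_state(det_params(D = 0.5))
  st$weights[1, ] <- 0.8
  expect_equal(unique(decay(st, 1.0)$weights[1, ]), 0.8 * exp(-0.5))
  expect_equal(decay(st, 0)$weights, st$weights)

  # splitting an interval changes nothing (event-driven equivalence)
  split2 <- decay(decay(st, 0.3), 0.7)
  expect_equal(split2$weights, decay(st, 1.0)$weights)
  expect_equal(split2$clock, 1.0)

  # ablation: decay rate zero freezes all weights
  st_off <- make_state(det_params(decay_enabled = FALSE))
  st_off$weights[2, ] <- 0.6
  expect_equal(decay(st_off, 5)$weights, st_off$weights)
  st_d0 <- make_state(det_params(D = 0))
  st_d0$weights[2, ] <- 0.6
  expect_equal(decay(st_d0, 5)$weights, st_d0$weights)
})

test_that("interference reproduces the worked example exactly", {
  ex <- worked_example()
  altered <- interfere(ex$memorandum, ex$distractor)
  expect_equal(altered$values, ex$altered)
  expect_equal(altered$values[6], 0.29)          # first altered unit
  expect_equal(altered$values[4:5], c(0.64, 0.33))  # untouched units
  expect_identical(altered$mask, ex$memorandum$mask)
})

test_that("averaging has the right fixed point and geometric convergence", {
  ex <- worked_example()
  # a distractor identical on shared units leaves the memorandum unchanged
  same <- ex$memorandum
  same$is_distractor <- TRUE
  expect_equal(interfere(ex$memorandum, same), ex$memorandum,
               ignore_attr = TRUE)

  # n applications close the gap to the distractor as 2^-n (brute force)
  shared <- ex$memorandum$mask & ex$distractor$mask
  gap0 <- ex$memorandum$values[shared] - ex$distractor$values[shared]
  wm <- ex$memorandum
  for (n in 1:8) {
    wm <- interfere(wm, ex$distractor)
    gap_n <- wm$values[shared] - ex$distractor$values[shared]
    expect_equal(gap_n, gap0 * 2^-n)
  }
})

test_that("restoration halves the gap to the engram and finds the right target", {
  lex <- tiny_lexicon(seed = 3)
  own <- lexicon_item(lex, 2)

  # fixed point: an undistorted copy restores to itself
  expect_equal(restore(own, lex), own, ignore_attr = TRUE)

  # halfway rule on a single distorted unit: (0.29 + 0.17) / 2 = 0.23
  distorted <- own
  u <- which(own$mask)[1]
  distorted$values[u] <- 0.29
  lex2 <- lex
  lex2$values[2, u] <- 0.17
  r <- restore(distorted, lex2)
  expect_equal(attr(r, "target"), 2L)
  expect_equal(r$values[u], 0.23)

  # n successive restorations: gap to the engram scales as 2^-n
  wm <- own
  wm$values[own$mask] <- own$values[own$mask] + 0.2
  gap0 <- wm$values[own$mask] - own$values[own$mask]
  for (n in 1:6) {
    wm <- restore(wm, lex)
    expect_equal(wm$values[own$mask] - own$values[own$mask], gap0 * 2^-n)
  }
})

test_that("identification returns the own engram unless distortion crossed over", {
  lex <- generate_lexicon(stimulus_spec(mdo = 1, mdd = 0.1,
                                        n_distractor_types = 2), seed = 8)
  own <- lexicon_item(lex, 3)
  expect_identical(identify_ltm(own, lex), 3L)

  # one averaging toward a full-overlap, low-distance distractor: still own
  once <- interfere(own, lexicon_item(lex, 27))
  expect_identical(identify_ltm(once, lex), 3L)

  # candidate pools: distractor engrams only compete when asked for
  d <- lexicon_item(lex, 27)
  expect_identical(identify_ltm(d, lex, candidates = "all"), 27L)
  expect_true(identify_ltm(d, lex, candidates = "memoranda") <= 26L)

  # an exact halfway tie goes to the lowest index, with a message
  # (0.25 / 0.5 / 0.75 are exactly representable, so the tie is exact)
  two <- generate_lexicon(stimulus_spec(n_memoranda = 2,
                                        n_distractor_types = 0,
                                        n_units = 16, domain_size = 8),
                          seed = 1)
  two$values[1, two$domain] <- 0.25
  two$values[2, two$domain] <- 0.75
  halfway <- item_vector(ifelse(seq_len(16) %in% two$domain, 0.5, NA))
  expect_message(win <- identify_ltm(halfway, two), "tie")
  expect_identical(win, 1L)
})

test_that("reactivation mirrors encoding and respects the ablation switch", {
  st <- make_state(det_params(D = 0))
  st$weights[1, st$positions$sets[[1]]] <- 0.3
  st$presented[1] <- TRUE
  re <- reactivate(st, 1, 1, duration = 0.08, rate = 6)
  expect_equal(unique(re$weights[1, st$positions$sets[[1]]]),
               1 - 0.7 * exp(-0.48), tolerance = 1e-12)

  off <- make_state(det_params(refresh_enabled = FALSE))
  off$weights[1, ] <- 0.3
  expect_identical(reactivate(off, 1, 1, duration = 0.08), off)
})

test_that("reactivation does not hijack the interference target", {
  st <- make_state()
  st <- encode(st, 1, 1, 0.5, rate = 6)
  st <- encode(st, 2, 2, 0.5, rate = 6)
  expect_identical(st$last_presented, 2L)
  st <- reactivate(st, 1, 1, 0.08, rate = 6)
  expect_identical(st$last_presented, 2L)
})

test_that("retrieval selects by summed weights, thresholds, and errs as Gaussians predict", {
  st <- make_state(det_params())
  units <- st$positions$sets[[2]]
  st$weights[3, units] <- 0.9 / length(units)
  st$presented[3] <- TRUE
  res <- retrieve(st, 2)
  expect_false(res$omission)
  expect_identical(res$item, 3L)
  expect_equal(res$activation, 0.9)
  expect_identical(res$wm_object$item_id, st$lexicon$item_id[3])

  # all activations below theta: omission
  st_lo <- make_state(det_params())
  st_lo$weights[3, units] <- 0.04 / length(units)
  expect_true(retrieve(st_lo, 2)$omission)

  # confusion probability between two candidates vs the Gaussian closed form
  sigma <- 0.05
  a1 <- 0.6; a2 <- 0.55
  stn <- make_state(model_params(sigma = sigma))
  stn$weights[1, units] <- a1 / length(units)
  stn$weights[2, units] <- a2 / length(units)
  stn$lexicon$is_distractor[-(1:2)] <- TRUE  # keep the pool at two candidates
  stn$weights <- stn$weights[1:2, , drop = FALSE]
  stn$lexicon$values <- stn$lexicon$values[1:2, , drop = FALSE]
  stn$lexicon$mask <- stn$lexicon$mask[1:2, , drop = FALSE]
  stn$lexicon$item_id <- stn$lexicon$item_id[1:2]
  stn$lexicon$is_distractor <- stn$lexicon$is_distractor[1:2]
  stn$wm_values <- stn$wm_values[1:2, , drop = FALSE]
  set.seed(99)
  wins2 <- vapply(1:4000, function(i) retrieve(stn, 2)$item, integer(1))
  p_hat <- mean(wins2 == 2)
  p_theory <- pnorm(-(a1 - a2) / (sigma * sqrt(2)))
  expect_equal(p_hat, p_theory, tolerance = 0.035)
})

test_that("weights never go negative through any operation sequence", {
  set.seed(5)
  st <- make_state(model_params())
  for (i in 1:30) {
    op <- sample(3, 1)
    st <- switch(op,
                 encode(st, sample(6, 1), sample(4, 1), runif(1, 0, 0.6)),
                 decay(st, runif(1, 0, 2)),
                 reactivate(st, sample(6, 1), sample(4, 1), runif(1, 0, 0.1)))
    expect_true(all(st$weights >= 0))
    expect_true(all(st$weights <= 1 + 1e-12))
  }
})
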