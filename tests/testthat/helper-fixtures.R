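# Shared fixtures: all stimuli are generated in code at test time.

# deterministic-timing parameters: all stochastic draws collapse onto means
det_params <- function(...) {
  model_params(s = 0, sigma = 0, duration_cv = 0, ...)
}

# a tiny lexicon with known structure, for hand-checkable network tests
tiny_lexicon <- function(seed = 42, mdo = 0.5, mdd = 1, n_types = 4) {
  generate_lexicon(
    stimulus_spec(mdo = mdo, mdd = mdd, hod = "distinct",
                  n_memoranda = 6, n_distractor_types = n_types,
                  n_units = 16, domain_size = 8),
    seed = seed
  )
}

# reduced factorial grid: full duration crossing, one stimulus condition
mini_grid <- function(nd = c(1, 4), dac = c(0.3, 0.5, 0.7),
                      ft = c(0, 0.1, 0.6, 1.2, 2.0), mdo = 0, mdd = 0,
                      hod = "distinct", list_length = c(2, 4, 6),
                      runs_per_case = 10, seed = 1, variant = "full") {
  grid_spec(nd = nd, dac = dac, ft = ft, mdo = mdo, mdd = mdd, hod = hod,
            list_length = list_length, runs_per_case = runs_per_case,
            seed = seed, variant = variant)
}

# span means by one factor from a wm_grid
span_by <- function(grid, factor) {
  agg <- aggregate_spans(grid, by = factor)
  agg[order(agg[[factor]]), ]
}

# the printed worked-example vectors (memorandum, distractor, altered result)
worked_example <- function() {
  list(
    memorandum = item_vector(c(NA, NA, NA, 0.64, 0.33, 0.17, 0.49, 0.02,
                               0.10, NA, NA, NA, NA), item_id = "F"),
    distractor = item_vector(c(NA, NA, NA, NA, NA, 0.41, 0.45, 0.22, 0.10,
                               0.90, 0.09, NA, NA), item_id = "dist",
                             is_distractor = TRUE),
    altered = c(NA, NA, NA, 0.64, 0.33, 0.29, 0.47, 0.12, 0.10, NA, NA, NA, NA)
  )
}
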