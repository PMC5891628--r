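#' Cognitive load of a distracting phase
#'
#' The proportion of distracting-phase time during which attention is
#' captured: `dac / (dac + ft)`, where `dac` is the attentional-capture
#' duration of one distractor step and `ft` the free time following it.
#' Cognitive load is 1 when there is no free time at all.
#'
#' @param dac Duration of attentional capture per distractor (s).
#' @param ft Free time following each distractor (s).
#' @return `dac / (dac + ft)`, vectorised.
#' @export
#' @examples
#' cognitive_load(0.3, 2.0)  # about 0.13: attention captured 13% of the time
cognitive_load <- function(dac, ft) {
  if (any(dac < 0) || any(ft < 0)) stop("dac and ft must be non-negative")
  if (any(dac == 0 & ft == 0)) {
    stop("cognitive load undefined when dac and ft are both zero")
  }
  dac / (dac + ft)
}

#' Configure one complex span trial
#'
#' Bundles the manipulated task factors, the stimulus factors, the model
#' parameters and a seed. The published factor grids are `list_length` 1-9,
#' `nd` in {0, 1, 4, 8}, `dac` in {0.3, 0.5, 0.7} s, `ft` in
#' {0, 0.1, 0.6, 1.2, 2.0} s, `mdo` in {0, .2, .4, .6, .8, 1}, `mdd` in
#' {0, .5, ..., 3} and `hod` identical/distinct, but any admissible values
#' are accepted.
#'
#' @param list_length Number of memoranda (1-9 with the default position
#'   code).
#' @param nd Number of distractors in the burst following each memorandum.
#' @param dac Duration of attentional capture per distractor (s).
#' @param ft Free time after each encoding and after each distractor (s).
#' @param mdo,mdd,hod Stimulus factors, see [stimulus_spec()].
#' @param params A [model_params()].
#' @param seed Optional seed; recorded and used by [run_trial()].
#' @return An object of class `wm_trial_config`.
#' @export
trial_config <- function(list_length, nd = 0, dac = 0.5, ft = 0.6,
                         mdo = 0, mdd = 0, hod = c("distinct", "identical"),
                         params = model_params(), seed = NULL) {
  hod <- match.arg(hod)
  stopifnot(list_length >= 1, nd >= 0, dac >= 0, ft >= 0,
            inherits(params, "wm_params"))
  structure(
    list(list_length = as.integer(list_length), nd = as.integer(nd),
         dac = dac, ft = ft, mdo = mdo, mdd = mdd, hod = hod,
         params = params, seed = seed),
    class = "wm_trial_config"
  )
}

# number of distractor types a trial needs from the lexicon
n_types_needed <- function(config) {
  if (config$nd == 0) 0L
  else if (config$hod == "identical") 1L
  else config$nd * config$list_length
}

# lexicon matching a trial config (one type per token when distinct)
default_lexicon <- function(config) {
  generate_lexicon(stimulus_spec(
    mdo = config$mdo, mdd = config$mdd, hod = config$hod,
    n_distractor_types = n_types_needed(config)
  ))
}

#' Build the event timeline of a complex span trial
#'
#' Each memorandum is encoded (duration drawn around `Te`), followed by free
#' time, then by `nd` repetitions of one distractor processing step (duration
#' drawn around `dac`) plus free time -- so free time follows every encoding
#' and every distractor, including the last one before recall. Recall is one
#' timed retrieval event per position (durations drawn around `1/R`). With
#' homogeneous (repeated) distractors and the reduced-capture mechanism
#' enabled, every distractor after the first of its burst gets the short
#' `repeated_capture` mean duration instead of `dac`.
#'
#' Durations are drawn when the timeline is built; refreshing steps are not
#' timeline events but fill the free-time intervals at execution.
#'
#' @param config A [trial_config()].
#' @return A tibble of class `wm_timeline`: `event`, `kind` (encode /
#'   distractor / free_time / recall), `position`, `item` (memorandum index
#'   within the list, or distractor token index), `onset`, `duration`.
#' @export
#' @examples
#' tl <- build_timeline(trial_config(list_length = 5, nd = 2, seed = 1))
#' table(tl$kind)  # 5 encode, 10 distractor, 15 free_time, 5 recall
build_timeline <- function(config) {
  stopifnot(inherits(config, "wm_trial_config"))
  p <- config$params
  L <- config$list_length
  rows <- list()
  token <- 0L
  reduced <- config$hod == "identical" && !is.null(p$repeated_capture)
  for (i in seq_len(L)) {
    rows[[length(rows) + 1L]] <-
      list(kind = "encode", position = i, item = i,
           duration = draw_duration(p$Te, p))
    if (config$ft > 0) {
      rows[[length(rows) + 1L]] <-
        list(kind = "free_time", position = i, item = NA_integer_,
             duration = config$ft)
    }
    for (d in seq_len(config$nd)) {
      token <- token + 1L
      mean_cap <- if (reduced && d > 1) p$repeated_capture else config$dac
      rows[[length(rows) + 1L]] <-
        list(kind = "distractor", position = i, item = token,
             duration = draw_duration(mean_cap, p))
      if (config$ft > 0) {
        rows[[length(rows) + 1L]] <-
          list(kind = "free_time", position = i, item = NA_integer_,
               duration = config$ft)
      }
    }
  }
  for (i in seq_len(L)) {
    rows[[length(rows) + 1L]] <-
      list(kind = "recall", position = i, item = NA_integer_,
           duration = draw_duration(1 / p$R, p))
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  out$onset <- cumsum(dplyr::lag(out$duration, default = 0))
  out <- dplyr::mutate(out, event = dplyr::row_number(),
                       .before = dplyr::everything())
  class(out) <- c("wm_timeline", class(out))
  out
}

#' Run cumulative refreshing over a free-time interval
#'
#' Positions 1 to `n_encoded` are visited cyclically, starting from position
#' 1 at each new free-time slot. Each step draws a duration around `Tr`; if
#' the remaining budget cannot accommodate it the step is skipped and the
#' interval ends (decay still spans the full interval). A step retrieves the
#' item best bound to the current position (with retrieval noise); unless
#' that fails, the winner's binding to the position is reactivated and its
#' working-memory representation restored toward its closest long-term
#' engram. With refreshing disabled, the interval is pure decay.
#'
#' @param state A `wm_state`.
#' @param duration Free-time budget (s).
#' @param n_encoded Number of positions encoded so far (cycle range);
#'   defaults to the number of presented memoranda.
#' @return The updated `wm_state`, clock advanced by exactly `duration`;
#'   `state$refresh_steps` accumulates the number of steps executed.
#' @export
run_free_time <- function(state, duration,
                          n_encoded = sum(state$presented & !state$lexicon$is_distractor)) {
  stopifnot(inherits(state, "wm_state"), duration >= 0)
  p <- state$params
  if (duration == 0) return(state)
  if (!p$refresh_enabled || n_encoded == 0) return(decay(state, duration))
  used <- 0
  pos <- 1L
  repeat {
    step <- draw_duration(p$Tr, p)
    if (used + step > duration) break
    res <- retrieve(state, pos)
    if (res$omission) {
      state <- decay(state, step)  # nothing retrievable; time still passes
    } else {
      state <- reactivate(state, res$item, pos, step)  # decays + strengthens
      if (!state$lexicon$is_distractor[res$item]) {
        # restore the memorandum's representation (bindings are untouched)
        restored <- restore(res$wm_object, state$lexicon)
        state$wm_values[res$item, state$lexicon$mask[res$item, ]] <-
          restored$values[restored$mask]
      }
    }
    state$refresh_steps <- state$refresh_steps + 1L
    used <- used + step
    pos <- if (pos >= n_encoded) 1L else pos + 1L
  }
  if (duration > used) state <- decay(state, duration - used)
  state
}

#' Simulate one complex span trial
#'
#' Executes the full trial: each memorandum of the list (sampled without
#' replacement from the lexicon's memoranda pool) is encoded at its position,
#' distractors are bound to the current position at reduced strength and
#' distort the last-presented memorandum's representation by halfway
#' averaging on shared units, free time is filled with cumulative refreshing,
#' and recall retrieves each position in turn while decay continues. Each
#' recalled working-memory object is mapped to its closest long-term engram;
#' the response is correct when that engram is the memorandum presented at
#' the cued position. Omissions and intrusions are simply incorrect.
#'
#' @param config A [trial_config()].
#' @param lexicon Optional `wm_lexicon`; by default one is generated from the
#'   config's stimulus factors (with one distractor type per token when
#'   `hod = "distinct"`).
#' @param positions A [position_code()].
#' @param keep_state Return the final `wm_state` (for inspection)?
#' @return An object of class `wm_trial`: `recalled` (lexicon indices, `NA`
#'   for omissions), `correct` (logical per position), `proportion_correct`,
#'   the `timeline`, the presented `list_items`, `refresh_steps`, and
#'   optionally `state`.
#' @export
#' @examples
#' tr <- run_trial(trial_config(list_length = 4, nd = 2, seed = 7))
#' tr$proportion_correct
run_trial <- function(config, lexicon = NULL, positions = position_code(),
                      keep_state = FALSE) {
  stopifnot(inherits(config, "wm_trial_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(lexicon)) lexicon <- default_lexicon(config)
  need <- n_types_needed(config)
  if (sum(lexicon$is_distractor) < need) {
    stop("lexicon provides ", sum(lexicon$is_distractor),
         " distractor types but the trial needs ", need)
  }
  L <- config$list_length
  stopifnot(L <= positions$n_positions,
            L <= sum(!lexicon$is_distractor))
  p <- config$params
  n_mem <- sum(!lexicon$is_distractor)
  list_items <- sample.int(n_mem, L)
  # token -> lexicon index of the distractor type
  token_type <- if (config$nd == 0) integer(0)
  else if (config$hod == "identical") rep(n_mem + 1L, config$nd * L)
  else n_mem + seq_len(config$nd * L)

  state <- wm_state(lexicon, positions, p)
  timeline <- build_timeline(config)
  recalled <- integer(0)
  for (e in seq_len(nrow(timeline))) {
    ev <- timeline[e, ]
    switch(ev$kind,
      encode = {
        state <- encode(state, list_items[ev$item], ev$position, ev$duration)
      },
      free_time = {
        state <- run_free_time(state, ev$duration)
      },
      distractor = {
        d_idx <- token_type[ev$item]
        state <- encode(state, d_idx, ev$position, ev$duration,
                        strength = p$distractor_strength)
        tgt <- state$last_presented
        if (!is.na(tgt)) {
          new_wm <- interfere(wm_copy_of(state, tgt), lexicon_item(lexicon, d_idx))
          state$wm_values[tgt, lexicon$mask[tgt, ]] <- new_wm$values[new_wm$mask]
        }
      },
      recall = {
        res <- retrieve(state, ev$position)
        recalled <- c(recalled,
                      if (res$omission) NA_integer_
                      else if (lexicon$is_distractor[res$item]) res$item
                      else identify_ltm(res$wm_object, lexicon))
        state <- decay(state, ev$duration)
      }
    )
  }
  correct <- !is.na(recalled) & recalled == list_items
  structure(
    list(recalled = recalled, correct = correct,
         proportion_correct = mean(correct),
         list_items = list_items, timeline = timeline,
         refresh_steps = state$refresh_steps,
         config = config,
         state = if (keep_state) state else NULL),
    class = "wm_trial"
  )
}

#' @export
print.wm_trial <- function(x, ...) {
  cat("<wm_trial> list length", x$config$list_length,
      "| nd", x$config$nd, "| recalled",
      sum(x$correct), "/", length(x$correct), "in position\n")
  invisible(x)
}

#' Tidy a trial result into one row per serial position
#'
#' @param x A `wm_trial`.
#' @param ... Unused.
#' @return A tibble with `position`, `presented`, `recalled` (item ids, `NA`
#'   for omissions) and `correct`.
#' @export
tidy.wm_trial <- function(x, ...) {
  tibble::tibble(
    position = seq_along(x$list_items),
    presented = x$list_items,
    recalled = x$recalled,
    correct = x$correct
  )
}

#' @export
glance.wm_trial <- function(x, ...) {
  tibble::tibble(
    list_length = x$config$list_length, nd = x$config$nd,
    dac = x$config$dac, ft = x$config$ft,
    cl = if (x$config$dac + x$config$ft > 0)
      cognitive_load(x$config$dac, x$config$ft) else NA_real_,
    proportion_correct = x$proportion_correct,
    refresh_steps = x$refresh_steps
  )
}

#' Serialise a trial result to JSON lines
#'
#' Writes one JSON object per serial position plus a final summary object,
#' embedding the seed and factor levels so a run can be reproduced.
#'
#' @param trial A `wm_trial`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_json <- function(trial, path) {
  stopifnot(inherits(trial, "wm_trial"))
  rows <- tidy.wm_trial(trial)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(rows))) {
    writeLines(jsonlite::toJSON(as.list(rows[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  summary <- list(
    proportion_correct = trial$proportion_correct,
    refresh_steps = trial$refresh_steps,
    seed = trial$config$seed,
    factors = trial$config[c("list_length", "nd", "dac", "ft",
                             "mdo", "mdd", "hod")]
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              na = "null"), con)
  invisible(path)
}
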