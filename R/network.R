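#' Model parameters of the working-memory network
#'
#' The parameter set of the simulator, with the conventional defaults of the
#' TBRS* lineage. Attention-demanding operations (encoding, refreshing,
#' recall) proceed at a processing rate drawn per operation from a Gaussian
#' with mean `R` and standard deviation `s` (floored at 0.1/s); item-position
#' association weights grow toward an asymptote at that rate while attention
#' is on the item, and decay exponentially at rate `D` whenever it is not.
#' Retrieval adds Gaussian noise (`sigma`) to each candidate's summed
#' activation and reports an omission when the winner's noiseless activation
#' falls below the threshold `theta`.
#'
#' Operation durations are stochastic: each is drawn from a Gaussian centred
#' on its mean (`Te` for encoding, `Tr` for a refreshing step, the trial's
#' distractor capture duration for distractor processing, `1/R` for each
#' recall step) with coefficient of variation `duration_cv`, floored at 10 ms.
#'
#' @param R Mean processing rate of encoding, refreshing and recall (1/s).
#' @param s Standard deviation of the processing rate.
#' @param theta Retrieval threshold on the noiseless winning activation.
#' @param sigma Standard deviation of Gaussian retrieval noise.
#' @param D Decay rate of association weights (1/s).
#' @param Tr Mean duration of one refreshing step (s).
#' @param Ta Mean duration of attentional capture per distractor step (s);
#'   task-dependent, overridden by the trial's `dac` factor.
#' @param Te Mean encoding duration per memorandum (s).
#' @param distractor_strength Encoding-strength multiplier for distractors
#'   (asymptote of their item-position weights); memoranda use 1.
#' @param repeated_capture When a number (e.g. 0.05), repeated distractors
#'   after the first of each burst are processed with this much shorter mean
#'   capture duration; `NULL` disables the mechanism.
#' @param duration_cv Coefficient of variation of stochastic durations; set
#'   to 0 for a deterministic-timing model.
#' @param decay_enabled,refresh_enabled Ablation switches: disable temporal
#'   decay (equivalently `D = 0`) or the whole refreshing process.
#' @return An object of class `wm_params`.
#' @export
#' @examples
#' model_params()                       # published defaults
#' model_params(decay_enabled = FALSE)  # interference-only ablation
model_params <- function(R = 6, s = 1, theta = 0.05, sigma = 0.02, D = 0.5,
                         Tr = 0.08, Ta = 0.5, Te = 0.5,
                         distractor_strength = 0.5, repeated_capture = NULL,
                         duration_cv = 0.25,
                         decay_enabled = TRUE, refresh_enabled = TRUE) {
  stopifnot(
    R > 0, s >= 0, theta >= 0, sigma >= 0, D >= 0,
    Tr >= 0, Ta >= 0, Te >= 0,
    distractor_strength > 0, distractor_strength <= 1,
    is.null(repeated_capture) || (is.numeric(repeated_capture) && repeated_capture > 0),
    duration_cv >= 0
  )
  structure(
    list(R = R, s = s, theta = theta, sigma = sigma, D = D,
         Tr = Tr, Ta = Ta, Te = Te,
         distractor_strength = distractor_strength,
         repeated_capture = repeated_capture,
         duration_cv = duration_cv,
         decay_enabled = isTRUE(decay_enabled),
         refresh_enabled = isTRUE(refresh_enabled)),
    class = "wm_params"
  )
}

#' @export
print.wm_params <- function(x, ...) {
  cat("<wm_params> R =", x$R, "s =", x$s, "theta =", x$theta,
      "sigma =", x$sigma, "D =", x$D, "Tr =", x$Tr, "Te =", x$Te, "\n")
  cat("  distractor strength =", x$distractor_strength,
      " repeated capture =", if (is.null(x$repeated_capture)) "off" else x$repeated_capture,
      " duration cv =", x$duration_cv, "\n")
  cat("  decay:", if (x$decay_enabled) "on" else "OFF",
      " refreshing:", if (x$refresh_enabled) "on" else "OFF", "\n")
  invisible(x)
}

# effective decay rate: 0 under the no-decay ablation
decay_rate <- function(params) if (params$decay_enabled) params$D else 0

# Gaussian draws floored at a minimum; floor keeps one RNG draw per value so
# the R and compiled paths consume identical stream lengths.
draw_duration <- function(mean, params, floor = 0.01) {
  if (mean <= 0) return(0)
  max(floor, stats::rnorm(1, mean, params$duration_cv * mean))
}
draw_rate <- function(params) max(0.1, stats::rnorm(1, params$R, params$s))

#' Overlapping positional context code
#'
#' Serial positions are coded by sets of position units; adjacent positions
#' share a fixed proportion of their units so that neighbouring positions are
#' partially confusable, while non-adjacent positions share none. Position
#' `i` occupies a window of `units_per_position` consecutive unit indices
#' advanced by `units_per_position - shared` per step, which realises exactly
#' `round(overlap_adjacent * units_per_position)` shared units between
#' neighbours and zero beyond (as long as overlap < 1/2).
#'
#' @param n_positions Number of serial positions (default 9, the maximum list
#'   length of the benchmark grid).
#' @param units_per_position Units coding each position.
#' @param overlap_adjacent Proportion of units shared by adjacent positions.
#' @return An object of class `wm_positions`: `sets` (list of unit-index
#'   vectors) and `n_units` (total position units).
#' @export
#' @examples
#' pc <- position_code()
#' intersect(pc$sets[[1]], pc$sets[[2]])
position_code <- function(n_positions = 9, units_per_position = 16,
                          overlap_adjacent = 0.3) {
  stopifnot(n_positions >= 1, units_per_position >= 1,
            overlap_adjacent >= 0, overlap_adjacent < 0.5)
  shared <- round(overlap_adjacent * units_per_position)
  stride <- units_per_position - shared
  sets <- lapply(seq_len(n_positions) - 1L,
                 function(i) seq.int(i * stride + 1L, i * stride + units_per_position))
  structure(list(sets = sets, n_positions = n_positions,
                 units_per_position = units_per_position,
                 overlap_adjacent = overlap_adjacent,
                 n_shared = shared,
                 n_units = (n_positions - 1L) * stride + units_per_position),
            class = "wm_positions")
}

#' @export
print.wm_positions <- function(x, ...) {
  cat("<wm_positions>", x$n_positions, "positions x", x$units_per_position,
      "units,", x$n_shared, "shared between neighbours\n")
  invisible(x)
}

#' Initialise an empty working-memory state
#'
#' The mutable state of a trial: the item-by-position-unit association weight
#' matrix (all zeros before anything is presented), the working-memory copies
#' of item representations (initialised to the long-term engrams and only
#' meaningful once an item has been presented), the identity of the
#' last-presented memorandum (the target of distractor interference), and the
#' simulated clock.
#'
#' @param lexicon A [generate_lexicon()] result; also the retrieval candidate
#'   pool.
#' @param positions A [position_code()].
#' @param params A [model_params()].
#' @return An object of class `wm_state`.
#' @export
wm_state <- function(lexicon, positions = position_code(),
                     params = model_params()) {
  stopifnot(inherits(lexicon, "wm_lexicon"), inherits(positions, "wm_positions"))
  n_items <- lexicon_size(lexicon)
  wm_values <- lexicon$values
  wm_values[is.na(wm_values)] <- 0  # dense copy; masks live in the lexicon
  structure(
    list(weights = matrix(0, n_items, positions$n_units),
         wm_values = wm_values,
         presented = logical(n_items),
         last_presented = NA_integer_,
         clock = 0,
         refresh_steps = 0L,
         positions = positions, params = params, lexicon = lexicon),
    class = "wm_state"
  )
}

#' @export
print.wm_state <- function(x, ...) {
  cat("<wm_state> t =", round(x$clock, 3), "s,",
      sum(x$presented), "items presented,",
      x$refresh_steps, "refresh steps\n")
  invisible(x)
}

#' Exponential decay of all association weights
#'
#' Every item-position weight is multiplied by `exp(-D * duration)` and the
#' clock advances. A no-op (apart from the clock) when decay is disabled or
#' `D = 0`. Because the exponential is a semigroup, splitting an interval
#' into sub-intervals yields identical weights.
#'
#' @param state A `wm_state`.
#' @param duration Elapsed time in seconds (non-negative).
#' @return The updated `wm_state`.
#' @export
decay <- function(state, duration) {
  stopifnot(inherits(state, "wm_state"), duration >= 0)
  d <- decay_rate(state$params)
  if (d > 0 && duration > 0) state$weights <- state$weights * exp(-d * duration)
  state$clock <- state$clock + duration
  state
}

# shared saturating-growth law for encode/reactivate:
# w <- A - (A - w) * exp(-rate * duration), asymptote A = strength
saturate <- function(w, rate, duration, strength) {
  strength - (strength - w) * exp(-rate * duration)
}

#' Encode an item at a serial position
#'
#' While attention is on the presented item, the weights between the item and
#' the current position's units grow toward an asymptote equal to `strength`
#' following a saturating exponential in time,
#' `w <- A - (A - w) exp(-rate * duration)` with `A = strength`; meanwhile
#' all other weights decay for the same interval. On first presentation the
#' item's working-memory copy is (re)set to its long-term engram. Memoranda
#' are encoded at full strength; distractors at `distractor_strength`.
#'
#' @param state A `wm_state`.
#' @param item Item index (or id) in the lexicon.
#' @param position Serial position (1-based).
#' @param duration Encoding duration in seconds.
#' @param rate Processing rate (1/s); defaults to a fresh draw from
#'   `N(R, s)` floored at 0.1.
#' @param strength Asymptotic weight (1 for memoranda).
#' @param update_last Whether this presentation becomes the target of
#'   subsequent distractor interference (`TRUE` for real presentations,
#'   `FALSE` for refreshing reactivations).
#' @return The updated `wm_state`.
#' @export
#' @examples
#' lex <- generate_lexicon(stimulus_spec(), seed = 1)
#' st <- wm_state(lex)
#' st <- encode(st, 1, 1, duration = 0.5, rate = 6)
#' sum(st$weights[1, st$positions$sets[[1]]])  # 16 * (1 - exp(-3))
encode <- function(state, item, position, duration, rate = draw_rate(state$params),
                   strength = 1, update_last = TRUE) {
  stopifnot(inherits(state, "wm_state"))
  if (duration < 0) stop("negative encoding duration")
  if (is.character(item)) item <- match(item, state$lexicon$item_id)
  stopifnot(position >= 1, position <= state$positions$n_positions)
  state <- decay(state, duration)
  units <- state$positions$sets[[position]]
  state$weights[item, units] <-
    saturate(state$weights[item, units], rate, duration, strength)
  if (!state$presented[item]) {
    v <- state$lexicon$values[item, ]
    v[is.na(v)] <- 0
    state$wm_values[item, ] <- v
    state$presented[item] <- TRUE
  }
  if (update_last && !state$lexicon$is_distractor[item]) {
    state$last_presented <- as.integer(item)
  }
  state
}

#' Reactivate an item-position binding during refreshing
#'
#' The binding-strengthening half of refreshing: identical to [encode()] with
#' strength 1 but over the (much shorter) refreshing step duration. A no-op
#' when refreshing is disabled.
#'
#' @inheritParams encode
#' @return The updated `wm_state`; unchanged (a true no-op) when refreshing
#'   is disabled, since a disabled system never initiates the step.
#' @export
reactivate <- function(state, item, position, duration,
                       rate = draw_rate(state$params)) {
  if (!state$params$refresh_enabled) return(state)
  encode(state, item, position, duration, rate, strength = 1,
         update_last = FALSE)
}

#' Distort a working-memory representation by a distractor
#'
#' Interference by superposition/confusion: on every unit used by *both* the
#' working-memory copy and the distractor, the value is set halfway between
#' the two (their average). Units used by only one of the vectors are
#' untouched. Applying the same distractor n times leaves a gap to the
#' distractor value that shrinks as 2^-n.
#'
#' @param wm_copy A `wm_item`: the current working-memory representation.
#' @param distractor A `wm_item` with the same number of units.
#' @return The distorted `wm_item`.
#' @export
#' @examples
#' m <- item_vector(c(NA, 0.64, 0.33, 0.17, NA))
#' d <- item_vector(c(NA, NA, NA, 0.41, 0.9))
#' interfere(m, d)$values  # only unit 4 moves, to (0.17 + 0.41) / 2
interfere <- function(wm_copy, distractor) {
  stopifnot(inherits(wm_copy, "wm_item"), inherits(distractor, "wm_item"),
            wm_copy$n_units == distractor$n_units)
  shared <- wm_copy$mask & distractor$mask
  wm_copy$values[shared] <- (wm_copy$values[shared] + distractor$values[shared]) / 2
  wm_copy
}

#' Restore a working-memory representation from long-term memory
#'
#' The representation-repair half of refreshing: the closest stable engram
#' is identified by [identify_ltm()], and every unit shared between the
#' working-memory copy and that engram is averaged halfway toward the engram
#' value -- the same operator as [interfere()] pointed at long-term memory
#' instead of a distractor. If distortion has crossed the decision boundary,
#' restoration converges on the *wrong* engram.
#'
#' @param wm_copy A `wm_item`.
#' @param lexicon The `wm_lexicon` holding the candidate engrams.
#' @param candidates Candidate engram pool, see [identify_ltm()].
#' @return The restored `wm_item`, with attribute `"target"` giving the index
#'   of the engram used.
#' @export
restore <- function(wm_copy, lexicon, candidates = c("memoranda", "all")) {
  stopifnot(inherits(wm_copy, "wm_item"), inherits(lexicon, "wm_lexicon"))
  target <- identify_ltm(wm_copy, lexicon, candidates)
  engram <- lexicon_item(lexicon, target)
  out <- interfere(wm_copy, engram)
  attr(out, "target") <- target
  out
}

#' Identify the long-term engram of a working-memory object
#'
#' Returns the lexicon index whose engram minimises [ltm_distance()] to the
#' given (possibly distorted) working-memory object. By default the
#' candidate engrams are the memoranda: restoration and recall output map a
#' degraded memorandum representation back onto the stable memoranda
#' knowledge it came from (distractor intrusions arise at the
#' binding-competition step of [retrieve()], where the full pool competes).
#' Ties are broken by the lowest item index, with a message.
#'
#' @param wm_object A `wm_item`.
#' @param lexicon A `wm_lexicon`.
#' @param candidates `"memoranda"` (default) or `"all"` to also consider
#'   distractor engrams.
#' @return The winning item index (integer).
#' @export
identify_ltm <- function(wm_object, lexicon,
                         candidates = c("memoranda", "all")) {
  candidates <- match.arg(candidates)
  idx <- if (candidates == "memoranda") which(!lexicon$is_distractor)
         else seq_len(lexicon_size(lexicon))
  d <- vapply(idx,
              function(i) ltm_distance(wm_object, lexicon_item(lexicon, i)),
              numeric(1))
  winners <- idx[which(d == min(d))]
  if (length(winners) > 1) {
    message("identify_ltm: ", length(winners),
            "-way distance tie; keeping lowest index ", winners[1])
  }
  winners[1]
}

#' Retrieve the item best bound to a position
#'
#' Every lexicon item -- presented or not -- is a candidate. Each candidate's
#' activation is the sum of its association weights over the position's
#' units; independent Gaussian noise (`sigma`) is added to every activation
#' and the noisy maximum wins. If the winner's *noiseless* activation is
#' below the threshold `theta`, retrieval fails (an omission). Otherwise the
#' winner's current working-memory object is returned: the (possibly
#' distorted) copy for presented items, the intact engram for never-presented
#' candidates.
#'
#' @param state A `wm_state`.
#' @param position Serial position to cue with.
#' @param params Parameters (defaults to the state's).
#' @return A list: `item` (index, or `NA` on omission), `omission`,
#'   `activation` (winner's noiseless activation), `wm_object` (a `wm_item`
#'   or `NULL`).
#' @export
retrieve <- function(state, position, params = state$params) {
  stopifnot(inherits(state, "wm_state"),
            position >= 1, position <= state$positions$n_positions)
  n <- nrow(state$weights)
  if (n == 0) stop("empty candidate pool")
  units <- state$positions$sets[[position]]
  act <- rowSums(state$weights[, units, drop = FALSE])
  noisy <- act + stats::rnorm(n, 0, params$sigma)
  winner <- which.max(noisy)
  if (act[winner] < params$theta) {
    return(list(item = NA_integer_, omission = TRUE,
                activation = act[winner], wm_object = NULL))
  }
  wm <- item_vector(ifelse(state$lexicon$mask[winner, ],
                           state$wm_values[winner, ], NA_real_),
                    state$lexicon$mask[winner, ],
                    item_id = state$lexicon$item_id[winner],
                    is_distractor = state$lexicon$is_distractor[winner])
  list(item = winner, omission = FALSE, activation = act[winner], wm_object = wm)
}

# wm copy of item i as a wm_item (helper shared by task code)
wm_copy_of <- function(state, i) {
  item_vector(ifelse(state$lexicon$mask[i, ], state$wm_values[i, ], NA_real_),
              state$lexicon$mask[i, ],
              item_id = state$lexicon$item_id[i],
              is_distractor = state$lexicon$is_distractor[i])
}
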