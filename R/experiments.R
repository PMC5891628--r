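#' Specify a factorial simulation grid
#'
#' The benchmark study crosses seven factors: number of distractors per
#' burst, distractor capture duration, free time, memoranda-distractor
#' overlap and distance, distractor homogeneity, and list length. The
#' published levels (the defaults here) give 4 x 3 x 5 x 6 x 7 x 2 x 9 =
#' 45,360 cases; any subset of levels defines a smaller grid. Each case is
#' simulated `runs_per_case` times with seeds derived deterministically from
#' the grid seed and the case index, so results are reproducible and
#' variants can be compared with common random numbers.
#'
#' @param nd,dac,ft,mdo,mdd,hod,list_length Factor levels (vectors).
#' @param runs_per_case Monte-Carlo runs per case.
#' @param seed Base seed for the case-wise seed sequence.
#' @param variant Model variant: `"full"`, `"no_decay"` (decay rate 0),
#'   `"no_refresh"` (refreshing disabled), or `"reduced_repeated_capture"`
#'   (repeated distractors after the first of a burst captured for only
#'   50 ms).
#' @return An object of class `wm_grid_spec`.
#' @export
#' @examples
#' grid_spec()$n_cases  # 45360
grid_spec <- function(nd = c(0, 1, 4, 8), dac = c(0.3, 0.5, 0.7),
                      ft = c(0, 0.1, 0.6, 1.2, 2.0),
                      mdo = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                      mdd = c(0, 0.5, 1, 1.5, 2, 2.5, 3),
                      hod = c("identical", "distinct"),
                      list_length = 1:9,
                      runs_per_case = 20, seed = 1,
                      variant = c("full", "no_decay", "no_refresh",
                                  "reduced_repeated_capture")) {
  variant <- match.arg(variant)
  stopifnot(runs_per_case >= 1, all(hod %in% c("identical", "distinct")),
            all(list_length >= 1), all(nd >= 0))
  levels <- list(nd = nd, dac = dac, ft = ft, mdo = mdo, mdd = mdd,
                 hod = hod, list_length = sort(as.integer(list_length)))
  structure(
    list(levels = levels,
         n_cases = prod(vapply(levels, length, integer(1))),
         runs_per_case = as.integer(runs_per_case),
         seed = as.integer(seed), variant = variant),
    class = "wm_grid_spec"
  )
}

#' @export
print.wm_grid_spec <- function(x, ...) {
  cat("<wm_grid_spec>", x$n_cases, "cases x", x$runs_per_case,
      "runs, variant:", x$variant, "seed:", x$seed, "\n")
  invisible(x)
}

#' Case table of a grid specification
#'
#' @param grid A [grid_spec()].
#' @return A tibble with one row per factor combination, in the order used
#'   for the case-wise seed sequence, with a `case` index column.
#' @export
grid_cases <- function(grid) {
  stopifnot(inherits(grid, "wm_grid_spec"))
  lv <- grid$levels
  out <- tidyr::crossing(
    list_length = lv$list_length, nd = lv$nd, dac = lv$dac, ft = lv$ft,
    mdo = lv$mdo, mdd = lv$mdd, hod = lv$hod
  )
  dplyr::mutate(out, case = dplyr::row_number(), .before = 1)
}

# deterministic per-case seed, kept inside 32-bit integer range
case_seed <- function(seed, case) {
  as.integer((as.numeric(seed) + as.numeric(case) * 1000003) %% 2147483647L) + 1L
}

# apply a grid variant to a parameter set
variant_params <- function(params, variant) {
  switch(variant,
    full = params,
    no_decay = { params$decay_enabled <- FALSE; params },
    no_refresh = { params$refresh_enabled <- FALSE; params },
    reduced_repeated_capture = { params$repeated_capture <- 0.05; params }
  )
}

# parameter list in the form the compiled engine expects
par_for_engine <- function(params) {
  p <- unclass(params)
  p$repeated_capture <- if (is.null(p$repeated_capture)) -1 else p$repeated_capture
  p
}

#' Run a factorial simulation grid
#'
#' Simulates every factor combination of the grid `runs_per_case` times and
#' returns per-case mean recall plus span scores. Spans sum the mean
#' proportion correct over the grid's list lengths within each combination
#' of the remaining factors (with the full 1-9 lengths this is the usual
#' 0-9 span score). Each case gets its own seed derived from
#' `(seed, case index)`, so the result is independent of execution order and
#' identical across variants at the level of random-number streams.
#'
#' @param grid A [grid_spec()].
#' @param params A [model_params()]; the grid's `variant` is applied on top.
#' @param engine `"compiled"` (the C++ engine; default) or `"r"` (the pure-R
#'   trial runner; only sensible for very small grids).
#' @param positions A [position_code()] covering the longest list.
#' @param stimulus Base [stimulus_spec()] supplying pool sizes; its
#'   `mdo`/`mdd`/`hod` are overridden per case.
#' @param progress Print progress messages every ~10% of cases.
#' @return An object of class `wm_grid`: tibbles `cases` (factors +
#'   `mean_pc`) and `spans` (factors + `span` + nominal `cl`), plus the spec,
#'   parameters and variant.
#' @export
#' @examples
#' g <- grid_spec(nd = c(0, 4), dac = 0.5, ft = c(0, 0.6), mdo = 0, mdd = 0,
#'                hod = "distinct", list_length = c(2, 5), runs_per_case = 5)
#' r <- run_grid(g)
#' r$spans
run_grid <- function(grid, params = model_params(),
                     engine = c("compiled", "r"),
                     positions = position_code(
                       n_positions = max(grid$levels$list_length)),
                     stimulus = stimulus_spec(), progress = FALSE) {
  stopifnot(inherits(grid, "wm_grid_spec"))
  engine <- match.arg(engine)
  params <- variant_params(params, grid$variant)
  cases <- grid_cases(grid)
  mean_pc <- numeric(nrow(cases))
  par <- par_for_engine(params)
  t0 <- Sys.time()
  tick <- max(1L, nrow(cases) %/% 10L)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    set.seed(case_seed(grid$seed, cs$case))
    if (engine == "compiled") {
      props <- engine_run_case(
        grid$runs_per_case, cs$list_length, cs$nd, cs$dac, cs$ft,
        cs$mdo, cs$mdd, cs$hod == "identical", par,
        positions$sets, positions$n_units,
        stimulus$n_memoranda, stimulus$domain_size
      )
    } else {
      cfg <- trial_config(cs$list_length, cs$nd, cs$dac, cs$ft,
                          cs$mdo, cs$mdd, cs$hod, params = params)
      props <- vapply(seq_len(grid$runs_per_case), function(run) {
        run_trial(cfg, positions = positions)$proportion_correct
      }, numeric(1))
    }
    mean_pc[i] <- mean(props)
    if (progress && i %% tick == 0) {
      message(sprintf("run_grid: %d/%d cases (%.1f s)", i, nrow(cases),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  cases$mean_pc <- mean_pc
  spans <- cases |>
    dplyr::group_by(dplyr::across(c("nd", "dac", "ft", "mdo", "mdd", "hod"))) |>
    dplyr::summarise(span = sum(.data$mean_pc),
                     n_lengths = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(cl = round(cognitive_load(.data$dac, .data$ft), 10))
  structure(
    list(cases = tibble::as_tibble(cases), spans = spans, spec = grid,
         params = params, variant = grid$variant, seed = grid$seed,
         runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "wm_grid"
  )
}

#' @export
print.wm_grid <- function(x, ...) {
  cat("<wm_grid>", nrow(x$cases), "cases x", x$spec$runs_per_case,
      "runs, variant:", x$variant, "\n")
  cat("  grand mean span:", round(mean(x$spans$span), 3),
      " (", nrow(x$spans), "span records )\n")
  invisible(x)
}

#' Span score from per-length recall proportions
#'
#' The span score of a factor combination is the sum over list lengths 1-9
#' of the mean proportion of memoranda recalled in correct position, a
#' number between 0 and 9.
#'
#' @param proportions_by_length Numeric vector of mean proportions correct.
#'   If named, names must be the list lengths; all of 1-9 must be present.
#' @return The span (scalar).
#' @export
#' @examples
#' span_score(c(1, 1, 1, 0.5, 0.5, 0, 0, 0, 0))  # 4
span_score <- function(proportions_by_length) {
  x <- proportions_by_length
  if (!is.null(names(x))) {
    idx <- suppressWarnings(as.integer(names(x)))
    if (anyNA(idx) || !setequal(idx, 1:9)) {
      stop("span_score needs proportions for every list length 1..9")
    }
    x <- x[order(idx)]
  } else if (length(x) != 9) {
    stop("span_score needs proportions for every list length 1..9")
  }
  stopifnot(all(x >= 0 & x <= 1))
  sum(x)
}

#' Tidy span records of a grid run
#' @param x A `wm_grid`.
#' @param ... Unused.
#' @return The span tibble (one row per non-length factor combination).
#' @export
tidy.wm_grid <- function(x, ...) x$spans

#' One-row summary of a grid run
#' @param x A `wm_grid`.
#' @param ... Unused.
#' @return A tibble with case/run counts, variant, seed and grand means.
#' @export
glance.wm_grid <- function(x, ...) {
  tibble::tibble(
    n_cases = nrow(x$cases), runs_per_case = x$spec$runs_per_case,
    variant = x$variant, seed = x$seed,
    mean_span = mean(x$spans$span), mean_pc = mean(x$cases$mean_pc),
    runtime_s = x$runtime_s
  )
}

#' Aggregate span scores over grid factors
#'
#' Grouped means of the span score by any subset of the grid factors, or by
#' the derived cognitive load (`by = "cl"`, computed from the nominal `dac`
#' and `ft` levels). This is the marginalisation behind the benchmark
#' figures: span as a function of cognitive load, of the number of
#' distractors by homogeneity, of overlap, and so on.
#'
#' @param grid A `wm_grid` (or its span tibble).
#' @param by Character vector of grouping columns among
#'   `nd, dac, ft, mdo, mdd, hod, cl`; `NULL` gives the grand mean.
#' @param ci Add a percentile bootstrap confidence interval on each mean
#'   (resampling span records within group)?
#' @param boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @return A tibble of group means (`mean_span`, `n_records`, optionally
#'   `lower`/`upper`).
#' @export
#' @examples
#' g <- run_grid(grid_spec(nd = c(0, 4), dac = 0.5, ft = c(0, 0.6), mdo = 0,
#'                         mdd = 0, hod = "distinct", list_length = c(2, 5),
#'                         runs_per_case = 5))
#' aggregate_spans(g, by = "nd")
aggregate_spans <- function(grid, by = "cl", ci = FALSE, boot = 200,
                            conf = 0.95) {
  spans <- if (inherits(grid, "wm_grid")) grid$spans else grid
  stopifnot(is.data.frame(spans), "span" %in% names(spans))
  if (!is.null(by)) {
    bad <- setdiff(by, c(names(spans), "cl"))
    if (length(bad)) stop("unknown factor name(s): ", paste(bad, collapse = ", "))
    if ("cl" %in% by && !"cl" %in% names(spans)) {
      spans <- dplyr::mutate(spans, cl = cognitive_load(.data$dac, .data$ft))
    }
  }
  grouped <- if (is.null(by)) spans
             else dplyr::group_by(spans, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(grouped, mean_span = mean(.data$span),
                          n_records = dplyr::n(), .groups = "drop")
  if (ci) {
    alpha <- (1 - conf) / 2
    boot_q <- function(x, prob) {
      means <- vapply(seq_len(boot),
                      function(b) mean(sample(x, replace = TRUE)), numeric(1))
      stats::quantile(means, prob, names = FALSE)
    }
    boots <- dplyr::summarise(grouped,
                              lower = boot_q(.data$span, alpha),
                              upper = boot_q(.data$span, 1 - alpha),
                              .groups = "drop")
    out <- if (is.null(by)) dplyr::bind_cols(out, boots)
           else dplyr::left_join(out, boots, by = by)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Meta-analytic span-by-cognitive-load reference line
#'
#' The linear relationship between mean memory span and cognitive load
#' estimated from a meta-analysis of human complex span experiments,
#' `span = intercept + slope * cl`, used as an overlay when comparing
#' simulated spans with human data.
#'
#' @param cl Cognitive-load values at which to evaluate the line.
#' @param slope,intercept Coefficients (defaults -8.33 and 8.13).
#' @return A tibble with `cl` and `span`.
#' @export
cl_reference_line <- function(cl = seq(0.1, 1, by = 0.01),
                              slope = -8.33, intercept = 8.13) {
  tibble::tibble(cl = cl, span = intercept + slope * cl)
}
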