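#' Describe a stimulus set for a complex span simulation
#'
#' A stimulus specification controls how a lexicon of memoranda and
#' distractors is generated, in particular the two properties that drive
#' interference between distractors and memoranda:
#'
#' * `mdo` (memoranda-distractor overlap) is the proportion of a distractor's
#'   feature units that fall inside the memoranda feature domain. Overlapping
#'   units are the channel for *interference by confusion*: only shared units
#'   can be distorted by a distractor.
#' * `mdd` (memoranda-distractor distance) is the standard deviation of the
#'   value difference between a distractor and the memoranda pool reference
#'   on shared units, the channel for *interference by superposition*:
#'   distant values distort more when superposed.
#'
#' Items are abstract feature vectors: each item uses a subset of `n_units`
#' feature units and carries a real value on each used unit. All memoranda
#' use one common contiguous block of `domain_size` units (their "domain"),
#' with values drawn independently and uniformly on \[0, 1\]. Each distractor
#' type uses `domain_size` units as well: `round(mdo * domain_size)` units
#' sampled inside the domain and the remainder outside it.
#'
#' @param mdo Proportion of distractor units overlapping the memoranda
#'   domain, in \[0, 1\]. The benchmark grid uses 0, 0.2, 0.4, 0.6, 0.8, 1.
#' @param mdd Standard deviation of the distractor-minus-reference value on
#'   shared units (non-negative; grid levels 0 to 3 by 0.5).
#' @param hod Homogeneity of distractors within a trial: `"distinct"` (every
#'   distractor token in a trial is a different type) or `"identical"` (one
#'   type repeated throughout the trial).
#' @param n_memoranda Size of the memoranda pool (the "alphabet" from which
#'   lists are sampled and which competes at retrieval). Default 26.
#' @param n_distractor_types Number of distractor types to generate.
#' @param n_units Total number of feature units per item. Default 64.
#' @param domain_size Number of units used by each item. Default 16.
#'
#' @return An object of class `wm_stimulus_spec` (a validated list).
#' @seealso [generate_lexicon()]
#' @export
#' @examples
#' stimulus_spec(mdo = 0.5, mdd = 1, hod = "distinct")
stimulus_spec <- function(mdo = 0, mdd = 0, hod = c("distinct", "identical"),
                          n_memoranda = 26, n_distractor_types = 8,
                          n_units = 64, domain_size = 16) {
  hod <- match.arg(hod)
  stopifnot(
    length(mdo) == 1, mdo >= 0, mdo <= 1,
    length(mdd) == 1, mdd >= 0,
    n_memoranda >= 1, n_distractor_types >= 0,
    n_units >= 1, domain_size >= 1, domain_size <= n_units
  )
  k <- mdo * domain_size
  if (abs(k - round(k)) > 1e-8) {
    message("mdo * domain_size = ", signif(k, 4),
            " is not an integer; rounding shared-unit count to ", round(k))
  }
  # non-overlapping distractor units must fit outside the domain
  if (n_units - domain_size < domain_size - round(k)) {
    stop("n_units too small: ", domain_size - round(k),
         " non-overlapping distractor units requested but only ",
         n_units - domain_size, " units lie outside the memoranda domain")
  }
  structure(
    list(mdo = mdo, mdd = mdd, hod = hod,
         n_memoranda = as.integer(n_memoranda),
         n_distractor_types = as.integer(n_distractor_types),
         n_units = as.integer(n_units),
         domain_size = as.integer(domain_size),
         n_shared = as.integer(round(k))),
    class = "wm_stimulus_spec"
  )
}

#' @export
print.wm_stimulus_spec <- function(x, ...) {
  cat("<wm_stimulus_spec>\n")
  cat(sprintf("  %d memoranda + %d distractor types on %d units (domain %d)\n",
              x$n_memoranda, x$n_distractor_types, x$n_units, x$domain_size))
  cat(sprintf("  MDO = %g (%d shared units), MDD = %g, HOD = %s\n",
              x$mdo, x$n_shared, x$mdd, x$hod))
  invisible(x)
}

#' Construct a single distributed item representation
#'
#' An item vector carries a value on each feature unit it uses; unused units
#' are `NA` and masked out. Item vectors are the working currency of the
#' interference machinery: [interfere()] and [restore()] average unit values
#' on shared units, and [ltm_distance()] compares vectors.
#'
#' @param values Numeric vector of unit values; `NA` marks unused units
#'   unless `mask` is given explicitly.
#' @param mask Logical vector flagging used units. Defaults to `!is.na(values)`.
#' @param item_id Identifier string.
#' @param is_distractor Flag.
#' @return An object of class `wm_item`.
#' @export
#' @examples
#' item_vector(c(NA, NA, 0.64, 0.33, NA), item_id = "F")
item_vector <- function(values, mask = !is.na(values), item_id = "item",
                        is_distractor = FALSE) {
  stopifnot(is.numeric(values), length(mask) == length(values), is.logical(mask))
  values[!mask] <- NA_real_
  if (anyNA(values[mask])) stop("NA value on a used unit")
  structure(list(values = as.numeric(values), mask = mask,
                 n_units = length(values), item_id = item_id,
                 is_distractor = isTRUE(is_distractor)),
            class = "wm_item")
}

#' @export
print.wm_item <- function(x, digits = 2, ...) {
  v <- ifelse(x$mask, format(round(x$values, digits)), "-")
  cat("<wm_item ", x$item_id, if (x$is_distractor) " (distractor)", ">\n",
      paste(v, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Generate a lexicon of memoranda and distractors
#'
#' Draws a memoranda pool and a set of distractor types under the overlap and
#' distance constraints of a [stimulus_spec()]. Memoranda values are i.i.d.
#' uniform on \[0, 1\] over the common domain block. For each distractor type,
#' `round(mdo * domain_size)` shared units are sampled from the domain, and on
#' each shared unit the distractor value is the memoranda-pool reference value
#' (the per-unit mean over the pool) plus zero-mean Gaussian noise with
#' standard deviation `mdd`, truncated to the \[0, 1\] feature scale that all
#' item values live on (so large `mdd` drives distractor values toward the
#' extremes of the scale rather than off it); the remaining units lie outside
#' the domain with uniform values.
#'
#' The lexicon doubles as the long-term-memory store: its item vectors are the
#' immutable engrams against which working-memory copies are restored and
#' identified, and the full lexicon (including never-presented items) is the
#' candidate pool at retrieval.
#'
#' @param spec A [stimulus_spec()].
#' @param seed Optional integer seed for reproducible generation.
#' @return An object of class `wm_lexicon`: matrices `values` (items x units,
#'   `NA` on unused units) and `mask`, vectors `item_id` and `is_distractor`,
#'   the `domain` unit indices, per-type shared-unit indices, and the spec.
#' @export
#' @examples
#' lex <- generate_lexicon(stimulus_spec(mdo = 0.5, mdd = 1), seed = 1)
#' lexicon_item(lex, 1)
generate_lexicon <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "wm_stimulus_spec"))
  if (!is.null(seed)) set.seed(seed)
  nu <- spec$n_units; ds <- spec$domain_size
  domain <- seq_len(ds)
  outside <- setdiff(seq_len(nu), domain)
  nm <- spec$n_memoranda; ndt <- spec$n_distractor_types
  k <- spec$n_shared

  values <- matrix(NA_real_, nrow = nm + ndt, ncol = nu)
  mask <- matrix(FALSE, nrow = nm + ndt, ncol = nu)
  values[seq_len(nm), domain] <- stats::runif(nm * ds)
  mask[seq_len(nm), domain] <- TRUE
  reference <- colMeans(values[seq_len(nm), domain, drop = FALSE])

  shared_units <- vector("list", ndt)
  for (j in seq_len(ndt)) {
    i <- nm + j
    sh <- sort(sample(domain, k))
    out <- sort(sample(outside, ds - k))
    shared_units[[j]] <- sh
    if (k > 0) {
      values[i, sh] <- pmin(1, pmax(0, reference[sh] + stats::rnorm(k, 0, spec$mdd)))
    }
    if (ds - k > 0) values[i, out] <- stats::runif(ds - k)
    mask[i, c(sh, out)] <- TRUE
  }

  structure(
    list(values = values, mask = mask,
         item_id = c(sprintf("M%02d", seq_len(nm)),
                     if (ndt > 0) sprintf("D%02d", seq_len(ndt))),
         is_distractor = c(rep(FALSE, nm), rep(TRUE, ndt)),
         domain = domain, reference = reference,
         shared_units = shared_units, seed = seed, spec = spec),
    class = "wm_lexicon"
  )
}

#' @export
print.wm_lexicon <- function(x, ...) {
  cat("<wm_lexicon> ", sum(!x$is_distractor), " memoranda, ",
      sum(x$is_distractor), " distractor types, ",
      ncol(x$values), " units\n", sep = "")
  invisible(x)
}

#' Number of items in a lexicon
#' @param lexicon A `wm_lexicon`.
#' @return Integer count of items (memoranda plus distractor types).
#' @export
lexicon_size <- function(lexicon) length(lexicon$item_id)

#' Extract one item of a lexicon as a `wm_item`
#' @param lexicon A `wm_lexicon`.
#' @param i Item index or id string.
#' @return A [item_vector()].
#' @export
lexicon_item <- function(lexicon, i) {
  if (is.character(i)) i <- match(i, lexicon$item_id)
  item_vector(lexicon$values[i, ], lexicon$mask[i, ],
              item_id = lexicon$item_id[i],
              is_distractor = lexicon$is_distractor[i])
}

#' Mean squared distance between two distributed representations
#'
#' The distance used both to identify the long-term engram corresponding to a
#' (possibly distorted) working-memory object and to restore it: the mean
#' squared value difference over the union of the units used by either
#' vector. A unit used by only one vector contributes that vector's squared
#' value (the other side is absent, i.e. zero). The function is symmetric,
#' non-negative, and zero exactly for identical used-unit sets and values.
#'
#' @param a,b `wm_item` objects with the same number of units.
#' @return A non-negative scalar.
#' @export
#' @examples
#' a <- item_vector(c(0.2, 0.4)); b <- item_vector(c(0.2, 0.8))
#' ltm_distance(a, b)  # ((0)^2 + (0.4)^2) / 2 = 0.08
ltm_distance <- function(a, b) {
  stopifnot(inherits(a, "wm_item"), inherits(b, "wm_item"),
            a$n_units == b$n_units)
  union_mask <- a$mask | b$mask
  if (!any(union_mask)) return(0)
  va <- ifelse(a$mask, a$values, 0)
  vb <- ifelse(b$mask, b$values, 0)
  mean((va[union_mask] - vb[union_mask])^2)
}

#' Write / read a lexicon as JSON
#'
#' Round-trips the full lexicon (values, masks, ids, domain, shared units,
#' generation seed) through a plain-text JSON file, for fixtures and for
#' archiving the exact stimuli of a simulation.
#'
#' @param lexicon A `wm_lexicon`.
#' @param path File path.
#' @return `write_lexicon_json()` returns `path` invisibly;
#'   `read_lexicon_json()` returns a `wm_lexicon`.
#' @export
write_lexicon_json <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "wm_lexicon"))
  payload <- list(
    values = lexicon$values, mask = lexicon$mask,
    item_id = lexicon$item_id, is_distractor = lexicon$is_distractor,
    domain = lexicon$domain, reference = lexicon$reference,
    shared_units = lexicon$shared_units, seed = lexicon$seed,
    spec = unclass(lexicon$spec)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_lexicon_json
#' @export
read_lexicon_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(stimulus_spec, p$spec[c("mdo", "mdd", "hod", "n_memoranda",
                                          "n_distractor_types", "n_units",
                                          "domain_size")])
  vals <- as.matrix(p$values); vals[is.na(vals)] <- NA_real_
  sh <- p$shared_units
  if (is.matrix(sh)) sh <- lapply(seq_len(nrow(sh)), function(i) sh[i, ])
  if (is.null(sh)) sh <- list()
  structure(
    list(values = vals, mask = as.matrix(p$mask),
         item_id = p$item_id, is_distractor = p$is_distractor,
         domain = p$domain, reference = p$reference,
         shared_units = lapply(sh, as.integer),
         seed = p$seed, spec = spec),
    class = "wm_lexicon"
  )
}
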