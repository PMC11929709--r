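#' Adaptive search interval for hard-pixel mining
#'
#' Hard (relatively worse predicted) pixels are those whose own-class
#' probability lies strictly inside `(lower, upper)`. The interval starts at
#' `(0.5, 0.55)` and is widened in increments of `step` until enough
#' candidates exist: the upper bound rises when the class contains correctly
#' predicted pixels, the lower bound falls when every pixel of the class is
#' mispredicted (own-class probability below 0.5).
#'
#' @param lower,upper Initial bounds, `0 <= lower < upper <= 1`.
#' @param step Widening increment, `> 0`.
#' @return An object of class `search_interval`.
#' @export
search_interval <- function(lower = 0.5, upper = 0.55, step = 0.05) {
  if (!(is.numeric(lower) && is.numeric(upper) && is.numeric(step))) {
    stop_antl("interval bounds and step must be numeric")
  }
  if (!(lower >= 0 && lower < upper && upper <= 1)) {
    stop_antl("search interval requires 0 <= lower < upper <= 1")
  }
  if (step <= 0) stop_antl("interval step must be positive")
  structure(
    list(lower = lower, upper = upper, step = step),
    class = "search_interval"
  )
}

new_pixel_selection <- function(class_id, kind, pixels) {
  structure(
    list(class_id = class_id, kind = kind, pixels = pixels),
    class = "pixel_selection"
  )
}

empty_pixels_df <- function() {
  data.frame(row = integer(0), col = integer(0), value = numeric(0))
}

#' Select the k best-predicted pixels of one class
#'
#' Ranks the class support by own-class probability and keeps the top `k`.
#' Ties at the k-th rank are broken deterministically by ascending row-major
#' coordinate. If the support holds fewer than `k` pixels the whole support
#' is returned with a warning; an empty support yields an empty selection
#' with a warning (never an error), since a class can be absent from an
#' image.
#'
#' @param masked A `class_masked_map` from [mask_by_class()].
#' @param k Number of anchors, positive integer.
#' @return A `pixel_selection` with `kind = "best"`.
#' @export
select_k_best <- function(masked, k) {
  if (!is_count(k) || k < 1) stop_antl("k must be a positive integer")
  px <- masked$pixels
  if (nrow(px) == 0) {
    warn_antl(
      sprintf("no pixels labeled %s: best-pixel selection is empty", masked$class_id),
      class = "antl_empty_support"
    )
    return(new_pixel_selection(masked$class_id, "best", empty_pixels_df()))
  }
  if (nrow(px) < k) {
    warn_antl(
      sprintf(
        "class %s has %d pixels, fewer than k = %d: returning all of them",
        masked$class_id, nrow(px), k
      ),
      class = "antl_short_support"
    )
    return(new_pixel_selection(masked$class_id, "best", px))
  }
  ord <- order(-px$value, rowmajor_key(px$row, px$col, masked$width))
  sel <- px[ord[seq_len(k)], , drop = FALSE]
  sel <- sel[order(sel$row, sel$col), , drop = FALSE]
  rownames(sel) <- NULL
  new_pixel_selection(masked$class_id, "best", sel)
}

# One widening move. Returns updated c(lower, upper) or NULL when the
# interval is fully expanded. `all_mis`: every own-class probability < 0.5.
# The upper bound may overshoot 1 by step/2 so that a probability of exactly
# 1 is admissible in a final half-open round (bounds are strict).
widen_interval <- function(lower, upper, step, all_mis) {
  cap <- 1 + step / 2
  if (all_mis && lower > 0) {
    c(max(0, lower - step), upper)
  } else if (upper < cap) {
    c(lower, min(cap, upper + step))
  } else if (lower > 0) {
    c(max(0, lower - step), upper)
  } else {
    NULL
  }
}

#' Select k relatively hard-to-predict pixels of one class
#'
#' Collects pixels whose own-class probability lies strictly inside the
#' search interval, widening the interval by `step` after every round with
#' fewer than `k` candidates: the lower bound falls when all pixels of the
#' class are mispredicted, otherwise the upper bound rises. When more than
#' `k` candidates result, exactly `k` are drawn uniformly at random using
#' `rng_seed`. If the interval expands fully (lower at 0, upper past 1) with
#' fewer than `k` candidates, all found candidates are kept and a warning is
#' raised.
#'
#' The full pre-subsampling candidate set and the final interval are
#' attached as attributes `candidates` and `final_interval`.
#'
#' @param masked A `class_masked_map` from [mask_by_class()].
#' @param k Positive integer.
#' @param interval A [search_interval()]; the search restarts from it on
#'   every invocation (the mining is stateless across calls).
#' @param rng_seed Integer seed for the random down-selection.
#' @return A `pixel_selection` with `kind = "hard"`.
#' @export
select_k_hard <- function(masked, k, interval = search_interval(), rng_seed = 0L) {
  if (!is_count(k) || k < 1) stop_antl("k must be a positive integer")
  if (!inherits(interval, "search_interval")) {
    stop_antl("interval must be a search_interval object")
  }
  px <- masked$pixels
  if (nrow(px) == 0) {
    warn_antl(
      sprintf("no pixels labeled %s: hard-pixel selection is empty", masked$class_id),
      class = "antl_empty_support"
    )
    out <- new_pixel_selection(masked$class_id, "hard", empty_pixels_df())
    attr(out, "candidates") <- empty_pixels_df()
    attr(out, "final_interval") <- interval
    return(out)
  }
  v <- px$value
  lower <- interval$lower
  upper <- interval$upper
  step <- interval$step
  exhausted <- FALSE
  repeat {
    in_band <- v > lower & v < upper
    if (sum(in_band) >= k) break
    # evaluated once per round, as the search is ordered; the predicate is a
    # property of the fixed input map
    all_mis <- all(v < 0.5)
    nxt <- widen_interval(lower, upper, step, all_mis)
    if (is.null(nxt)) {
      exhausted <- TRUE
      break
    }
    lower <- nxt[1]
    upper <- nxt[2]
  }
  cand <- px[in_band, , drop = FALSE]
  rownames(cand) <- NULL
  if (exhausted && nrow(cand) < k) {
    warn_antl(
      sprintf(
        "search interval exhausted for class %s: only %d hard candidates found (k = %d)",
        masked$class_id, nrow(cand), k
      ),
      class = "antl_interval_exhausted"
    )
  }
  sel <- cand
  if (nrow(cand) > k) {
    keep <- with_seed(rng_seed, sample.int(nrow(cand), k))
    sel <- cand[sort(keep), , drop = FALSE]
    rownames(sel) <- NULL
  }
  out <- new_pixel_selection(masked$class_id, "hard", sel)
  attr(out, "candidates") <- cand
  attr(out, "final_interval") <- search_interval(lower, min(upper, 1), step)
  attr(out, "final_bounds") <- c(lower = lower, upper = upper)
  out
}

#' Brute-force oracle for the hard-pixel candidate set
#'
#' Recomputes, by direct enumeration over an explicitly unrolled widening
#' schedule, the candidate set that [select_k_hard()] must draw from before
#' its random down-selection. Intended for testing the search loop against
#' an independent rendering of the same definition.
#'
#' @inheritParams select_k_hard
#' @return Data frame of candidate pixels (`row`, `col`, `value`).
#' @export
brute_force_hard_candidates <- function(masked, k, interval = search_interval()) {
  px <- masked$pixels
  if (nrow(px) == 0) return(empty_pixels_df())
  step <- interval$step
  cap <- 1 + step / 2
  all_mis <- all(px$value < 0.5)
  # Unroll the full schedule of intervals up front: the preferred direction
  # first (lower bound down if all pixels mispredicted, else upper bound up),
  # then the other direction until (0, cap) is reached.
  schedule <- list(c(interval$lower, interval$upper))
  bounds <- c(interval$lower, interval$upper)
  repeat {
    if (all_mis && bounds[1] > 0) {
      bounds <- c(max(0, bounds[1] - step), bounds[2])
    } else if (bounds[2] < cap) {
      bounds <- c(bounds[1], min(cap, bounds[2] + step))
    } else if (bounds[1] > 0) {
      bounds <- c(max(0, bounds[1] - step), bounds[2])
    } else {
      break
    }
    schedule[[length(schedule) + 1]] <- bounds
  }
  for (b in schedule) {
    hit <- px$value > b[1] & px$value < b[2]
    if (sum(hit) >= k) {
      out <- px[hit, , drop = FALSE]
      rownames(out) <- NULL
      return(out)
    }
  }
  b <- schedule[[length(schedule)]]
  out <- px[px$value > b[1] & px$value < b[2], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.pixel_selection <- function(x, ...) {
  cat(sprintf(
    "<pixel_selection class=%s kind=%s, %d pixels>\n",
    x$class_id, x$kind, nrow(x$pixels)
  ))
  invisible(x)
}
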