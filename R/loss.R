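#' ANTL configuration
#'
#' Bundles the tunable parameters of the adaptive neighborhood triplet loss.
#'
#' @param k Anchors (and hard seeds) per class. Default 10, the number of
#'   anchors that performed best in the dermoscopy experiments the loss was
#'   developed on.
#' @param delta Triplet margin. Default 1: with all triplet members valued on
#'   the object channel, a perfect prediction gives anchor and positive means
#'   of 1 (object anchors) and a negative mean of 0, so the squared-distance
#'   difference is -1 and a margin of 1 zeroes the term.
#' @param alpha Weight of the two ANTL terms against cross-entropy in the
#'   composite objective. Default 0.015 (the PH2 optimum); 0.04 suits
#'   noisier ISIC2017-like data.
#' @param num_layers Neighborhood layers accumulated around each hard pixel,
#'   1 to 5 explored; default 1.
#' @param interval Initial [search_interval()] for hard-pixel mining.
#' @param rng_seed Seed for the random down-selection of hard candidates.
#' @param hinge Clamp each triplet term below at 0 (standard triplet-loss
#'   stabilization; the unclamped term is unbounded below). Set `FALSE` for
#'   exact-formula comparison.
#' @return An object of class `antl_config`.
#' @export
antl_config <- function(k = 10, delta = 1, alpha = 0.015, num_layers = 1,
                        interval = search_interval(), rng_seed = 0L,
                        hinge = TRUE) {
  if (!is_count(k) || k < 1) stop_antl("k must be a positive integer")
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0) {
    stop_antl("delta must be a non-negative number")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0) {
    stop_antl("alpha must be a non-negative number")
  }
  if (!is_count(num_layers) || num_layers < 1) {
    stop_antl("num_layers must be a positive integer")
  }
  if (!inherits(interval, "search_interval")) {
    stop_antl("interval must be a search_interval object")
  }
  if (!is.numeric(rng_seed) || length(rng_seed) != 1) {
    stop_antl("rng_seed must be a single integer")
  }
  if (!is.logical(hinge) || length(hinge) != 1 || is.na(hinge)) {
    stop_antl("hinge must be TRUE or FALSE")
  }
  structure(
    list(
      k = as.integer(k), delta = delta, alpha = alpha,
      num_layers = as.integer(num_layers), interval = interval,
      rng_seed = as.integer(rng_seed), hinge = hinge
    ),
    class = "antl_config"
  )
}

set_mean_object_channel <- function(pixels, probs) {
  if (nrow(pixels) == 0) return(NA_real_)
  mean(probs$p_object[cbind(pixels$row, pixels$col)])
}

#' One anchor-direction triplet term
#'
#' Computes `(A - P)^2 - (A - N)^2 + delta` where `A`, `P`, `N` are the
#' means, over the anchor, positive and negative pixel sets respectively, of
#' the object-channel probability (every triplet member is valued on that
#' single common channel; own-class probabilities drive only the selection).
#' With `hinge = TRUE` the term is clamped below at 0. If any of the three
#' sets is empty the term is 0 and a warning is raised.
#'
#' @param anchors A `pixel_selection` of the anchor class (k best pixels).
#' @param positives A `neighborhood_set` of the same class as `anchors`.
#' @param negatives A `neighborhood_set` of the opposite class.
#' @param probs The [probability_map()].
#' @param delta Margin.
#' @param hinge Clamp below at zero.
#' @return A single number.
#' @examples
#' # ideal object-anchor case: A = 1, P = 1, N = 0, delta = 1 -> 0
#' @export
antl_term <- function(anchors, positives, negatives, probs, delta = 1,
                      hinge = TRUE) {
  if (!identical(anchors$class_id, positives$class_id)) {
    stop_antl(sprintf(
      "anchor class (%s) and positive class (%s) must match",
      anchors$class_id, positives$class_id
    ))
  }
  if (identical(anchors$class_id, negatives$class_id)) {
    stop_antl("negatives must come from the opposite class to the anchors")
  }
  if (nrow(anchors$pixels) == 0 || nrow(positives$pixels) == 0 ||
      nrow(negatives$pixels) == 0) {
    warn_antl(
      sprintf(
        "empty triplet member for %s anchors (|A|=%d, |P|=%d, |N|=%d): term set to 0",
        anchors$class_id, nrow(anchors$pixels), nrow(positives$pixels),
        nrow(negatives$pixels)
      ),
      class = "antl_empty_triplet"
    )
    return(0)
  }
  A <- set_mean_object_channel(anchors$pixels, probs)
  P <- set_mean_object_channel(positives$pixels, probs)
  N <- set_mean_object_channel(negatives$pixels, probs)
  term <- (A - P)^2 - (A - N)^2 + delta
  if (hinge) term <- max(0, term)
  term
}

#' Mean binary cross-entropy
#'
#' `-(1/N) sum[g ln S + (1 - g) ln(1 - S)]` over all pixels, with `g` the
#' 0/1 label and `S` the object-channel probability. Probabilities are
#' clipped to `[eps, 1 - eps]` before the logarithm so a perfect prediction
#' stays finite.
#'
#' @param probs A [probability_map()].
#' @param labels A [label_mask()] with matching dimensions.
#' @param eps Clipping constant, default `1e-7`.
#' @return A single non-negative number.
#' @export
cross_entropy <- function(probs, labels, eps = 1e-7) {
  check_same_dims(probs, labels)
  S <- pmin(pmax(probs$p_object, eps), 1 - eps)
  g <- labels$label
  -mean(g * log(S) + (1 - g) * log(1 - S))
}

#' Freeze the pixel selections of the full ANTL pipeline
#'
#' Runs class masking, k-best and k-hard selection and neighborhood
#' expansion for both classes and returns the resulting sets. The selections
#' are piecewise-constant in the probabilities, so freezing them gives the
#' fixed structure over which the loss is differentiable (selection is
#' treated as a stop-gradient step).
#'
#' @inheritParams antl_loss
#' @return A list with elements `best_object`, `best_background`,
#'   `hard_object`, `hard_background`, `nb_object`, `nb_background`.
#' @export
freeze_selections <- function(probs, labels, config = antl_config()) {
  check_same_dims(probs, labels)
  out <- list()
  for (cls in class_ids) {
    masked <- mask_by_class(probs, labels, cls)
    # same stream for both classes: keeps the pipeline exactly symmetric
    # under object<->background relabeling
    seed <- config$rng_seed
    if (nrow(masked$pixels) == 0) {
      warn_antl(
        sprintf("class %s absent from the image", cls),
        class = "antl_empty_support"
      )
      best <- new_pixel_selection(cls, "best", empty_pixels_df())
      hard <- new_pixel_selection(cls, "hard", empty_pixels_df())
      nb <- structure(
        list(
          class_id = cls, layer_span = c(1L, config$num_layers),
          pixels = data.frame(
            row = integer(0), col = integer(0),
            value = numeric(0), layer = integer(0)
          )
        ),
        class = "neighborhood_set"
      )
    } else {
      best <- select_k_best(masked, config$k)
      hard <- select_k_hard(masked, config$k, config$interval, seed)
      nb <- if (nrow(hard$pixels) > 0) {
        expand_layers(hard, labels, probs, config$num_layers)
      } else {
        structure(
          list(
            class_id = cls, layer_span = c(1L, config$num_layers),
            pixels = data.frame(
              row = integer(0), col = integer(0),
              value = numeric(0), layer = integer(0)
            )
          ),
          class = "neighborhood_set"
        )
      }
    }
    out[[paste0("best_", cls)]] <- best
    out[[paste0("hard_", cls)]] <- hard
    out[[paste0("nb_", cls)]] <- nb
  }
  out
}

#' Evaluate the composite loss over frozen selections
#'
#' @param probs A [probability_map()].
#' @param labels A [label_mask()].
#' @param selections Output of [freeze_selections()].
#' @param config An [antl_config()].
#' @return An `antl_loss_breakdown` (see [antl_loss()]).
#' @export
loss_from_selections <- function(probs, labels, selections, config = antl_config()) {
  l_o <- antl_term(
    selections$best_object, selections$nb_object, selections$nb_background,
    probs, config$delta, config$hinge
  )
  l_b <- antl_term(
    selections$best_background, selections$nb_background, selections$nb_object,
    probs, config$delta, config$hinge
  )
  l_ce <- cross_entropy(probs, labels)
  breakdown <- structure(
    list(
      l_antl_object = l_o,
      l_antl_background = l_b,
      l_ce = l_ce,
      total = config$alpha * (l_o + l_b) + l_ce
    ),
    class = "antl_loss_breakdown"
  )
  attr(breakdown, "counts") <- list(
    k_object = nrow(selections$best_object$pixels),
    k_background = nrow(selections$best_background$pixels),
    p_object = nrow(selections$nb_object$pixels),
    q_background = nrow(selections$nb_background$pixels)
  )
  breakdown
}

#' Adaptive neighborhood triplet loss
#'
#' Runs the full pipeline for one image (or a batch): per class, mask by
#' label, select the k best and k hard pixels, expand the hard pixels into
#' layered same-label neighborhoods; then assemble one triplet term per
#' anchor direction (object anchors with object neighborhoods as positives
#' and background neighborhoods as negatives, and vice versa), add mean
#' binary cross-entropy, and combine as
#' `total = alpha * (l_antl_object + l_antl_background) + l_ce`.
#'
#' @param probs A [probability_map()], or a list of them (a batch).
#' @param labels A [label_mask()] (or list) with matching dimensions.
#' @param config An [antl_config()].
#' @return An object of class `antl_loss_breakdown`: a list with fields
#'   `l_antl_object`, `l_antl_background`, `l_ce` and `total`. For a batch,
#'   each field is the unweighted mean over images. Selection set sizes are
#'   attached as attribute `counts`.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
#' lab <- label_mask(m)
#' perfect <- probability_map(matrix(as.numeric(m), 8, 8))
#' antl_loss(perfect, lab, antl_config(k = 2))
#' @export
antl_loss <- function(probs, labels, config = antl_config()) {
  if (is.list(probs) && !inherits(probs, "probability_map")) {
    if (!is.list(labels) || length(labels) != length(probs)) {
      stop_antl("batch inputs require equally long lists of maps and masks")
    }
    parts <- Map(function(p, l) antl_loss(p, l, config), probs, labels)
    fields <- c("l_antl_object", "l_antl_background", "l_ce", "total")
    out <- lapply(fields, function(f) mean(vapply(parts, `[[`, numeric(1), f)))
    names(out) <- fields
    return(structure(out, class = "antl_loss_breakdown"))
  }
  sel <- freeze_selections(probs, labels, config)
  loss_from_selections(probs, labels, sel, config)
}

#' @export
print.antl_loss_breakdown <- function(x, ...) {
  cat(sprintf(
    paste0(
      "ANTL loss breakdown\n",
      "  l_antl (object anchors):     %.6g\n",
      "  l_antl (background anchors): %.6g\n",
      "  cross-entropy:               %.6g\n",
      "  total:                       %.6g\n"
    ),
    x$l_antl_object, x$l_antl_background, x$l_ce, x$total
  ))
  invisible(x)
}

# Analytic gradient of the composite loss with respect to the object-channel
# probability at every pixel, with selections frozen. The loss reads only the
# object channel (valuation channel for triplet members; S in the
# cross-entropy), so this is the complete gradient.
#' Analytic gradient of the composite loss (selections frozen)
#'
#' @inheritParams loss_from_selections
#' @param eps Cross-entropy clipping constant (must match [cross_entropy()]).
#' @return A height x width matrix: d(total) / d(p_object).
#' @export
antl_gradient <- function(probs, labels, selections, config = antl_config(),
                          eps = 1e-7) {
  h <- probs$height; w <- probs$width
  grad <- matrix(0, h, w)
  S <- probs$p_object
  g <- labels$label
  npix <- h * w
  inside <- S > eps & S < 1 - eps
  gce <- matrix(0, h, w)
  gce[inside] <- (S[inside] - g[inside]) / (S[inside] * (1 - S[inside])) / npix
  grad <- grad + gce

  add_term_grad <- function(grad, anchors, positives, negatives) {
    if (nrow(anchors$pixels) == 0 || nrow(positives$pixels) == 0 ||
        nrow(negatives$pixels) == 0) {
      return(grad)
    }
    A <- set_mean_object_channel(anchors$pixels, probs)
    P <- set_mean_object_channel(positives$pixels, probs)
    N <- set_mean_object_channel(negatives$pixels, probs)
    t_raw <- (A - P)^2 - (A - N)^2 + config$delta
    if (config$hinge && t_raw <= 0) return(grad)
    ai <- cbind(anchors$pixels$row, anchors$pixels$col)
    pi_ <- cbind(positives$pixels$row, positives$pixels$col)
    ni <- cbind(negatives$pixels$row, negatives$pixels$col)
    grad[ai] <- grad[ai] + config$alpha * (2 * (A - P) - 2 * (A - N)) / nrow(ai)
    grad[pi_] <- grad[pi_] - config$alpha * 2 * (A - P) / nrow(pi_)
    grad[ni] <- grad[ni] + config$alpha * 2 * (A - N) / nrow(ni)
    grad
  }
  grad <- add_term_grad(
    grad, selections$best_object, selections$nb_object, selections$nb_background
  )
  grad <- add_term_grad(
    grad, selections$best_background, selections$nb_background, selections$nb_object
  )
  grad
}

#' Finite-difference check of the analytic gradient
#'
#' Freezes selections, then compares the analytic partial derivatives of the
#' total loss with central finite differences at randomly sampled pixels.
#' Pixels where the loss is non-differentiable or numerically fragile — at a
#' hinge kink, or with object probability inside the cross-entropy clipping
#' zone — are excluded and counted separately.
#'
#' @inheritParams antl_loss
#' @param n_points Number of pixels to probe.
#' @param h Finite-difference step.
#' @param seed Seed for pixel sampling.
#' @return An object of class `gradient_check_report`: list with
#'   `max_discrepancy`, `n_checked`, `n_excluded`, and the per-pixel table.
#' @export
gradient_check <- function(probs, labels, config = antl_config(),
                           n_points = 100, h = 1e-6, seed = 1L) {
  sel <- suppressWarnings(freeze_selections(probs, labels, config))
  grad <- antl_gradient(probs, labels, sel, config)
  eps <- 1e-7
  kink_tol <- 1e-4

  # hinge-kink zone: a term with |pre-hinge value| below tolerance
  pre_hinge <- function(anchors, positives, negatives) {
    if (nrow(anchors$pixels) == 0 || nrow(positives$pixels) == 0 ||
        nrow(negatives$pixels) == 0) {
      return(Inf)
    }
    A <- set_mean_object_channel(anchors$pixels, probs)
    P <- set_mean_object_channel(positives$pixels, probs)
    N <- set_mean_object_channel(negatives$pixels, probs)
    (A - P)^2 - (A - N)^2 + config$delta
  }
  t_o <- pre_hinge(sel$best_object, sel$nb_object, sel$nb_background)
  t_b <- pre_hinge(sel$best_background, sel$nb_background, sel$nb_object)
  at_kink <- config$hinge && (abs(t_o) < kink_tol || abs(t_b) < kink_tol)

  npix <- probs$height * probs$width
  pts <- with_seed(seed, sample.int(npix, min(n_points, npix)))
  rows <- ((pts - 1L) %% probs$height) + 1L
  cols <- ((pts - 1L) %/% probs$height) + 1L

  eval_total <- function(p_obj) {
    suppressWarnings(loss_from_selections(
      new_probability_map(p_obj), labels, sel, config
    ))$total
  }

  res <- data.frame(
    row = rows, col = cols,
    analytic = NA_real_, numeric = NA_real_, excluded = FALSE
  )
  for (i in seq_along(pts)) {
    r <- rows[i]; c <- cols[i]
    S <- probs$p_object[r, c]
    if (at_kink || S < eps + 10 * h || S > 1 - eps - 10 * h) {
      res$excluded[i] <- TRUE
      next
    }
    up <- probs$p_object; up[r, c] <- S + h
    dn <- probs$p_object; dn[r, c] <- S - h
    num <- (eval_total(up) - eval_total(dn)) / (2 * h)
    res$analytic[i] <- grad[r, c]
    res$numeric[i] <- num
  }
  checked <- !res$excluded
  disc <- abs(res$analytic[checked] - res$numeric[checked])
  structure(
    list(
      max_discrepancy = if (any(checked)) max(disc) else NA_real_,
      n_checked = sum(checked),
      n_excluded = sum(res$excluded),
      points = res
    ),
    class = "gradient_check_report"
  )
}

#' @export
print.gradient_check_report <- function(x, ...) {
  cat(sprintf(
    "<gradient check: max |analytic - numeric| = %.3g over %d pixels (%d excluded)>\n",
    x$max_discrepancy, x$n_checked, x$n_excluded
  ))
  invisible(x)
}
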