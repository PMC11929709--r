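#' Specification of a synthetic blob mask
#'
#' Describes lesion-like ground truth: one or more filled discs on a
#' background. Each blob is connected; blobs are placed so they fit inside
#' the grid with a one-pixel margin.
#'
#' @param width,height Grid size in pixels.
#' @param num_blobs Number of discs, `>= 1`.
#' @param radius_range `c(min, max)` disc radius in pixels.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return An object of class `blob_spec`.
#' @export
blob_spec <- function(width = 64, height = 64, num_blobs = 1,
                      radius_range = c(10, 18), seed = 1L) {
  if (!is_count(width) || !is_count(height) || width < 4 || height < 4) {
    stop_antl("width and height must be integers >= 4")
  }
  if (!is_count(num_blobs) || num_blobs < 1) {
    stop_antl("num_blobs must be a positive integer")
  }
  if (length(radius_range) != 2 || !is.numeric(radius_range) ||
      radius_range[1] <= 0 || radius_range[2] < radius_range[1]) {
    stop_antl("radius_range must be c(min, max) with 0 < min <= max")
  }
  if (2 * radius_range[2] + 3 > min(width, height)) {
    stop_antl(sprintf(
      "a blob of radius %.1f cannot fit in a %dx%d grid",
      radius_range[2], height, width
    ))
  }
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      num_blobs = as.integer(num_blobs),
      radius_range = as.numeric(radius_range), seed = as.integer(seed)
    ),
    class = "blob_spec"
  )
}

#' Generate a blob-shaped binary label mask
#'
#' @param spec A [blob_spec()].
#' @return A [label_mask()] whose object region is the union of the discs.
#' @export
make_mask <- function(spec) {
  if (!inherits(spec, "blob_spec")) stop_antl("spec must be a blob_spec")
  h <- spec$height; w <- spec$width
  m <- matrix(0L, h, w)
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  with_seed(spec$seed, {
    for (b in seq_len(spec$num_blobs)) {
      r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      cr <- stats::runif(1, r + 2, h - r - 1)
      cc <- stats::runif(1, r + 2, w - r - 1)
      m[(rowg - cr)^2 + (colg - cc)^2 <= r^2] <- 1L
    }
  })
  frac <- mean(m)
  if (frac <= 0 || frac >= 1) {
    stop_antl("infeasible blob spec: object fraction must lie strictly between 0 and 1")
  }
  label_mask(m)
}

#' Specification of prediction-map degradation
#'
#' Emulates the output of a segmentation network at a given training stage:
#' confident deep inside each region, decaying toward 0.5 (ambiguous) within
#' a band around the label boundary with additive noise, plus a fraction of
#' randomly flipped (mispredicted) pixels.
#'
#' @param interior_confidence Own-class probability deep inside a region,
#'   in `(0.5, 1]`.
#' @param boundary_band Width in pixels of the ambiguous band around the
#'   boundary, `>= 0` (0 = no band, prediction uniformly confident).
#' @param boundary_noise Standard deviation of Gaussian noise added to the
#'   own-class probability within the band, `>= 0`.
#' @param flip_fraction Fraction of pixels whose own-class probability is
#'   replaced by a sub-0.5 value (gross mispredictions), in `[0, 1)`.
#' @param seed RNG seed.
#' @return An object of class `corruption_spec`.
#' @export
corruption_spec <- function(interior_confidence = 0.9, boundary_band = 4,
                            boundary_noise = 0.08, flip_fraction = 0.02,
                            seed = 1L) {
  if (!(interior_confidence > 0.5 && interior_confidence <= 1)) {
    stop_antl("interior_confidence must lie in (0.5, 1]")
  }
  if (!(boundary_band >= 0)) stop_antl("boundary_band must be >= 0")
  if (!(boundary_noise >= 0)) stop_antl("boundary_noise must be >= 0")
  if (!(flip_fraction >= 0 && flip_fraction < 1)) {
    stop_antl("flip_fraction must lie in [0, 1)")
  }
  structure(
    list(
      interior_confidence = interior_confidence,
      boundary_band = boundary_band,
      boundary_noise = boundary_noise,
      flip_fraction = flip_fraction,
      seed = as.integer(seed)
    ),
    class = "corruption_spec"
  )
}

#' Euclidean distance to the opposite-label region
#'
#' For every pixel, the distance to the nearest pixel of the other class —
#' 1 for pixels touching the label boundary, growing inward on both sides.
#'
#' @param mask A [label_mask()].
#' @return A numeric matrix of distances, same dimensions as the mask.
#' @export
boundary_distance <- function(mask) {
  m <- mask$label
  EBImage::distmap(m, metric = "euclidean") +
    EBImage::distmap(1L - m, metric = "euclidean")
}

#' Generate a degraded probability map for a mask
#'
#' The own-class probability equals `interior_confidence` deep inside each
#' region and decays linearly toward 0.5 as the boundary is approached:
#' at boundary distance `d` the pre-noise value is
#' `0.5 + (interior_confidence - 0.5) * min(d / (boundary_band + 1), 1)`.
#' Gaussian noise of scale `boundary_noise` is added within the band
#' (`d <= boundary_band`), and `flip_fraction` of all pixels are replaced by
#' a uniform draw from `(0.05, 0.45)` on the own-class channel. Values are
#' clamped to `[0, 1]` and the softmax constraint is enforced by
#' construction (`p_background = 1 - p_object`).
#'
#' With `interior_confidence = 1`, `boundary_band = 0`, `boundary_noise = 0`
#' and `flip_fraction = 0`, the result is the ideal prediction equal to the
#' mask.
#'
#' @param mask A [label_mask()].
#' @param spec A [corruption_spec()].
#' @return A [probability_map()]. Deterministic for a fixed spec.
#' @export
make_prediction <- function(mask, spec) {
  if (!inherits(spec, "corruption_spec")) {
    stop_antl("spec must be a corruption_spec")
  }
  d <- boundary_distance(mask)
  conf <- spec$interior_confidence
  own <- 0.5 + (conf - 0.5) * pmin(d / (spec$boundary_band + 1), 1)
  with_seed(spec$seed, {
    if (spec$boundary_band > 0 && spec$boundary_noise > 0) {
      band <- d <= spec$boundary_band
      own[band] <- own[band] + stats::rnorm(sum(band), 0, spec$boundary_noise)
    }
    if (spec$flip_fraction > 0) {
      n_flip <- round(spec$flip_fraction * length(own))
      if (n_flip > 0) {
        idx <- sample.int(length(own), n_flip)
        own[idx] <- stats::runif(n_flip, 0.05, 0.45)
      }
    }
  })
  own <- pmin(pmax(own, 0), 1)
  p_obj <- ifelse(mask$label == 1L, own, 1 - own)
  probability_map(matrix(p_obj, mask$height, mask$width))
}

#' Ideal prediction for a mask
#'
#' The probability map whose object channel equals the label mask exactly —
#' the fixed point at which both ANTL terms vanish with margin 1.
#'
#' @param mask A [label_mask()].
#' @return A [probability_map()].
#' @export
perfect_prediction <- function(mask) {
  probability_map(matrix(as.numeric(mask$label), mask$height, mask$width))
}

#' Jaccard index of two binary masks
#'
#' Intersection over union of the object regions, in `[0, 1]`. Two empty
#' object regions score 1.
#'
#' @param pred,truth Binary matrices (or [label_mask()] objects).
#' @return A single number in `[0, 1]`.
#' @export
jaccard_index <- function(pred, truth) {
  if (inherits(pred, "label_mask")) pred <- pred$label
  if (inherits(truth, "label_mask")) truth <- truth$label
  p <- pred > 0.5
  t <- truth > 0.5
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p & t) / u
}

# Box-filter (moving-window mean) via an integral image, edge-clamped.
box_filter <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  A <- apply(m, 2, cumsum)
  B <- t(apply(A, 1, cumsum))
  I <- matrix(0, h + 1, w + 1)
  I[2:(h + 1), 2:(w + 1)] <- B
  r1 <- pmax(seq_len(h) - r, 1L); r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(w) - r, 1L); c2 <- pmin(seq_len(w) + r, w)
  sums <- I[r2 + 1, c2 + 1] - I[r1, c2 + 1] - I[r2 + 1, c1] + I[r1, c1]
  counts <- outer(r2 - r1 + 1, c2 - c1 + 1)
  sums / counts
}

# Synthetic grayscale observation of a mask: blurred contrast step plus
# pixel noise. Boundary blur width and noise level are taken from the
# corruption spec, so "hard" images have genuinely ambiguous boundaries.
synth_observation <- function(mask, corruption, seed) {
  r <- max(1L, as.integer(round(corruption$boundary_band / 2)))
  base <- box_filter(box_filter(matrix(as.numeric(mask$label), mask$height,
                                       mask$width), r), r)
  with_seed(seed, {
    0.3 + 0.4 * base +
      stats::rnorm(mask$height * mask$width, 0, corruption$boundary_noise)
  })
}

demo_features <- function(img) {
  cbind(
    1,
    as.vector(img),
    as.vector(box_filter(img, 1L)),
    as.vector(box_filter(img, 3L)),
    as.vector(box_filter(img, 5L)),
    as.vector(sqrt(pmax(box_filter(img^2, 1L) - box_filter(img, 1L)^2, 0)))
  )
}

#' Desk-scale segmentation demo: logistic pixel model trained with ANTL
#'
#' Trains a tiny per-pixel segmenter — a logistic model over a handful of
#' local box-filter features of a synthetic grayscale observation — by
#' full-batch gradient descent on the composite objective, and evaluates the
#' mean Jaccard index on held-out synthetic images. With
#' `train_with_antl = FALSE` the ANTL weight is forced to 0 and the model is
#' trained on cross-entropy alone; otherwise `config$alpha` is used and the
#' pixel selections are re-mined at every descent step (the adaptive part of
#' the loss).
#'
#' @param num_images Number of training images, `>= 1`.
#' @param blob A [blob_spec()] for the ground-truth masks.
#' @param corruption A [corruption_spec()]; its `boundary_band` and
#'   `boundary_noise` control the blur and noise of the observations.
#' @param config An [antl_config()].
#' @param train_with_antl Use the ANTL terms during training.
#' @param seed Master seed; all per-image seeds derive from it.
#' @param num_test Held-out images for evaluation.
#' @param steps Gradient-descent steps.
#' @param learning_rate Step size.
#' @return A list with `jaccard_mean`, `jaccard_per_image`, `alpha_used`,
#'   `final_loss`, and the learned `weights`.
#' @export
logistic_demo <- function(num_images = 6,
                          blob = blob_spec(width = 48, height = 48,
                                           radius_range = c(8, 14)),
                          corruption = corruption_spec(),
                          config = antl_config(alpha = 0.04),
                          train_with_antl = TRUE,
                          seed = 1L,
                          num_test = 4,
                          steps = 120,
                          learning_rate = 4) {
  if (!is_count(num_images) || num_images < 1) {
    stop_antl("num_images must be a positive integer")
  }
  alpha <- if (train_with_antl) config$alpha else 0
  cfg <- antl_config(
    k = config$k, delta = config$delta, alpha = alpha,
    num_layers = config$num_layers, interval = config$interval,
    rng_seed = config$rng_seed, hinge = config$hinge
  )
  make_case <- function(i) {
    bs <- blob_spec(blob$width, blob$height, blob$num_blobs,
                    blob$radius_range, seed = derive_seed(seed, i))
    mask <- make_mask(bs)
    img <- synth_observation(mask, corruption, derive_seed(seed, i + 10000L))
    list(mask = mask, feats = demo_features(img))
  }
  train <- lapply(seq_len(num_images), make_case)
  test <- lapply(num_images + seq_len(num_test), make_case)

  nf <- ncol(train[[1]]$feats)
  wgt <- numeric(nf)
  h <- blob$height; w <- blob$width
  for (step in seq_len(steps)) {
    gw <- numeric(nf)
    loss_acc <- 0
    for (case in train) {
      z <- as.vector(case$feats %*% wgt)
      p <- matrix(stats::plogis(z), h, w)
      pm <- new_probability_map(p)
      if (alpha > 0) {
        sel <- suppressWarnings(freeze_selections(pm, case$mask, cfg))
        gp <- antl_gradient(pm, case$mask, sel, cfg)
        loss_acc <- loss_acc +
          suppressWarnings(loss_from_selections(pm, case$mask, sel, cfg))$total
      } else {
        S <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        g <- case$mask$label
        gp <- (S - g) / (S * (1 - S)) / (h * w)
        loss_acc <- loss_acc + cross_entropy(pm, case$mask)
      }
      dz <- as.vector(gp * p * (1 - p))
      gw <- gw + as.vector(crossprod(case$feats, dz))
    }
    if (!all(is.finite(gw)) || !is.finite(loss_acc)) {
      stop_antl(sprintf("demo training diverged at step %d (non-finite loss)", step))
    }
    wgt <- wgt - learning_rate * gw / num_images
  }
  jacc <- vapply(test, function(case) {
    z <- as.vector(case$feats %*% wgt)
    p <- matrix(stats::plogis(z), h, w)
    jaccard_index(p, case$mask)
  }, numeric(1))
  list(
    jaccard_mean = mean(jacc),
    jaccard_per_image = jacc,
    alpha_used = alpha,
    final_loss = loss_acc / num_images,
    weights = wgt
  )
}
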