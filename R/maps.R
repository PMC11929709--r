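#' Two-channel per-pixel probability map
#'
#' Container for the softmax output of a two-class segmentation head: for
#' every pixel, the probability of the object class and of the background
#' class. The two channels must sum to 1 at every pixel (tolerance `1e-6`);
#' inputs violating this are rejected rather than renormalized, so that
#' accidentally supplied logits fail loudly.
#'
#' @param p_object Numeric matrix (height x width) of object-class
#'   probabilities in `[0, 1]`.
#' @param p_background Optional numeric matrix of background-class
#'   probabilities; defaults to `1 - p_object`.
#' @return An object of class `probability_map` with fields `p_object`,
#'   `p_background`, `width`, `height`. Pixels are addressed as 1-based
#'   `(row, col)`.
#' @examples
#' pm <- probability_map(matrix(c(0.9, 0.8, 0.6, 0.3), 2, 2, byrow = TRUE))
#' pm$p_background[1, 1]  # 0.1
#' @export
probability_map <- function(p_object, p_background = NULL) {
  if (!is.matrix(p_object) || !is.numeric(p_object)) {
    stop_antl("p_object must be a numeric matrix")
  }
  if (nrow(p_object) < 1 || ncol(p_object) < 1) {
    stop_antl("probability map must be at least 1x1")
  }
  if (anyNA(p_object)) stop_antl("p_object contains missing values")
  if (any(p_object < 0 | p_object > 1)) {
    stop_antl("p_object values must lie in [0, 1]")
  }
  if (is.null(p_background)) {
    p_background <- 1 - p_object
  } else {
    if (!is.matrix(p_background) || !identical(dim(p_background), dim(p_object))) {
      stop_antl(sprintf(
        "channel dimensions differ: p_object is %dx%d, p_background is %sx%s",
        nrow(p_object), ncol(p_object),
        nrow(p_background), ncol(p_background)
      ))
    }
    if (any(abs(p_object + p_background - 1) > 1e-6)) {
      stop_antl("p_object + p_background must equal 1 at every pixel (tolerance 1e-6); refusing to renormalize")
    }
  }
  structure(
    list(
      p_object = p_object,
      p_background = p_background,
      width = ncol(p_object),
      height = nrow(p_object)
    ),
    class = "probability_map"
  )
}

# Internal constructor without the softmax check; used by finite-difference
# perturbation where one channel is nudged off the simplex by +/- h.
new_probability_map <- function(p_object, p_background = NULL) {
  if (is.null(p_background)) p_background <- 1 - p_object
  structure(
    list(
      p_object = p_object, p_background = p_background,
      width = ncol(p_object), height = nrow(p_object)
    ),
    class = "probability_map"
  )
}

#' Binary ground-truth label mask
#'
#' @param label Matrix of labels: 1/TRUE for object, 0/FALSE for background.
#' @return An object of class `label_mask` with fields `label` (integer 0/1
#'   matrix), `width`, `height`.
#' @examples
#' lm <- label_mask(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE))
#' @export
label_mask <- function(label) {
  if (is.logical(label)) storage.mode(label) <- "integer"
  if (!is.matrix(label) || !is.numeric(label)) {
    stop_antl("label must be a numeric or logical matrix")
  }
  if (anyNA(label)) stop_antl("label contains missing values")
  if (!all(label %in% c(0, 1))) {
    stop_antl("labels must be binary: 1 = object, 0 = background")
  }
  lab <- matrix(as.integer(label), nrow(label), ncol(label))
  structure(
    list(label = lab, width = ncol(lab), height = nrow(lab)),
    class = "label_mask"
  )
}

check_same_dims <- function(probs, labels) {
  if (probs$width != labels$width || probs$height != labels$height) {
    stop_antl(sprintf(
      "dimension mismatch: probability map is %dx%d (h x w), label mask is %dx%d",
      probs$height, probs$width, labels$height, labels$width
    ))
  }
  invisible(TRUE)
}

class_ids <- c("object", "background")

check_class_id <- function(class_id) {
  if (!(length(class_id) == 1 && class_id %in% class_ids)) {
    stop_antl("class_id must be \"object\" or \"background\"")
  }
  class_id
}

other_class <- function(class_id) {
  if (class_id == "object") "background" else "object"
}

#' Restrict a probability map to the pixels of one labeled class
#'
#' Applies the class indicator: keeps, for each pixel whose ground-truth
#' label equals `class_id`, its own-class predicted probability. The result
#' is a sparse coordinate-to-value mapping rather than a zero-filled matrix,
#' so a genuine probability of 0 at a correctly-labeled pixel remains
#' distinguishable from "not this class".
#'
#' @param probs A [probability_map()].
#' @param labels A [label_mask()] with matching dimensions.
#' @param class_id `"object"` or `"background"`.
#' @return An object of class `class_masked_map`: fields `class_id`, `width`,
#'   `height`, and `pixels`, a data frame with columns `row`, `col`, `value`
#'   (own-class probability), ordered row-major.
#' @examples
#' pm <- probability_map(matrix(c(0.9, 0.8, 0.6, 0.3), 2, 2, byrow = TRUE))
#' lm <- label_mask(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE))
#' mask_by_class(pm, lm, "object")$pixels
#' @export
mask_by_class <- function(probs, labels, class_id) {
  check_class_id(class_id)
  check_same_dims(probs, labels)
  own <- if (class_id == "object") probs$p_object else probs$p_background
  target <- if (class_id == "object") 1L else 0L
  idx <- which(labels$label == target)
  h <- probs$height
  row <- ((idx - 1L) %% h) + 1L
  col <- ((idx - 1L) %/% h) + 1L
  ord <- order(row, col)
  structure(
    list(
      class_id = class_id,
      width = probs$width,
      height = probs$height,
      pixels = data.frame(
        row = row[ord], col = col[ord], value = own[idx][ord]
      )
    ),
    class = "class_masked_map"
  )
}

#' Object-channel probability at a pixel
#'
#' Every triplet member is valued on this single common channel when the
#' triplet term is assembled, regardless of the member's own label: a
#' perfectly predicted object pixel is worth 1 and a perfectly predicted
#' background pixel 0, which is what calibrates the margin to 1.
#'
#' @param probs A [probability_map()].
#' @param coord Integer vector `c(row, col)`, 1-based.
#' @return The object-class probability at `coord`.
#' @export
object_channel_value <- function(probs, coord) {
  row <- coord[1]; col <- coord[2]
  if (row < 1 || row > probs$height || col < 1 || col > probs$width) {
    stop_antl(sprintf(
      "coordinate (%d, %d) out of bounds for a %dx%d map",
      row, col, probs$height, probs$width
    ))
  }
  probs$p_object[row, col]
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf(
    "<probability_map %dx%d (h x w), p_object in [%.3f, %.3f]>\n",
    x$height, x$width, min(x$p_object), max(x$p_object)
  ))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf(
    "<label_mask %dx%d, object fraction %.3f>\n",
    x$height, x$width, mean(x$label)
  ))
  invisible(x)
}

#' @export
print.class_masked_map <- function(x, ...) {
  cat(sprintf(
    "<class_masked_map class=%s, %d pixels of %dx%d grid>\n",
    x$class_id, nrow(x$pixels), x$height, x$width
  ))
  invisible(x)
}
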