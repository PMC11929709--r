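#' 8-connected neighbors of a pixel
#'
#' @param coord Integer vector `c(row, col)`, 1-based, inside the grid.
#' @param width,height Grid dimensions in pixels.
#' @return Integer matrix with columns `row`, `col`: the up-to-8 neighbors
#'   of `coord` clipped to the image boundary (8 in the interior, 5 on an
#'   edge, 3 in a corner).
#' @export
eight_neighbors <- function(coord, width, height) {
  row <- coord[1]; col <- coord[2]
  if (row < 1 || row > height || col < 1 || col > width) {
    stop_antl(sprintf(
      "seed coordinate (%d, %d) out of bounds for a %dx%d grid",
      row, col, height, width
    ))
  }
  off <- neighbor_offsets()
  r <- row + off[, 1]
  c <- col + off[, 2]
  keep <- r >= 1 & r <= height & c >= 1 & c <= width
  cbind(row = r[keep], col = c[keep])
}

neighbor_offsets <- function() {
  o <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  o[!(o[, 1] == 0 & o[, 2] == 0), , drop = FALSE]
}

#' Expand hard pixels into layered same-label 8-connected neighborhoods
#'
#' Layer 1 is the union of the 8-neighborhoods of all seed pixels, minus the
#' seeds themselves, keeping only pixels whose ground-truth label matches the
#' seed class. Layer `i + 1` applies the same step to layer `i`'s members,
#' excluding everything already collected. The neighborhoods substitute the
#' seeds in the triplet: seeds never appear in the result, no coordinate is
#' counted twice, and expansion propagates only through same-label pixels.
#'
#' @param seeds A `pixel_selection` (normally `kind = "hard"`).
#' @param labels A [label_mask()].
#' @param probs A [probability_map()]; members are valued at their own-class
#'   probability.
#' @param num_layers Number of layers to accumulate (union of layers
#'   `1..num_layers`), integer `>= 1`.
#' @return An object of class `neighborhood_set`: fields `class_id`,
#'   `layer_span = c(1, num_layers)`, and `pixels`, a data frame with
#'   columns `row`, `col`, `value`, `layer`.
#' @export
expand_layers <- function(seeds, labels, probs, num_layers = 1) {
  if (!is_count(num_layers) || num_layers < 1) {
    stop_antl("num_layers must be a positive integer")
  }
  check_same_dims(probs, labels)
  class_id <- check_class_id(seeds$class_id)
  empty <- data.frame(
    row = integer(0), col = integer(0), value = numeric(0), layer = integer(0)
  )
  if (nrow(seeds$pixels) == 0) {
    warn_antl(
      sprintf("no seed pixels for class %s: neighborhood is empty", class_id),
      class = "antl_empty_support"
    )
    return(structure(
      list(class_id = class_id, layer_span = c(1L, as.integer(num_layers)), pixels = empty),
      class = "neighborhood_set"
    ))
  }
  h <- probs$height; w <- probs$width
  target <- if (class_id == "object") 1L else 0L
  own <- if (class_id == "object") probs$p_object else probs$p_background
  off <- neighbor_offsets()

  collected <- pix_key(seeds$pixels$row, seeds$pixels$col, h)
  frontier <- cbind(seeds$pixels$row, seeds$pixels$col)
  layers <- list()
  for (layer in seq_len(num_layers)) {
    if (nrow(frontier) == 0) break
    nr <- rep(frontier[, 1], each = nrow(off)) + rep(off[, 1], nrow(frontier))
    nc <- rep(frontier[, 2], each = nrow(off)) + rep(off[, 2], nrow(frontier))
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    nr <- nr[ok]; nc <- nc[ok]
    key <- pix_key(nr, nc, h)
    first <- !duplicated(key)
    nr <- nr[first]; nc <- nc[first]; key <- key[first]
    new <- !(key %in% collected) & labels$label[cbind(nr, nc)] == target
    nr <- nr[new]; nc <- nc[new]; key <- key[new]
    ord <- order(nr, nc)
    nr <- nr[ord]; nc <- nc[ord]; key <- key[ord]
    collected <- c(collected, key)
    if (length(nr) > 0) {
      layers[[layer]] <- data.frame(
        row = nr, col = nc, value = own[cbind(nr, nc)], layer = layer
      )
    }
    frontier <- cbind(nr, nc)
  }
  pixels <- if (length(layers)) do.call(rbind, layers) else empty
  rownames(pixels) <- NULL
  structure(
    list(
      class_id = class_id,
      layer_span = c(1L, as.integer(num_layers)),
      pixels = pixels
    ),
    class = "neighborhood_set"
  )
}

#' @export
print.neighborhood_set <- function(x, ...) {
  cat(sprintf(
    "<neighborhood_set class=%s layers %d..%d, %d pixels>\n",
    x$class_id, x$layer_span[1], x$layer_span[2], nrow(x$pixels)
  ))
  invisible(x)
}
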