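# Shared fixtures and independent oracles, built in code at test time.

# Random label mask + softmax probability map on a small grid.
random_case <- function(h, w, object_frac = 0.5) {
  lab <- label_mask(matrix(stats::rbinom(h * w, 1, object_frac), h, w))
  pm <- probability_map(matrix(stats::runif(h * w), h, w))
  list(labels = lab, probs = pm)
}

# Hand-built selection objects for arithmetic tests on antl_term.
make_sel <- function(class_id, kind, row, col, value) {
  antl:::new_pixel_selection(
    class_id, kind, data.frame(row = row, col = col, value = value)
  )
}

make_nb <- function(class_id, row, col, value, layer = 1L) {
  structure(
    list(
      class_id = class_id,
      layer_span = c(1L, if (length(layer)) max(layer) else 1L),
      pixels = data.frame(row = row, col = col, value = value, layer = layer)
    ),
    class = "neighborhood_set"
  )
}

# Label-constrained breadth-first-search oracle for layered neighborhoods:
# a pixel belongs to layers 1..L iff it is reachable from some seed through
# same-label 8-connected steps in at most L moves (and is not itself a
# seed). Returns sorted matrix linear indices.
bfs_layers_oracle <- function(seeds, labels, class_id, num_layers) {
  h <- labels$height
  w <- labels$width
  target <- if (class_id == "object") 1L else 0L
  dist <- matrix(Inf, h, w)
  frontier <- cbind(seeds$pixels$row, seeds$pixels$col)
  dist[frontier] <- 0
  depth <- 0
  while (nrow(frontier) > 0 && depth < num_layers) {
    depth <- depth + 1
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      r <- frontier[i, 1]; c <- frontier[i, 2]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (labels$label[rr, cc] != target) next
        if (is.finite(dist[rr, cc])) next
        dist[rr, cc] <- depth
        nxt <- rbind(nxt, c(rr, cc))
      }
    }
    frontier <- if (is.null(nxt)) matrix(0L, 0, 2) else nxt
  }
  sort(which(is.finite(dist) & dist >= 1))
}

nb_keys <- function(nb, h) {
  sort((nb$pixels$col - 1L) * h + nb$pixels$row)
}
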