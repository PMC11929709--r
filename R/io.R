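# File formats: label masks as single-channel PNG/TIFF, probability maps as
# NPY arrays, selections as TSV, debug overlays as RGB PNG.

#' Read a binary label mask from a PNG or TIFF file
#'
#' Accepts 0/1 or 0/255 encodings (any positive object value): pixel values
#' above half of the maximum are object. Multi-channel images use the first
#' channel.
#'
#' @param path File path; format inferred from the extension.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop_antl(sprintf("mask file not found: %s", path))
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- t(a)  # EBImage stores (x, y); convert to (row, col)
  mx <- max(m)
  lab <- if (mx > 0) m > mx / 2 else matrix(FALSE, nrow(m), ncol(m))
  label_mask(lab)
}

#' Write a label mask as an image file
#'
#' Object pixels are written at full intensity (255 in 8-bit PNG),
#' background at 0.
#'
#' @param mask A [label_mask()].
#' @param path Output path; `.png` or `.tif`/`.tiff`.
#' @export
write_label_mask <- function(mask, path) {
  img <- EBImage::Image(t(matrix(as.numeric(mask$label), mask$height, mask$width)))
  EBImage::writeImage(img, path)
  invisible(path)
}

# --- minimal NPY v1.0 support (little-endian float arrays, C order) -------

npy_magic <- as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))

#' Write a numeric array as an NPY file
#'
#' NPY version 1.0, dtype `<f8`, C order.
#'
#' @param arr Numeric matrix or array.
#' @param path Output path.
#' @export
write_npy <- function(arr, path) {
  dims <- dim(arr)
  if (is.null(dims)) dims <- length(arr)
  shape <- paste0("(", paste0(dims, ",", collapse = " "), ")")
  shape <- sub(", \\)$", ")", sub(",\\)$", ",)", shape))
  header <- sprintf(
    "{'descr': '<f8', 'fortran_order': False, 'shape': %s, }", shape
  )
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  if (pad == 64) pad <- 0
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(npy_magic, con)
  writeBin(as.raw(c(1, 0)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  # C order: last axis fastest; R arrays are column-major (first axis
  # fastest), so permute before flattening
  flat <- if (length(dims) > 1) as.vector(aperm(arr, rev(seq_along(dims)))) else as.vector(arr)
  writeBin(as.numeric(flat), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NPY array file
#'
#' Supports NPY version 1.0/2.0 with dtypes `<f8`, `<f4`, `<i8`, `<i4`,
#' `|b1`, C or Fortran order.
#'
#' @param path File path.
#' @return A numeric vector, matrix or array with the stored shape.
#' @export
read_npy <- function(path) {
  if (!file.exists(path)) stop_antl(sprintf("NPY file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, npy_magic)) stop_antl(sprintf("not an NPY file: %s", path))
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- readChar(con, hlen, useBytes = TRUE)
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  if (length(shape) == 0 || anyNA(shape)) shape <- integer(0)
  n <- if (length(shape)) prod(shape) else 1L
  data <- switch(descr,
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "<f4" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "<i8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "<i4" = readBin(con, "integer", n, size = 4, endian = "little"),
    "|b1" = as.numeric(readBin(con, "raw", n)),
    stop_antl(sprintf("unsupported NPY dtype: %s", descr))
  )
  if (length(shape) <= 1) return(data)
  if (fortran) {
    array(data, dim = shape)
  } else {
    aperm(array(data, dim = rev(shape)), rev(seq_along(shape)))
  }
}

#' Read a probability map from an NPY file
#'
#' Accepts shape `(2, height, width)` (object channel first, then
#' background) or `(height, width)` (object channel only; background
#' inferred as `1 - p`).
#'
#' @param path NPY file path.
#' @return A [probability_map()].
#' @export
read_probability_map <- function(path) {
  a <- read_npy(path)
  d <- dim(a)
  if (length(d) == 2) {
    probability_map(a)
  } else if (length(d) == 3 && d[1] == 2) {
    probability_map(a[1, , ], a[2, , ])
  } else {
    stop_antl(sprintf(
      "probability NPY must have shape (2, h, w) or (h, w); got (%s)",
      paste(d, collapse = ", ")
    ))
  }
}

#' Write a probability map as an NPY file
#'
#' @param probs A [probability_map()].
#' @param path Output path.
#' @param channels 2 for shape `(2, h, w)`, 1 for object channel only.
#' @export
write_probability_map <- function(probs, path, channels = 2) {
  if (channels == 1) {
    write_npy(probs$p_object, path)
  } else {
    a <- array(0, c(2, probs$height, probs$width))
    a[1, , ] <- probs$p_object
    a[2, , ] <- probs$p_background
    write_npy(a, path)
  }
  invisible(path)
}

#' Export selections and neighborhoods as TSV
#'
#' One row per pixel with 1-based coordinates; columns `row`, `col`,
#' `value`, `class`, `kind`, `layer` (`NA` for plain selections). Header
#' comment lines (prefixed `#`) record the resolved parameters and any
#' warnings.
#'
#' @param sets A list of `pixel_selection` and/or `neighborhood_set`
#'   objects.
#' @param path Output path.
#' @param comments Character vector written as `# `-prefixed header lines.
#' @export
write_selection_tsv <- function(sets, path, comments = character(0)) {
  rows <- lapply(sets, function(s) {
    if (inherits(s, "pixel_selection")) {
      if (nrow(s$pixels) == 0) return(NULL)
      data.frame(
        row = s$pixels$row, col = s$pixels$col, value = s$pixels$value,
        class = s$class_id, kind = s$kind, layer = NA_integer_
      )
    } else if (inherits(s, "neighborhood_set")) {
      if (nrow(s$pixels) == 0) return(NULL)
      data.frame(
        row = s$pixels$row, col = s$pixels$col, value = s$pixels$value,
        class = s$class_id, kind = "neighborhood", layer = s$pixels$layer
      )
    } else {
      stop_antl("sets must contain pixel_selection or neighborhood_set objects")
    }
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(
      row = integer(0), col = integer(0), value = numeric(0),
      class = character(0), kind = character(0), layer = integer(0)
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a selection TSV written by [write_selection_tsv()]
#'
#' @param path File path.
#' @return A data frame with the exported columns.
#' @export
read_selection_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a debug overlay PNG
#'
#' Grayscale mask as background, object-class hard-pixel neighborhoods in
#' green and background-class neighborhoods in yellow; hard seeds in red
#' (object) / orange (background), best pixels in blue (object) / cyan
#' (background).
#'
#' @param mask A [label_mask()].
#' @param selections Output of [freeze_selections()].
#' @param path Output PNG path.
#' @export
write_overlay_png <- function(mask, selections, path) {
  h <- mask$height; w <- mask$width
  base <- 0.2 + 0.35 * mask$label
  rch <- base; gch <- base; bch <- base
  paint <- function(px, rgb) {
    if (is.null(px) || nrow(px) == 0) return(invisible(NULL))
    idx <- cbind(px$row, px$col)
    rch[idx] <<- rgb[1]; gch[idx] <<- rgb[2]; bch[idx] <<- rgb[3]
    invisible(NULL)
  }
  paint(selections$nb_object$pixels, c(0, 1, 0))        # green
  paint(selections$nb_background$pixels, c(1, 1, 0))    # yellow
  paint(selections$hard_object$pixels, c(1, 0, 0))      # red
  paint(selections$hard_background$pixels, c(1, 0.6, 0))# orange
  paint(selections$best_object$pixels, c(0, 0.3, 1))    # blue
  paint(selections$best_background$pixels, c(0, 1, 1))  # cyan
  a <- array(0, c(w, h, 3))
  a[, , 1] <- t(rch); a[, , 2] <- t(gch); a[, , 3] <- t(bch)
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}
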