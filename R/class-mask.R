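#' Three-class label masks
#'
#' A class mask is the central currency of the package: a dense integer
#' matrix labelling every pixel of a micrograph as background (0), node (1)
#' or tube (2). Nodes are clusters of endothelial cells from which vessels
#' grow; tubes are the thin capillary-like structures connecting them.
#'
#' @param labels An integer matrix with values in \{0, 1, 2\}.
#' @return An object of class `class_mask` (an integer matrix with a
#'   `class_names` attribute).
#' @examples
#' m <- class_mask(matrix(c(0L, 0L, 1L, 2L), 2, 2))
#' table(m)
#' @export
class_mask <- function(labels) {
  if (is.null(dim(labels)) || length(dim(labels)) != 2L)
    abort("`labels` must be a 2-D matrix.")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L))
  if (length(bad) > 0L)
    abort(paste0("mask contains labels outside {0, 1, 2}: ",
                 paste(sort(bad), collapse = ", ")))
  if (length(labels) == 0L) abort("mask must be nonempty.")
  structure(labels,
            class_names = c("background", "nodes", "tubes"),
            class = c("class_mask", "matrix", "array"))
}

#' @export
print.class_mask <- function(x, ...) {
  cat(sprintf("<class_mask> %d x %d px\n", nrow(x), ncol(x)))
  px <- tabulate(as.vector(x) + 1L, nbins = 3L)
  cat(sprintf("  background %d | nodes %d | tubes %d\n",
              px[1], px[2], px[3]))
  invisible(x)
}

is_class_mask <- function(x) inherits(x, "class_mask")

as_label_matrix <- function(mask) {
  m <- unclass(mask)
  attr(m, "class_names") <- NULL
  m
}

check_same_shape <- function(a, b, what = "masks") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    abort(sprintf("%s have mismatched shapes: %s vs %s", what,
                  paste(dim(a)[1:2], collapse = "x"),
                  paste(dim(b)[1:2], collapse = "x")))
  invisible(TRUE)
}

#' Read and write class masks as 8-bit PNG
#'
#' Masks are stored as single-channel 8-bit PNG files whose pixel values are
#' the raw labels 0/1/2 (so they look almost black in an image viewer).
#'
#' @param path Path to a PNG file.
#' @return `read_mask()` returns a [class_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort(paste0("mask file not found: ", path))
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  class_mask(matrix(as.integer(round(v * 255)), nrow(v), ncol(v)))
}

#' @param mask A [class_mask()].
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_class_mask(mask))
  png::writePNG(as_label_matrix(mask) / 255, target = path)
  invisible(path)
}

#' Plot a class mask
#'
#' Renders the three classes as filled tiles (background grey, nodes blue,
#' tubes red) in image orientation (row 1 at the top).
#'
#' @param mask A [class_mask()].
#' @return A ggplot object.
#' @export
plot_mask <- function(mask) {
  stopifnot(is_class_mask(mask))
  df <- tibble(
    row = rep(seq_len(nrow(mask)), times = ncol(mask)),
    col = rep(seq_len(ncol(mask)), each = nrow(mask)),
    class = factor(as.vector(as_label_matrix(mask)), levels = 0:2,
                   labels = c("background", "nodes", "tubes"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(background = "grey85",
                                          nodes = "#3366bb",
                                          tubes = "#cc3333")) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}
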