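#' Load a micrograph and its mask
#'
#' Reads a PNG or TIFF image (8- or 16-bit, grayscale or RGB), normalises
#' intensities to \[0, 1\], collapses RGB to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B), and optionally attaches a label mask
#' validated against the \{0, 1, 2\} code and the image shape.
#'
#' @param image_path Path to the image file.
#' @param mask_path Optional path to a single-channel label-mask PNG.
#' @param category Acquisition category: one of Good, Dark, Defective,
#'   Different.
#' @param id Sample identifier; defaults to the image file name.
#' @param pixel_size Optional micrometres per pixel.
#' @return A list of class `annotated_image` with fields id, image, mask,
#'   category, pixel_size.
#' @export
load_sample <- function(image_path, mask_path = NULL,
                        category = c("Good", "Dark", "Defective",
                                     "Different"),
                        id = NULL, pixel_size = NULL) {
  category <- match.arg(category)
  img <- read_intensity(image_path)
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- read_mask(mask_path)
    if (!identical(dim(mask), dim(img)))
      abort(sprintf("image (%s) and mask (%s) shapes differ.",
                    paste(dim(img), collapse = "x"),
                    paste(dim(mask), collapse = "x")))
  }
  structure(list(id = id %||% tools::file_path_sans_ext(basename(image_path)),
                 image = img, mask = mask, category = category,
                 pixel_size = pixel_size),
            class = "annotated_image")
}

read_intensity <- function(path) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        abort("reading TIFF requires the 'tiff' package.")
      tiff::readTIFF(path)
    },
    abort(paste0("unsupported image format: .", ext))
  )
  if (length(dim(v)) == 3L) {
    if (dim(v)[3] >= 3L)
      v <- 0.2126 * v[, , 1] + 0.7152 * v[, , 2] + 0.0722 * v[, , 3]
    else v <- v[, , 1]
  }
  pmin(pmax(v, 0), 1)
}

#' Import CVAT polygon annotations
#'
#' Parses a "CVAT for images 1.1" XML export with polygon shapes labelled
#' `node` or `tube` (case-insensitive) and rasterises them into class
#' masks. Tubes are drawn first and nodes second, so pixels claimed by
#' both are labelled node (nodes are the cell clusters tubes emanate
#' from). Pixels are filled when their centre lies inside the polygon
#' (even-odd rule, half-open so shared edges are not double-counted);
#' polygons are clipped to the canvas.
#'
#' @param xml_path Path to the CVAT XML file.
#' @param canvas Optional (height, width) overriding the per-image sizes
#'   recorded in the XML.
#' @return A named list mapping image name to [class_mask()].
#' @export
import_cvat_annotations <- function(xml_path, canvas = NULL) {
  doc <- tryCatch(xml2::read_xml(xml_path),
                  error = function(e) abort(paste0("malformed XML: ",
                                                   conditionMessage(e))))
  images <- xml2::xml_find_all(doc, ".//image")
  if (length(images) == 0L) abort("no <image> elements found.")
  out <- list()
  for (im in images) {
    name <- xml2::xml_attr(im, "name")
    h <- canvas[1] %||% as.integer(xml2::xml_attr(im, "height"))
    w <- canvas[2] %||% as.integer(xml2::xml_attr(im, "width"))
    lab <- matrix(0L, h, w)
    polys <- xml2::xml_find_all(im, ".//polygon")
    labels <- tolower(xml2::xml_attr(polys, "label"))
    bad <- setdiff(unique(labels), c("node", "tube"))
    if (length(bad) > 0L)
      abort(paste0("unknown annotation label(s): ",
                   paste(bad, collapse = ", "),
                   "; accepted labels are 'node' and 'tube'."))
    for (value in c(2L, 1L)) { # tubes first, nodes on top
      want <- if (value == 2L) "tube" else "node"
      for (pg in polys[labels == want]) {
        pts <- parse_cvat_points(xml2::xml_attr(pg, "points"))
        lab <- fill_polygon(lab, pts, value)
      }
    }
    out[[name]] <- class_mask(lab)
  }
  out
}

parse_cvat_points <- function(s) {
  pairs <- strsplit(strsplit(s, ";")[[1]], ",")
  m <- do.call(rbind, lapply(pairs, as.numeric))
  colnames(m) <- c("x", "y") # CVAT order: x = column, y = row, 0-based
  m
}

# Even-odd scanline fill on pixel centres (0-based pixel (r, c) has centre
# (r + 0.5, c + 0.5)); half-open crossing rule.
fill_polygon <- function(lab, pts, value) {
  h <- nrow(lab); w <- ncol(lab)
  x <- pts[, "x"]; y <- pts[, "y"]
  r0 <- max(1L, floor(min(y)) + 1L); r1 <- min(h, ceiling(max(y)))
  c0 <- max(1L, floor(min(x)) + 1L); c1 <- min(w, ceiling(max(x)))
  if (r0 > r1 || c0 > c1) return(lab)
  n <- length(x)
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  for (r in r0:r1) {
    yc <- r - 0.5
    cross <- (y <= yc) != (ny <= yc)
    if (!any(cross)) next
    xs <- x[cross] + (yc - y[cross]) / (ny[cross] - y[cross]) *
      (nx[cross] - x[cross])
    cc <- c0:c1
    xc <- cc - 0.5
    inside <- (vapply(xc, function(v) sum(xs > v), numeric(1)) %% 2) == 1
    lab[r, cc[inside]] <- value
  }
  lab
}

#' Stratified train/test split
#'
#' Within each acquisition category the sample ids are shuffled by seed and
#' the first `floor(train_fraction * n_category)` go to the training set.
#' At the study's category sizes (114 Good, 54 Dark, 79 Defective, 28
#' Different) and a 0.68 train fraction this floor rule yields train counts
#' 77/36/53/19.
#'
#' @param index Data frame with columns `id` and `category`.
#' @param train_fraction Fraction of each category assigned to training
#'   (strictly between 0 and 1).
#' @param seed Integer seed for the within-category shuffles.
#' @return A `dataset_split` list with `train_ids`, `test_ids` and a tidy
#'   `assignment` tibble (id, category, subset).
#' @export
split_dataset <- function(index, train_fraction = 0.68, seed = 0L) {
  if (nrow(index) == 0L) abort("empty dataset index.")
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must be strictly between 0 and 1.")
  stopifnot(all(c("id", "category") %in% names(index)))
  bad <- setdiff(unique(index$category), the_categories)
  if (length(bad) > 0L)
    abort(paste0("unknown categories: ", paste(bad, collapse = ", ")))
  set.seed(seed)
  assignment <- index |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(function(d, key) {
      ord <- sample.int(nrow(d))
      n_tr <- floor(train_fraction * nrow(d))
      d$subset <- "test"
      d$subset[ord[seq_len(n_tr)]] <- "train"
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("id", "category", "subset")))
  structure(list(train_ids = assignment$id[assignment$subset == "train"],
                 test_ids = assignment$id[assignment$subset == "test"],
                 train_fraction = train_fraction,
                 assignment = assignment),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (fraction %.2f)\n",
              length(x$train_ids), length(x$test_ids), x$train_fraction))
  print(table(x$assignment$category, x$assignment$subset))
  invisible(x)
}

#' Pooled class proportions of a mask collection
#'
#' Pixel counts are pooled over all masks, so differently sized masks are
#' weighted by their pixel counts (N_c / N over the whole collection).
#'
#' @param masks A list of [class_mask()] objects (or a single mask).
#' @return Named numeric vector (background, nodes, tubes) summing to 1.
#' @export
class_proportions <- function(masks) {
  if (is_class_mask(masks)) masks <- list(masks)
  if (length(masks) == 0L) abort("empty mask collection.")
  counts <- Reduce(`+`, lapply(masks, function(m)
    tabulate(as.vector(as_label_matrix(m)) + 1L, nbins = 3L)))
  setNames(counts / sum(counts), c("background", "nodes", "tubes"))
}
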