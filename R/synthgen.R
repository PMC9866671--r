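#' Rendering style for synthetic micrographs
#'
#' The generator emulates the four acquisition categories of real
#' tube-formation micrographs: `Good` (even illumination), `Dark`
#' (globally lowered illumination from altered microscope optics),
#' `Defective` (debris blobs, shadows, defocus blur) and `Different`
#' (early-stage incomplete networks; realised by open, dangling tubes in
#' the layout rather than by rendering). The photometric defaults are
#' calibration knobs of the simulator, not measurements of the real data.
#'
#' @param category One of `"Good"`, `"Dark"`, `"Defective"`, `"Different"`.
#' @param background_level Background intensity in \[0, 1\].
#' @param cell_contrast How much darker cells are than the background.
#' @param illumination_gradient Linear shading coefficients (row, col);
#'   full-canvas intensity drop per axis.
#' @param noise_sigma Gaussian pixel-noise standard deviation.
#' @param debris_count Number of debris ellipses (Defective imagery).
#' @param blur_sigma Gaussian defocus blur in pixels.
#' @return A `render_style` list.
#' @export
render_style <- function(category = c("Good", "Dark", "Defective",
                                      "Different"),
                         background_level = NULL,
                         cell_contrast = 0.25,
                         illumination_gradient = c(0, 0),
                         noise_sigma = 0.02,
                         debris_count = NULL,
                         blur_sigma = NULL) {
  category <- match.arg(category)
  background_level <- background_level %||%
    switch(category, Dark = 0.40, 0.72)
  debris_count <- debris_count %||%
    switch(category, Defective = 6L, 0L)
  blur_sigma <- blur_sigma %||%
    switch(category, Defective = 0.8, 0)
  if (category == "Dark" && background_level >= 0.72)
    abort("Dark style requires a background level below the Good default.")
  if (category == "Defective" && debris_count == 0L && blur_sigma == 0)
    abort("Defective style requires debris_count > 0 or blur_sigma > 0.")
  structure(list(category = category,
                 background_level = background_level,
                 cell_contrast = cell_contrast,
                 illumination_gradient = illumination_gradient,
                 noise_sigma = noise_sigma,
                 debris_count = as.integer(debris_count),
                 blur_sigma = blur_sigma),
            class = "render_style")
}

#' Sample a synthetic vessel-network layout
#'
#' Places node centres (cell clusters, drawn as disks) on the canvas with
#' enough separation for unambiguous skeleton recovery, then connects them
#' with curvilinear tube centre-lines (quadratic Bezier bends through 0-2
#' control points). Candidate edges whose chord passes near a third node
#' disk or crosses an accepted edge are rejected, so rasterised branches
#' map one-to-one onto layout edges. With `open_fraction > 0` that
#' fraction of edges is replaced by dangling tubes that end free of any
#' node, emulating early-stage incomplete ("Different") networks.
#'
#' @param n_nodes Number of node disks (>= 1).
#' @param n_edges Number of tubes (at most `choose(n_nodes, 2)`).
#' @param canvas (height, width) in px, at least 64 x 64.
#' @param seed Integer seed; layouts are bitwise reproducible per seed.
#' @param open_fraction Fraction of edges converted to dangling tubes.
#' @param tube_half_width Tube half-width in px.
#' @param radius_range Node disk radius range in px.
#' @return A `network_layout` list: `node_centers` (n x 2, row/col),
#'   `node_radii`, `edges` (tibble: from, to, open, with centre-line
#'   polylines), `tube_half_width`, `canvas_size`.
#' @export
sample_layout <- function(n_nodes, n_edges, canvas = c(256L, 256L),
                          seed = 0L, open_fraction = 0,
                          tube_half_width = 3, radius_range = c(8, 13)) {
  if (n_nodes < 1L) abort("`n_nodes` must be >= 1.")
  if (n_edges > choose(n_nodes, 2))
    abort(sprintf("n_edges = %d exceeds the %d distinct node pairs.",
                  n_edges, choose(n_nodes, 2)))
  if (any(canvas < 64L)) abort("canvas must be at least 64 x 64 px.")
  if (open_fraction < 0 || open_fraction > 1)
    abort("`open_fraction` must lie in [0, 1].")
  set.seed(seed)
  hw <- tube_half_width
  margin <- max(radius_range) + 2
  ok <- FALSE
  edges <- NULL
  for (attempt in 1:400) {
    centers <- matrix(NA_real_, n_nodes, 2)
    radii <- runif(n_nodes, radius_range[1], radius_range[2])
    placed_all <- TRUE
    for (i in seq_len(n_nodes)) {
      placed <- FALSE
      for (try in 1:200) {
        p <- c(runif(1, margin, canvas[1] - margin),
               runif(1, margin, canvas[2] - margin))
        if (i == 1L || all(sqrt(rowSums(sweep(centers[seq_len(i - 1), ,
                                                      drop = FALSE],
                                              2, p)^2)) >=
                           radii[seq_len(i - 1)] + radii[i] + 4 * hw + 8)) {
          centers[i, ] <- p; placed <- TRUE; break
        }
      }
      if (!placed) { placed_all <- FALSE; break }
    }
    if (!placed_all) next
    edges <- choose_edges(centers, radii, n_edges, hw)
    if (is.null(edges)) next
    if (nrow(edges) > 0L) {
      edges$line <- purrr::pmap(edges, function(from, to, open, ...) {
        bend_line(centers[from, ], centers[to, ], canvas, margin = hw + 1)
      })
      if (!curves_well_separated(edges, centers, radii, hw)) next
    }
    ok <- TRUE
    break
  }
  if (!ok)
    abort("could not place the requested layout on this canvas (placement error).")
  if (n_edges == 0L)
    edges <- tibble(from = integer(), to = integer(), open = logical(),
                    line = list())
  n_open <- round(open_fraction * nrow(edges))
  if (n_open > 0L) {
    which_open <- sample.int(nrow(edges), n_open)
    edges$open[which_open] <- TRUE
    # truncate open edges so the far end dangles well clear of the node it
    # was headed for (the free end must not read as an eroded contact)
    for (k in which_open) {
      ln <- edges$line[[k]]
      seg <- sqrt(rowSums(diff(ln)^2))
      cum <- c(0, cumsum(seg))
      total <- cum[length(cum)]
      r_to <- radii[edges$to[k]]
      keep_len <- min(0.6 * total, max(0.35 * total, total - r_to - 28))
      keep <- seq_len(max(2L, which.max(cum >= keep_len)))
      edges$line[[k]] <- ln[keep, , drop = FALSE]
      edges$to[k] <- NA_integer_
    }
  }
  structure(list(node_centers = centers, node_radii = radii,
                 edges = edges, tube_half_width = hw,
                 canvas_size = as.integer(canvas), seed = as.integer(seed)),
            class = "network_layout")
}

# Distance from point p to segment a-b.
point_seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

# Min distance between segments a-b and c-d (sampled; exact enough for
# clearance tests with generous margins).
seg_seg_dist <- function(a, b, c, d) {
  ts <- seq(0, 1, length.out = 25)
  pa <- outer(ts, b - a) + rep(a, each = 25)
  min(vapply(seq_len(25), function(i)
    point_seg_dist(pa[i, ], c, d), numeric(1)))
}

# The rendered tube bands (radius hw around each centre-line) must stay
# disjoint except inside/near their shared node disk, or the rasterised
# skeleton would grow spurious junctions. Curves too close to a
# non-incident node disk are also rejected.
curves_well_separated <- function(edges, centers, radii, hw) {
  thin <- function(p) p[seq(1, nrow(p), by = 8L), , drop = FALSE] # ~2 px
  pts <- lapply(edges$line, thin)
  n_e <- nrow(edges)
  # tubes must enter their node disks near-radially: a glancing entry
  # leaves a long tapered band along the disk arc whose skeleton erodes
  # far past the anchor radius
  entry_ok <- function(line, node) {
    ctr <- centers[node, ]; r <- radii[node]
    d <- sqrt((line[, 1] - ctr[1])^2 + (line[, 2] - ctr[2])^2)
    out <- which(d > r + 2)
    if (length(out) == 0L) return(TRUE)
    k <- out[1]
    k2 <- min(nrow(line), k + 32L)
    tang <- line[k2, ] - line[k, ]
    radial <- line[k, ] - ctr
    ca <- abs(sum(tang * radial)) /
      max(sqrt(sum(tang^2)) * sqrt(sum(radial^2)), 1e-9)
    ca >= cos(25 * pi / 180)
  }
  for (a in seq_len(n_e)) {
    if (!entry_ok(edges$line[[a]], edges$from[a])) return(FALSE)
    rev_line <- edges$line[[a]][rev(seq_len(nrow(edges$line[[a]]))), ,
                               drop = FALSE]
    if (!entry_ok(rev_line, edges$to[a])) return(FALSE)
  }
  for (a in seq_len(n_e)) {
    inc <- c(edges$from[a], edges$to[a])
    for (k in setdiff(seq_len(nrow(centers)), inc)) {
      d <- sqrt((pts[[a]][, 1] - centers[k, 1])^2 +
                  (pts[[a]][, 2] - centers[k, 2])^2)
      if (any(d < radii[k] + 2 * hw + 3)) return(FALSE)
    }
  }
  if (n_e < 2L) return(TRUE)
  for (a in seq_len(n_e - 1L)) for (b in (a + 1L):n_e) {
    shared <- intersect(c(edges$from[a], edges$to[a]),
                        c(edges$from[b], edges$to[b]))
    pa <- pts[[a]]; pb <- pts[[b]]
    for (s in shared) {
      # near the shared disk the bands may meet; any junction that forms
      # there lies within the anchor radius and collapses onto the node
      excl <- radii[s] + 2
      pa <- pa[(pa[, 1] - centers[s, 1])^2 + (pa[, 2] - centers[s, 2])^2 >
                 excl^2, , drop = FALSE]
      pb <- pb[(pb[, 1] - centers[s, 1])^2 + (pb[, 2] - centers[s, 2])^2 >
                 excl^2, , drop = FALSE]
    }
    if (nrow(pa) == 0L || nrow(pb) == 0L) next
    dmin <- min(sqrt(outer(pa[, 1], pb[, 1], `-`)^2 +
                       outer(pa[, 2], pb[, 2], `-`)^2))
    if (dmin < 2 * hw + 3) return(FALSE)
  }
  TRUE
}

# Pick n_edges node pairs whose chords stay clear of other node disks and
# of each other; NULL if impossible for this node placement.
choose_edges <- function(centers, radii, n_edges, hw) {
  n <- nrow(centers)
  if (n_edges == 0L)
    return(tibble(from = integer(), to = integer(), open = logical(),
                  line = list()))
  pairs <- t(combn(n, 2L))
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  clear_of_nodes <- function(i, j) {
    others <- setdiff(seq_len(n), c(i, j))
    all(vapply(others, function(k)
      point_seg_dist(centers[k, ], centers[i, ], centers[j, ]) >=
        radii[k] + 4 * hw + 6, logical(1)))
  }
  edge_angle <- function(at, other) {
    v <- centers[other, ] - centers[at, ]
    atan2(v[1], v[2])
  }
  chosen <- matrix(integer(), 0, 2)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!clear_of_nodes(i, j)) next
    crosses <- FALSE
    if (nrow(chosen) > 0) {
      for (s in seq_len(nrow(chosen))) {
        ii <- chosen[s, 1]; jj <- chosen[s, 2]
        shared <- intersect(c(i, j), c(ii, jj))
        if (length(shared) > 0) {
          # tubes leaving one node must fan out enough that their bands
          # separate right at the disk boundary
          o1 <- setdiff(c(i, j), shared)
          o2 <- setdiff(c(ii, jj), shared)
          dang <- abs(edge_angle(shared, o1) - edge_angle(shared, o2))
          dang <- min(dang, 2 * pi - dang)
          # bands must separate by the time they leave the shared disk:
          # separation at the boundary is 2 r sin(angle/2)
          need <- 2 * asin(min(1, (hw + 1) / radii[shared]))
          if (dang < need) { crosses <- TRUE; break }
          next
        }
        if (seg_seg_dist(centers[i, ], centers[j, ],
                         centers[ii, ], centers[jj, ]) < 4 * hw + 8) {
          crosses <- TRUE; break
        }
      }
    }
    if (crosses) next
    chosen <- rbind(chosen, c(i, j))
    if (nrow(chosen) == n_edges) break
  }
  if (nrow(chosen) < n_edges) return(NULL)
  tibble(from = chosen[, 1], to = chosen[, 2],
         open = rep(FALSE, n_edges), line = vector("list", n_edges))
}

# Curvilinear centre-line: quadratic Bezier through 0-2 random control
# points offset perpendicular to the chord, densely sampled (~0.25 px).
bend_line <- function(a, b, canvas, margin = 4) {
  len <- sqrt(sum((b - a)^2))
  n_ctrl <- sample(0:2, 1)
  perp <- c(-(b - a)[2], (b - a)[1]) / max(len, 1e-9)
  pts <- rbind(a, b)
  if (n_ctrl > 0) {
    ts <- sort(runif(n_ctrl, 0.3, 0.7))
    off <- runif(n_ctrl, -1, 1) * min(8, len / 8)
    ctrl <- t(vapply(seq_len(n_ctrl), function(k) {
      p <- a + ts[k] * (b - a) + off[k] * perp
      pmin(pmax(p, margin), canvas - margin)
    }, numeric(2)))
    pts <- rbind(a, ctrl, b)
  }
  dense_curve(pts, spacing = 0.25)
}

# Piecewise quadratic Bezier through the waypoints, resampled at a fixed
# spacing; straight chord when only two points.
dense_curve <- function(pts, spacing = 0.25) {
  if (nrow(pts) == 2L) {
    len <- sqrt(sum((pts[2, ] - pts[1, ])^2))
    m <- max(2L, ceiling(len / spacing) + 1L)
    ts <- seq(0, 1, length.out = m)
    return(cbind(pts[1, 1] + ts * (pts[2, 1] - pts[1, 1]),
                 pts[1, 2] + ts * (pts[2, 2] - pts[1, 2])))
  }
  quad_bezier <- function(p0, p1, p2) {
    ts <- seq(0, 1, length.out = 200)
    cbind((1 - ts)^2 * p0[1] + 2 * ts * (1 - ts) * p1[1] + ts^2 * p2[1],
          (1 - ts)^2 * p0[2] + 2 * ts * (1 - ts) * p1[2] + ts^2 * p2[2])
  }
  if (nrow(pts) == 3L) {
    path <- quad_bezier(pts[1, ], pts[2, ], pts[3, ])
  } else {
    # two control points: composite quadratic pieces joined at their
    # midpoint (the usual quadratic B-spline construction)
    m <- (pts[2, ] + pts[3, ]) / 2
    path <- rbind(quad_bezier(pts[1, ], pts[2, ], m),
                  quad_bezier(m, pts[3, ], pts[4, ])[-1, ])
  }
  resample_polyline(path, spacing)
}

resample_polyline <- function(path, spacing) {
  d <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(d))
  total <- cum[length(cum)]
  if (total < spacing) return(path[c(1, nrow(path)), , drop = FALSE])
  ts <- seq(0, total, by = spacing)
  if (ts[length(ts)] < total) ts <- c(ts, total)
  cbind(stats::approx(cum, path[, 1], xout = ts)$y,
        stats::approx(cum, path[, 2], xout = ts)$y)
}

polyline_length <- function(p) sum(sqrt(rowSums(diff(p)^2)))

#' Rasterise a layout into a mask and exact ground truth
#'
#' Tube pixels are those within `tube_half_width` of a centre-line; node
#' disks are drawn on top, so overlapping pixels are labelled node (nodes
#' are the cell clusters tubes emanate from). Ground-truth branch lengths
#' are centre-line arc lengths clipped at the node-disk boundaries; the
#' closed-network count is the cyclomatic number E - V + C of the layout
#' graph; node area is the analytic disk area (dangling ends and the tube
#' area come from the raster).
#'
#' @param layout A [sample_layout()] result.
#' @return A list: `mask` (a [class_mask()]) and `truth` (a one-row tibble:
#'   n_branches, total_branch_length, n_closed_networks, node_area,
#'   tube_area, plus a `degree_histogram` list-column).
#' @export
rasterize_ground_truth <- function(layout) {
  cz <- layout$canvas_size
  lab <- matrix(0L, cz[1], cz[2])
  hw <- layout$tube_half_width
  for (ln in layout$edges$line)
    lab <- stamp_band(lab, ln, hw, 2L)
  for (i in seq_len(nrow(layout$node_centers))) {
    lab <- stamp_disk(lab, layout$node_centers[i, ], layout$node_radii[i],
                      1L)
  }
  # clipped arc length: sum of segment pieces whose midpoints lie outside
  # every node disk
  total_len <- 0
  for (ln in layout$edges$line) {
    mid <- (ln[-1, , drop = FALSE] + ln[-nrow(ln), , drop = FALSE]) / 2
    seg <- sqrt(rowSums(diff(ln)^2))
    inside <- rep(FALSE, nrow(mid))
    for (i in seq_len(nrow(layout$node_centers))) {
      ctr <- layout$node_centers[i, ]
      inside <- inside |
        ((mid[, 1] - ctr[1])^2 + (mid[, 2] - ctr[2])^2 <=
           layout$node_radii[i]^2)
    }
    total_len <- total_len + sum(seg[!inside])
  }
  closed <- layout$edges[!layout$edges$open, , drop = FALSE]
  n_nodes <- nrow(layout$node_centers)
  comp <- if (nrow(closed) > 0) {
    g <- igraph::graph_from_edgelist(cbind(closed$from, closed$to),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
    igraph::count_components(g)
  } else n_nodes
  n_closed <- nrow(closed) - n_nodes + comp
  deg <- tabulate(c(layout$edges$from,
                    layout$edges$to[!is.na(layout$edges$to)]),
                  nbins = n_nodes)
  truth <- tibble(
    n_branches = nrow(layout$edges),
    total_branch_length = total_len,
    n_closed_networks = n_closed,
    node_area = sum(pi * layout$node_radii^2),
    tube_area = sum(lab == 2L),
    degree_histogram = list(table(deg))
  )
  list(mask = class_mask(lab), truth = truth)
}

stamp_disk <- function(lab, center, radius, value) {
  h <- nrow(lab); w <- ncol(lab)
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(h, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(w, ceiling(center[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  dd <- outer((rr - center[1])^2, (cc - center[2])^2, `+`)
  sub <- lab[rr, cc, drop = FALSE]
  sub[dd <= radius^2] <- value
  lab[rr, cc] <- sub
  lab
}

# Mark pixels within `hw` of the (densely sampled) polyline.
stamp_band <- function(lab, line, hw, value) {
  h <- nrow(lab); w <- ncol(lab)
  rad <- ceiling(hw) + 1L
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  pr <- round(line[, 1]); pc <- round(line[, 2])
  for (k in seq_len(nrow(offs))) {
    rr <- pr + offs$dr[k]; cc <- pc + offs$dc[k]
    keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    if (!any(keep)) next
    d2 <- (rr[keep] - line[keep, 1])^2 + (cc[keep] - line[keep, 2])^2
    hit <- d2 <= hw^2
    if (any(hit)) {
      idx <- cbind(rr[keep][hit], cc[keep][hit])
      lab[idx] <- value
    }
  }
  lab
}

#' Render a synthetic micrograph from a mask
#'
#' Cells (nodes and tubes) are rendered darker than the background, as in
#' phase-contrast imagery of endothelial networks; the style then applies
#' an illumination gradient, debris ellipses, defocus blur and Gaussian
#' noise. With zero noise, gradient, debris and blur the output is exactly
#' two-level.
#'
#' @param mask A [class_mask()].
#' @param style A [render_style()].
#' @param seed Integer seed (noise and debris placement).
#' @return Numeric intensity matrix in \[0, 1\], same size as the mask.
#' @export
render_image <- function(mask, style = render_style("Good"), seed = 0L) {
  stopifnot(is_class_mask(mask), inherits(style, "render_style"))
  set.seed(seed)
  lab <- as_label_matrix(mask)
  h <- nrow(lab); w <- ncol(lab)
  img <- matrix(style$background_level, h, w)
  img[lab > 0L] <- style$background_level - style$cell_contrast
  if (style$debris_count > 0L)
    img <- add_debris(img, lab, style)
  gr <- style$illumination_gradient
  if (any(gr != 0)) {
    img <- img + outer((seq_len(h) / h - 0.5) * gr[1],
                       (seq_len(w) / w - 0.5) * gr[2], `+`)
  }
  if (style$blur_sigma > 0)
    img <- gaussian_blur(img, style$blur_sigma)
  if (style$noise_sigma > 0)
    img <- img + matrix(rnorm(h * w, sd = style$noise_sigma), h, w)
  pmin(pmax(img, 0), 1)
}

# Debris: small filled ellipses at background locations, intensity halfway
# between cell and background levels, kept apart so blobs stay distinct.
add_debris <- function(img, lab, style) {
  h <- nrow(img); w <- ncol(img)
  level <- style$background_level - style$cell_contrast / 2
  placed <- matrix(numeric(0), 0, 2)
  n_done <- 0L
  for (try in 1:500) {
    if (n_done >= style$debris_count) break
    ctr <- c(runif(1, 10, h - 10), runif(1, 10, w - 10))
    ax <- runif(2, 2, 5)
    rr <- max(1, floor(ctr[1] - 6)):min(h, ceiling(ctr[1] + 6))
    cc <- max(1, floor(ctr[2] - 6)):min(w, ceiling(ctr[2] + 6))
    if (any(lab[rr, cc] > 0L)) next # keep debris off the cells
    if (nrow(placed) > 0 &&
        min(sqrt(rowSums(sweep(placed, 2, ctr)^2))) < 16) next
    ang <- runif(1, 0, pi)
    for (r in rr) for (cl in cc) {
      dr <- r - ctr[1]; dc <- cl - ctr[2]
      u <- dr * cos(ang) + dc * sin(ang)
      v <- -dr * sin(ang) + dc * cos(ang)
      if ((u / ax[1])^2 + (v / ax[2])^2 <= 1) img[r, cl] <- level
    }
    placed <- rbind(placed, ctr)
    n_done <- n_done + 1L
  }
  img
}

# Separable Gaussian blur via the package's conv kernel (edge-padded).
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  kern <- outer(k, k)
  x <- array(img, dim = c(dim(img), 1L))
  wgt <- array(kern, dim = c(2L * r + 1L, 2L * r + 1L, 1L))
  out <- .conv2d_fwd(x, wgt, 0, 1L, r, 1L)[, , 1]
  # renormalise near borders where the kernel is truncated by zero padding
  ones <- array(1, dim = dim(x))
  norm <- .conv2d_fwd(ones, wgt, 0, 1L, r, 1L)[, , 1]
  out / norm
}

#' Generate a synthetic dataset on disk
#'
#' Writes image/mask/ground-truth triples plus an index CSV. Category
#' counts follow largest-remainder apportionment of `n` by `category_mix`,
#' so exact mixes reproduce exactly. `Different` samples use open layouts;
#' the other categories differ in rendering style only.
#'
#' @param n Number of samples (>= 1).
#' @param category_mix Fractions for (Good, Dark, Defective, Different),
#'   summing to 1. The default mirrors the real dataset's category
#'   proportions 114:54:79:28.
#' @param seed Integer seed; the dataset is reproducible bit-for-bit.
#' @param out_dir Output directory (created if needed).
#' @param canvas Canvas size for every sample.
#' @param n_nodes,n_edges Ranges (min, max) for per-sample layout sizes.
#' @return The dataset index tibble (id, image_path, mask_path, category),
#'   invisibly written to `index.csv`.
#' @export
generate_dataset <- function(n, category_mix = c(114, 54, 79, 28) / 275,
                             seed = 0L, out_dir,
                             canvas = c(192L, 192L),
                             n_nodes = c(4L, 6L), n_edges = c(3L, 6L)) {
  if (n < 1L) abort("`n` must be >= 1.")
  if (abs(sum(category_mix) - 1) > 1e-9)
    abort("`category_mix` must sum to 1.")
  counts <- apportion_largest_remainder(n, category_mix)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create out_dir: ", out_dir))
  cats <- rep(the_categories, counts)
  index <- vector("list", n)
  for (k in seq_len(n)) {
    cat_k <- cats[k]
    smp <- synth_sample(cat_k, seed = seed + k, canvas = canvas,
                        n_nodes = n_nodes, n_edges = n_edges)
    id <- sprintf("synth_%03d", k)
    img_path <- file.path(out_dir, paste0(id, ".png"))
    msk_path <- file.path(out_dir, paste0(id, "_mask.png"))
    gt_path <- file.path(out_dir, paste0(id, "_truth.json"))
    png::writePNG(smp$image, target = img_path)
    write_mask(smp$mask, msk_path)
    jsonlite::write_json(
      c(list(id = id, category = cat_k),
        as.list(smp$truth[1, setdiff(names(smp$truth),
                                     "degree_histogram")])),
      gt_path, auto_unbox = TRUE, digits = NA)
    index[[k]] <- tibble(id = id, image_path = img_path,
                         mask_path = msk_path, category = cat_k)
  }
  index <- dplyr::bind_rows(index)
  write.csv(index, file.path(out_dir, "index.csv"), row.names = FALSE)
  index
}

# One in-memory synthetic sample (image + mask + ground truth). Node radii
# and tube width scale down on small canvases so layouts stay placeable.
synth_sample <- function(category, seed, canvas = c(192L, 192L),
                         n_nodes = c(4L, 6L), n_edges = c(3L, 6L)) {
  set.seed(seed)
  nn <- sample(n_nodes[1]:n_nodes[2], 1)
  ne <- min(sample(n_edges[1]:n_edges[2], 1), choose(nn, 2))
  open_frac <- if (category == "Different") 0.4 else 0
  small <- min(canvas) < 112
  hw <- if (small) 2 else 3
  rr <- if (small) c(5, 7) else c(8, 13)
  layout <- NULL
  for (s in 0:30) {
    layout <- tryCatch(
      sample_layout(nn, ne, canvas, seed = seed * 37L + s,
                    open_fraction = open_frac,
                    tube_half_width = hw, radius_range = rr),
      error = function(e) NULL)
    if (!is.null(layout)) break
    if (ne > 1L && s %% 3 == 2) ne <- ne - 1L # relax if crowded
    if (nn > 2L && s %% 7 == 6) { nn <- nn - 1L; ne <- min(ne, choose(nn, 2)) }
  }
  if (is.null(layout)) abort("synthetic layout placement failed.")
  rg <- rasterize_ground_truth(layout)
  style <- render_style(category)
  img <- render_image(rg$mask, style, seed = seed + 7L)
  list(image = img, mask = rg$mask, truth = rg$truth, layout = layout,
       category = category)
}

apportion_largest_remainder <- function(n, mix) {
  quota <- n * mix
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
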