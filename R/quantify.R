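# Mask -> skeleton graph -> network parameters.
#
# The three-class mask is split into node components (cell clusters) and a
# tube pixel set, the tubes are thinned to a one-pixel skeleton, the
# skeleton is traced into a graph whose vertices are junctions, free
# endpoints and node contacts, and the graph yields the vessel-network
# parameters: branches, closed networks (independent cycles), nodes,
# network areas/structures, triple- and quad-branched nodes, total and
# average branch length, branch-to-node ratio, tube length, tube coverage
# area and node area.

# Reference frame of the assay's full-resolution micrographs; the default
# small-object threshold scales with image area relative to it.
REF_PIXELS <- 2584 * 1936

#' Split a mask into node components and tube pixels
#'
#' Node components are 8-connected components of node-labelled pixels with
#' at least `min_object_px` pixels. Tube pixels are tube-labelled pixels
#' whose cell-union component (nodes and tubes together) either contains a
#' retained node or itself exceeds `min_object_px`; smaller specks --
#' typically single cells and debris carrying no network information --
#' are dropped.
#'
#' @param mask A [class_mask()].
#' @param min_object_px Minimum object size in px; defaults to 50 at the
#'   full 2584 x 1936 micrograph resolution, scaled by relative image area
#'   (with a floor of 5 px) for other sizes.
#' @return A list: `nodes` (integer label matrix, 0 = none), `tubes`
#'   (logical matrix), `min_object_px`.
#' @export
split_mask <- function(mask, min_object_px = NULL) {
  stopifnot(is_class_mask(mask))
  lab <- as_label_matrix(mask)
  min_object_px <- min_object_px %||%
    max(5, round(50 * length(lab) / REF_PIXELS))
  node_lab <- .label_components8(matrix(as.integer(lab == 1L), nrow(lab)))
  keep <- which(tabulate(node_lab[node_lab > 0L]) >= min_object_px)
  node_lab[!(node_lab %in% keep)] <- 0L
  # relabel retained components 1..k
  node_lab <- matrix(match(node_lab, c(0L, keep)) - 1L, nrow(lab))
  cells <- .label_components8(matrix(as.integer(lab > 0L), nrow(lab)))
  cell_sizes <- tabulate(cells[cells > 0L])
  has_node <- unique(cells[node_lab > 0L])
  keep_cell <- union(has_node, which(cell_sizes >= min_object_px))
  tubes <- lab == 2L & matrix(cells %in% keep_cell, nrow(lab))
  list(nodes = node_lab, tubes = tubes, min_object_px = min_object_px)
}

#' Skeletonize the tube set
#'
#' Guo-Hall two-subiteration thinning (followed by a minimality pass that
#' strips doubled staircase pixels) to a one-pixel-wide, 8-connected
#' medial skeleton;
#' elongated structures keep their connectivity and holes (a filled ring
#' thins to a closed curve).
#'
#' When `plug` is given (the node label matrix), the node blobs are merged
#' into the foreground before thinning and their pixels removed from the
#' skeleton afterwards. Tube bands then run into the node blob instead of
#' ending in a bare raster cut at the disk boundary, which parallel
#' thinning can otherwise erode far along the band; the resulting chain
#' ends sit directly at the node contact.
#'
#' @param tubes Logical matrix of tube pixels.
#' @param plug Optional integer node-label matrix from [split_mask()].
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize_tubes <- function(tubes, plug = NULL) {
  stopifnot(is.matrix(tubes))
  fg <- tubes
  if (!is.null(plug)) fg <- fg | plug > 0L
  out <- .thin_minimal(.thin_guohall(matrix(as.integer(fg), nrow(fg))))
  out <- out == 1L
  if (!is.null(plug)) out <- out & plug == 0L
  out
}

#' Build the skeleton graph
#'
#' Vertices are (a) skeleton junction clusters (pixels with three or more
#' skeleton neighbours, adjacent ones merged), (b) free endpoints (one
#' neighbour), each possibly anchored to a node component when it lies
#' within `anchor_px` of one, and (c) one vertex per contacted node
#' component -- all anchors of the same node collapse onto it, so tubes
#' meeting at a cell cluster meet at one graph vertex. Edges are skeleton
#' chains traced between vertices; chain length is the 8-connected step
#' length (diagonal steps weigh sqrt(2)). An edge end anchored to a node
#' is extended by the Euclidean gap between the skeleton terminal and the
#' nearest node pixel, compensating the end erosion of thinning. Spur
#' branches shorter than `prune_px` hanging off a junction are removed and
#' the junction degrees recomputed (degree-2 junction remnants are merged
#' back into a single branch).
#'
#' @param skeleton Logical matrix from [skeletonize_tubes()].
#' @param nodes Integer node-label matrix from [split_mask()].
#' @param prune_px Spur-prune threshold in px.
#' @param anchor_px Maximum skeleton-to-node gap for an anchor.
#' @return An `angio_graph`: tibbles `vertices` (id, kind, row, col,
#'   node_id) and `edges` (from, to, length), plus the skeleton.
#' @export
build_graph <- function(skeleton, nodes, prune_px = 5, anchor_px = 8) {
  g <- trace_skeleton(skeleton, nodes, anchor_px)
  g <- prune_graph(g, prune_px)
  structure(c(g, list(skeleton = skeleton, nodes = nodes)),
            class = "angio_graph")
}

#' @export
print.angio_graph <- function(x, ...) {
  cat(sprintf("<angio_graph> %d vertices, %d edges\n",
              nrow(x$vertices), nrow(x$edges)))
  invisible(x)
}

# --- internal tracing machinery -------------------------------------------

neighbors8 <- function(i, j, h, w) {
  di <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  ii <- i + di; jj <- j + dj
  keep <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
  cbind(ii[keep], jj[keep])
}

trace_skeleton <- function(skeleton, nodes, anchor_px) {
  h <- nrow(skeleton); w <- ncol(skeleton)
  ski <- matrix(as.integer(skeleton), h, w)
  nb <- .neighbor_count8(ski)
  vert_px <- skeleton & (nb >= 3L | nb == 1L)
  vert_lab <- .label_components8(matrix(as.integer(vert_px), h))
  n_vclust <- max(vert_lab)
  # vertex cluster centroids and kinds
  vertices <- list(); vmap <- integer(n_vclust)
  node_vertex <- integer(0) # node component id -> vertex id
  vid <- 0L
  add_vertex <- function(kind, row, col, node_id = NA_integer_) {
    vid <<- vid + 1L
    vertices[[vid]] <<- tibble(id = vid, kind = kind, row = row, col = col,
                               node_id = node_id)
    vid
  }
  nearest_node <- function(i, j) {
    r0 <- max(1L, i - anchor_px); r1 <- min(h, i + anchor_px)
    c0 <- max(1L, j - anchor_px); c1 <- min(w, j + anchor_px)
    win <- nodes[r0:r1, c0:c1, drop = FALSE]
    hit <- which(win > 0L, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    d <- sqrt((hit[, 1] + r0 - 1L - i)^2 + (hit[, 2] + c0 - 1L - j)^2)
    best <- which.min(d)
    if (d[best] > anchor_px) return(NULL)
    list(node = win[hit[best, 1], hit[best, 2]], dist = d[best])
  }
  # Endpoints whose window search misses can still be eroded tube ends:
  # walk back a few skeleton steps to get the local tangent and cast a ray
  # outward; a node component hit within reach anchors the endpoint with
  # the ray length as the erosion gap.
  ray_anchor <- function(p) {
    prev <- p; cur <- p
    for (s in 1:6) {
      nbs <- neighbors8(cur[1], cur[2], h, w)
      nxt <- NULL
      for (q in seq_len(nrow(nbs))) {
        cand <- nbs[q, ]
        if (skeleton[cand[1], cand[2]] &&
            !(cand[1] == prev[1] && cand[2] == prev[2]) &&
            !(cand[1] == cur[1] && cand[2] == cur[2])) {
          nxt <- cand; break
        }
      }
      if (is.null(nxt)) break
      prev <- cur; cur <- nxt
    }
    dir <- p - cur
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) return(NULL)
    dir <- dir / nrm
    perp <- c(-dir[2], dir[1])
    for (t in seq(1, 3 * anchor_px, by = 0.5)) {
      for (off in c(0, -1, 1)) {
        pos <- round(p + t * dir + off * perp)
        if (pos[1] < 1 || pos[1] > h || pos[2] < 1 || pos[2] > w) next
        if (nodes[pos[1], pos[2]] > 0L)
          return(list(node = nodes[pos[1], pos[2]], dist = t))
      }
    }
    NULL
  }
  anchor_gap <- numeric(0)
  for (v in seq_len(n_vclust)) {
    px <- which(vert_lab == v, arr.ind = TRUE)
    ctr <- round(colMeans(px))
    nn <- nearest_node(px[1, 1], px[1, 2])
    if (is.null(nn) && nb[px[1, 1], px[1, 2]] == 1L)
      nn <- ray_anchor(px[1, ])
    if (!is.null(nn)) {
      if (nn$node > length(node_vertex) || length(node_vertex) < nn$node ||
          is.na(node_vertex[nn$node]) || node_vertex[nn$node] == 0L) {
        node_vertex[nn$node] <- add_vertex("node-anchor", ctr[1], ctr[2],
                                           nn$node)
      }
      vmap[v] <- node_vertex[nn$node]
      anchor_gap[v] <- nn$dist
    } else {
      kind <- if (nb[px[1, 1], px[1, 2]] >= 3L) "junction" else "endpoint"
      vmap[v] <- add_vertex(kind, ctr[1], ctr[2])
      anchor_gap[v] <- 0
    }
  }
  # chains: skeleton minus vertex pixels
  chain_lab <- .label_components8(matrix(as.integer(skeleton & !vert_px), h))
  n_chain <- max(chain_lab)
  edges <- list()
  add_edge <- function(from, to, length) {
    edges[[length(edges) + 1L]] <<- tibble(from = from, to = to,
                                           length = length)
  }
  step_len <- function(a, b) if (abs(a[1] - b[1]) + abs(a[2] - b[2]) == 2L)
    sqrt(2) else 1
  for (ch in seq_len(n_chain)) {
    px <- which(chain_lab == ch, arr.ind = TRUE)
    # order the chain by walking from an end
    ordered <- order_chain(px, h, w, chain_lab, ch)
    ends <- ordered[c(1, nrow(ordered)), , drop = FALSE]
    # vertex clusters adjacent to each chain end
    touch <- function(p) {
      nbs <- neighbors8(p[1], p[2], h, w)
      vl <- vert_lab[nbs]
      hits <- nbs[vl > 0L, , drop = FALSE]
      if (nrow(hits) == 0L) return(NULL)
      # nearest adjacent vertex pixel
      list(cluster = vert_lab[hits[1, 1], hits[1, 2]],
           step = step_len(p, hits[1, ]))
    }
    len <- chain_length(ordered)
    t1 <- touch(ends[1, ]); t2 <- touch(ends[2, ])
    if (is.null(t1) && is.null(t2)) {
      # isolated chain: either a free segment or a pixel ring (cycle)
      is_cycle <- all(.neighbor_count8(
        matrix(as.integer(chain_lab == ch), h))[px] >= 2L)
      if (is_cycle && nrow(px) >= 8L) {
        v <- add_vertex("junction", ordered[1, 1], ordered[1, 2])
        close_len <- len + step_len(ordered[nrow(ordered), ], ordered[1, ])
        add_edge(v, v, close_len)
        anchor_gap[length(anchor_gap) + 1L] <- 0
      }
      # stray non-cycle chains with no vertex contact are thinning dust
      next
    }
    if (is.null(t1) || is.null(t2)) {
      # chain touching a vertex only at one end (other end merged into the
      # vertex cluster during labelling); treat as spur handled by pruning
      tt <- if (is.null(t1)) t2 else t1
      other_end <- if (is.null(t1)) ends[1, ] else ends[2, ]
      v_far <- add_vertex("endpoint", other_end[1], other_end[2])
      anchor_gap[length(anchor_gap) + 1L] <- 0
      add_edge(vmap[tt$cluster], v_far, len + tt$step +
                 gap_for(vmap[tt$cluster], vertices, anchor_gap_of(tt$cluster,
                                                                   anchor_gap)))
      next
    }
    total <- len + t1$step + t2$step +
      gap_for(vmap[t1$cluster], vertices,
              anchor_gap_of(t1$cluster, anchor_gap)) +
      gap_for(vmap[t2$cluster], vertices,
              anchor_gap_of(t2$cluster, anchor_gap))
    add_edge(vmap[t1$cluster], vmap[t2$cluster], total)
  }
  # direct vertex-vertex adjacency with no chain between (tiny branches)
  edges_direct <- direct_vertex_edges(vert_lab, vmap, h, w)
  empty_v <- tibble(id = integer(), kind = character(), row = numeric(),
                    col = numeric(), node_id = integer())
  empty_e <- tibble(from = integer(), to = integer(), length = numeric())
  vertices <- dplyr::bind_rows(c(list(empty_v), vertices))
  edges <- dplyr::bind_rows(c(list(empty_e), edges, edges_direct))
  list(vertices = vertices, edges = edges)
}

anchor_gap_of <- function(cluster, anchor_gap) {
  if (cluster <= length(anchor_gap)) anchor_gap[cluster] else 0
}

gap_for <- function(vertex_id, vertices, gap) {
  if (length(gap) == 0L || is.na(gap)) return(0)
  v <- vertices[[vertex_id]]
  if (!is.null(v) && v$kind[1] == "node-anchor") gap else 0
}

# Adjacent distinct vertex clusters form zero-chain edges.
direct_vertex_edges <- function(vert_lab, vmap, h, w) {
  px <- which(vert_lab > 0L, arr.ind = TRUE)
  seen <- character(0)
  out <- list()
  for (r in seq_len(nrow(px))) {
    p <- px[r, ]
    a <- vert_lab[p[1], p[2]]
    nbs <- neighbors8(p[1], p[2], h, w)
    for (q in seq_len(nrow(nbs))) {
      b <- vert_lab[nbs[q, 1], nbs[q, 2]]
      if (b > 0L && b != a) {
        key <- paste(sort(c(a, b)), collapse = "-")
        if (!(key %in% seen) && vmap[a] != vmap[b]) {
          seen <- c(seen, key)
          d <- if (sum(abs(p - nbs[q, ])) == 2L) sqrt(2) else 1
          out[[length(out) + 1L]] <- tibble(from = vmap[a], to = vmap[b],
                                            length = d)
        }
      }
    }
  }
  out
}

# Length of an ordered pixel chain. Raw 8-connected step sums (1 / sqrt(2))
# overestimate oblique digital curves by up to ~8%, so the pixel centres
# are smoothed with a short moving average before summing Euclidean steps;
# axis-aligned runs are unaffected.
chain_length <- function(ordered) {
  n <- nrow(ordered)
  if (n < 2L) return(0)
  if (n < 5L) {
    len <- 0
    for (s in 2:n)
      len <- len + sqrt(sum((ordered[s, ] - ordered[s - 1L, ])^2))
    return(len)
  }
  sm <- apply(ordered, 2, function(x)
    as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2)))
  # partial windows at the chain ends: keep the raw pixel centres there
  sm[1:2, ] <- ordered[1:2, ]
  sm[(n - 1L):n, ] <- ordered[(n - 1L):n, ]
  sum(sqrt(rowSums(diff(sm)^2)))
}

# Order chain pixels by walking; chains are paths or cycles of degree <= 2.
order_chain <- function(px, h, w, chain_lab, ch) {
  if (nrow(px) == 1L) return(px)
  sub <- matrix(as.integer(chain_lab == ch), h)
  deg <- .neighbor_count8(sub)
  degs <- deg[px]
  start <- if (any(degs <= 1L)) px[which(degs <= 1L)[1], ] else px[1, ]
  n <- nrow(px)
  keyset <- new.env(hash = TRUE)
  for (r in seq_len(n)) assign(paste(px[r, ], collapse = ","), TRUE, keyset)
  visited <- new.env(hash = TRUE)
  path <- matrix(NA_integer_, n, 2)
  cur <- start
  for (s in seq_len(n)) {
    path[s, ] <- cur
    assign(paste(cur, collapse = ","), TRUE, visited)
    nbs <- neighbors8(cur[1], cur[2], h, w)
    nxt <- NULL
    best <- Inf
    for (q in seq_len(nrow(nbs))) {
      key <- paste(nbs[q, ], collapse = ",")
      if (exists(key, keyset, inherits = FALSE) &&
          !exists(key, visited, inherits = FALSE)) {
        d <- sum(abs(nbs[q, ] - cur)) # prefer 4-neighbours
        if (d < best) { best <- d; nxt <- nbs[q, ] }
      }
    }
    if (is.null(nxt)) break
    cur <- nxt
  }
  path[!is.na(path[, 1]), , drop = FALSE]
}

# Remove short spur edges ending in a free endpoint, then merge the two
# edges of any junction whose degree drops to 2.
prune_graph <- function(g, prune_px) {
  v <- g$vertices; e <- g$edges
  if (nrow(e) == 0L) return(list(vertices = v, edges = e))
  repeat {
    deg <- vertex_degrees(v, e)
    is_free_end <- v$kind == "endpoint" & deg[v$id] == 1L
    spur <- rep(FALSE, nrow(e))
    for (r in seq_len(nrow(e))) {
      ends <- c(e$from[r], e$to[r])
      if (e$length[r] < prune_px &&
          any(is_free_end[ends]) &&
          # never remove a vertex's only connection to the network core
          any(v$kind[ends] != "endpoint" | deg[ends] > 1L))
        spur[r] <- TRUE
      # short self-loops on a node contact are skeleton arcs hugging the
      # disk boundary, not closed networks
      if (ends[1] == ends[2] && v$kind[ends[1]] == "node-anchor" &&
          e$length[r] < 4 * prune_px)
        spur[r] <- TRUE
    }
    changed <- any(spur)
    e <- e[!spur, , drop = FALSE]
    # merge through degree-2 junctions (not node anchors, not endpoints)
    deg <- vertex_degrees(v, e)
    merge_v <- v$id[v$kind == "junction" & deg[v$id] == 2L]
    for (mv in merge_v) {
      idx <- which(e$from == mv | e$to == mv)
      if (length(idx) != 2L) next # self-loop or parallel, leave alone
      a <- e[idx[1], ]; b <- e[idx[2], ]
      end_a <- if (a$from == mv) a$to else a$from
      end_b <- if (b$from == mv) b$to else b$from
      e <- e[-idx, , drop = FALSE]
      e <- dplyr::bind_rows(e, tibble(from = end_a, to = end_b,
                                      length = a$length + b$length))
      changed <- TRUE
    }
    if (!changed) break
  }
  keep_v <- v$id %in% c(e$from, e$to) | v$kind == "node-anchor"
  list(vertices = v[keep_v, , drop = FALSE], edges = e)
}

vertex_degrees <- function(v, e) {
  deg <- integer(max(v$id))
  if (nrow(e) > 0L) {
    tab <- table(c(e$from, e$to))
    deg[as.integer(names(tab))] <- as.integer(tab)
  }
  deg
}

#' Measure vessel-network parameters
#'
#' Computes the quantitative parameters of an angiogenesis network from the
#' skeleton graph and mask: branch count, closed networks (independent
#' cycles, the cyclomatic number E - V + C of the pruned graph), node
#' count, per-network areas and structure count (connected components of
#' the cell union), triple-/quad-branched nodes (node components with
#' exactly 3 or 4 incident branches), total and average branch length,
#' branch-to-node ratio, tube length (alias of total branch length), tube
#' coverage area and node area. With `pixel_size` given, lengths are in
#' micrometres and areas in square micrometres.
#'
#' @param graph An `angio_graph` from [build_graph()].
#' @param mask The originating [class_mask()].
#' @param split The [split_mask()] result (for the filtered node/tube sets);
#'   recomputed when omitted.
#' @param pixel_size Micrometres per pixel, or `NULL` for pixel units.
#' @return An `angio_quant` one-row tibble with the parameters above, a
#'   `network_areas` list-column and a `units` column ("px" or "um").
#' @export
measure_network <- function(graph, mask, split = NULL, pixel_size = NULL) {
  stopifnot(inherits(graph, "angio_graph"))
  split <- split %||% split_mask(mask)
  v <- graph$vertices; e <- graph$edges
  n_nodes <- max(split$nodes)
  branches <- nrow(e)
  total_len <- sum(e$length)
  # cyclomatic number E - V + C over the traced graph
  if (nrow(v) > 0L) {
    ig <- igraph::graph_from_data_frame(
      if (nrow(e) > 0L) data.frame(from = e$from, to = e$to)
      else data.frame(from = integer(), to = integer()),
      directed = FALSE,
      vertices = data.frame(name = v$id))
    closed <- nrow(e) - nrow(v) + igraph::count_components(ig)
  } else closed <- 0L
  # incident branch count per node component
  node_deg <- integer(max(1L, n_nodes))
  if (nrow(e) > 0L && n_nodes > 0L) {
    vmapn <- setNames(v$node_id, v$id)
    incid <- c(vmapn[as.character(e$from)], vmapn[as.character(e$to)])
    incid <- incid[!is.na(incid)]
    tabn <- table(incid)
    node_deg[as.integer(names(tabn))] <- as.integer(tabn)
  }
  cell_union <- split$nodes > 0L | split$tubes
  comp <- .label_components8(matrix(as.integer(cell_union), nrow(cell_union)))
  areas <- if (max(comp) > 0L) as.numeric(tabulate(comp[comp > 0L]))
           else numeric(0)
  s <- pixel_size %||% 1
  units <- if (is.null(pixel_size)) "px" else "um"
  structure(tibble(
    branches = branches,
    closed_networks = as.integer(closed),
    nodes = as.integer(n_nodes),
    network_structures = as.integer(max(comp)),
    network_areas = list(areas * s^2),
    triple_branched_nodes = if (n_nodes > 0L) sum(node_deg[seq_len(n_nodes)] == 3L) else 0L,
    quad_branched_nodes = if (n_nodes > 0L) sum(node_deg[seq_len(n_nodes)] == 4L) else 0L,
    total_branch_length = total_len * s,
    average_branch_length = if (branches > 0L) total_len * s / branches
                            else NA_real_,
    branch_to_node_ratio = if (n_nodes > 0L) branches / n_nodes
                           else NA_real_,
    tube_length = total_len * s,
    tube_coverage_area = sum(split$tubes) * s^2,
    node_area = sum(split$nodes > 0L) * s^2,
    units = units
  ), class = c("angio_quant", class(tibble())))
}

#' Quantify a mask in one call
#'
#' Convenience wrapper running [split_mask()], [skeletonize_tubes()],
#' [build_graph()] and [measure_network()].
#'
#' @inheritParams split_mask
#' @inheritParams measure_network
#' @param prune_px Spur-prune threshold in px.
#' @return An `angio_quant` one-row tibble (see [measure_network()]).
#' @examples
#' layout <- sample_layout(3, 3, c(256, 256), seed = 7)
#' rg <- rasterize_ground_truth(layout)
#' quantify_mask(rg$mask)
#' @export
quantify_mask <- function(mask, pixel_size = NULL, min_object_px = NULL,
                          prune_px = 5) {
  split <- split_mask(mask, min_object_px)
  sk <- skeletonize_tubes(split$tubes, plug = split$nodes)
  graph <- build_graph(sk, split$nodes, prune_px = prune_px)
  measure_network(graph, mask, split, pixel_size)
}
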