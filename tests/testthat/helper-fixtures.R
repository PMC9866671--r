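# Shared fixtures, all built in code.

# Two node disks joined by one straight horizontal tube; the analytic
# clipped branch length is 100 - 2 * 10 = 80 px.
two_node_layout <- function() {
  structure(list(
    node_centers = rbind(c(50, 50), c(50, 150)),
    node_radii = c(10, 10),
    edges = tibble::tibble(
      from = 1L, to = 2L, open = FALSE,
      line = list(cbind(rep(50, 401), seq(50, 150, length.out = 401)))),
    tube_half_width = 3,
    canvas_size = c(200L, 200L),
    seed = 0L
  ), class = "network_layout")
}

random_mask <- function(h = 16, w = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  class_mask(matrix(sample(0:2, h * w, replace = TRUE), h, w))
}

# Generic multi-category Cohen's kappa from the full confusion matrix --
# the independent oracle for the channel-sum formula.
kappa_confusion_oracle <- function(I, J) {
  li <- factor(as.vector(unclass(I)), levels = 0:2)
  lj <- factor(as.vector(unclass(J)), levels = 0:2)
  cm <- table(li, lj)
  n <- sum(cm)
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (p0 - pe) / (1 - pe)
}

# Exhaustive sign-pattern enumeration of the one-sided signed-rank p-value
# (zero differences dropped, mid-ranks for ties); independent of the
# package's shift-algorithm implementation.
wilcoxon_enum_oracle <- function(a, b) {
  d <- (a - b)[a != b]
  k <- length(d)
  if (k == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  hits <- 0L
  for (m in 0:(2^k - 1)) {
    signs <- as.integer(intToBits(m))[1:k]
    if (sum(r[signs == 1L]) >= w_obs - 1e-9) hits <- hits + 1L
  }
  hits / 2^k
}

# Small in-memory synthetic dataset tibble for training tests.
synthetic_set <- function(n, seed0, canvas = c(64L, 64L),
                          categories = c("Good", "Dark", "Defective",
                                         "Different"),
                          n_nodes = c(2L, 4L), n_edges = c(1L, 3L)) {
  cats <- rep(categories, length.out = n)
  purrr::map_dfr(seq_len(n), function(i) {
    smp <- angioquant:::synth_sample(cats[i], seed = seed0 + i,
                                     canvas = canvas,
                                     n_nodes = n_nodes,
                                     n_edges = n_edges)
    tibble::tibble(id = sprintf("s%04d", seed0 + i),
                   image = list(smp$image), mask = list(smp$mask),
                   category = cats[i])
  })
}
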