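#' Class weights from pooled class proportions
#'
#' Converts per-class pixel fractions into focal-loss class weights
#' \eqn{\alpha_c = 1 - N_c/N}, so that rare classes (tubes, typically about
#' 5\% of pixels) receive large weights and the dominant background a small
#' one.
#'
#' @param proportions Numeric vector of three per-class pixel fractions
#'   (background, nodes, tubes), summing to 1.
#' @return Named numeric vector of three weights in \[0, 1\].
#' @examples
#' derive_alpha(c(background = 0.69, nodes = 0.26, tubes = 0.05))
#' @export
derive_alpha <- function(proportions) {
  if (length(proportions) != 3L || any(proportions < 0) ||
      any(proportions > 1))
    abort("`proportions` must be three fractions in [0, 1].")
  if (abs(sum(proportions) - 1) > 1e-6)
    abort(sprintf("class proportions must sum to 1 (got %.8f).",
                  sum(proportions)))
  out <- 1 - as.numeric(proportions)
  names(out) <- c("background", "nodes", "tubes")
  out
}

#' Multiclass focal loss
#'
#' The optimisation loss used for training the segmenters. For each pixel
#' and class c, with \eqn{p_t = p_c} when the true label is c and
#' \eqn{1 - p_c} otherwise, the per-class contribution is
#' \eqn{-\alpha_c (1 - p_t)^\gamma \log p_t}; the multiclass loss is the sum
#' over the three class channels, averaged over pixels. `gamma = 0` reduces
#' it to an \eqn{\alpha}-weighted sum of binary cross-entropies. Probabilities
#' are clamped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param probs H x W x 3 array of per-pixel class probabilities
#'   (each pixel summing to 1).
#' @param truth A [class_mask()] of the same H x W.
#' @param alpha Three per-class weights, e.g. from [derive_alpha()].
#' @param gamma Focusing parameter (>= 0); the package default is 0.5.
#' @param eps Clamp applied to probabilities before taking logs.
#' @return A nonnegative scalar.
#' @export
focal_loss <- function(probs, truth, alpha, gamma = 0.5, eps = 1e-7) {
  check_focal_inputs(probs, truth, alpha, gamma)
  pt <- focal_pt(probs, truth, eps)
  total <- 0
  for (c in 1:3)
    total <- total + sum(-alpha[c] * (1 - pt[, , c])^gamma * log(pt[, , c]))
  total / (dim(probs)[1] * dim(probs)[2])
}

check_focal_inputs <- function(probs, truth, alpha, gamma) {
  if (length(dim(probs)) != 3L || dim(probs)[3] != 3L)
    abort("`probs` must be an H x W x 3 array.")
  check_same_shape(probs, truth, "probs and truth")
  if (any(probs < 0) || any(probs > 1))
    abort("probabilities must lie in [0, 1].")
  if (gamma < 0) abort("`gamma` must be nonnegative.")
  if (length(alpha) != 3L) abort("`alpha` must have three entries.")
}

# p_t per pixel and class channel, clamped away from 0/1.
focal_pt <- function(probs, truth, eps = 1e-7) {
  lab <- as_label_matrix(truth)
  pt <- probs
  for (c in 1:3) {
    is_c <- lab == (c - 1L)
    pt[, , c] <- ifelse(is_c, probs[, , c], 1 - probs[, , c])
  }
  pmin(pmax(pt, eps), 1 - eps)
}

# dL/dp for the focal loss (used by the training backward pass).
focal_grad_p <- function(probs, truth, alpha, gamma = 0.5, eps = 1e-7) {
  lab <- as_label_matrix(truth)
  npx <- length(lab)
  dp <- probs * 0
  for (c in 1:3) {
    is_c <- lab == (c - 1L)
    p <- pmin(pmax(probs[, , c], eps), 1 - eps)
    # true-class branch: L = -a (1-p)^g log p
    d_true <- alpha[c] * (gamma * safe_pow(1 - p, gamma - 1) * log(p) -
                            safe_pow(1 - p, gamma) / p)
    # other-class branch: L = -a p^g log(1-p)
    d_false <- alpha[c] * (-gamma * safe_pow(p, gamma - 1) * log(1 - p) +
                             safe_pow(p, gamma) / (1 - p))
    dp[, , c] <- ifelse(is_c, d_true, d_false) / npx
  }
  dp
}

safe_pow <- function(x, p) {
  if (p == 0) return(x * 0 + 1)
  x^p
}

#' Per-class intersection-over-union
#'
#' \eqn{|T_c \cap P_c| / |T_c \cup P_c|} for one class channel. A class
#' absent from both masks scores 1 (vacuous agreement), so per-image
#' summaries stay defined on images lacking a class.
#'
#' @param truth,pred [class_mask()] objects of identical shape.
#' @param class Class label: 0 (background), 1 (nodes) or 2 (tubes).
#' @return A scalar in \[0, 1\].
#' @export
iou_class <- function(truth, pred, class) {
  check_same_shape(truth, pred)
  t_c <- as_label_matrix(truth) == class
  p_c <- as_label_matrix(pred) == class
  uni <- sum(t_c | p_c)
  if (uni == 0L) return(1)
  sum(t_c & p_c) / uni
}

#' Summary IoU over classes
#'
#' `mode = "three"` (IoU3) averages the per-class IoU of background, nodes
#' and tubes (classes absent from both masks are left out of the average)
#' and measures how well the three classes are told apart.
#' `mode = "two"` (IoU2) averages IoU(background) and IoU(cells), where
#' cells = nodes union tubes, and measures how well the cell/background
#' boundary is found irrespective of the node/tube distinction.
#'
#' @inheritParams iou_class
#' @param mode `"three"` or `"two"`.
#' @return A scalar in \[0, 1\].
#' @export
iou_summary <- function(truth, pred, mode = c("three", "two")) {
  mode <- match.arg(mode)
  check_same_shape(truth, pred)
  t_l <- as_label_matrix(truth)
  p_l <- as_label_matrix(pred)
  if (mode == "three") {
    present <- vapply(0:2, function(c) any(t_l == c) || any(p_l == c),
                      logical(1))
    # classes absent from both masks carry no information and are left out
    # of the average (they would otherwise score a vacuous 1)
    mean(vapply((0:2)[present], function(c) iou_class(truth, pred, c),
                numeric(1)))
  } else {
    cells_t <- t_l > 0L
    cells_p <- p_l > 0L
    iou_bin <- function(a, b) {
      u <- sum(a | b)
      if (u == 0L) NA_real_ else sum(a & b) / u
    }
    mean(c(iou_bin(!cells_t, !cells_p), iou_bin(cells_t, cells_p)),
         na.rm = TRUE)
  }
}

#' Per-image IoU report
#'
#' Computes per-class IoU, IoU3 and IoU2 for each (truth, prediction) pair
#' and returns one tidy row per image. The mean of a column (with its
#' standard error) is the per-image-averaged test metric; pass the pooled
#' masks yourself if you want the dataset-pooled alternative.
#'
#' @param data A data frame with list-columns `truth` and `pred` holding
#'   [class_mask()] objects, and optionally an `id` column.
#' @return A tibble with columns id, iou_background, iou_nodes, iou_tubes,
#'   iou3, iou2.
#' @export
iou_report <- function(data) {
  stopifnot(all(c("truth", "pred") %in% names(data)))
  ids <- if ("id" %in% names(data)) data$id else as.character(seq_len(nrow(data)))
  purrr::map2_dfr(data$truth, data$pred, function(t, p) {
    tibble(
      iou_background = iou_class(t, p, 0L),
      iou_nodes = iou_class(t, p, 1L),
      iou_tubes = iou_class(t, p, 2L),
      iou3 = iou_summary(t, p, "three"),
      iou2 = iou_summary(t, p, "two")
    )
  }) |>
    dplyr::mutate(id = ids, .before = 1L)
}
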