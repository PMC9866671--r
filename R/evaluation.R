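#' One-sided Wilcoxon signed-rank model comparison
#'
#' Paired test over per-fold scores: the null hypothesis is that the first
#' model's median is no greater than the second's; it is rejected (decision
#' `"a_greater"`) when the one-sided p-value falls below `alpha`, otherwise
#' no claim is made. Zero differences are dropped before ranking
#' (Wilcoxon's original treatment) and ties among |differences| receive
#' mid-ranks. The null distribution is exact (a shift-algorithm
#' convolution over the signed ranks, valid with ties) up to
#' `exact_threshold` retained pairs; beyond that a normal approximation
#' with continuity and tie correction is used.
#'
#' @param scores_a,scores_b Equal-length (k >= 5) numeric vectors, paired
#'   by fold.
#' @param alpha Significance level (default 0.05).
#' @param exact_threshold Largest k for which the exact null is used;
#'   defaults to 25 so a 25-fold comparison is exact.
#' @return An `angio_comparison` one-row tibble: statistic (W+), p_value,
#'   alpha, decision, n_used.
#' @examples
#' wilcoxon_one_sided(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
#' @export
wilcoxon_one_sided <- function(scores_a, scores_b, alpha = 0.05,
                               exact_threshold = 25L) {
  if (length(scores_a) != length(scores_b))
    abort("score vectors must have equal length.")
  if (length(scores_a) < 5L)
    abort("need at least 5 paired scores.")
  d <- scores_a - scores_b
  d <- d[d != 0]
  k <- length(d)
  if (k == 0L) {
    return(comparison_row(statistic = 0, p = 1, alpha = alpha,
                          decision = "no_claim", n_used = 0L))
  }
  r <- rank(abs(d)) # mid-ranks for ties
  w_pos <- sum(r[d > 0])
  if (k <= exact_threshold) {
    p <- signed_rank_exact_p(r, w_pos)
  } else {
    mu <- k * (k + 1) / 4
    ties <- table(r)
    sig2 <- k * (k + 1) * (2 * k + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_pos - mu - 0.5) / sqrt(sig2)
    p <- pnorm(z, lower.tail = FALSE)
  }
  comparison_row(statistic = w_pos, p = p, alpha = alpha,
                 decision = if (p < alpha) "a_greater" else "no_claim",
                 n_used = k)
}

comparison_row <- function(statistic, p, alpha, decision, n_used) {
  structure(tibble(statistic = statistic, p_value = p, alpha = alpha,
                   decision = decision, n_used = n_used),
            class = c("angio_comparison", class(tibble())))
}

# Exact P(W+ >= w_obs) by counting sign assignments with a polynomial
# (shift) convolution over doubled ranks, so mid-ranks (halves) stay
# integral. Cost O(k * sum(ranks)); trivial for k <= 25.
signed_rank_exact_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L) # counts[w + 1] = #assignments with 2W = w
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  w2 <- as.integer(round(2 * w_obs))
  sum(counts[(w2 + 1L):(total + 1L)]) / 2^length(r2)
}

#' Score models across train-group x test-group grids
#'
#' For each trained model (keyed by the data group it was trained on) and
#' each test group, predicts every test image and reports per-image mean
#' IoU3 and IoU2 with standard errors of the mean, one tidy row per
#' (train_group, test_group, metric) cell. Empty test groups produce an
#' NA-flagged cell.
#'
#' @param models Named list of `angio_model` objects (names = train group).
#' @param test_sets Named list of data frames with list-columns `image`
#'   and `mask` (names = test group).
#' @return An `angio_grid` tibble: train_group, test_group, metric, mean,
#'   sem, n.
#' @export
evaluate_grid <- function(models, test_sets) {
  if (length(models) == 0L || length(test_sets) == 0L)
    abort("`models` and `test_sets` must be nonempty named lists.")
  rows <- list()
  for (tg in names(models)) {
    for (sg in names(test_sets)) {
      te <- test_sets[[sg]]
      if (is.null(te) || nrow(te) == 0L) {
        rows[[length(rows) + 1L]] <-
          tibble(train_group = tg, test_group = sg,
                 metric = c("iou3", "iou2"), mean = NA_real_,
                 sem = NA_real_, n = 0L)
        next
      }
      sc <- score_set(models[[tg]], te)$per_image
      n <- nrow(sc)
      rows[[length(rows) + 1L]] <- tibble(
        train_group = tg, test_group = sg,
        metric = c("iou3", "iou2"),
        mean = c(mean(sc$iou3), mean(sc$iou2)),
        sem = c(sd(sc$iou3), sd(sc$iou2)) / sqrt(n),
        n = n
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (any(out$n == 1L)) out$sem[out$n == 1L] <- 0
  structure(out, class = c("angio_grid", class(out)))
}

#' Pairwise encoder/architecture comparison over shared folds
#'
#' Runs [wilcoxon_one_sided()] for every ordered pair of models on both
#' IoU3 and IoU2 fold-score vectors. All score sets must come from the
#' same fold assignment (pairing by fold is what makes the test valid).
#'
#' @param fold_scores Named list of `angio_fold_scores` (e.g. from
#'   [cross_validate()]), one per encoder or architecture.
#' @param alpha Significance level.
#' @param holm Apply a Holm correction across the pairwise p-values
#'   (off by default, matching the uncorrected study procedure).
#' @return An `angio_comparison` tibble with one row per ordered pair and
#'   metric: model_a, model_b, metric, statistic, p_value, alpha, decision.
#' @export
compare_encoders <- function(fold_scores, alpha = 0.05, holm = FALSE) {
  if (length(fold_scores) < 2L) abort("need at least two score sets.")
  ks <- vapply(fold_scores, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    abort("all fold-score sets must have the same number of folds.")
  folds <- lapply(fold_scores, attr, "folds")
  if (!all(vapply(folds[-1], identical, logical(1), folds[[1]])))
    abort("fold assignments differ between models; scores are not paired.")
  nms <- names(fold_scores)
  rows <- list()
  for (a in nms) for (b in nms) {
    if (a == b) next
    for (metric in c("iou3", "iou2")) {
      res <- wilcoxon_one_sided(fold_scores[[a]][[metric]],
                                fold_scores[[b]][[metric]], alpha)
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(res, model_a = a, model_b = b, metric = metric,
                      .before = 1L)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (holm) {
    out$p_value <- stats::p.adjust(out$p_value, method = "holm")
    out$decision <- ifelse(out$p_value < out$alpha, "a_greater", "no_claim")
  }
  structure(out, class = c("angio_comparison", class(out)))
}
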