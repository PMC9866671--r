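# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy an agreement matrix into pair rows
#'
#' @param x An `angio_agreement` from [kappa_matrix()].
#' @param ... Unused.
#' @return A tibble: participant_a, participant_b, role_pair, kappa, band.
#' @method tidy angio_agreement
#' @export
tidy.angio_agreement <- function(x, ...) {
  K <- x$kappa
  pairs <- which(upper.tri(K), arr.ind = TRUE)
  roles <- x$roster$role
  tibble(
    participant_a = rownames(K)[pairs[, 1]],
    participant_b = colnames(K)[pairs[, 2]],
    role_pair = paste(substr(roles[pairs[, 1]], 1, 1),
                      substr(roles[pairs[, 2]], 1, 1), sep = "-"),
    kappa = K[pairs],
    band = interpret_kappa(K[pairs])
  )
}

#' @rdname tidy.angio_agreement
#' @method glance angio_agreement
#' @export
glance.angio_agreement <- function(x, ...) {
  group_mean_kappa(x) |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("mean", "sd", "n_pairs"))
}

#' Tidy fold scores into long metric rows
#'
#' @param x An `angio_fold_scores` from [cross_validate()].
#' @param ... Unused.
#' @method tidy angio_fold_scores
#' @export
tidy.angio_fold_scores <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::all_of(c("iou3", "iou2")),
                      names_to = "metric", values_to = "score")
}

#' Model summaries
#'
#' `glance()` reports architecture, encoder and parameter counts;
#' `tidy()` one row per parameter set with its size and trainability.
#'
#' @param x An `angio_model`.
#' @param ... Unused.
#' @method glance angio_model
#' @export
glance.angio_model <- function(x, ...) {
  tibble(architecture = x$spec$architecture, encoder = x$spec$encoder,
         n_classes = x$spec$n_classes,
         n_params = n_parameters(x),
         n_encoder_params = n_parameters(x, "encoder"),
         n_decoder_params = n_parameters(x, "decoder"),
         n_trainable = n_parameters(x, "trainable"),
         best_epoch = x$best_epoch %||% NA_integer_)
}

#' @rdname glance.angio_model
#' @method tidy angio_model
#' @export
tidy.angio_model <- function(x, ...) {
  tibble(
    param = names(x$params),
    part = ifelse(names(x$params) %in% x$encoder_granules, "encoder",
                  "decoder"),
    n = vapply(x$params, nn_param_count, numeric(1)),
    trainable = names(x$params) %in% x$trainable
  )
}

#' Plot an agreement matrix as a heatmap
#'
#' Missing entries (participants who did not annotate the image) are shown
#' as blank cells.
#'
#' @param object An `angio_agreement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angio_agreement
#' @export
autoplot.angio_agreement <- function(object, ...) {
  K <- object$kappa
  df <- tidyr::expand_grid(a = rownames(K), b = colnames(K)) |>
    dplyr::mutate(kappa = as.vector(t(K)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a,
                                   fill = .data$kappa)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$kappa), "", sprintf("%.2f", .data$kappa))),
      size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "kappa") +
    ggplot2::theme_minimal()
}

#' Plot a train/test grid report
#'
#' One tile per (train group, test group) cell, faceted by metric, with
#' mean scores printed in the tiles.
#'
#' @param object An `angio_grid` from [evaluate_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angio_grid
#' @export
autoplot.angio_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$test_group,
                                       y = .data$train_group,
                                       fill = .data$mean)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$mean), "-",
                     sprintf("%.2f±%.2f", .data$mean, .data$sem))),
      size = 3) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "test group", y = "train group", fill = "mean") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss and validation IoU curves per epoch.
#'
#' @param object An `angio_history` (the `$history` of a trained model).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angio_history
#' @export
autoplot.angio_history <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"epoch",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot fold scores
#'
#' @param object An `angio_fold_scores`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot angio_fold_scores
#' @export
autoplot.angio_fold_scores <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$metric,
                                             y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "held-out IoU") +
    ggplot2::theme_minimal()
}

#' Overlay the skeleton graph on a mask
#'
#' Visual QC of the quantification: class mask underneath, skeleton pixels
#' and graph vertices on top.
#'
#' @param graph An `angio_graph` from [build_graph()].
#' @param mask The originating [class_mask()].
#' @return A ggplot object.
#' @export
plot_skeleton <- function(graph, mask) {
  p <- plot_mask(mask)
  sk <- which(graph$skeleton, arr.ind = TRUE)
  if (nrow(sk) > 0L)
    p <- p + ggplot2::geom_point(
      data = tibble(row = sk[, 1], col = sk[, 2]),
      ggplot2::aes(x = .data$col, y = .data$row),
      inherit.aes = FALSE, size = 0.2, color = "black")
  if (nrow(graph$vertices) > 0L)
    p <- p + ggplot2::geom_point(
      data = graph$vertices,
      ggplot2::aes(x = .data$col, y = .data$row, shape = .data$kind),
      inherit.aes = FALSE, size = 2, color = "yellow")
  p
}
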