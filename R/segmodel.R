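#' Specify a segmentation model
#'
#' The package builds small encoder--decoder networks for three-class
#' (background/node/tube) segmentation. Three decoder families are
#' available: plain Unet (skip connections at each resolution), Unet++
#' (nested skip pathways, additional intermediate decoder nodes) and a
#' DeepLabV3+-style design (parallel dilated convolutions over the deepest
#' features plus a low-level skip). The `"toy"` encoder is a six-layer
#' convolutional feature extractor (under 1M parameters) that always
#' resolves offline and trains in minutes on a CPU; named ImageNet
#' classifiers are not shipped and are rejected unless resolvable.
#'
#' @param architecture `"unet"`, `"unetpp"` or `"deeplabv3p"`.
#' @param encoder Encoder name; only `"toy"` resolves without external
#'   weights.
#' @param encoder_pretrained Logical; requesting pretrained weights for an
#'   unresolvable encoder is an error.
#' @param base_filters Width of the first toy-encoder stage.
#' @param input_size Expected (H, W); both must be divisible by the model's
#'   downsampling factor of 4.
#' @return A `model_spec` list.
#' @export
model_spec <- function(architecture = c("unetpp", "unet", "deeplabv3p"),
                       encoder = "toy", encoder_pretrained = FALSE,
                       base_filters = 8L, input_size = c(128L, 128L)) {
  architecture <- match.arg(architecture)
  if (any(input_size %% 4L != 0L))
    abort("`input_size` must be divisible by the downsampling factor (4).")
  if (encoder != "toy")
    abort(paste0("encoder '", encoder, "' is not resolvable offline; ",
                 "use encoder = 'toy'."))
  if (encoder_pretrained)
    abort("no pretrained weights are available for the toy encoder.")
  structure(list(architecture = architecture, encoder = encoder,
                 encoder_pretrained = encoder_pretrained,
                 base_filters = as.integer(base_filters),
                 n_classes = 3L,
                 input_size = as.integer(input_size)),
            class = "angio_model_spec")
}

# Toy encoder: three stages of two 3x3 convs, max-pooled between stages.
# Returns the graph with nodes for e0 (full res), e1 (/2), e2 (/4) and the
# ordered list of encoder parameter names (the fine-tuning granules).
build_encoder <- function(g, f) {
  conv_block <- function(g, input, name, cin, cout) {
    g$params[[name]] <- nn_init_conv(3L, 3L, cin, cout)
    g <- nn_add(g, "conv", input, param = name, pad = 1L, dil = 1L)
    nn_add(g, "relu", g$id)
  }
  g <- nn_add(g, "input"); in_id <- g$id
  g <- conv_block(g, in_id, "enc1a", 1L, f)
  g <- conv_block(g, g$id, "enc1b", f, f);      e0 <- g$id
  g <- nn_add(g, "pool", e0)
  g <- conv_block(g, g$id, "enc2a", f, 2L * f)
  g <- conv_block(g, g$id, "enc2b", 2L * f, 2L * f); e1 <- g$id
  g <- nn_add(g, "pool", e1)
  g <- conv_block(g, g$id, "enc3a", 2L * f, 4L * f)
  g <- conv_block(g, g$id, "enc3b", 4L * f, 4L * f); e2 <- g$id
  list(g = g, e0 = e0, e1 = e1, e2 = e2,
       granules = c("enc1a", "enc1b", "enc2a", "enc2b", "enc3a", "enc3b"))
}

add_conv <- function(g, input, name, cin, cout, k = 3L, dil = 1L,
                     relu = TRUE) {
  pad <- if (k == 1L) 0L else dil
  g$params[[name]] <- nn_init_conv(k, k, cin, cout)
  g <- nn_add(g, "conv", input, param = name, pad = pad, dil = dil)
  if (relu) g <- nn_add(g, "relu", g$id)
  g
}

#' Build a segmentation model
#'
#' Instantiates the network of a [model_spec()] with seeded He-normal
#' weights. The returned model maps an H x W image (H, W divisible by 4)
#' to an H x W x 3 per-pixel class-probability array.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An `angio_model` object.
#' @examples
#' m <- build_model(model_spec("unet"), seed = 1)
#' n_parameters(m)
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "angio_model_spec"))
  f <- spec$base_filters
  set.seed(seed)
  enc <- build_encoder(nn_graph_new(), f)
  g <- enc$g
  if (spec$architecture == "unet") {
    g <- nn_add(g, "up", enc$e2)
    g <- nn_add(g, "concat", c(g$id, enc$e1))
    g <- add_conv(g, g$id, "dec2", 6L * f, 2L * f)
    g <- nn_add(g, "up", g$id)
    g <- nn_add(g, "concat", c(g$id, enc$e0))
    g <- add_conv(g, g$id, "dec1", 3L * f, f)
    g <- add_conv(g, g$id, "out", f, 3L, k = 1L, relu = FALSE)
  } else if (spec$architecture == "unetpp") {
    # nested skip pathway: X01 and X11 are intermediate decoder nodes,
    # X02 fuses the full-resolution chain
    g <- nn_add(g, "up", enc$e1)
    g <- nn_add(g, "concat", c(enc$e0, g$id))
    g <- add_conv(g, g$id, "dec01", 3L * f, f); x01 <- g$id
    g <- nn_add(g, "up", enc$e2)
    g <- nn_add(g, "concat", c(enc$e1, g$id))
    g <- add_conv(g, g$id, "dec11", 6L * f, 2L * f)
    g <- nn_add(g, "up", g$id)
    g <- nn_add(g, "concat", c(enc$e0, x01, g$id))
    g <- add_conv(g, g$id, "dec02", 4L * f, f)
    g <- add_conv(g, g$id, "out", f, 3L, k = 1L, relu = FALSE)
  } else { # deeplabv3p
    g <- add_conv(g, enc$e0, "lowproj", f, f, k = 1L); low <- g$id
    g <- add_conv(g, enc$e2, "aspp1", 4L * f, f, k = 1L); a1 <- g$id
    g <- add_conv(g, enc$e2, "aspp2", 4L * f, f, dil = 2L); a2 <- g$id
    g <- add_conv(g, enc$e2, "aspp3", 4L * f, f, dil = 4L); a3 <- g$id
    g <- nn_add(g, "concat", c(a1, a2, a3))
    g <- add_conv(g, g$id, "asppproj", 3L * f, f, k = 1L)
    g <- nn_add(g, "up", g$id)
    g <- nn_add(g, "up", g$id)
    g <- nn_add(g, "concat", c(g$id, low))
    g <- add_conv(g, g$id, "refine", 2L * f, f)
    g <- add_conv(g, g$id, "out", f, 3L, k = 1L, relu = FALSE)
  }
  model <- structure(list(
    spec = spec, graph = g, params = g$params,
    encoder_granules = enc$granules,
    decoder_params = setdiff(names(g$params), enc$granules),
    trainable = names(g$params),
    seed = as.integer(seed)
  ), class = "angio_model")
  model
}

#' @export
print.angio_model <- function(x, ...) {
  cat(sprintf("<angio_model> %s / %s encoder, %d parameters\n",
              x$spec$architecture, x$spec$encoder, n_parameters(x)))
  cat(sprintf("  encoder %d | decoder %d | trainable %d\n",
              n_parameters(x, "encoder"), n_parameters(x, "decoder"),
              n_parameters(x, "trainable")))
  invisible(x)
}

#' Parameter counts of a model
#'
#' @param model An `angio_model`.
#' @param which `"all"`, `"encoder"`, `"decoder"` or `"trainable"`.
#' @return Integer count.
#' @export
n_parameters <- function(model, which = c("all", "encoder", "decoder",
                                          "trainable")) {
  which <- match.arg(which)
  nms <- switch(which, all = names(model$params),
                encoder = model$encoder_granules,
                decoder = model$decoder_params,
                trainable = model$trainable)
  sum(vapply(model$params[nms], nn_param_count, numeric(1)))
}

param_checksums <- function(model) {
  vapply(model$params, function(p) digest::digest(list(p$W, p$b)),
         character(1))
}

#' Freeze the encoder of a model
#'
#' Restricts training to the decoder parameters (the usual first step when
#' the encoder acts as a fixed feature extractor).
#'
#' @param model An `angio_model`.
#' @return The model with only decoder parameters trainable.
#' @export
freeze_encoder <- function(model) {
  model$trainable <- model$decoder_params
  model
}

set_trainable <- function(model, names) {
  stopifnot(all(names %in% names(model$params)))
  model$trainable <- names
  model
}

#' Partition the encoder into near-equal parameter blocks
#'
#' Greedy in-order packing of the encoder's layer granules (a layer's
#' weight+bias set is indivisible): granules are accumulated until the
#' cumulative parameter count reaches `round(total / n_blocks * i)` for
#' block i. Blocks are ordered from the input side to the output side,
#' are disjoint and cover the encoder exactly.
#'
#' @param model An `angio_model`.
#' @param n_blocks Number of blocks (at most the number of granules).
#' @return An `angio_partition`: list of character vectors of parameter
#'   names, with per-block parameter counts as an attribute.
#' @export
partition_encoder <- function(model, n_blocks) {
  gran <- model$encoder_granules
  if (n_blocks < 1L || n_blocks > length(gran))
    abort(sprintf("`n_blocks` must be in 1..%d (one per layer granule).",
                  length(gran)))
  sizes <- vapply(model$params[gran], nn_param_count, numeric(1))
  idx <- greedy_partition(sizes, n_blocks)
  blocks <- lapply(idx, function(i) gran[i])
  structure(blocks,
            sizes = vapply(idx, function(i) sum(sizes[i]), numeric(1)),
            class = "angio_partition")
}

# Greedy in-order packing of granule sizes into n near-equal blocks:
# block b accumulates consecutive granules until the cumulative size
# reaches round(total / n * b). Every block gets at least one granule and
# enough granules are held back that later blocks are never empty.
# Returns a list of index vectors.
greedy_partition <- function(sizes, n_blocks) {
  n_gran <- length(sizes)
  stopifnot(n_blocks >= 1L, n_blocks <= n_gran)
  total <- sum(sizes)
  blocks <- vector("list", n_blocks)
  cum <- 0; gi <- 1L
  for (b in seq_len(n_blocks)) {
    target <- round(total / n_blocks * b)
    take <- integer()
    repeat {
      room <- (n_gran - gi) >= (n_blocks - b)
      if (gi > n_gran || !room) break
      take <- c(take, gi)
      cum <- cum + sizes[gi]
      gi <- gi + 1L
      if (cum >= target && b < n_blocks) break
    }
    if (b == n_blocks && gi <= n_gran) {
      take <- c(take, gi:n_gran)
      gi <- n_gran + 1L
    }
    blocks[[b]] <- take
  }
  blocks
}

#' @export
print.angio_partition <- function(x, ...) {
  cat(sprintf("<angio_partition> %d blocks (params: %s)\n", length(x),
              paste(attr(x, "sizes"), collapse = ", ")))
  invisible(x)
}

#' Training configuration
#'
#' @param gamma Focal-loss focusing parameter (default 0.5, the value found
#'   to work best for this assay).
#' @param alpha Per-class focal weights; `NULL` derives them from the
#'   training masks via [class_proportions()] and [derive_alpha()].
#' @param epochs,batch_size,learning_rate Usual optimiser knobs (Adam).
#' @param seed Seed controlling shuffling, augmentation and any weight
#'   re-initialisation.
#' @param k_folds Folds for [cross_validate()] / fine-tuning stages.
#' @param augmentation Random flips and 90-degree rotations during training.
#' @return A `train_config` list.
#' @export
train_config <- function(gamma = 0.5, alpha = NULL, epochs = 8L,
                         batch_size = 4L, learning_rate = 3e-3,
                         seed = 0L, k_folds = 5L, augmentation = TRUE) {
  stopifnot(gamma >= 0, epochs >= 1, batch_size >= 1, learning_rate > 0,
            k_folds >= 2)
  structure(list(gamma = gamma, alpha = alpha, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 k_folds = as.integer(k_folds),
                 augmentation = isTRUE(augmentation)),
            class = "angio_train_config")
}

as_input_array <- function(image) {
  if (length(dim(image)) == 2L) array(image, dim = c(dim(image), 1L))
  else image
}

forward_probs <- function(model, image) {
  outs <- nn_forward(model$graph, as_input_array(image))
  z <- outs[[length(outs)]]$y
  list(outs = outs, probs = softmax_channels(z))
}

augment_pair <- function(image, mask) {
  k <- sample.int(4L, 1L) - 1L
  fl <- sample.int(2L, 1L) == 2L
  rot <- function(m, k) { for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE]); m }
  img <- rot(image, k); msk <- rot(as_label_matrix(mask), k)
  if (fl) { img <- img[nrow(img):1, , drop = FALSE]; msk <- msk[nrow(msk):1, , drop = FALSE] }
  list(image = img, mask = class_mask(msk))
}

#' Train a segmentation model
#'
#' Optimises the multiclass focal loss with Adam. The history records the
#' per-epoch mean training loss and validation IoU3/IoU2 (per-image
#' averages); the snapshot with the best validation IoU3 is returned.
#' Only the model's trainable parameter set is updated, so the same
#' function drives initial decoder training and block-wise fine-tuning.
#'
#' @param model An `angio_model` (use [freeze_encoder()] first to train the
#'   decoder only).
#' @param train,val Data frames with list-columns `image` and `mask`
#'   (`val` may have zero rows to skip validation).
#' @param config A [train_config()].
#' @return The best model, with `$history` (a tibble: epoch, loss, val_iou3,
#'   val_iou2) and `$best_epoch` attached.
#' @export
train_model <- function(model, train, val, config = train_config()) {
  stopifnot(nrow(train) >= 1L)
  alpha <- config$alpha %||%
    derive_alpha(class_proportions(train$mask))
  set.seed(config$seed)
  opt <- adam_init(model$params)
  history <- vector("list", config$epochs)
  best <- list(iou3 = -Inf, params = model$params, epoch = 0L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nrow(train))
    losses <- numeric(0)
    pending <- 0L; acc <- NULL
    for (i in ord) {
      pair <- list(image = train$image[[i]], mask = train$mask[[i]])
      if (config$augmentation) pair <- augment_pair(pair$image, pair$mask)
      fw <- forward_probs(model, pair$image)
      loss <- focal_loss(fw$probs, pair$mask, alpha, config$gamma)
      if (!is.finite(loss))
        abort(sprintf("training diverged at epoch %d (non-finite loss).", ep))
      losses <- c(losses, loss)
      dp <- focal_grad_p(fw$probs, pair$mask, alpha, config$gamma)
      dz <- softmax_backward(fw$probs, dp)
      gr <- nn_backward(model$graph, fw$outs, dz)$params
      acc <- if (is.null(acc)) gr else accumulate_grads(acc, gr)
      pending <- pending + 1L
      if (pending == config$batch_size || i == ord[length(ord)]) {
        acc <- scale_grads(acc, 1 / pending)
        st <- adam_step(model$params, acc, opt, model$trainable,
                        lr = config$learning_rate)
        model$params <- st$params
        model$graph$params <- st$params
        opt <- st$state
        acc <- NULL; pending <- 0L
      }
    }
    vi3 <- NA_real_; vi2 <- NA_real_
    if (nrow(val) > 0L) {
      sc <- score_set(model, val)
      vi3 <- sc$iou3; vi2 <- sc$iou2
      if (vi3 > best$iou3) best <- list(iou3 = vi3, params = model$params,
                                        epoch = ep)
    } else {
      best <- list(iou3 = NA_real_, params = model$params, epoch = ep)
    }
    history[[ep]] <- tibble(epoch = ep, loss = mean(losses),
                            val_iou3 = vi3, val_iou2 = vi2)
  }
  model$params <- best$params
  model$graph$params <- best$params
  model$history <- dplyr::bind_rows(history)
  model$best_epoch <- best$epoch
  model$alpha <- alpha
  class(model$history) <- c("angio_history", class(model$history))
  model
}

accumulate_grads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) a[[nm]] <- b[[nm]]
    else {
      a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
      a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
    }
  }
  a
}

scale_grads <- function(g, s) {
  lapply(g, function(p) list(W = p$W * s, b = p$b * s))
}

# Mean per-image IoU3/IoU2 of model predictions over a dataset tibble.
score_set <- function(model, data) {
  scores <- purrr::map2(data$image, data$mask, function(img, msk) {
    pred <- predict(model, img)
    c(iou_summary(msk, pred, "three"), iou_summary(msk, pred, "two"))
  })
  m <- do.call(rbind, scores)
  list(iou3 = mean(m[, 1]), iou2 = mean(m[, 2]),
       per_image = tibble(iou3 = m[, 1], iou2 = m[, 2]))
}

#' Predict a class mask for an image
#'
#' Runs the network and decodes the per-pixel argmax (ties broken toward
#' the lower class index, i.e. background first). Images larger than
#' `tile` are processed in overlapping tiles (25\% overlap) whose logits
#' are averaged in the overlaps before decoding, so full-resolution
#' micrographs fit in memory.
#'
#' @param object An `angio_model`.
#' @param image Numeric H x W matrix with intensities in \[0, 1\].
#' @param tile Tile side used for large images; must be divisible by 4.
#' @param ... Unused.
#' @return A [class_mask()] of the same H x W.
#' @export
predict.angio_model <- function(object, image, tile = 256L, ...) {
  h0 <- nrow(image); w0 <- ncol(image)
  # pad to a multiple of the downsampling factor by edge replication
  h <- ceiling(h0 / 4) * 4L; w <- ceiling(w0 / 4) * 4L
  if (h != h0 || w != w0)
    image <- image[pmin(seq_len(h), h0), pmin(seq_len(w), w0), drop = FALSE]
  logits_of <- function(img) {
    outs <- nn_forward(object$graph, as_input_array(img))
    outs[[length(outs)]]$y
  }
  if (h <= tile && w <= tile) {
    z <- logits_of(image)
  } else {
    step <- max(4L, (tile - tile %/% 4L) %/% 4L * 4L) # 25% overlap
    z <- array(0, dim = c(h, w, 3L))
    cnt <- matrix(0, h, w)
    starts <- function(n) {
      if (n <= tile) return(1L)
      s <- seq(1L, n - tile, by = step)
      unique(c(s, n - tile + 1L))
    }
    for (i0 in starts(h)) for (j0 in starts(w)) {
      ti <- min(tile, h); tj <- min(tile, w)
      ii <- i0:(i0 + ti - 1L); jj <- j0:(j0 + tj - 1L)
      zt <- logits_of(image[ii, jj, drop = FALSE])
      z[ii, jj, ] <- z[ii, jj, , drop = FALSE] + zt
      cnt[ii, jj] <- cnt[ii, jj] + 1
    }
    z <- z / as.vector(cnt)
  }
  lab <- max.col(matrix(z, h * w, 3L), ties.method = "first") - 1L
  out <- matrix(as.integer(lab), h, w)
  class_mask(out[seq_len(h0), seq_len(w0), drop = FALSE])
}

#' k-fold cross-validation of a model specification
#'
#' Shuffles the images into k folds by seed, trains one model per fold on
#' the remaining folds and scores it on the held-out fold (per-image mean
#' IoU3/IoU2). The per-fold score vectors are the paired samples consumed
#' by the Wilcoxon model comparison.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with list-columns `image` and `mask` and
#'   optionally `id`.
#' @param config A [train_config()]; `config$k_folds` sets k.
#' @return An `angio_fold_scores` tibble (fold, iou3, iou2) with the fold
#'   assignment in `attr(, "folds")`.
#' @export
cross_validate <- function(spec, data, config = train_config()) {
  k <- config$k_folds
  n <- nrow(data)
  if (n < k) abort("dataset smaller than the number of folds.")
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(k), n))
  ids <- if ("id" %in% names(data)) data$id else as.character(seq_len(n))
  res <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    model <- freeze_encoder(build_model(spec, seed = config$seed + f))
    model <- train_model(model, tr, te, config)
    sc <- score_set(model, te)
    tibble(fold = f, iou3 = sc$iou3, iou2 = sc$iou2)
  })
  structure(res, folds = setNames(fold, ids),
            class = c("angio_fold_scores", class(res)))
}

#' Sequential block-wise fine-tuning
#'
#' Starting from a model whose decoder has been trained with a frozen
#' encoder, the encoder blocks of a [partition_encoder()] partition are
#' unfrozen one at a time: at each stage all parameters are frozen, the
#' current block alone is unfrozen and trained under k-fold
#' cross-validation, and the best-validation-IoU3 fold model is carried
#' into the next stage. `direction = "reverse"` visits blocks from the
#' output side back to the input side. With `reset_weights = TRUE` the
#' newly unfrozen block is re-initialised to random values before training
#' (the ablation variant, which underperforms carrying the weights).
#'
#' @param model A trained `angio_model`.
#' @param partition An `angio_partition` of this model's encoder.
#' @param data Data frame with list-columns `image` and `mask`.
#' @param config A [train_config()]; `config$k_folds` folds per stage.
#' @param direction `"forward"` (input to output) or `"reverse"`.
#' @param reset_weights Re-initialise each block before its stage.
#' @return List of per-stage results: `block` (parameter names), `model`
#'   (the carried best model) and `fold_scores`.
#' @export
finetune_sequential <- function(model, partition, data,
                                config = train_config(),
                                direction = c("forward", "reverse"),
                                reset_weights = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(partition, "angio_partition"))
  if (!all(unlist(partition) %in% names(model$params)))
    abort("partition does not match this model's parameters.")
  order_ <- if (direction == "forward") seq_along(partition)
            else rev(seq_along(partition))
  k <- config$k_folds
  n <- nrow(data)
  stages <- list()
  current <- model
  for (s in seq_along(order_)) {
    block <- partition[[order_[s]]]
    set.seed(config$seed + 1000L * s)
    if (reset_weights) {
      for (nm in block) {
        p <- current$params[[nm]]
        current$params[[nm]] <- nn_init_conv(p$kh, p$kw, p$cin, p$cout)
      }
      current$graph$params <- current$params
    }
    fold <- sample(rep_len(seq_len(k), n))
    fold_models <- vector("list", k)
    scores <- purrr::map_dfr(seq_len(k), function(f) {
      m <- set_trainable(current, block)
      cfg <- config; cfg$seed <- config$seed + 1000L * s + f
      m <- train_model(m, data[fold != f, , drop = FALSE],
                       data[fold == f, , drop = FALSE], cfg)
      sc <- score_set(m, data[fold == f, , drop = FALSE])
      fold_models[[f]] <<- m
      tibble(fold = f, iou3 = sc$iou3, iou2 = sc$iou2)
    })
    best_fold <- which.max(scores$iou3) # ties: earlier fold wins
    current <- fold_models[[best_fold]]
    stages[[s]] <- list(block = block,
                        model = current,
                        best_fold = best_fold,
                        fold_scores = structure(
                          scores, folds = fold,
                          class = c("angio_fold_scores", class(scores))))
  }
  stages
}
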