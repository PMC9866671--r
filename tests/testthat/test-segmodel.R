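test_that("build_model produces valid probability maps deterministically", {
  spec <- model_spec("unet", input_size = c(32L, 32L))
  m1 <- build_model(spec, seed = 5)
  fw <- angioquant:::forward_probs(m1, matrix(runif(32 * 32), 32, 32))
  expect_equal(dim(fw$probs), c(32L, 32L, 3L))
  sums <- fw$probs[, , 1] + fw$probs[, , 2] + fw$probs[, , 3]
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-6)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))

  m2 <- build_model(spec, seed = 5)
  expect_identical(angioquant:::param_checksums(m1),
                   angioquant:::param_checksums(m2))
  m3 <- build_model(spec, seed = 6)
  expect_false(identical(angioquant:::param_checksums(m1),
                         angioquant:::param_checksums(m3)))
  expect_lt(n_parameters(m1), 1e6) # toy encoder stays desk-sized
})

test_that("unetpp has at least as many decoder parameters as unet", {
  u <- build_model(model_spec("unet"), seed = 1)
  upp <- build_model(model_spec("unetpp"), seed = 1)
  expect_identical(n_parameters(u, "encoder"), n_parameters(upp, "encoder"))
  expect_gte(n_parameters(upp, "decoder"), n_parameters(u, "decoder"))
  d <- build_model(model_spec("deeplabv3p"), seed = 1)
  fw <- angioquant:::forward_probs(d, matrix(0.5, 32, 32))
  expect_equal(dim(fw$probs), c(32L, 32L, 3L))
})

test_that("model specs validate their contracts", {
  expect_error(model_spec("unet", input_size = c(30L, 32L)), "divisible")
  expect_error(model_spec(encoder = "efficientnet-b7"), "resolvable")
  expect_error(model_spec(encoder_pretrained = TRUE), "pretrained")
})

test_that("greedy partition reproduces hand-traced blockings", {
  # equal granules: one per block
  expect_equal(angioquant:::greedy_partition(rep(20, 5), 5),
               list(1L, 2L, 3L, 4L, 5L))
  # ten equal granules into two blocks of five
  expect_equal(angioquant:::greedy_partition(rep(10, 10), 2),
               list(1:5, 6:10))
  # the cumulative-target trace: targets 33, 67 -> {30,10}, {10,30}, {20}
  expect_equal(angioquant:::greedy_partition(c(30, 10, 10, 30, 20), 3),
               list(1:2, 3:4, 5L))
  # a dominant first granule still leaves no block empty
  expect_equal(angioquant:::greedy_partition(c(100, 1, 1), 3),
               list(1L, 2L, 3L))
})

test_that("partition_encoder covers the encoder disjointly in order", {
  m <- build_model(model_spec("unetpp"), seed = 2)
  for (k in c(1, 2, 3, 6)) {
    part <- partition_encoder(m, k)
    expect_length(part, k)
    flat <- unlist(part)
    expect_identical(flat, m$encoder_granules) # order and coverage
    expect_equal(sum(attr(part, "sizes")), n_parameters(m, "encoder"))
    expect_true(all(lengths(part) >= 1L))
  }
  expect_error(partition_encoder(m, 7), "granule")
})

test_that("training reduces the focal loss and tracks history", {
  data <- synthetic_set(8, seed0 = 3000, canvas = c(64L, 64L))
  m <- freeze_encoder(build_model(model_spec("unetpp",
                                             input_size = c(64L, 64L)),
                                  seed = 1))
  cfg <- train_config(epochs = 3, seed = 1, augmentation = FALSE)
  fit <- train_model(m, data[1:6, ], data[7:8, ], cfg)
  expect_equal(nrow(fit$history), 3L)
  expect_lt(fit$history$loss[3], fit$history$loss[1])
  expect_true(all(!is.na(fit$history$val_iou3)))
  expect_true(fit$best_epoch %in% 1:3)
  # only decoder parameters moved
  m0 <- build_model(model_spec("unetpp", input_size = c(64L, 64L)), seed = 1)
  cks0 <- angioquant:::param_checksums(m0)
  cks1 <- angioquant:::param_checksums(fit)
  expect_identical(cks0[m0$encoder_granules], cks1[m0$encoder_granules])
  expect_false(any(cks0[m0$decoder_params] == cks1[m0$decoder_params]))
})

test_that("training is reproducible for a fixed seed", {
  data <- synthetic_set(6, seed0 = 4000, canvas = c(64L, 64L))
  cfg <- train_config(epochs = 2, seed = 7)
  run <- function() {
    m <- freeze_encoder(build_model(model_spec("unet",
                                               input_size = c(64L, 64L)),
                                    seed = 7))
    train_model(m, data[1:4, ], data[5:6, ], cfg)$history
  }
  expect_equal(run(), run(), tolerance = 1e-12)
})

test_that("the network can overfit a single image", {
  # one image per epoch means one optimiser update per epoch, so the
  # memorisation check needs a few hundred epochs
  smp <- angioquant:::synth_sample("Good", seed = 77, canvas = c(128L, 128L),
                                   n_nodes = c(3L, 4L), n_edges = c(3L, 4L))
  data <- tibble::tibble(id = "one", image = list(smp$image),
                         mask = list(smp$mask))
  m <- build_model(model_spec("unetpp", input_size = c(128L, 128L)), seed = 2)
  cfg <- train_config(epochs = 200, seed = 2, augmentation = FALSE,
                      learning_rate = 1e-2, batch_size = 1)
  fit <- train_model(m, data, data, cfg)
  pred <- predict(fit, smp$image)
  expect_gt(iou_summary(smp$mask, pred, "three"), 0.9)
})

test_that("prediction decodes argmax with background-first ties", {
  m <- build_model(model_spec("unet", input_size = c(32L, 32L)), seed = 1)
  # zero all weights: logits identical -> every pixel ties -> background
  for (nm in names(m$params)) {
    m$params[[nm]]$W[] <- 0
    m$params[[nm]]$b[] <- 0
  }
  m$graph$params <- m$params
  pred <- predict(m, matrix(runif(32 * 32), 32, 32))
  expect_true(all(unclass(pred) == 0L))
  # tiled prediction equals untiled on a constant image
  big <- matrix(0.4, 96, 64)
  expect_identical(unclass(predict(m, big, tile = 32L)),
                   unclass(predict(m, big, tile = 512L)))
  # non-multiple-of-4 sizes are padded and cropped back
  odd <- predict(m, matrix(0.3, 33, 30))
  expect_equal(dim(odd), c(33L, 30L))
})

test_that("cross_validate partitions images into reproducible folds", {
  data <- synthetic_set(4, seed0 = 5000, canvas = c(64L, 64L))
  cfg <- train_config(epochs = 1, seed = 3, k_folds = 2)
  fs <- cross_validate(model_spec("unet", input_size = c(64L, 64L)),
                       data, cfg)
  expect_equal(nrow(fs), 2L)
  expect_true(all(fs$iou3 >= 0 & fs$iou3 <= 1))
  folds <- attr(fs, "folds")
  expect_length(folds, 4L)
  expect_setequal(unique(folds), 1:2)
  fs2 <- cross_validate(model_spec("unet", input_size = c(64L, 64L)),
                        data, cfg)
  expect_identical(attr(fs2, "folds"), folds)
  expect_error(cross_validate(model_spec("unet"), data,
                              train_config(k_folds = 5)), "folds")
})

test_that("sequential fine-tuning freezes exactly one block per stage", {
  data <- synthetic_set(4, seed0 = 6000, canvas = c(64L, 64L))
  base <- freeze_encoder(build_model(model_spec("unet",
                                                input_size = c(64L, 64L)),
                                     seed = 4))
  cfg0 <- train_config(epochs = 1, seed = 4, k_folds = 2)
  base <- train_model(base, data[1:3, ], data[4, ], cfg0)
  part <- partition_encoder(base, 2)
  stages <- finetune_sequential(base, part, data, cfg0)
  expect_length(stages, 2L)
  for (s in 1:2) {
    st <- stages[[s]]
    expect_identical(sort(st$block), sort(part[[s]]))
    # trainable set of the carried model is exactly the stage block
    expect_setequal(st$model$trainable, part[[s]])
    expect_equal(n_parameters(st$model, "trainable"),
                 unname(attr(part, "sizes")[s]))
    expect_equal(st$best_fold, which.max(st$fold_scores$iou3))
  }
  # reverse order visits blocks output-side first
  rev_stages <- finetune_sequential(base, part, data, cfg0,
                                    direction = "reverse")
  expect_identical(rev_stages[[1]]$block, part[[2]])
})

test_that("weight reset reinitialises only the unfrozen block", {
  data <- synthetic_set(4, seed0 = 7000, canvas = c(64L, 64L))
  base <- freeze_encoder(build_model(model_spec("unet",
                                                input_size = c(64L, 64L)),
                                     seed = 5))
  cfg <- train_config(epochs = 1, seed = 5, k_folds = 2)
  base <- train_model(base, data[1:3, ], data[4, ], cfg)
  part <- partition_encoder(base, 2)
  cks_before <- angioquant:::param_checksums(base)
  stages <- finetune_sequential(base, part, data, cfg,
                                reset_weights = TRUE)
  # during stage 1 the carried model's block-1 weights were re-initialised
  # (and then trained); block 2 was still frozen and untouched
  cks_after1 <- angioquant:::param_checksums(stages[[1]]$model)
  expect_false(any(cks_before[part[[1]]] == cks_after1[part[[1]]]))
  expect_identical(cks_before[part[[2]]], cks_after1[part[[2]]])
})

test_that("models serialize to JSON and back without drift", {
  dir <- withr::local_tempdir()
  m <- build_model(model_spec("unetpp", input_size = c(32L, 32L)), seed = 9)
  img <- matrix(runif(32 * 32), 32, 32)
  p1 <- predict(m, img)
  save_model(m, file.path(dir, "ck.json"))
  m2 <- load_model(file.path(dir, "ck.json"))
  expect_identical(unclass(predict(m2, img)), unclass(p1))
  for (nm in names(m$params))
    expect_equal(m2$params[[nm]]$W, m$params[[nm]]$W, tolerance = 1e-12)
})
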