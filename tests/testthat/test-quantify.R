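test_that("split_mask filters specks and keeps node-bearing structures", {
  empty <- class_mask(matrix(0L, 32, 32))
  s <- split_mask(empty, min_object_px = 20)
  expect_equal(max(s$nodes), 0L)
  expect_equal(sum(s$tubes), 0L)

  lab <- matrix(0L, 32, 32)
  lab[5:14, 5:14] <- 1L # 100-px node blob
  s2 <- split_mask(class_mask(lab), min_object_px = 20)
  expect_equal(max(s2$nodes), 1L)

  specks <- matrix(0L, 32, 32)
  specks[2, 1:5] <- 1L
  specks[20, 1:5] <- 2L
  s3 <- split_mask(class_mask(specks), min_object_px = 20)
  expect_equal(max(s3$nodes), 0L)
  expect_equal(sum(s3$tubes), 0L)
})

test_that("skeletonization thins bars to unit-width paths", {
  bar <- matrix(FALSE, 20, 120)
  bar[8:12, 11:110] <- TRUE # 5 px wide, 100 px long
  sk <- skeletonize_tubes(bar)
  expect_equal(max(angioquant:::.label_components8(
    matrix(as.integer(sk), 20))), 1L)
  nb <- angioquant:::.neighbor_count8(matrix(as.integer(sk), 20))
  expect_true(all(nb[sk] <= 2L)) # a simple path, no junction pixels
  expect_gte(sum(sk), 100 - 5)
  expect_lte(sum(sk), 101)
  expect_equal(sum(skeletonize_tubes(matrix(FALSE, 10, 10))), 0L)
})

test_that("skeletonization preserves the topology of a ring", {
  ring <- matrix(FALSE, 60, 60)
  for (i in 1:60) for (j in 1:60) {
    d <- sqrt((i - 30)^2 + (j - 30)^2)
    ring[i, j] <- d >= 12 && d <= 20
  }
  sk <- skeletonize_tubes(ring)
  ski <- matrix(as.integer(sk), 60)
  expect_equal(max(angioquant:::.label_components8(ski)), 1L)
  # still encloses the hole: the inner background cannot reach the border
  # (4-connected background flood from the rim, the dual of 8-connected
  # foreground)
  reach <- matrix(FALSE, 60, 60)
  reach[1, ] <- reach[60, ] <- reach[, 1] <- reach[, 60] <- !sk[1, ] | TRUE
  reach <- reach & !sk
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-60, ]
    grown[-60, ] <- grown[-60, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -60]
    grown[, -60] <- grown[, -60] | reach[, -1]
    grown <- grown & !sk
    if (identical(grown, reach)) break
    reach <- grown
  }
  expect_gt(sum(!reach & !sk), 0) # interior pixels the rim flood misses
  # closed curve: every skeleton pixel keeps two neighbours
  nb <- angioquant:::.neighbor_count8(ski)
  expect_true(all(nb[sk] >= 2L))
})

test_that("build_graph traces bars, Ys and rings correctly", {
  no_nodes <- matrix(0L, 40, 140)
  bar <- matrix(FALSE, 40, 140)
  bar[19:23, 21:120] <- TRUE
  g <- build_graph(skeletonize_tubes(bar), no_nodes)
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(g$vertices$kind, "endpoint")
  expect_equal(g$edges$length, 100, tolerance = 0.08)

  # Y: three 50-px arms meeting at (60, 60)
  yimg <- matrix(FALSE, 120, 120)
  for (t in 0:50) {
    yimg[60 - t, 60] <- TRUE
    yimg[60 + round(0.7 * t), 60 - round(0.7 * t)] <- TRUE
    yimg[60 + round(0.7 * t), 60 + round(0.7 * t)] <- TRUE
  }
  # thicken to 3 px so thinning has something to do
  thick <- matrix(FALSE, 120, 120)
  idx <- which(yimg, arr.ind = TRUE)
  for (r in seq_len(nrow(idx)))
    thick[idx[r, 1] + (-1:1), idx[r, 2] + (-1:1)] <- TRUE
  gy <- build_graph(skeletonize_tubes(thick), matrix(0L, 120, 120))
  expect_equal(sum(gy$vertices$kind == "junction"), 1L)
  expect_equal(sum(gy$vertices$kind == "endpoint"), 3L)
  expect_equal(nrow(gy$edges), 3L)

  ring <- matrix(FALSE, 60, 60)
  for (i in 1:60) for (j in 1:60) {
    d <- sqrt((i - 30)^2 + (j - 30)^2)
    ring[i, j] <- d >= 12 && d <= 18
  }
  gr <- build_graph(skeletonize_tubes(ring), matrix(0L, 60, 60))
  expect_equal(nrow(gr$edges), 1L)
  expect_equal(gr$edges$from, gr$edges$to) # self-loop: one cycle
})

test_that("the two-node fixture yields the textbook measurements", {
  rg <- rasterize_ground_truth(two_node_layout())
  q <- quantify_mask(rg$mask, min_object_px = 20)
  expect_equal(q$branches, 1L)
  expect_equal(q$nodes, 2L)
  expect_equal(q$closed_networks, 0L)
  expect_equal(q$network_structures, 1L)
  expect_equal(q$total_branch_length, 80, tolerance = 0.1)
  expect_equal(q$tube_length, q$total_branch_length)
  expect_equal(q$node_area, 2 * pi * 100, tolerance = 0.02)
  expect_equal(q$units, "px")
})

test_that("the triangle layout closes one network", {
  lay <- sample_layout(3, 3, c(256, 256), seed = 7)
  rg <- rasterize_ground_truth(lay)
  q <- quantify_mask(rg$mask, min_object_px = 20)
  expect_equal(q$branches, 3L)
  expect_equal(q$nodes, 3L)
  expect_equal(q$closed_networks, 1L)
  expect_equal(q$branch_to_node_ratio, 1)
  expect_equal(q$triple_branched_nodes + q$quad_branched_nodes, 0L)
  expect_equal(q$average_branch_length * q$branches, q$total_branch_length,
               tolerance = 1e-9)
})

test_that("an empty mask measures all zeros with an absent ratio", {
  q <- quantify_mask(class_mask(matrix(0L, 64, 64)))
  expect_equal(q$branches, 0L)
  expect_equal(q$closed_networks, 0L)
  expect_equal(q$nodes, 0L)
  expect_true(is.na(q$branch_to_node_ratio))
  expect_true(is.na(q$average_branch_length))
  expect_equal(q$tube_coverage_area, 0)
})

test_that("generator layouts are recovered within the stated bands", {
  for (s in 1:10) {
    lay <- sample_layout(5, 5, c(320, 320), seed = 100 + s)
    rg <- rasterize_ground_truth(lay)
    q <- quantify_mask(rg$mask, min_object_px = 20)
    expect_equal(q$branches, rg$truth$n_branches)
    expect_equal(q$closed_networks, rg$truth$n_closed_networks)
    expect_lt(abs(q$total_branch_length - rg$truth$total_branch_length) /
                rg$truth$total_branch_length, 0.05)
    expect_lt(abs(q$node_area - rg$truth$node_area) / rg$truth$node_area,
              0.02)
  }
})

test_that("micrometre calibration scales lengths and areas exactly", {
  lay <- sample_layout(3, 3, c(256, 256), seed = 7)
  rg <- rasterize_ground_truth(lay)
  px <- quantify_mask(rg$mask, min_object_px = 20)
  um <- quantify_mask(rg$mask, pixel_size = 0.646, min_object_px = 20)
  expect_equal(um$total_branch_length, px$total_branch_length * 0.646)
  expect_equal(um$tube_coverage_area, px$tube_coverage_area * 0.646^2)
  expect_equal(um$node_area, px$node_area * 0.646^2)
  expect_equal(um$network_areas[[1]], px$network_areas[[1]] * 0.646^2)
  expect_equal(um$branches, px$branches)
  expect_equal(um$units, "um")
})

test_that("quantification is invariant under 90-degree rotation", {
  lay <- sample_layout(4, 4, c(300, 300), seed = 55)
  rg <- rasterize_ground_truth(lay)
  m <- unclass(rg$mask)
  rot <- t(m[nrow(m):1, ])
  q1 <- quantify_mask(rg$mask, min_object_px = 20)
  q2 <- quantify_mask(class_mask(rot), min_object_px = 20)
  expect_equal(q2$branches, q1$branches)
  expect_equal(q2$closed_networks, q1$closed_networks)
  expect_equal(q2$nodes, q1$nodes)
  expect_equal(q2$node_area, q1$node_area)
  expect_equal(q2$total_branch_length, q1$total_branch_length,
               tolerance = 0.01)
})
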