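test_that("load_sample round-trips images and validates masks", {
  dir <- withr::local_tempdir()
  img <- matrix(runif(32 * 24), 32, 24)
  png::writePNG(img, file.path(dir, "a.png"))
  msk <- random_mask(32, 24, seed = 1)
  write_mask(msk, file.path(dir, "a_mask.png"))
  s <- load_sample(file.path(dir, "a.png"), file.path(dir, "a_mask.png"),
                   category = "Good")
  expect_equal(dim(s$image), c(32L, 24L))
  expect_identical(dim(s$mask), dim(s$image))
  expect_equal(unclass(s$mask), unclass(msk), ignore_attr = TRUE)
  expect_true(all(s$image >= 0 & s$image <= 1))
})

test_that("a mask with labels outside {0,1,2} is rejected by name", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(c(0, 1, 2, 3) / 255, 2, 2), file.path(dir, "bad.png"))
  png::writePNG(matrix(0.5, 2, 2), file.path(dir, "img.png"))
  expect_error(load_sample(file.path(dir, "img.png"),
                           file.path(dir, "bad.png"), "Good"), "3")
})

test_that("shape mismatch and unknown formats are named errors", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "img.png"))
  write_mask(random_mask(3, 3), file.path(dir, "m.png"))
  expect_error(load_sample(file.path(dir, "img.png"),
                           file.path(dir, "m.png"), "Good"), "shape")
  writeLines("x", file.path(dir, "img.bmp"))
  expect_error(load_sample(file.path(dir, "img.bmp"), category = "Good"),
               "format")
})

test_that("RGB with equal channels loads like its grayscale equivalent", {
  dir <- withr::local_tempdir()
  g <- matrix(runif(16 * 16), 16, 16)
  png::writePNG(g, file.path(dir, "gray.png"))
  png::writePNG(array(rep(g, 3), dim = c(16, 16, 3)),
                file.path(dir, "rgb.png"))
  a <- load_sample(file.path(dir, "gray.png"), category = "Good")
  b <- load_sample(file.path(dir, "rgb.png"), category = "Good")
  expect_equal(a$image, b$image, tolerance = 1e-7)
})

cvat_xml <- function(path, shapes, h = 40, w = 40) {
  poly <- paste(vapply(shapes, function(s)
    sprintf('<polygon label="%s" points="%s" occluded="0"/>',
            s$label, s$points), character(1)), collapse = "\n")
  writeLines(sprintf(
    '<?xml version="1.0" encoding="utf-8"?>
<annotations><version>1.1</version>
<image id="0" name="img0" width="%d" height="%d">%s</image>
</annotations>', w, h, poly), path)
  path
}

test_that("CVAT polygons rasterize with the pixel-centre convention", {
  dir <- withr::local_tempdir()
  f <- cvat_xml(file.path(dir, "a.xml"), list(
    list(label = "node", points = "5.0,5.0;15.0,5.0;15.0,15.0;5.0,15.0")))
  masks <- import_cvat_annotations(f)
  expect_named(masks, "img0")
  expect_equal(sum(unclass(masks$img0) == 1L), 100L)
})

test_that("node polygons take precedence over tube polygons", {
  dir <- withr::local_tempdir()
  f <- cvat_xml(file.path(dir, "a.xml"), list(
    list(label = "tube", points = "10,10;20,10;20,20;10,20"),
    list(label = "node", points = "5,5;25,5;25,25;5,25")))
  masks <- import_cvat_annotations(f)
  expect_equal(sum(unclass(masks$img0) == 2L), 0L)
  expect_equal(sum(unclass(masks$img0) == 1L), 400L)
})

test_that("empty annotations and bad labels behave per contract", {
  dir <- withr::local_tempdir()
  f <- cvat_xml(file.path(dir, "empty.xml"), list())
  masks <- import_cvat_annotations(f)
  expect_true(all(unclass(masks$img0) == 0L))

  g <- cvat_xml(file.path(dir, "bad.xml"), list(
    list(label = "vessel", points = "1,1;5,1;5,5")))
  expect_error(import_cvat_annotations(g), "vessel")
  writeLines("<annotations><image", file.path(dir, "broken.xml"))
  expect_error(import_cvat_annotations(file.path(dir, "broken.xml")),
               "malformed|error", ignore.case = TRUE)
})

test_that("CVAT import is idempotent under re-rasterization", {
  dir <- withr::local_tempdir()
  f <- cvat_xml(file.path(dir, "a.xml"), list(
    list(label = "tube", points = "2.5,8.0;30.0,9.5;30.0,14.0;2.5,12.0"),
    list(label = "node", points = "20,20;32,22;28,34;18,30")))
  m1 <- import_cvat_annotations(f)$img0
  write_mask(m1, file.path(dir, "m.png"))
  expect_identical(unclass(read_mask(file.path(dir, "m.png"))),
                   unclass(m1))
  m2 <- import_cvat_annotations(f)$img0
  expect_identical(unclass(m1), unclass(m2))
})

test_that("the stratified floor split reproduces the study's table", {
  index <- tibble::tibble(
    id = sprintf("im%03d", 1:275),
    category = rep(c("Good", "Dark", "Defective", "Different"),
                   times = c(114, 54, 79, 28)))
  split <- split_dataset(index, train_fraction = 0.68, seed = 42)
  counts <- table(split$assignment$category[split$assignment$subset ==
                                              "train"])
  expect_equal(as.integer(counts[c("Good", "Dark", "Defective",
                                   "Different")]),
               c(77L, 36L, 53L, 19L))
  expect_equal(length(split$train_ids), 185L)
  expect_equal(length(split$test_ids), 90L)
  # partition invariants
  expect_length(intersect(split$train_ids, split$test_ids), 0)
  expect_setequal(c(split$train_ids, split$test_ids), index$id)
})

test_that("splits are deterministic per seed and floor-exact", {
  index <- tibble::tibble(id = letters[1:10], category = rep("Good", 10))
  s1 <- split_dataset(index, 0.5, seed = 9)
  s2 <- split_dataset(index, 0.5, seed = 9)
  expect_identical(s1$train_ids, s2$train_ids)
  expect_length(s1$train_ids, 5L)
  s3 <- split_dataset(index, 0.5, seed = 10)
  expect_false(identical(s1$train_ids, s3$train_ids))
  expect_error(split_dataset(index[0, ], 0.5, 1), "empty")
  expect_error(split_dataset(index, 1, 1), "between")
})

test_that("class proportions pool pixel counts over masks", {
  m <- class_mask(matrix(c(0L, 0L, 1L, 2L), 2, 2))
  expect_equal(unname(class_proportions(m)), c(0.5, 0.25, 0.25))
  allbg <- class_mask(matrix(0L, 4, 4))
  expect_equal(unname(class_proportions(allbg)), c(1, 0, 0))
  nodes <- class_mask(matrix(1L, 4, 4))
  tubes <- class_mask(matrix(2L, 4, 4))
  expect_equal(unname(class_proportions(list(nodes, tubes))),
               c(0, 0.5, 0.5))
  # pooled (not averaged): differently sized masks weigh by pixel count
  big_bg <- class_mask(matrix(0L, 4, 8))
  expect_equal(unname(class_proportions(list(nodes, big_bg))),
               c(2 / 3, 1 / 3, 0))
  for (s in 1:5) {
    masks <- lapply(1:3, function(i) random_mask(8, 8, seed = s * 10 + i))
    expect_equal(sum(class_proportions(masks)), 1, tolerance = 1e-12)
  }
})
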