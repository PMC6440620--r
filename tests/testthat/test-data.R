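test_that("the published census is internally consistent", {
  census <- breakhis_census()
  expect_identical(sum(census), 7909L)
  expect_identical(sum(census[c("A", "F", "TA", "PT"), ]), 2480L)
  expect_identical(sum(census[c("DC", "LC", "MC", "PC"), ]), 5429L)
  expect_identical(unname(colSums(census)), c(1995, 2081, 2013, 1820))
})

test_that("generate + scan round-trips the census exactly", {
  dir <- toy_dataset_dir()          # 6 images per (subtype, magnification)
  idx <- scan_breakhis(dir)
  expect_s3_class(idx, "breakhis_index")
  expect_identical(nrow(idx$records), 8L * 4L * 6L)
  expect_true(all(idx$census == 6L))
  # subtype determines the class label
  expect_identical(as.vector(table(idx$records$class_label)),
                   c(4L * 4L * 6L, 4L * 4L * 6L))
  benign <- idx$records$subtype %in% c("A", "F", "TA", "PT")
  expect_true(all(idx$records$class_label[benign] == "benign"))
  expect_true(all(idx$records$class_label[!benign] == "malignant"))
  # filenames follow the community convention
  expect_true(all(grepl("^SOB_[BM]_[A-Z]+-S\\d+-\\d+-\\d{3}\\.png$",
                        basename(idx$records$path))))
  expect_error(scan_breakhis(file.path(dir, "no-such")), "directory")
  empty <- withr::local_tempdir()
  expect_error(scan_breakhis(empty), "no PNG")
})

test_that("generation is deterministic and unparseable names are reported", {
  census <- breakhis_census(); census[] <- 0L
  census["A", "40"] <- 2L; census["DC", "400"] <- 2L
  spec <- synthetic_spec(census = census, image_size = 12, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_synthetic_breakhis(spec, d1)
  generate_synthetic_breakhis(spec, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # an alien file triggers a warning and lands in the unparsed attribute
  write_png(array(128, c(4, 4, 3)), file.path(d1, "stray.png"))
  expect_warning(idx <- scan_breakhis(d1), "unparseable")
  expect_identical(basename(attr(idx, "unparsed")), "stray.png")
  expect_identical(nrow(idx$records), 4L)
})

test_that("benign and malignant textures are separated in pixel variance", {
  census <- breakhis_census(); census[] <- 0L
  census[c("A", "F", "TA", "PT"), "100"] <- 25L   # 100 benign
  census[c("DC", "LC", "MC", "PC"), "100"] <- 25L # 100 malignant
  spec <- synthetic_spec(census = census, image_size = 24, seed = 31)
  d <- withr::local_tempdir()
  idx <- generate_synthetic_breakhis(spec, d)
  v <- vapply(seq_len(nrow(idx$records)), function(i)
    var(as.vector(read_png(idx$records$path[i]))), numeric(1))
  benign <- idx$records$class_label == "benign"
  expect_gte(mean(v[!benign]) - mean(v[benign]), spec$texture$margin)
})

test_that("split_index is stratified, exhaustive, and census-conserving", {
  dir <- toy_dataset_dir()
  idx <- scan_breakhis(dir)
  sp <- split_index(idx, 0.5, seed = 7, level = "subtype")
  expect_identical(sp$train$census + sp$test$census, idx$census)
  expect_true(all(sp$train$census == 3L))
  expect_identical(nrow(sp$train$records) + nrow(sp$test$records),
                   nrow(idx$records))
  expect_length(intersect(sp$train$records$path, sp$test$records$path), 0L)
  # determinism
  sp2 <- split_index(idx, 0.5, seed = 7, level = "subtype")
  expect_identical(sp$train$records$path, sp2$train$records$path)
  sp3 <- split_index(idx, 0.5, seed = 8, level = "subtype")
  expect_false(identical(sp$train$records$path, sp3$train$records$path))
  # binary level stratifies by class within magnification: 60/40 of 24
  spb <- split_index(idx, 0.6, seed = 1, level = "binary")
  per <- table(spb$train$records$magnification, spb$train$records$class_label)
  expect_true(all(per == round(24 * 0.6)))
})

test_that("preprocessing standardizes with training statistics", {
  dir <- toy_dataset_dir()
  idx <- scan_breakhis(dir)
  sp <- split_index(idx, 0.5, seed = 3)
  raw <- load_images(sp$train, 8)
  stats <- channel_stats(raw$x)
  tr <- load_images(sp$train, 8, stats)
  expect_identical(dim(tr$x)[1:3], c(8L, 8L, 3L))
  for (c in 1:3) {
    expect_equal(mean(tr$x[, , c, ]), 0, tolerance = 1e-6)
    expect_equal(sd(as.vector(tr$x[, , c, ])), 1, tolerance = 1e-2)
  }
  # labels: benign = 1, malignant = 2
  expect_identical(sort(unique(tr$y)), c(1L, 2L))
  expect_identical(tr$levels, c("benign", "malignant"))
  sub <- load_images(sp$train, 8, stats, level = "subtype")
  expect_identical(sort(unique(sub$y)), 1:8)
  # constant image maps to all zeros under any stats with unit-sd floor
  cst <- preprocess_image(array(37, c(10, 10, 3)), 4,
                          list(mean = rep(37, 3), sd = rep(1e-6, 3)))
  expect_true(all(cst == 0))
  expect_error(preprocess_image(matrix(0, 4, 4), 4), "RGB")
})

test_that("bilinear resize preserves constants and means approximately", {
  img <- array(200, c(30, 20, 3))
  expect_equal(resize_bilinear(img, 7, 5), array(200, c(7, 5, 3)))
  set.seed(4)
  ramp <- array(rep(seq(0, 255, length.out = 32), 32 * 3), c(32, 32, 3))
  small <- resize_bilinear(ramp, 8, 8)
  expect_identical(dim(small), c(8L, 8L, 3L))
  expect_equal(mean(small), mean(ramp), tolerance = 1)
  expect_true(all(diff(small[, 1, 1]) > 0))
})

test_that("augmentation obeys its invariants and bookkeeping", {
  set.seed(5)
  img <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  # zero shift, no flip: identity
  expect_identical(augment_image(img, shift = c(0, 0), flip = FALSE), img)
  # flip twice: identity
  once <- augment_image(img, shift = c(0, 0), flip = TRUE)
  expect_false(identical(once, img))
  expect_identical(augment_image(once, shift = c(0, 0), flip = TRUE), img)
  # +0.125 * W = 1 pixel shift on an 8-wide ramp: exposed column is the fill
  ramp <- array(rep(1:8, each = 8), c(8, 8, 1)) * 1.0
  sh <- augment_image(ramp, shift = c(0, 1), flip = FALSE, fill = -7)
  expect_true(all(sh[, 1, ] == -7))
  expect_equal(sh[, 2:8, , drop = FALSE], ramp[, 1:7, , drop = FALSE],
               ignore_attr = TRUE)
  # shape and range never change
  out <- augment_image(img)
  expect_identical(dim(out), dim(img))
  expect_lte(max(out), max(img))
  # random draws come from R's RNG: reproducible under a seed
  set.seed(77); a1 <- augment_image(img)
  set.seed(77); a2 <- augment_image(img)
  expect_identical(a1, a2)
})
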