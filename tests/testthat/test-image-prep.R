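# write a few synthetic images to disk so directory loading is exercised
write_image_tree <- function(dir, nPerClass = 2, mixed = FALSE) {
  recs <- makeImages(nPerClass = 4, height = 16, width = 16, seed = 3)
  for (r in recs[c(1:nPerClass, 5:(4 + nPerClass))]) {
    d <- file.path(dir, r$label)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    img <- EBImage::Image(t(r$pixels) / 255)
    ext <- if (mixed && runif(1) < 0.5) "jpg" else "png"
    EBImage::writeImage(img, file.path(d, paste0(basename(r$id), ".", ext)))
  }
  dir
}

test_that("image directories load with labels in deterministic order", {
  d <- tempfile()
  write_image_tree(d, nPerClass = 3)
  recs <- loadImageDir(d)
  expect_length(recs, 6)
  expect_identical(unique(vapply(recs, `[[`, character(1), "label")),
                   c("grating_h", "grating_v"))
  ids <- vapply(recs, `[[`, character(1), "id")
  expect_identical(ids, sort(ids))
  expect_error(loadImageDir(tempfile()), "no such directory")
  empty <- tempfile(); dir.create(empty)
  expect_error(loadImageDir(empty), "no readable images")
  set.seed(8)
  dm <- tempfile()
  write_image_tree(dm, nPerClass = 3, mixed = TRUE)
  expect_length(loadImageDir(dm), 6)
})

test_that("grayscale conversion uses BT.601 luma and is idempotent", {
  white <- imageRecord(array(255, c(2, 2, 3)), "w", "w1")
  expect_equal(toGrayscale(white)$pixels, matrix(255, 2, 2))
  red <- imageRecord(array(rep(c(255, 0, 0), each = 4), c(2, 2, 3)),
                     "r", "r1")
  expect_equal(toGrayscale(red)$pixels, matrix(76, 2, 2))
  g <- imageRecord(matrix(5, 3, 3), "g", "g1")
  expect_identical(toGrayscale(g), g)
  expect_identical(toGrayscale(toGrayscale(red)), toGrayscale(red))
})

test_that("bilinear resize matches a closed-form oracle", {
  # constant images stay constant under any resize
  cst <- imageRecord(matrix(90, 51, 33), "c", "c1")
  out <- resizeImage(cst, 64, 64)
  expect_equal(dim(out$pixels), c(64, 64))
  expect_equal(max(abs(out$pixels - 90)), 0, tolerance = 1e-9)
  # identity resize leaves content unchanged (within rounding)
  set.seed(4)
  img <- imageRecord(matrix(runif(64 * 64, 0, 255), 64, 64), "i", "i1")
  same <- resizeImage(img, 64, 64)
  expect_equal(same$pixels, img$pixels, tolerance = 1e-6)
  # checkerboard upsample equals hand-computed bilinear weights
  chk <- imageRecord(matrix(c(0, 255, 255, 0), 2, 2), "k", "k1")
  up <- resizeImage(chk, 4, 4)
  expect_equal(up$pixels, oracle_bilinear(chk$pixels, 4, 4),
               tolerance = 1e-6)
  # and a non-square case against the same oracle
  src <- imageRecord(matrix(runif(6 * 4, 0, 255), 6, 4), "s", "s1")
  dn <- resizeImage(src, 3, 8)
  expect_equal(dn$pixels, oracle_bilinear(src$pixels, 3, 8),
               tolerance = 1e-6)
  expect_error(resizeImage(chk, 0, 4), "positive")
})

test_that("vectorization is row-major and round-trips", {
  m <- matrix(1:6, 2, 3, byrow = TRUE)
  v <- vectorizeImage(imageRecord(m, "x", "x1"))
  expect_equal(v, 1:6)
  expect_equal(matrix(v, 2, 3, byrow = TRUE), m)
  big <- vectorizeImage(imageRecord(matrix(0, 64, 64), "x", "x2"))
  expect_length(big, 4096)
  rgb <- imageRecord(array(0, c(2, 2, 3)), "x", "x3")
  expect_error(vectorizeImage(rgb), "grayscale")
  expect_equal(normalizePixels(c(0, 255)), c(0, 1))
})

test_that("stratified split reproduces per-class count arithmetic", {
  # nearest-train rounding on the three-class size profile 708/1426/930
  lab <- rep(c("meningioma", "glioma", "pituitary"), c(708, 1426, 930))
  sp <- stratifiedSplit(lab, rounding = "nearest_train", seed = 2)
  trainCounts <- table(lab[sp$train])
  testCounts <- table(lab[sp$test])
  expect_equal(as.integer(trainCounts[c("meningioma", "glioma",
                                        "pituitary")]), c(566, 1141, 744))
  expect_equal(as.integer(testCounts[c("meningioma", "glioma",
                                       "pituitary")]), c(142, 285, 186))
  # partition property and seed behavior
  expect_setequal(c(sp$train, sp$test), seq_along(lab))
  sp2 <- stratifiedSplit(lab, rounding = "nearest_train", seed = 2)
  expect_identical(sp, sp2)
  sp3 <- stratifiedSplit(lab, rounding = "nearest_train", seed = 3)
  expect_false(identical(sp$train, sp3$train))
  expect_equal(table(lab[sp3$train]), trainCounts)
  # small class and floor rounding
  sp10 <- stratifiedSplit(rep("a", 10), seed = 1)
  expect_length(sp10$train, 8)
  expect_error(stratifiedSplit(c("a", "b", "b")), "at least 2")
})

test_that("backbone adapter enforces the registered contract", {
  registerBackbone("mock8", function(recs)
    matrix(seq_len(8 * length(recs)), length(recs), 8), dim = 8)
  recs <- makeImages(nPerClass = 4, height = 8, width = 8, nClasses = 2,
                     seed = 1)
  ft <- cnnFeatureAdapter(recs, "mock8")
  expect_equal(nFeatures(ft), 8)
  expect_equal(nSamples(ft), 8)
  expect_error(cnnFeatureAdapter(recs, "nope"), "not registered")
  # conventional names carry fixed widths
  expect_error(registerBackbone("alexnet", function(recs) NULL, dim = 8),
               "4096")
  registerBackbone("alexnet", function(recs)
    matrix(0, length(recs), 4096))
  expect_equal(nFeatures(cnnFeatureAdapter(recs, "alexnet")), 4096)
  # a lying backbone is caught
  registerBackbone("liar", function(recs) matrix(0, length(recs), 3),
                   dim = 9)
  expect_error(cnnFeatureAdapter(recs, "liar"), "contract")
})
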