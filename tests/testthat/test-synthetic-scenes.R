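test_that("generation is byte-identical under a fixed seed", {
  p <- protocol4x5()
  cfg <- sceneConfig(seed = 3, minInstancesPerClass = 2)
  b1 <- generateBenchmark(p, 40, cfg)
  b2 <- generateBenchmark(p, 40, cfg)
  expect_identical(b1$gt$instances, b2$gt$instances)
  expect_identical(b1$images, b2$images)
})

test_that("the per-class minimum instance guarantee holds", {
  p <- protocol3x2()
  b <- generateBenchmark(p, 120, sceneConfig(seed = 5, minInstancesPerClass = 30))
  counts <- table(factor(b$gt$instances$class_id,
                         levels = seq_along(classRegistry(p))))
  expect_true(all(counts >= 30))
  expect_error(generateBenchmark(p, 4, sceneConfig(seed = 5,
                                                   minInstancesPerClass = 30)),
               "cannot guarantee")
})

test_that("rendered boxes have positive area and lie inside the frame", {
  p <- protocol4x5()
  b <- generateBenchmark(p, 30, sceneConfig(seed = 9, minInstancesPerClass = 1))
  inst <- b$gt$instances
  expect_true(all(inst$x2 > inst$x1 & inst$y2 > inst$y1))
  sz <- b$config$imageSize
  expect_true(all(inst$x1 >= 0 & inst$y1 >= 0 & inst$x2 <= sz & inst$y2 <= sz))
  expect_true(all(vapply(b$images, function(im)
    all(im >= 0 & im <= 1) && identical(dim(im), c(sz, sz, 3L)), logical(1))))
})

test_that("benchmark images write as PNG files", {
  p <- protocol3x2()
  b <- generateBenchmark(p, 4, sceneConfig(seed = 2, minInstancesPerClass = 0))
  d <- withr::local_tempdir()
  out <- writeBenchmarkImages(b, d)
  expect_true(all(file.exists(file.path(d, paste0(names(b$images), ".png")))))
  back <- png::readPNG(file.path(d, paste0(names(b$images)[1], ".png")))
  expect_equal(dim(back), dim(b$images[[1]]))
})

test_that("the zero-noise simulator reproduces ground truth with ideal metrics", {
  p <- protocol4x5()
  b <- generateBenchmark(p, 40, sceneConfig(seed = 3, minInstancesPerClass = 2))
  det <- simulateDetections(b$gt, detectionNoiseModel(),
                            knownClasses = knownAfter(p, 1), seed = 1)
  expect_equal(nrow(det), nrow(b$gt$instances))
  expect_true(all(det$score == 1))
  r <- suppressWarnings(evaluateTask(det, b$gt, p, 1))
  expect_equal(r@knownMAP, 100)
  expect_equal(r@currMAP, 100)
  expect_equal(r@aose, 0)
  expect_equal(r@uRecall, 1)
})

test_that("a miss rate of one silences the detector", {
  p <- protocol3x2()
  b <- generateBenchmark(p, 10, sceneConfig(seed = 2, minInstancesPerClass = 0))
  det <- simulateDetections(b$gt, detectionNoiseModel(missRate = 1),
                            knownClasses = 1:2, seed = 1)
  expect_equal(nrow(det), 0L)
})

test_that("invalid noise models are rejected", {
  expect_error(detectionNoiseModel(missRate = 1.2), "rates")
  expect_error(detectionNoiseModel(confusion = matrix(c(0.5, 0.2, 0.5, 0.5), 2,
                                                      dimnames = list(1:2, 1:2))),
               "sum to 1")
})

test_that("miss and leak rates reproduce their analytic expectations", {
  ## unknown-only world: E[U-R] = (1-m)(1-leak), E[A-OSE]/n = (1-m) leak
  gts <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(instance_id = sprintf("u%d_%d", i, 1:8),
               image_id = sprintf("im%d", i),
               x1 = rep(c(0, 16, 32, 48), 2),
               y1 = rep(c(0, 30), each = 4),
               x2 = rep(c(12, 28, 44, 60), 2),
               y2 = rep(c(12, 42), each = 4),
               class_id = 9L, stringsAsFactors = FALSE)
  }))
  gt <- structure(list(instances = gts,
                       images = data.frame(image_id = unique(gts$image_id),
                                           width = 64, height = 64,
                                           file_name = NA_character_),
                       categories = data.frame(id = c(1:2, 9L),
                                               name = c("a", "b", "u"))),
                  class = "cocoGroundTruth")
  m <- 0.2; leak <- 0.4
  nm <- detectionNoiseModel(missRate = m, opensetLeakRate = leak)
  ur <- aose <- numeric(30)
  for (s in 1:30) {
    det <- simulateDetections(gt, nm, knownClasses = 1:2, seed = s)
    ur[s] <- unknownRecall(det, gts, 9L)
    aose[s] <- absoluteOpenSetError(det, gts, 9L) / nrow(gts)
  }
  se <- function(pr) sqrt(pr * (1 - pr) / (nrow(gts) * 30))
  expect_lt(abs(mean(ur) - (1 - m) * (1 - leak)), 3 * se((1 - m) * (1 - leak)))
  expect_lt(abs(mean(aose) - (1 - m) * leak), 3 * se((1 - m) * leak))
})
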