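test_that("the window grid covers every generated lesion at IoU >= 0.5", {
  p <- protocol4x5()
  b <- generateBenchmark(p, 30, sceneConfig(seed = 13, minInstancesPerClass = 1))
  cfg <- toyConfig()
  grid <- windowGrid(b$config$imageSize, cfg$scales, cfg$strides)
  gb <- as.matrix(grid[, c("x1", "y1", "x2", "y2")])
  inst <- b$gt$instances
  best <- apply(pairwiseIoU(as.matrix(inst[, c("x1", "y1", "x2", "y2")]), gb),
                1, max)
  expect_true(all(best >= 0.5))
})

test_that("proposals are deterministic and ranked by objectness", {
  p <- protocol3x2()
  b <- generateBenchmark(p, 2, sceneConfig(seed = 4, minInstancesPerClass = 0))
  m <- toyDetector(toyConfig(seed = 1))
  pr1 <- propose(m, b$images[[1]], "img_0001")
  pr2 <- propose(m, b$images[[1]], "img_0001")
  expect_identical(pr1, pr2)
  expect_true(all(diff(pr1$objectness) <= 1e-12))
  expect_lte(nrow(pr1), m@config$topN)
})

test_that("contrastive clustering loss matches its definition term by term", {
  proto <- matrix(c(0, 0, 3, 0, 0, 3), 3, 2, byrow = TRUE,
                  dimnames = list(c("1", "2", "3"), NULL))
  ## feature exactly on its prototype, others >= margin away -> zero
  expect_equal(contrastiveClusteringLoss(matrix(c(0, 0), 1), 1, proto,
                                         margin = 1), 0)
  ## all prototypes identical: each feature at the prototype pays (k-1)*margin
  protoSame <- matrix(0, 3, 2, dimnames = list(c("1", "2", "3"), NULL))
  expect_equal(contrastiveClusteringLoss(matrix(c(0, 0), 1), 2, protoSame,
                                         margin = 1.5), 2 * 1.5)
  ## random batch equals a direct hand summation
  set.seed(19)
  feats <- matrix(rnorm(10 * 2), 10, 2)
  labs <- sample(1:3, 10, replace = TRUE)
  want <- 0
  for (i in 1:10) {
    for (cl in c("1", "2", "3")) {
      d <- sqrt(sum((feats[i, ] - proto[cl, ])^2))
      want <- want + if (cl == as.character(labs[i])) d else max(0, 1.2 - d)
    }
  }
  expect_equal(contrastiveClusteringLoss(feats, labs, proto, margin = 1.2),
               want)
  expect_error(contrastiveClusteringLoss(matrix(0, 1, 2), 7, proto, 1),
               "prototype")
})

test_that("training with zero iterations leaves all weights untouched", {
  p <- protocol3x2()
  b <- generateBenchmark(p, 20, sceneConfig(seed = 6, minInstancesPerClass = 2))
  s <- splitDataset(b$gt, p, seed = 2)
  m0 <- toyDetector(toyConfig(seed = 1, iterations = 0L))
  m1 <- trainTask(m0, p, 1, b, s)
  expect_identical(m1@Wobj, m0@Wobj)
  expect_identical(m1@Wf, m0@Wf)
  expect_identical(m1@Wr, m0@Wr)
  ## the head gains rows for the new classes but existing rows are untouched
  expect_equal(m1@knownClasses, currentClasses(p, 1))
  expect_equal(m1@Wc[3:4, ], m0@Wc[1:2, ])
})

test_that("head extension preserves old class rows and never touches the regressor", {
  p <- protocol3x2()
  b <- generateBenchmark(p, 40, sceneConfig(seed = 6, minInstancesPerClass = 4))
  s <- splitDataset(b$gt, p, seed = 2)
  m1 <- trainTask(toyDetector(toyConfig(seed = 1, iterations = 120L)),
                  p, 1, b, s, seed = 5)
  WrBefore <- m1@Wr
  WcClassRows <- m1@Wc[1:2, ]
  m2 <- trainTask(m1, p, 2, b, s, seed = 6)
  expect_equal(length(m2@knownClasses), 4L)
  expect_equal(nrow(m2@Wc), 6L)      # 4 classes + unknown + background
  expect_equal(nrow(m2@Wr), 4L)      # class-agnostic: 4 outputs, always
  ## old class rows are carried over verbatim by the extension
  m2ext <- owdet:::extendHead(m1, currentClasses(p, 2))
  expect_equal(m2ext@Wc[1:2, ], WcClassRows)
  expect_identical(m2ext@Wr, WrBefore)
})

test_that("inference emits logits, respects NMS, and stays quiet on background", {
  p <- protocol3x2()
  b <- generateBenchmark(p, 40, sceneConfig(seed = 8, minInstancesPerClass = 4))
  s <- splitDataset(b$gt, p, seed = 3)
  m <- trainTask(toyDetector(toyConfig(seed = 2, iterations = 400L)),
                 p, 1, b, s, seed = 7)
  dets <- inferDetections(m, b$images[s$test_images[1:4]])
  expect_gt(nrow(dets), 0)
  expect_true(all(vapply(dets$logits, length, integer(1)) ==
                  length(m@knownClasses)))
  ## per class and image, no two surviving boxes overlap above the NMS bound
  for (key in unique(paste(dets$image_id, dets$label))) {
    dd <- dets[paste(dets$image_id, dets$label) == key, , drop = FALSE]
    if (nrow(dd) < 2) next
    M <- pairwiseIoU(as.matrix(dd[, c("x1", "y1", "x2", "y2")]),
                     as.matrix(dd[, c("x1", "y1", "x2", "y2")]))
    expect_lte(max(M[upper.tri(M)]), m@config$nmsIou + 1e-9)
  }
  ## a pure-background scene yields no confident detections
  blank <- owdet:::renderScene(b$config$imageSize, "tomato",
                               data.frame()[0, ], classAppearance(6), 0.02)
  trained_obj <- propose(m, blank, "blank")
  lesioned_obj <- propose(m, b$images[[s$test_images[1]]], "t")
  expect_lt(max(trained_obj$objectness), max(lesioned_obj$objectness))
  detsBlank <- inferDetections(m, list(blank = blank))
  expect_lt(nrow(detsBlank), 5)
})

test_that("NMS keeps one of two identical boxes", {
  kept <- owdet:::nmsKeep(rbind(c(0, 0, 10, 10), c(0, 0, 10, 10)),
                          c(0.9, 0.8), 0.5)
  expect_equal(kept, 1L)
})
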