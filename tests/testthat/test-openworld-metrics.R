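test_that("greedy matching honors the single-match rule and score priority", {
  gts <- data.frame(instance_id = "g1", image_id = "im1",
                    x1 = 0, y1 = 0, x2 = 10, y2 = 10, class_id = 1L)
  det1 <- data.frame(image_id = "im1", x1 = 0, y1 = 0, x2 = 10, y2 = 10,
                     label = 1L, score = 0.9)
  mr <- matchDetections(det1, gts)
  expect_equal(sum(mr$detections$tp), 1L)

  two <- rbind(det1, within(det1, score <- 0.5))
  mr2 <- matchDetections(two, gts)
  expect_equal(mr2$detections$tp, c(TRUE, FALSE))
  expect_equal(mr2$detections$score, c(0.9, 0.5))

  ## wrong class never matches
  detWrong <- within(det1, label <- 2L)
  expect_equal(sum(matchDetections(detWrong, gts)$detections$tp), 0L)
})

test_that("matching agrees with the brute-force reference on random cases", {
  set.seed(77)
  for (rep in 1:60) {
    gts <- randomGts(nImages = 2, perImage = sample(2:5, 1))
    dets <- randomDets(gts, extraFp = sample(0:6, 1))
    mr <- matchDetections(dets, gts)
    for (cl in unique(dets$label)) {
      d <- dets[dets$label == cl, , drop = FALSE]
      d <- d[order(-d$score), , drop = FALSE]
      ref <- refGreedyMatch(d, gts[gts$class_id == cl, , drop = FALSE])
      got <- mr$detections[mr$detections$label == cl, ]
      expect_equal(got$tp, ref$tp)
    }
  }
})

test_that("11-point AP reproduces the interpolated-envelope definition", {
  expect_equal(averagePrecision11pt(rep(TRUE, 7), 7), 1)
  expect_equal(averagePrecision11pt(c(TRUE, TRUE, FALSE), 2), 1)
  expect_equal(averagePrecision11pt(rep(FALSE, 5), 3), 0)
  expect_true(is.na(averagePrecision11pt(logical(0), 0)))
  ## hand computation: flags (TP,FP,TP,FP,TP), 5 GT
  ## recalls .2 .2 .4 .4 .6; precisions 1 .5 .667 .5 .6
  ## P(r)=1 for r<=.2, 2/3 for r in {.3,.4}, .6 for {.5,.6}, 0 beyond
  flags <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  expect_equal(averagePrecision11pt(flags, 5), (3 * 1 + 2 * 2/3 + 2 * 0.6) / 11)
  expect_equal(averagePrecision11pt(flags, 5), refAP11(flags, 5))
  ## random agreement with the direct evaluation
  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    flags <- runif(n) < 0.5
    nGt <- sum(flags) + sample(0:4, 1)
    if (nGt == 0) next
    expect_equal(averagePrecision11pt(flags, nGt), refAP11(flags, nGt))
  }
})

test_that("AP is 1 exactly when all GT are matched before any false positive", {
  expect_equal(averagePrecision11pt(c(TRUE, TRUE, TRUE, FALSE), 3), 1)
  expect_lt(averagePrecision11pt(c(TRUE, FALSE, TRUE, TRUE), 3), 1)
})

test_that("Unknown Recall is TP_U/AU with a not-applicable marker at AU = 0", {
  gts <- randomGts(nImages = 2, perImage = 5, classes = 9)
  dets <- gts
  dets$label <- UNKNOWN_CLASS; dets$score <- 0.8
  dets$instance_id <- dets$class_id <- NULL
  expect_equal(unknownRecall(dets[1:3, ], gts, 9), 0.3)
  expect_equal(unknownRecall(dets[0, ], gts, 9), 0)
  expect_true(is.na(unknownRecall(dets, gts, unknownClassIds = 4)))
})

test_that("A-OSE counts FP known detections on unknown objects, once per object", {
  gts <- data.frame(instance_id = c("u1", "k1"), image_id = "im1",
                    x1 = c(0, 30), y1 = c(0, 30), x2 = c(10, 40), y2 = c(10, 40),
                    class_id = c(9L, 1L))
  noDet <- emptyDetections()
  expect_equal(absoluteOpenSetError(noDet, gts, 9L), 0L)
  dOnU <- data.frame(image_id = "im1", x1 = 0, y1 = 0, x2 = 10, y2 = 10,
                     label = 1L, score = 0.9)
  expect_equal(absoluteOpenSetError(dOnU, gts, 9L), 1L)
  ## two known dets on one unknown object still count it once
  expect_equal(absoluteOpenSetError(rbind(dOnU, within(dOnU, score <- 0.4)),
                                    gts, 9L), 1L)
  ## a correct TP of a known class is not an open-set error, even if it
  ## also overlaps an unknown object
  gts2 <- rbind(gts, data.frame(instance_id = "u2", image_id = "im1",
                                x1 = 31, y1 = 31, x2 = 41, y2 = 41,
                                class_id = 9L))
  dTp <- data.frame(image_id = "im1", x1 = 30, y1 = 30, x2 = 40, y2 = 40,
                    label = 1L, score = 0.9)
  expect_equal(absoluteOpenSetError(dTp, gts2, 9L), 0L)
})

test_that("evaluateTask assembles P/C/K/U-R/A-OSE with correct partitions", {
  p <- protocol4x5()
  b <- generateBenchmark(p, 40, sceneConfig(seed = 3, minInstancesPerClass = 2))
  det <- simulateDetections(b$gt, detectionNoiseModel(),
                            knownClasses = knownAfter(p, 2), seed = 1)
  r <- suppressWarnings(evaluateTask(det, b$gt, p, 2))
  expect_equal(r@prevMAP, 100); expect_equal(r@currMAP, 100)
  expect_equal(r@aose, 0); expect_equal(r@uRecall, 1)
  expect_setequal(names(r@classAP), as.character(knownAfter(p, 2)))
  ## U-R at task 1 is computed over the 15 unknown classes' instances
  det1 <- simulateDetections(b$gt, detectionNoiseModel(),
                             knownClasses = knownAfter(p, 1), seed = 1)
  inst <- b$gt$instances
  expect_equal(sum(inst$class_id %in% unknownAt(p, 1)),
               sum(inst$class_id > 5))
  expect_error(evaluateTask(det, b$gt, p, 9), "out of range")
})

test_that("reports are invariant to detection order and class relabeling", {
  set.seed(55)
  p <- protocol3x2()
  b <- generateBenchmark(p, 30, sceneConfig(seed = 5, minInstancesPerClass = 2))
  det <- simulateDetections(b$gt, detectionNoiseModel(
    missRate = 0.2, opensetLeakRate = 0.3,
    scoreModel = list(tpBeta = c(8, 2), fpBeta = c(2, 5))),
    knownClasses = knownAfter(p, 1), seed = 2)
  r1 <- suppressWarnings(evaluateTask(det, b$gt, p, 1))
  shuffled <- det[sample(nrow(det)), ]
  r2 <- suppressWarnings(evaluateTask(shuffled, b$gt, p, 1))
  expect_equal(r1@classAP, r2@classAP)
  expect_equal(r1@aose, r2@aose)
  expect_equal(r1@uRecall, r2@uRecall)
})

test_that("report serialization mirrors the evaluation-table abbreviations", {
  p <- protocol3x2()
  b <- generateBenchmark(p, 30, sceneConfig(seed = 5, minInstancesPerClass = 2))
  det <- simulateDetections(b$gt, detectionNoiseModel(),
                            knownClasses = knownAfter(p, 1), seed = 1)
  r <- suppressWarnings(evaluateTask(det, b$gt, p, 1))
  f <- withr::local_tempfile(fileext = ".json")
  writeMetricReport(r, f)
  j <- jsonlite::fromJSON(f)
  expect_equal(j$K, 100)
  expect_equal(j$A, 0)
  expect_equal(j[["U-R"]], 1)
  row <- reportAsRow(r)
  expect_equal(row$K, 100)
})
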