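test_that("energy score matches its closed forms and direct summation", {
  expect_equal(energyScore(rep(0, 5)), -log(5))
  expect_equal(energyScore(0), 0)
  expect_equal(energyScore(c(1, 2, 3)), -log(exp(1) + exp(2) + exp(3)))
  ## C equal logits l at temperature T: E = -l - T log C
  expect_equal(energyScore(rep(1.7, 4), temperature = 2.5),
               -1.7 - 2.5 * log(4))
  expect_error(energyScore(numeric(0)), "logit")
  expect_error(energyScore(c(1, 2), temperature = 0))
})

test_that("energy is monotone decreasing in any single logit", {
  set.seed(31)
  for (i in 1:20) {
    l <- rnorm(4)
    j <- sample(4, 1)
    l2 <- l; l2[j] <- l2[j] + runif(1, 0.1, 2)
    expect_lt(energyScore(l2), energyScore(l))
  }
})

test_that("gaussian fit places the decision boundary strictly between the modes", {
  set.seed(5)
  ek <- rnorm(200, -8, 1)
  eu <- rnorm(200, -2, 1)
  m <- fitEnergyModel(ek, eu, family = "gaussian")
  ## scan for the crossing of the prior-weighted densities
  grid <- seq(-8, -2, by = 0.01)
  dk <- dnorm(grid, m@knownPar["mean"], m@knownPar["sd"])
  du <- dnorm(grid, m@unknownPar["mean"], m@unknownPar["sd"])
  cross <- grid[which(diff(sign(dk - du)) != 0)[1]]
  expect_gt(cross, -8)
  expect_lt(cross, -2)
  ## location parameters ordered like the sample means
  expect_lt(m@knownPar["mean"], m@unknownPar["mean"])
})

test_that("identical samples make relabeling a no-op (ties keep the known label)", {
  set.seed(6)
  e <- rnorm(50, -4, 1)
  m <- fitEnergyModel(e, e, family = "gaussian", priorKnown = 0.5)
  det <- data.frame(image_id = "im1", x1 = 0, y1 = 0, x2 = 5, y2 = 5,
                    label = 1L, score = 0.9)
  det$logits <- I(list(c(3, 0)))
  expect_equal(relabelUnknown(det, m)$label, 1L)
})

test_that("undersized or degenerate samples are refused with a fallback hint", {
  expect_error(fitEnergyModel(rnorm(5), rnorm(30)), "fall back")
  expect_error(fitEnergyModel(rep(1, 30), rnorm(30)), "zero-variance")
})

test_that("shifted-Weibull parameters are recovered within 10% at n = 500", {
  shape <- 2.5; scale <- 3; loc <- -12
  fits <- t(vapply(1:20, function(s) {
    set.seed(s)
    x <- loc + rweibull(500, shape, scale)
    m <- fitEnergyModel(x, x + 6, family = "weibull")
    m@knownPar
  }, c(shape = 0, scale = 0, loc = 0)))
  avg <- colMeans(fits)
  expect_lt(abs(avg["shape"] - shape) / shape, 0.10)
  expect_lt(abs(avg["scale"] - scale) / scale, 0.10)
  expect_lt(abs(avg["loc"] - loc) / abs(loc), 0.10)
})

test_that("relabeling moves labels only known->unknown and preserves geometry", {
  set.seed(9)
  ek <- rnorm(100, -8, 0.8)
  eu <- rnorm(100, -2, 0.8)
  for (fam in c("gaussian", "weibull")) {
    m <- fitEnergyModel(ek, eu, family = fam)
    det <- data.frame(image_id = rep("im1", 4),
                      x1 = 1:4, y1 = 1:4, x2 = 11:14, y2 = 11:14,
                      label = c(1L, 1L, UNKNOWN_CLASS, 2L),
                      score = c(0.9, 0.8, 0.7, 0.6))
    det$logits <- I(list(c(-2.2, -2.3),   # energy ~ -1.5: unknown mode
                         c(7.5, 0),       # energy ~ -7.5: known mode
                         c(-2, -2), NULL))
    out <- relabelUnknown(det, m)
    expect_equal(out$label, c(UNKNOWN_CLASS, 1L, UNKNOWN_CLASS, 2L))
    expect_equal(out[, c("x1", "y1", "x2", "y2", "score")],
                 det[, c("x1", "y1", "x2", "y2", "score")])
  }
  expect_equal(nrow(relabelUnknown(emptyDetections(),
                                   fitEnergyModel(ek, eu, "gaussian"))), 0L)
})

test_that("energy models serialize losslessly to JSON", {
  set.seed(10)
  m <- fitEnergyModel(rnorm(40, -6), rnorm(40, -2), family = "weibull",
                      temperature = 1.5, priorKnown = 0.4)
  f <- withr::local_tempfile(fileext = ".json")
  writeEnergyModel(m, f)
  back <- readEnergyModel(f)
  expect_equal(back@knownPar, m@knownPar, tolerance = 1e-12)
  expect_equal(back@unknownPar, m@unknownPar, tolerance = 1e-12)
  expect_equal(back@temperature, m@temperature)
  expect_equal(back@priorKnown, m@priorKnown)
  expect_equal(back@family, m@family)
})

test_that("relabeling raises Unknown Recall and lowers A-OSE when energies separate", {
  ## construct a world where detections on unknown lesions carry flat logits
  ## (high energy) and detections on known lesions carry peaked logits
  set.seed(13)
  nK <- 30; nU <- 25
  mkInst <- function(n, cls, prefix) {
    b <- randomBoxes(n, size = 300, minSide = 10, maxSide = 14)
    data.frame(instance_id = paste0(prefix, seq_len(n)),
               image_id = paste0("im", seq_len(n) %% 5),
               x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4],
               class_id = cls, stringsAsFactors = FALSE)
  }
  gts <- rbind(mkInst(nK, 1L, "k"), mkInst(nU, 9L, "u"))
  det <- gts
  det$label <- 1L
  det$score <- runif(nrow(det), 0.5, 1)
  det$logits <- I(lapply(seq_len(nrow(det)), function(i)
    if (gts$class_id[i] == 1L) c(8, 0) + rnorm(2, 0, 0.3)
    else c(-1.5, -1.6) + rnorm(2, 0, 0.3)))
  det$instance_id <- det$class_id <- NULL
  eK <- vapply(which(gts$class_id == 1L), function(i) energyScore(det$logits[[i]]), 0)
  eU <- vapply(which(gts$class_id == 9L), function(i) energyScore(det$logits[[i]]), 0)
  for (fam in c("weibull", "gaussian")) {
    m <- fitEnergyModel(eK, eU, family = fam)
    out <- relabelUnknown(det, m)
    urBefore <- unknownRecall(det, gts, 9L)
    urAfter <- unknownRecall(out, gts, 9L)
    aoseBefore <- absoluteOpenSetError(det, gts, 9L)
    aoseAfter <- absoluteOpenSetError(out, gts, 9L)
    expect_gt(urAfter, urBefore)
    expect_lt(aoseAfter, aoseBefore)
  }
})
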