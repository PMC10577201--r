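## Independent reference implementations used as oracles. These are written
## against the definitions, not against the package internals.

## IoU by counting unit-lattice cells; exact for integer-coordinate boxes
latticeIoU <- function(a, b) {
  cells <- function(box) {
    g <- expand.grid(x = seq(box[1] + 0.5, box[3] - 0.5, by = 1),
                     y = seq(box[2] + 0.5, box[4] - 0.5, by = 1))
    paste(g$x, g$y)
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

## brute-force greedy matcher: walk detections in priority order, scan every
## ground-truth record each time
refGreedyMatch <- function(det, gt, thr = 0.5) {
  iou1 <- function(a, b) {
    iw <- min(a[3], b[3]) - max(a[1], b[1])
    ih <- min(a[4], b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    i <- iw * ih
    i / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - i)
  }
  taken <- logical(nrow(gt))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    bestIou <- -1; bestJ <- NA
    for (j in seq_len(nrow(gt))) {
      if (taken[j]) next
      if (gt$image_id[j] != det$image_id[i]) next
      v <- iou1(as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
                as.numeric(gt[j, c("x1", "y1", "x2", "y2")]))
      if (v >= thr && v > bestIou) { bestIou <- v; bestJ <- j }
    }
    if (!is.na(bestJ)) { tp[i] <- TRUE; taken[bestJ] <- TRUE }
  }
  list(tp = tp, gtMatched = taken)
}

## 11-point AP straight from its definition
refAP11 <- function(tpFlags, nGt) {
  if (nGt == 0) return(NA_real_)
  ap <- 0
  for (r in seq(0, 1, by = 0.1)) {
    best <- 0
    for (k in seq_along(tpFlags)) {
      rec <- sum(tpFlags[seq_len(k)]) / nGt
      prec <- sum(tpFlags[seq_len(k)]) / k
      if (rec >= r - 1e-12 && prec > best) best <- prec
    }
    ap <- ap + best
  }
  ap / 11
}

## per-class reference evaluation built on the brute-force matcher
refClassAP <- function(dets, gts, cl, thr = 0.5) {
  d <- dets[dets$label == cl, , drop = FALSE]
  d <- d[order(-d$score), , drop = FALSE]
  g <- gts[gts$class_id == cl, , drop = FALSE]
  refAP11(refGreedyMatch(d, g, thr)$tp, nrow(g))
}

refUnknownRecall <- function(dets, gts, unknownIds, thr = 0.5) {
  g <- gts[gts$class_id %in% unknownIds, , drop = FALSE]
  if (nrow(g) == 0) return(NA_real_)
  d <- dets[dets$label == owdet::UNKNOWN_CLASS, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  d <- d[order(-d$score), , drop = FALSE]
  sum(refGreedyMatch(d, g, thr)$tp) / nrow(g)
}

refAOSE <- function(dets, gts, unknownIds, thr = 0.5) {
  gU <- gts[gts$class_id %in% unknownIds, , drop = FALSE]
  dK <- dets[dets$label != owdet::UNKNOWN_CLASS, , drop = FALSE]
  if (nrow(gU) == 0 || nrow(dK) == 0) return(0)
  ## a detection is an A-OSE candidate only if it is a false positive for
  ## its claimed class
  fpRows <- do.call(rbind, lapply(unique(dK$label), function(cl) {
    d <- dK[dK$label == cl, , drop = FALSE]
    d <- d[order(-d$score), , drop = FALSE]
    g <- gts[gts$class_id == cl, , drop = FALSE]
    d[!refGreedyMatch(d, g, thr)$tp, , drop = FALSE]
  }))
  if (is.null(fpRows) || nrow(fpRows) == 0) return(0)
  fpRows <- fpRows[order(-fpRows$score), , drop = FALSE]
  sum(refGreedyMatch(fpRows, gU, thr)$gtMatched)
}

## random instance/detection tables on a small world
randomBoxes <- function(n, size = 60, minSide = 6, maxSide = 18) {
  w <- runif(n, minSide, maxSide); h <- runif(n, minSide, maxSide)
  x1 <- runif(n, 0, size - w); y1 <- runif(n, 0, size - h)
  cbind(x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h)
}

randomGts <- function(nImages = 2, perImage = 4, classes = 1:3) {
  rows <- lapply(seq_len(nImages), function(i) {
    b <- randomBoxes(perImage)
    data.frame(instance_id = sprintf("i%d_%d", i, seq_len(perImage)),
               image_id = sprintf("im%d", i),
               x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4],
               class_id = sample(rep(classes, 2), perImage, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

randomDets <- function(gts, extraFp = 4, jitter = 3, labels = 1:3,
                       unknownFrac = 0.2) {
  n <- nrow(gts)
  b <- as.matrix(gts[, c("x1", "y1", "x2", "y2")]) +
    matrix(rnorm(4 * n, 0, jitter), n, 4)
  b[, 3] <- pmax(b[, 3], b[, 1] + 1); b[, 4] <- pmax(b[, 4], b[, 2] + 1)
  lab <- ifelse(runif(n) < unknownFrac, owdet::UNKNOWN_CLASS,
                sample(rep(labels, 2), n, replace = TRUE))
  det <- data.frame(image_id = gts$image_id, x1 = b[, 1], y1 = b[, 2],
                    x2 = b[, 3], y2 = b[, 4], label = lab,
                    score = runif(n), stringsAsFactors = FALSE)
  if (extraFp > 0) {
    fb <- randomBoxes(extraFp)
    det <- rbind(det, data.frame(
      image_id = sample(unique(gts$image_id), extraFp, replace = TRUE),
      x1 = fb[, 1], y1 = fb[, 2], x2 = fb[, 3], y2 = fb[, 4],
      label = sample(rep(labels, 2), extraFp, replace = TRUE),
      score = runif(extraFp), stringsAsFactors = FALSE))
  }
  det$logits <- I(vector("list", nrow(det)))
  det
}

## shared tiny protocol fixtures
protocol4x5 <- function() buildProtocol(defaultProtocolConfig(4, 5))
protocol3x2 <- function() buildProtocol(defaultProtocolConfig(3, 2))

## per-class AP through the package's own matcher + AP, for oracle comparison
pkgClassAP <- function(dets, gts, cl, thr = 0.5) {
  mr <- matchDetections(dets, gts, thr)
  d <- mr$detections[mr$detections$label == cl, , drop = FALSE]
  averagePrecision11pt(d$tp, sum(gts$class_id == cl))
}
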