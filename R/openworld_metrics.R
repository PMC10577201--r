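#' @include AllClasses.R task_protocol.R
NULL

## greedy score-ordered matcher shared by AP, U-R and A-OSE.
## det must already be sorted in matching priority order (descending score,
## ties by input index); each detection takes the highest-IoU unmatched GT
## of the candidate table in the same image with IoU >= threshold.
greedyMatch <- function(det, gt, iouThreshold) {
  n <- NROW(det); m <- NROW(gt)
  tp <- logical(n); gtIdx <- rep(NA_integer_, n); iou <- numeric(n)
  taken <- logical(m)
  if (m > 0L && n > 0L) {
    db <- as.matrix(det[, c("x1", "y1", "x2", "y2")])
    gb <- as.matrix(gt[, c("x1", "y1", "x2", "y2")])
    for (i in seq_len(n)) {
      cand <- which(gt$image_id == det$image_id[i] & !taken)
      if (!length(cand)) next
      ious <- vapply(cand, function(j) boxIoU(db[i, ], gb[j, ]), numeric(1))
      best <- which(ious >= iouThreshold)
      if (!length(best)) next
      pick <- best[which.max(ious[best])]
      tp[i] <- TRUE
      gtIdx[i] <- cand[pick]
      iou[i] <- ious[pick]
      taken[cand[pick]] <- TRUE
    }
  }
  list(tp = tp, gtIdx = gtIdx, iou = iou, gtMatched = taken)
}

#' Greedy per-class matching of detections against ground truth
#'
#' Detections are matched class by class: within a class, detections are
#' taken in order of descending score (ties by input index) and each claims
#' the highest-IoU unmatched same-class ground-truth instance in its image
#' with IoU at or above the threshold; everything else is a false positive.
#' Each ground-truth instance is matched at most once. Deterministic.
#'
#' @param dets detection data.frame
#' @param gts ground-truth instance data.frame
#' @param iouThreshold IoU threshold (default 0.5, the mAP@50 convention)
#' @return a list of class \code{"MatchResult"}: \code{detections} (input
#'   rows, in per-class score order, with \code{tp}, \code{matched_gt},
#'   \code{iou}) and \code{gts} (input rows with a \code{matched} flag)
#' @export
matchDetections <- function(dets, gts, iouThreshold = 0.5) {
  gts <- as.data.frame(gts)
  matched <- logical(NROW(gts))
  detParts <- list()
  for (cl in sort(unique(dets$label))) {
    d <- dets[dets$label == cl, , drop = FALSE]
    d <- d[order(-d$score, seq_len(nrow(d))), , drop = FALSE]
    gIdx <- which(gts$class_id == cl)
    res <- greedyMatch(d, gts[gIdx, , drop = FALSE], iouThreshold)
    d$tp <- res$tp
    d$matched_gt <- ifelse(is.na(res$gtIdx), NA_character_,
                           gts$instance_id[gIdx[res$gtIdx]])
    d$iou <- res$iou
    matched[gIdx[res$gtIdx[!is.na(res$gtIdx)]]] <- TRUE
    detParts[[as.character(cl)]] <- d
  }
  out <- do.call(rbind, detParts)
  if (is.null(out)) {
    out <- dets
    out$tp <- logical(0); out$matched_gt <- character(0); out$iou <- numeric(0)
  }
  rownames(out) <- NULL
  gts$matched <- matched
  structure(list(detections = out, gts = gts,
                 iouThreshold = iouThreshold), class = "MatchResult")
}

#' 11-point interpolated average precision
#'
#' The VOC-style formula: \eqn{AP = \frac{1}{11} \sum_{r \in \{0, 0.1, ..., 1\}}
#' P(r)} where \eqn{P(r)} is the maximum measured precision at any recall at
#' or above \eqn{r}. AP is 1 exactly when every ground-truth instance is
#' matched before the first false positive.
#'
#' @param tpFlags logical vector of per-detection match outcomes, in
#'   descending score order
#' @param nGt number of ground-truth instances of the class
#' @return AP in [0,1]; \code{NA} when \code{nGt} is 0 (not applicable,
#'   never a division by zero)
#' @export
averagePrecision11pt <- function(tpFlags, nGt) {
  if (nGt == 0L) return(NA_real_)
  if (!length(tpFlags) || !any(tpFlags)) return(0)
  cumTp <- cumsum(tpFlags)
  precision <- cumTp / seq_along(tpFlags)
  recall <- cumTp / nGt
  mean(vapply(seq(0, 1, by = 0.1), function(r) {
    ok <- recall >= r - 1e-12
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1)))
}

#' Unknown Recall
#'
#' \eqn{U\text{-}R = TP_U / A_U}: the fraction of unknown ground-truth
#' instances recovered by \code{unknown}-labeled detections. Matching is
#' greedy by descending score, class-blind within the unknown set.
#'
#' @param dets detection data.frame
#' @param gts ground-truth instance data.frame
#' @param unknownClassIds integer ids of classes unknown at the evaluated task
#' @param iouThreshold IoU threshold (default 0.5)
#' @return recall in [0,1]; \code{NA} when no unknown ground truth exists
#'   (the final task of a complete schedule)
#' @export
unknownRecall <- function(dets, gts, unknownClassIds, iouThreshold = 0.5) {
  gtU <- gts[gts$class_id %in% unknownClassIds, , drop = FALSE]
  if (nrow(gtU) == 0L) return(NA_real_)
  d <- dets[dets$label == UNKNOWN_CLASS, , drop = FALSE]
  if (nrow(d) == 0L) return(0)
  d <- d[order(-d$score, seq_len(nrow(d))), , drop = FALSE]
  res <- greedyMatch(d, gtU, iouThreshold)
  sum(res$tp) / nrow(gtU)
}

#' Absolute Open-Set Error
#'
#' The number of unknown ground-truth objects misclassified as any known
#' class: unknown instances matched (greedy, descending score, IoU at or
#' above threshold) by a known-labeled detection that is a false positive
#' for its claimed class, each unknown instance counted at most once.
#' Detections that are true positives of their own class are accounted for
#' by mAP and never tallied here.
#'
#' @param dets detection data.frame
#' @param gts ground-truth instance data.frame
#' @param unknownClassIds integer ids of classes unknown at the evaluated task
#' @param iouThreshold IoU threshold (default 0.5)
#' @return nonnegative integer count
#' @export
absoluteOpenSetError <- function(dets, gts, unknownClassIds, iouThreshold = 0.5) {
  gtU <- gts[gts$class_id %in% unknownClassIds, , drop = FALSE]
  d <- dets[dets$label != UNKNOWN_CLASS, , drop = FALSE]
  if (nrow(gtU) == 0L || nrow(d) == 0L) return(0L)
  gtK <- gts[!gts$class_id %in% unknownClassIds, , drop = FALSE]
  mr <- matchDetections(d, gtK, iouThreshold)
  fp <- mr$detections[!mr$detections$tp, , drop = FALSE]
  if (nrow(fp) == 0L) return(0L)
  fp <- fp[order(-fp$score, seq_len(nrow(fp))), , drop = FALSE]
  res <- greedyMatch(fp, gtU, iouThreshold)
  sum(res$gtMatched)
}

#' Evaluate one task of the open-world sequence
#'
#' Computes the full report for a task: per-class 11-point AP at the IoU
#' threshold over the shared test set, the unweighted mAP means over
#' previous-task classes (P), current-task classes (C) and all known classes
#' (K) on the percent scale, plus Unknown Recall and Absolute Open-Set Error
#' against the classes still unknown at this task. Known classes without any
#' ground truth are excluded from the means with a warning. Known-labeled
#' detections that land on unknown ground truth count as false positives for
#' their claimed class and are tallied in A-OSE; unknown-labeled detections
#' never count as false positives against known classes.
#'
#' @param dets detection data.frame over the test images
#' @param gts a \code{"cocoGroundTruth"} or instance data.frame for the same
#'   images (unknown classes included)
#' @param protocol a \linkS4class{TaskProtocol}
#' @param taskIndex position in the task sequence
#' @param iouThreshold IoU threshold (default 0.5)
#' @return a \linkS4class{MetricReport}
#' @export
evaluateTask <- function(dets, gts, protocol, taskIndex, iouThreshold = 0.5) {
  if (inherits(gts, "cocoGroundTruth")) gts <- gts$instances
  if (taskIndex < 1 || taskIndex > nTasks(protocol))
    stop("taskIndex out of range")
  known <- knownAfter(protocol, taskIndex)
  prev <- previousClasses(protocol, taskIndex)
  curr <- currentClasses(protocol, taskIndex)
  unknown <- unknownAt(protocol, taskIndex)
  classAP <- stats::setNames(rep(NA_real_, length(known)), known)
  for (cl in known) {
    g <- gts[gts$class_id == cl, , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- dets[dets$label == cl, , drop = FALSE]
    d <- d[order(-d$score, seq_len(nrow(d))), , drop = FALSE]
    res <- greedyMatch(d, g, iouThreshold)
    classAP[as.character(cl)] <- averagePrecision11pt(res$tp, nrow(g))
  }
  noGt <- known[is.na(classAP)]
  if (length(noGt))
    warning("classes without ground truth excluded from mAP means: ",
            paste(noGt, collapse = ", "))
  meanAP <- function(cls) {
    ap <- classAP[as.character(intersect(cls, known))]
    ap <- ap[!is.na(ap)]
    if (!length(ap)) NA_real_ else 100 * mean(ap)
  }
  haveUnknownGt <- any(gts$class_id %in% unknown)
  new("MetricReport",
      classAP = classAP[!is.na(classAP)],
      prevMAP = meanAP(prev), currMAP = meanAP(curr), knownMAP = meanAP(known),
      uRecall = if (haveUnknownGt)
        unknownRecall(dets, gts, unknown, iouThreshold) else NA_real_,
      aose = if (haveUnknownGt)
        as.numeric(absoluteOpenSetError(dets, gts, unknown, iouThreshold))
      else NA_real_,
      taskIndex = as.integer(taskIndex))
}

setMethod("show", "MetricReport", function(object) {
  fmt <- function(x, d = 1) if (is.na(x)) "-" else formatC(x, format = "f", digits = d)
  cat(sprintf("MetricReport (task %d)\n", object@taskIndex))
  cat(sprintf("  P = %s  C = %s  K = %s  A-OSE = %s  U-R = %s\n",
              fmt(object@prevMAP), fmt(object@currMAP), fmt(object@knownMAP),
              fmt(object@aose, 0), fmt(object@uRecall, 3)))
})

#' Convert a metric report to a one-row data.frame
#' @param report a \linkS4class{MetricReport}
#' @return data.frame with columns task, P, C, K, A_OSE, U_R
#' @export
reportAsRow <- function(report) {
  data.frame(task = report@taskIndex, P = report@prevMAP, C = report@currMAP,
             K = report@knownMAP, A_OSE = report@aose, U_R = report@uRecall)
}

#' Write a metric report to JSON (Table-style abbreviations)
#' @param report a \linkS4class{MetricReport}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeMetricReport <- function(report, path) {
  jsonlite::write_json(list(task = report@taskIndex, P = report@prevMAP,
                            C = report@currMAP, K = report@knownMAP,
                            A = report@aose, `U-R` = report@uRecall,
                            class_AP = as.list(report@classAP)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
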