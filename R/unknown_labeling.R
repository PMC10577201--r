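#' Unknown-aware pseudo-labeling of region proposals
#'
#' The auto-labeling rule of the unknown-aware proposal stage: per image,
#' proposals with high objectness that do not overlap any ground-truth object
#' (max IoU with every GT below \code{bgIouMax}) are relabeled as
#' pseudo-ground-truth of the \code{unknown} class. The top \code{k} such
#' background proposals by objectness are taken (default \code{k = 1}: one
#' unknown instance per image); if fewer than \code{k} exist, all of them are
#' returned; objectness ties break toward the lower proposal index. Pseudo
#' labels are training targets only -- they are never written back into
#' persistent ground truth.
#'
#' @param proposals data.frame with columns \code{image_id}, \code{x1},
#'   \code{y1}, \code{x2}, \code{y2}, \code{objectness}
#' @param gts ground-truth instance data.frame (may span multiple images;
#'   only same-image instances are compared)
#' @param k pseudo-instances per image (>= 1)
#' @param bgIouMax IoU bound below which a proposal counts as background
#'   (default 0.3, the conventional negative-assignment bound of two-stage
#'   detectors; "does not overlap" is otherwise unquantified)
#' @return instance data.frame labeled \code{\link{UNKNOWN_CLASS}}; empty
#'   when no background proposal exists
#' @export
selectUnknownPseudolabels <- function(proposals, gts, k = 1L, bgIouMax = 0.3) {
  stopifnot(k >= 1L)
  if (NROW(proposals) == 0L) return(emptyInstances())
  out <- lapply(split(seq_len(nrow(proposals)), proposals$image_id), function(ix) {
    pr <- proposals[ix, , drop = FALSE]
    g <- gts[gts$image_id == pr$image_id[1], , drop = FALSE]
    maxIou <- if (nrow(g) == 0L) rep(0, nrow(pr)) else
      apply(pairwiseIoU(as.matrix(pr[, c("x1", "y1", "x2", "y2")]),
                        as.matrix(g[, c("x1", "y1", "x2", "y2")])), 1, max)
    bg <- which(maxIou < bgIouMax)
    if (!length(bg)) return(NULL)
    take <- bg[order(-pr$objectness[bg], bg)][seq_len(min(k, length(bg)))]
    data.frame(instance_id = sprintf("%s_pseudo%02d", pr$image_id[1],
                                     seq_along(take)),
               image_id = pr$image_id[take],
               x1 = pr$x1[take], y1 = pr$y1[take],
               x2 = pr$x2[take], y2 = pr$y2[take],
               class_id = UNKNOWN_CLASS, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) emptyInstances() else { rownames(out) <- NULL; out }
}
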