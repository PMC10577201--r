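## Axis-aligned box geometry in continuous pixel coordinates, origin top-left.
## Boxes are (x1, y1, x2, y2) with x2 > x1, y2 > y1; area = (x2-x1)*(y2-y1).

#' Validate a box matrix
#'
#' @param b numeric matrix (or vector of length 4) of columns x1, y1, x2, y2
#' @return the input as a 4-column matrix; errors on zero/negative extent
#' @keywords internal
asBoxMatrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, ncol = 4, byrow = TRUE)
  b <- as.matrix(b)
  if (ncol(b) != 4) stop("boxes need 4 columns: x1, y1, x2, y2")
  if (any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
    stop("invalid box: x2 must exceed x1 and y2 must exceed y1 (positive area)")
  b
}

#' Box areas
#' @param b box matrix (columns x1, y1, x2, y2)
#' @return numeric vector of areas
#' @export
boxArea <- function(b) {
  b <- asBoxMatrix(b)
  (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
}

#' Intersection over union of two boxes
#'
#' Symmetric, 0 for disjoint boxes, 1 iff identical. This is the overlap
#' measure behind every matching decision in the evaluation protocol
#' (mAP@50 uses threshold 0.5).
#'
#' @param a,b boxes as length-4 vectors (x1, y1, x2, y2)
#' @return scalar in [0, 1]
#' @export
boxIoU <- function(a, b) {
  a <- as.numeric(asBoxMatrix(a)); b <- as.numeric(asBoxMatrix(b))
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

#' Pairwise IoU matrix
#'
#' @param A,B box matrices (n x 4 and m x 4)
#' @return n x m matrix of IoU values
#' @export
pairwiseIoU <- function(A, B) {
  A <- asBoxMatrix(A); B <- asBoxMatrix(B)
  ix1 <- outer(A[, 1], B[, 1], pmax); ix2 <- outer(A[, 3], B[, 3], pmin)
  iy1 <- outer(A[, 2], B[, 2], pmax); iy2 <- outer(A[, 4], B[, 4], pmin)
  w <- pmax(ix2 - ix1, 0); h <- pmax(iy2 - iy1, 0)
  inter <- w * h
  union <- outer(boxArea(A), boxArea(B), `+`) - inter
  inter / union
}

#' Encode a target box as normalized deltas relative to a proposal
#'
#' The class-agnostic parameterization used by the ROI head: center shift
#' scaled by proposal size plus log size ratios,
#' \code{(dx, dy, dw, dh) = ((gx-px)/pw, (gy-py)/ph, log(gw/pw), log(gh/ph))}.
#' The signature admits no class id: one shared delta per proposal, never one
#' per class, which is what lets localization knowledge transfer to classes
#' the classifier has not seen.
#'
#' @param proposal,target boxes as length-4 vectors (x1, y1, x2, y2)
#' @return numeric 4-vector (dx, dy, dw, dh)
#' @export
encodeBoxDelta <- function(proposal, target) {
  p <- as.numeric(asBoxMatrix(proposal)); g <- as.numeric(asBoxMatrix(target))
  pw <- p[3] - p[1]; ph <- p[4] - p[2]
  if (pw <= 0 || ph <= 0) stop("degenerate proposal: zero-sized side")
  gw <- g[3] - g[1]; gh <- g[4] - g[2]
  c((g[1] + g[3] - p[1] - p[3]) / 2 / pw,
    (g[2] + g[4] - p[2] - p[4]) / 2 / ph,
    log(gw / pw), log(gh / ph))
}

#' Decode normalized deltas into a box
#'
#' Exact inverse of \code{\link{encodeBoxDelta}}:
#' \code{decodeBoxDelta(p, encodeBoxDelta(p, g)) == g} to floating precision.
#'
#' @param proposal box as length-4 vector
#' @param delta numeric 4-vector (dx, dy, dw, dh)
#' @return box as numeric 4-vector (x1, y1, x2, y2)
#' @export
decodeBoxDelta <- function(proposal, delta) {
  p <- as.numeric(asBoxMatrix(proposal))
  pw <- p[3] - p[1]; ph <- p[4] - p[2]
  if (pw <= 0 || ph <= 0) stop("degenerate proposal: zero-sized side")
  cx <- (p[1] + p[3]) / 2 + delta[1] * pw
  cy <- (p[2] + p[4]) / 2 + delta[2] * ph
  w <- pw * exp(delta[3]); h <- ph * exp(delta[4])
  c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}
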