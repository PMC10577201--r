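#' @include AllClasses.R task_protocol.R unknown_labeling.R energy_unknown.R
NULL

## ---- fixed window descriptor ------------------------------------------------
## The descriptor replaces the deep backbone: per window it summarizes color
## (channel means and SDs), texture (mean absolute horizontal/vertical
## gradient of the gray plane), a center-vs-full contrast, and the window
## size. It is fixed (untrained), which keeps task training a sequence of
## linear-model updates and therefore CPU-fast.

DESCRIPTOR_DIM <- 13L

## padded integral image: P[i+1, j+1] = sum(m[1:i, 1:j])
integralImage <- function(m) {
  H <- nrow(m); W <- ncol(m)
  P <- matrix(0, H + 1, W + 1)
  P[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  P
}

## sum of m over windows of side s with top-left (row y0+1, col x0+1), vectorized
winSum <- function(P, y0, x0, sy, sx) {
  P[cbind(y0 + sy + 1, x0 + sx + 1)] - P[cbind(y0 + 1, x0 + sx + 1)] -
    P[cbind(y0 + sy + 1, x0 + 1)] + P[cbind(y0 + 1, x0 + 1)]
}

## all grid windows for one image side length, as continuous boxes
#' Dense multi-scale window grid
#'
#' @param size image side in pixels
#' @param scales square window sides
#' @param strides per-scale strides
#' @return data.frame x1, y1, x2, y2, scale (continuous pixel coordinates)
#' @export
windowGrid <- function(size, scales, strides) {
  parts <- lapply(seq_along(scales), function(k) {
    s <- scales[k]
    if (s > size) return(NULL)
    o <- seq(0, size - s, by = strides[k])
    g <- expand.grid(x0 = o, y0 = o)
    data.frame(x1 = g$x0, y1 = g$y0, x2 = g$x0 + s, y2 = g$y0 + s, scale = s)
  })
  do.call(rbind, parts)
}

## descriptors for all grid windows of an image, via integral images
gridDescriptors <- function(image, scales, strides) {
  size <- dim(image)[1]
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  gray <- (R + G + B) / 3
  gx <- cbind(abs(gray[, -1] - gray[, -ncol(gray)]), 0)
  gy <- rbind(abs(gray[-1, ] - gray[-nrow(gray), ]), 0)
  Ps <- lapply(list(R, G, B, R^2, G^2, B^2, gx, gy, gray), integralImage)
  parts <- list(); boxes <- list()
  for (k in seq_along(scales)) {
    s <- scales[k]
    if (s > size) next
    o <- seq(0, size - s, by = strides[k])
    g <- expand.grid(x0 = o, y0 = o)
    x0 <- g$x0; y0 <- g$y0
    n <- s * s
    mR <- winSum(Ps[[1]], y0, x0, s, s) / n
    mG <- winSum(Ps[[2]], y0, x0, s, s) / n
    mB <- winSum(Ps[[3]], y0, x0, s, s) / n
    sdR <- sqrt(pmax(winSum(Ps[[4]], y0, x0, s, s) / n - mR^2, 0))
    sdG <- sqrt(pmax(winSum(Ps[[5]], y0, x0, s, s) / n - mG^2, 0))
    sdB <- sqrt(pmax(winSum(Ps[[6]], y0, x0, s, s) / n - mB^2, 0))
    tX <- winSum(Ps[[7]], y0, x0, s, s) / n
    tY <- winSum(Ps[[8]], y0, x0, s, s) / n
    inset <- floor(s / 4); si <- s - 2L * inset
    inner <- winSum(Ps[[9]], y0 + inset, x0 + inset, si, si) / (si * si)
    full <- winSum(Ps[[9]], y0, x0, s, s) / n
    half <- floor(s / 2)
    lh <- winSum(Ps[[9]], y0, x0, s, half) / (s * half)
    rh <- winSum(Ps[[9]], y0, x0 + s - half, s, half) / (s * half)
    th <- winSum(Ps[[9]], y0, x0, half, s) / (s * half)
    bh <- winSum(Ps[[9]], y0 + s - half, x0, half, s) / (s * half)
    X <- cbind(mR, mG, mB, sdR, sdG, sdB, tX * 8, tY * 8,
               inner - full, lh - rh, th - bh, s / size, s / size)
    parts[[length(parts) + 1L]] <- X
    boxes[[length(boxes) + 1L]] <- data.frame(x1 = x0, y1 = y0,
                                              x2 = x0 + s, y2 = y0 + s)
  }
  list(X = do.call(rbind, parts), boxes = do.call(rbind, boxes))
}

## ---- model construction -----------------------------------------------------

#' Default toy-detector configuration
#'
#' The schedule defaults (300 task iterations, 100 fine-tune iterations,
#' batch size 4) are a desk-scale stand-in for the full-scale schedule of
#' 18,000 / 4,000 iterations at batch 4; every entry is configurable.
#'
#' @param ... overrides of individual entries
#' @return named list of configuration values
#' @export
toyConfig <- function(...) {
  cfg <- list(scales = c(12, 15, 19, 24), strides = c(3, 3, 4, 5),
              embDim = 10L, iterations = 300L, finetuneIterations = 100L,
              batchSize = 4L, lr = 0.5, lrProj = 0.05, lrReg = 0.2,
              margin = 1.0, lambdaCtr = 0.05, protoEta = 0.05,
              protoGamma = 1.0,
              posIou = 0.5, bgIouMax = 0.3, k = 1L,
              roisPerImage = 48L, topN = 200L, nmsIou = 0.5,
              scoreFloor = 0.05, pseudoPhaseFrac = 0.4,
              energyFamily = "weibull", minEnergySamples = 20L, seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Construct an untrained toy detector
#'
#' @param config a \code{\link{toyConfig}} list
#' @return a \linkS4class{ToyDetector} with an empty known-class set
#' @export
toyDetector <- function(config = toyConfig()) {
  d <- DESCRIPTOR_DIM
  emb <- config$embDim
  Wf <- withSeed(config$seed,
                 matrix(stats::rnorm(emb * (d + 1), 0, 0.3), emb, d + 1))
  new("ToyDetector", knownClasses = integer(),
      Wobj = numeric(d + 1),
      Wf = Wf,
      Wc = matrix(0, 2, emb + 1),              # unknown + background only
      Wr = matrix(0, 4, d + 1),
      prototypes = matrix(numeric(), 0, emb),
      config = config)
}

setMethod("show", "ToyDetector", function(object) {
  cat(sprintf("ToyDetector: %d known classes, descriptor dim %d, embedding %d\n",
              length(object@knownClasses), DESCRIPTOR_DIM, object@config$embDim))
  if (length(object@knownClasses))
    cat("  classes:", paste(object@knownClasses, collapse = " "), "\n")
})

## append head rows for classes new at this task; previous class rows, the
## unknown/background rows and the class-agnostic regressor are preserved
extendHead <- function(model, newClasses) {
  add <- setdiff(newClasses, model@knownClasses)
  if (!length(add)) return(model)
  K <- length(model@knownClasses)
  emb <- model@config$embDim
  Wc <- rbind(model@Wc[seq_len(K), , drop = FALSE],
              matrix(0, length(add), emb + 1),
              model@Wc[K + 1:2, , drop = FALSE])
  proto <- rbind(model@prototypes,
                 matrix(NA_real_, length(add), emb,
                        dimnames = list(as.character(add), NULL)))
  initialize(model, knownClasses = c(model@knownClasses, as.integer(add)),
             Wc = Wc, prototypes = proto)
}

## ---- contrastive clustering -------------------------------------------------

#' Contrastive clustering loss over class prototypes
#'
#' For each feature \eqn{f} with class \eqn{c}:
#' \eqn{d(f, p_c) + \sum_{j \ne c} \max(0, \Delta - d(f, p_j))} with
#' Euclidean distance \eqn{d} and margin \eqn{\Delta}; the total is the sum
#' over features. Prototypes are maintained elsewhere as running class means
#' of the embedding. A feature sitting exactly on its prototype with all
#' other prototypes at least \eqn{\Delta} away contributes zero.
#'
#' @param features numeric matrix, one row per feature
#' @param labels class ids, one per feature row
#' @param prototypes matrix with rownames the class ids
#' @param margin the separation margin \eqn{\Delta}
#' @return nonnegative scalar loss
#' @export
contrastiveClusteringLoss <- function(features, labels, prototypes, margin) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  miss <- setdiff(as.character(unique(labels)), rownames(prototypes))
  if (length(miss)) stop("no prototype for class ", miss[1])
  total <- 0
  for (i in seq_len(nrow(features))) {
    dists <- sqrt(rowSums(sweep(prototypes, 2, features[i, ])^2))
    own <- as.character(labels[i])
    total <- total + dists[[own]] +
      sum(pmax(0, margin - dists[setdiff(rownames(prototypes), own)]))
  }
  unname(total)
}

## gradient of the per-feature contrastive term w.r.t. the feature
contrastiveGrad <- function(z, ownProto, otherProtos, margin) {
  eps <- 1e-8
  dOwn <- sqrt(sum((z - ownProto)^2))
  g <- (z - ownProto) / max(dOwn, eps)
  if (NROW(otherProtos)) {
    for (j in seq_len(nrow(otherProtos))) {
      dj <- sqrt(sum((z - otherProtos[j, ])^2))
      if (dj < margin) g <- g - (z - otherProtos[j, ]) / max(dj, eps)
    }
  }
  g
}

## known-class logits carry a prototype-distance penalty:
## l_c = w_c . z + b_c - gamma * d(z, p_c). Features far from every class
## prototype depress all known logits at once, which is what raises the
## energy score on out-of-distribution regions; the unknown and background
## logits are purely linear. Classes whose prototype is not yet initialized
## get no penalty. Returns the logits and the per-class distances.
computeLogits <- function(model, Z) {
  K <- length(model@knownClasses)
  logits <- model@Wc %*% rbind(Z, 1)
  gam <- model@config$protoGamma
  dists <- NULL
  if (gam > 0 && K > 0 && nrow(model@prototypes)) {
    dists <- matrix(0, K, ncol(Z))
    for (ci in seq_len(K)) {
      key <- as.character(model@knownClasses[ci])
      if (!key %in% rownames(model@prototypes) ||
          is.na(model@prototypes[key, 1])) next
      d <- sqrt(colSums((Z - model@prototypes[key, ])^2))
      dists[ci, ] <- d
      logits[ci, ] <- logits[ci, ] - gam * d
    }
  }
  list(logits = logits, dists = dists)
}

## ---- proposals --------------------------------------------------------------

#' Generate scored proposals for one image
#'
#' Scores the dense multi-scale window grid with the model's linear
#' objectness scorer and returns the top-N windows by objectness (ties break
#' toward the lower window index). Deterministic: the same image always
#' yields the same proposals.
#'
#' @param model a \linkS4class{ToyDetector}
#' @param image size x size x 3 array in [0,1]
#' @param imageId identifier carried into the proposal table
#' @param topN number of proposals to return (default from config)
#' @return data.frame image_id, x1, y1, x2, y2, objectness with the window
#'   descriptor matrix attached as attribute \code{"descriptors"}
#' @export
propose <- function(model, image, imageId = "img", topN = model@config$topN) {
  gd <- gridDescriptors(image, model@config$scales, model@config$strides)
  obj <- stats::plogis(cbind(gd$X, 1) %*% model@Wobj)[, 1]
  keep <- order(-obj, seq_along(obj))[seq_len(min(topN, length(obj)))]
  out <- data.frame(image_id = imageId,
                    x1 = gd$boxes$x1[keep], y1 = gd$boxes$y1[keep],
                    x2 = gd$boxes$x2[keep], y2 = gd$boxes$y2[keep],
                    objectness = obj[keep], stringsAsFactors = FALSE)
  attr(out, "descriptors") <- gd$X[keep, , drop = FALSE]
  out
}

## ---- training ---------------------------------------------------------------

## per-image precomputation: grid descriptors, IoU-based labels and
## regression targets against a ground-truth view
prepareImage <- function(image, imageId, gtView, config) {
  gd <- gridDescriptors(image, config$scales, config$strides)
  g <- gtView[gtView$image_id == imageId, , drop = FALSE]
  nW <- nrow(gd$boxes)
  label <- rep(NA_integer_, nW)      # class id; NA = ignore band
  fg <- logical(nW)
  targets <- matrix(NA_real_, nW, 4)
  if (nrow(g)) {
    iou <- pairwiseIoU(as.matrix(gd$boxes), as.matrix(g[, c("x1", "y1", "x2", "y2")]))
    maxIou <- apply(iou, 1, max)
    best <- apply(iou, 1, which.max)
    pos <- maxIou >= config$posIou
    bg <- maxIou < config$bgIouMax
    label[pos] <- g$class_id[best[pos]]
    label[bg] <- 0L                  # background marker
    fg[pos] <- TRUE
    for (i in which(pos))
      targets[i, ] <- encodeBoxDelta(as.numeric(gd$boxes[i, 1:4]),
                                     as.numeric(g[best[i], c("x1", "y1", "x2", "y2")]))
  } else {
    label[] <- 0L
  }
  list(X = gd$X, boxes = gd$boxes, label = label, fg = fg, targets = targets,
       image_id = imageId, pseudo = integer())
}

## one SGD step over a set of sampled ROIs; returns the updated model
sgdStep <- function(model, Xa, slots, fgMask, regTargets, lr) {
  cfg <- model@config
  K <- length(model@knownClasses)
  nOut <- K + 2L
  n <- ncol(Xa)
  Z <- model@Wf %*% Xa
  Za <- rbind(Z, 1)
  cl <- computeLogits(model, Z)
  logits <- sweep(cl$logits, 2, apply(cl$logits, 2, max))
  P <- exp(logits); P <- sweep(P, 2, colSums(P), "/")
  Y <- matrix(0, nOut, n)
  Y[cbind(slots, seq_len(n))] <- 1
  dL <- (P - Y) / n
  ## contrastive term on known-labeled ROIs, through the projection
  dZ <- crossprod(model@Wc[, seq_len(cfg$embDim), drop = FALSE], dL)
  ## the prototype-distance penalty also backpropagates into the embedding
  if (!is.null(cl$dists)) {
    for (ci in seq_len(K)) {
      key <- as.character(model@knownClasses[ci])
      if (!key %in% rownames(model@prototypes) ||
          is.na(model@prototypes[key, 1])) next
      d <- pmax(cl$dists[ci, ], 1e-8)
      dZ <- dZ - cfg$protoGamma *
        sweep(sweep(Z, 1, model@prototypes[key, ]), 2, dL[ci, ] / d, `*`)
    }
  }
  proto <- model@prototypes
  knownCols <- which(slots <= K)
  if (length(knownCols) && nrow(proto)) {
    ready <- rownames(proto)[!is.na(proto[, 1])]
    for (i in knownCols) {
      cl <- as.character(model@knownClasses[slots[i]])
      if (!cl %in% ready) next
      others <- proto[setdiff(ready, cl), , drop = FALSE]
      dZ[, i] <- dZ[, i] + cfg$lambdaCtr *
        contrastiveGrad(Z[, i], proto[cl, ], others, cfg$margin) / n
    }
  }
  model@Wc <- model@Wc - lr * tcrossprod(dL, Za)
  model@Wf <- model@Wf - cfg$lrProj * tcrossprod(dZ, Xa)
  ## running-mean prototype update on the (new) embedding
  if (length(knownCols)) {
    Z2 <- model@Wf %*% Xa[, knownCols, drop = FALSE]
    cls <- model@knownClasses[slots[knownCols]]
    for (cl in unique(cls)) {
      m <- rowMeans(Z2[, cls == cl, drop = FALSE])
      key <- as.character(cl)
      if (is.na(model@prototypes[key, 1])) model@prototypes[key, ] <- m
      else model@prototypes[key, ] <- (1 - cfg$protoEta) * model@prototypes[key, ] +
          cfg$protoEta * m
    }
  }
  ## objectness: foreground (real or pseudo) vs background
  o <- stats::plogis(model@Wobj %*% Xa)[1, ]
  model@Wobj <- model@Wobj - lr * as.numeric(Xa %*% (o - fgMask)) / n
  ## class-agnostic regressor on ROIs with real targets
  hasT <- which(!is.na(regTargets[, 1]))
  if (length(hasT)) {
    Xr <- Xa[, hasT, drop = FALSE]
    Tm <- t(regTargets[hasT, , drop = FALSE])
    E <- model@Wr %*% Xr - Tm
    model@Wr <- model@Wr - cfg$lrReg * tcrossprod(E, Xr) / length(hasT)
  }
  model
}

## sample ROI indices for one prepared image
sampleRois <- function(prep, nRoi) {
  pos <- which(prep$fg)
  pseudo <- prep$pseudo
  bg <- which(!is.na(prep$label) & prep$label == 0L)
  nBg <- min(length(bg), max(8L, 2L * length(pos)), nRoi)
  c(pos, pseudo, if (length(bg)) sample(bg, nBg))
}

## run an SGD loop over prepared images
runSgd <- function(model, preps, iterations, lr) {
  cfg <- model@config
  K <- length(model@knownClasses)
  ids <- names(preps)
  for (it in seq_len(iterations)) {
    batch <- sample(ids, cfg$batchSize, replace = length(ids) < cfg$batchSize)
    Xs <- list(); slots <- integer(); fgm <- numeric(); regT <- list()
    for (id in batch) {
      p <- preps[[id]]
      take <- sampleRois(p, cfg$roisPerImage)
      if (!length(take)) next
      Xs[[length(Xs) + 1L]] <- t(cbind(p$X[take, , drop = FALSE], 1))
      sl <- integer(length(take))
      for (j in seq_along(take)) {
        w <- take[j]
        sl[j] <- if (w %in% p$pseudo) K + 1L
        else if (p$fg[w]) match(p$label[w], model@knownClasses)
        else K + 2L
      }
      slots <- c(slots, sl)
      fgm <- c(fgm, as.numeric(p$fg[take] | take %in% p$pseudo))
      regT[[length(regT) + 1L]] <- p$targets[take, , drop = FALSE]
    }
    if (!length(Xs)) next
    model <- sgdStep(model, do.call(cbind, Xs), slots, fgm,
                     do.call(rbind, regT), lr)
  }
  model
}

#' Train the detector on one task of the sequence
#'
#' Extends the classifier head with the task's new classes (previous class
#' rows, the unknown and background rows, and the class-agnostic regressor
#' are preserved), then runs seeded mini-batch SGD over the task's training
#' view in two phases: a warm-up on the annotated classes that trains the
#' objectness scorer, followed by a phase in which the now-trained scorer
#' pseudo-labels the top background proposal of each image as \code{unknown}
#' (one per image by default) and the unknown slot is trained on them.
#' The contrastive clustering term pulls embeddings toward their class
#' prototype and pushes them beyond the margin from the others. With zero
#' iterations no weight is updated.
#'
#' @param model a \linkS4class{ToyDetector}
#' @param protocol a \linkS4class{TaskProtocol}
#' @param taskIndex task position
#' @param bench a \code{"syntheticBenchmark"}
#' @param split a \code{"DatasetSplit"} from \code{\link{splitDataset}}
#' @param seed training seed (ROI sampling and batch order)
#' @return the trained \linkS4class{ToyDetector}
#' @export
trainTask <- function(model, protocol, taskIndex, bench, split,
                      seed = model@config$seed) {
  cfg <- model@config
  view <- trainView(bench$gt, split, taskIndex)
  model <- extendHead(model, currentClasses(protocol, taskIndex))
  if (cfg$iterations == 0L || nrow(view) == 0L) return(model)
  ids <- unique(view$image_id)
  preps <- lapply(ids, function(id)
    prepareImage(bench$images[[id]], id, view, cfg))
  names(preps) <- ids
  withSeed(seed, {
    itA <- ceiling(cfg$iterations * (1 - cfg$pseudoPhaseFrac))
    model <- runSgd(model, preps, itA, cfg$lr)
    ## pseudo-label one unknown per image with the warmed-up objectness
    for (id in ids) {
      p <- preps[[id]]
      obj <- stats::plogis(cbind(p$X, 1) %*% model@Wobj)[, 1]
      prop <- data.frame(image_id = id, p$boxes[, c("x1", "y1", "x2", "y2")],
                         objectness = obj, stringsAsFactors = FALSE)
      ps <- selectUnknownPseudolabels(prop, view, k = cfg$k,
                                      bgIouMax = cfg$bgIouMax)
      if (nrow(ps)) {
        key <- paste(prop$x1, prop$y1, prop$x2, prop$y2)
        preps[[id]]$pseudo <- match(paste(ps$x1, ps$y1, ps$x2, ps$y2), key)
      }
    }
    runSgd(model, preps, cfg$iterations - itA, cfg$lr)
  })
}

#' Fine-tune on the balanced replay pool
#'
#' Runs the same SGD loop (without pseudo-labeling) over the union of the
#' replay exemplars and the current task's instances, restoring gradient
#' signal for previously learned classes.
#'
#' @param model a trained \linkS4class{ToyDetector}
#' @param pool instance data.frame from \code{\link{finetunePool}}
#' @param bench the \code{"syntheticBenchmark"} holding the images
#' @param seed fine-tuning seed
#' @return the fine-tuned model
#' @export
finetuneReplay <- function(model, pool, bench, seed = model@config$seed) {
  cfg <- model@config
  if (cfg$finetuneIterations == 0L || nrow(pool) == 0L) return(model)
  ids <- unique(pool$image_id)
  preps <- lapply(ids, function(id)
    prepareImage(bench$images[[id]], id, pool, cfg))
  names(preps) <- ids
  withSeed(seed, runSgd(model, preps, cfg$finetuneIterations, cfg$lr / 2))
}

## ---- inference --------------------------------------------------------------

## greedy per-class non-maximum suppression; returns kept row indices
nmsKeep <- function(boxes, scores, iouThreshold) {
  ord <- order(-scores, seq_along(scores))
  keep <- integer()
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (!length(ord)) break
    ious <- vapply(ord, function(j) boxIoU(boxes[i, ], boxes[j, ]), numeric(1))
    ord <- ord[ious <= iouThreshold]
  }
  keep
}

#' Run inference over a set of images
#'
#' Proposals from the objectness-ranked window grid are classified (softmax
#' over known classes + unknown + background), refined by the single
#' class-agnostic box delta, filtered by score floor, and reduced by
#' per-class non-maximum suppression. Every emitted detection carries its
#' known-class logits so downstream energy scoring can run; when an
#' \linkS4class{EnergyModel} is supplied, energy-based relabeling of
#' over-confident known detections is applied.
#'
#' @param model a trained \linkS4class{ToyDetector}
#' @param images named list of image arrays
#' @param energyModel optional \linkS4class{EnergyModel}
#' @return detection data.frame sorted by (image_id, descending score)
#' @export
inferDetections <- function(model, images, energyModel = NULL) {
  cfg <- model@config
  K <- length(model@knownClasses)
  if (K == 0L) stop("model has no known classes; train a task first")
  rows <- list()
  for (id in names(images)) {
    pr <- propose(model, images[[id]], id)
    X <- attr(pr, "descriptors")
    Xa <- t(cbind(X, 1))
    Z <- model@Wf %*% Xa
    logits <- computeLogits(model, Z)$logits
    P <- exp(sweep(logits, 2, apply(logits, 2, max)))
    P <- sweep(P, 2, colSums(P), "/")
    lab_slot <- apply(P[seq_len(K + 1L), , drop = FALSE], 2, which.max)
    ## detection confidence = class posterior weighted by proposal objectness,
    ## so confidently-classified but object-less windows rank low
    score <- P[cbind(lab_slot, seq_len(ncol(P)))] * pr$objectness
    keep <- which(score >= cfg$scoreFloor)
    if (!length(keep)) next
    size <- dim(images[[id]])[1]
    det <- data.frame(image_id = id, x1 = 0, y1 = 0, x2 = 0, y2 = 0,
                      label = ifelse(lab_slot[keep] <= K,
                                     model@knownClasses[lab_slot[keep]],
                                     UNKNOWN_CLASS),
                      score = score[keep], stringsAsFactors = FALSE)
    for (j in seq_along(keep)) {
      i <- keep[j]
      b <- decodeBoxDelta(as.numeric(pr[i, c("x1", "y1", "x2", "y2")]),
                          as.numeric(model@Wr %*% Xa[, i]))
      b[c(1, 3)] <- pmin(pmax(b[c(1, 3)], 0), size)
      b[c(2, 4)] <- pmin(pmax(b[c(2, 4)], 0), size)
      if (b[3] <= b[1]) b[3] <- b[1] + 0.5
      if (b[4] <= b[2]) b[4] <- b[2] + 0.5
      det[j, c("x1", "y1", "x2", "y2")] <- b
    }
    det$logits <- I(lapply(keep, function(i) as.numeric(logits[seq_len(K), i])))
    parts <- lapply(split(seq_len(nrow(det)), det$label), function(ix) {
      kp <- nmsKeep(as.matrix(det[ix, c("x1", "y1", "x2", "y2")]),
                    det$score[ix], cfg$nmsIou)
      det[ix[kp], , drop = FALSE]
    })
    rows[[id]] <- do.call(rbind, parts)
  }
  out <- if (length(rows)) do.call(rbind, rows) else emptyDetections()
  rownames(out) <- NULL
  out <- orderDetections(out)
  if (!is.null(energyModel)) out <- relabelUnknown(out, energyModel)
  out
}

#' Fit the energy model from a validation split
#'
#' Runs inference on the validation images and collects the energies of
#' known-labeled detections matched (IoU >= 0.5) to known versus unknown
#' ground truth -- the validation split is the only place unknown
#' annotations are available -- then fits the two densities. Returns NULL
#' (with a message) when either side has fewer than the minimum sample
#' count, in which case the pipeline proceeds without relabeling.
#'
#' @param model a trained \linkS4class{ToyDetector}
#' @param bench the \code{"syntheticBenchmark"}
#' @param split a \code{"DatasetSplit"}
#' @param protocol a \linkS4class{TaskProtocol}
#' @param taskIndex task position
#' @return an \linkS4class{EnergyModel} or NULL
#' @export
fitEnergyFromValidation <- function(model, bench, split, protocol, taskIndex) {
  cfg <- model@config
  known <- knownAfter(protocol, taskIndex)
  dets <- inferDetections(model, bench$images[split$val_images])
  gts <- bench$gt$instances
  gts <- gts[gts$image_id %in% split$val_images, , drop = FALSE]
  eK <- numeric(); eU <- numeric()
  for (i in seq_len(nrow(dets))) {
    if (dets$label[i] == UNKNOWN_CLASS) next
    lg <- dets$logits[[i]]
    if (is.null(lg) || !length(lg)) next
    g <- gts[gts$image_id == dets$image_id[i], , drop = FALSE]
    if (!nrow(g)) next
    ious <- vapply(seq_len(nrow(g)), function(j)
      boxIoU(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
             as.numeric(g[j, c("x1", "y1", "x2", "y2")])), numeric(1))
    j <- which.max(ious)
    if (ious[j] < 0.5) next
    e <- energyScore(lg)
    if (g$class_id[j] %in% known) eK <- c(eK, e) else eU <- c(eU, e)
  }
  tryCatch(fitEnergyModel(eK, eU, family = cfg$energyFamily,
                          minSamples = cfg$minEnergySamples),
           error = function(err) {
             message("energy model not fitted: ", conditionMessage(err))
             NULL
           })
}
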