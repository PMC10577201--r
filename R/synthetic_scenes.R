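## Seeded synthetic lesion scenes. The generator emulates the structure the
## open-world protocol assumes -- multi-instance images drawn from a 20-class
## registry, later-task classes deliberately confusable with earlier ones,
## a species shift for the final task -- without attempting photorealism.

#' Scene generator configuration
#'
#' Appearance is colored elliptical "lesions" with a per-class hue and a
#' per-class texture frequency on a leaf-green background. Classes of the
#' second half of the registry reuse the hues of the first half with a
#' different texture frequency, creating the realistic confusability of
#' diseases with similar symptoms; the margin that keeps classes separable
#' for the fixed window descriptor is the (hue, texture-frequency) grid
#' spacing of 0.1 in hue and ~0.3 cycles/px in frequency.
#'
#' @param imageSize square image side in pixels
#' @param instancesPerImage integer range \code{c(lo, hi)} of lesions per image
#' @param radiusRange lesion semi-axis range in pixels
#' @param jitter pixel-level appearance noise SD added to all channels
#' @param minInstancesPerClass guaranteed minimum number of rendered instances
#'   per registry class across the benchmark
#' @param seed integer root seed; generation is deterministic given it
#' @return list of class \code{"SceneConfig"}
#' @export
sceneConfig <- function(imageSize = 64, instancesPerImage = c(2, 4),
                        radiusRange = c(6, 11), jitter = 0.02,
                        minInstancesPerClass = 3, seed = 1) {
  stopifnot(instancesPerImage[1] >= 1, radiusRange[1] > 0,
            jitter >= 0, minInstancesPerClass >= 0)
  structure(list(imageSize = as.integer(imageSize),
                 instancesPerImage = as.integer(instancesPerImage),
                 radiusRange = radiusRange, jitter = jitter,
                 minInstancesPerClass = as.integer(minInstancesPerClass),
                 seed = as.integer(seed)),
            class = "SceneConfig")
}

#' Per-class appearance table
#'
#' Deterministic mapping from class id to rendering parameters: hue cycles
#' over a 10-step wheel, texture frequency switches between a low and a high
#' band for hue-sharing classes, saturation and axis ratio vary mildly.
#'
#' @param nClasses number of registry classes
#' @return data.frame: class_id, hue, sat, texFreq, axisRatio
#' @export
classAppearance <- function(nClasses) {
  i <- seq_len(nClasses)
  data.frame(class_id = i,
             hue = ((i - 1) %% 10) / 10,
             sat = 0.7 + 0.1 * ((i %% 3) / 2),
             texFreq = ifelse(((i - 1) %/% 10) %% 2 == 0, 0.10, 0.42),
             axisRatio = 0.8 + 0.2 * ((i * 7) %% 5) / 4)
}

## vectorized HSV -> RGB for scalar h, s and a vector of values v
hsvToRgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6); f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  switch(as.character(i %% 6),
         "0" = cbind(v, t, p), "1" = cbind(q, v, p), "2" = cbind(p, v, t),
         "3" = cbind(p, q, v), "4" = cbind(t, p, v), "5" = cbind(v, p, q))
}

## render one scene: background + lesions; boxes tightly bound the ellipses
renderScene <- function(size, species, lesions, appearance, jitter) {
  img <- array(0, dim = c(size, size, 3))
  base <- if (species == "paprika") c(0.32, 0.52, 0.12) else c(0.20, 0.46, 0.18)
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)  # column index (x)
  ys <- matrix(seq_len(size), size, size)                # row index (y)
  shade <- 0.06 * sin(2 * pi * xs / size) * cos(2 * pi * ys / size)
  for (ch in 1:3) img[, , ch] <- base[ch] + shade
  if (species == "paprika") {                       # narrower leaf silhouette
    cx <- size / 2; cy <- size / 2
    outside <- ((xs - cx) / (0.52 * size))^2 + ((ys - cy) / (0.75 * size))^2 > 1
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[outside] <- plane[outside] * 0.45
      img[, , ch] <- plane
    }
  }
  for (j in seq_len(NROW(lesions))) {
    L <- lesions[j, ]
    ap <- appearance[appearance$class_id == L$class_id, ]
    inside <- ((xs - L$cx) / L$rx)^2 + ((ys - L$cy) / L$ry)^2 <= 1
    idx <- which(inside)
    if (!length(idx)) next
    tex <- 0.62 + 0.30 * sin(2 * pi * ap$texFreq * xs[idx] + L$phase)
    rgb <- hsvToRgb(ap$hue, ap$sat, tex)
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[idx] <- rgb[, ch]; img[, , ch] <- plane
    }
  }
  if (jitter > 0) img <- img + array(stats::rnorm(length(img), 0, jitter), dim(img))
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic open-world detection benchmark
#'
#' Renders \code{nImages} seeded lesion scenes covering the protocol's full
#' class registry (every class occurs at least
#' \code{cfg$minInstancesPerClass} times). Each image is collected for one
#' task, drawn uniformly over the schedule: all its lesions come from that
#' task's class set and its background follows that task's species tag --
#' mirroring how real disease images are gathered in per-task campaigns, so
#' per-task training image pools are disjoint while the shared validation
#' and test pools mix every task's (hence also still-unknown) instances.
#' Returns the images together with COCO-dialect ground truth whose boxes
#' tightly bound the rendered ellipses.
#'
#' @param protocol a \linkS4class{TaskProtocol}
#' @param nImages number of images
#' @param cfg a \code{\link{sceneConfig}}
#' @return list of class \code{"syntheticBenchmark"}: \code{images} (named
#'   list of size x size x 3 arrays in [0,1]) and \code{gt}
#'   (a \code{"cocoGroundTruth"})
#' @export
generateBenchmark <- function(protocol, nImages, cfg = sceneConfig()) {
  nC <- length(classRegistry(protocol))
  appearance <- classAppearance(nC)
  size <- cfg$imageSize
  nT <- nTasks(protocol)
  withSeed(cfg$seed, {
    counts <- sample(seq(cfg$instancesPerImage[1], cfg$instancesPerImage[2]),
                     nImages, replace = TRUE)
    ## balanced assignment of images to collection tasks
    imgTask <- sample(rep(seq_len(nT), length.out = nImages))
    ## fill each task's instance slots from its own class set, honoring the
    ## global per-class minimum
    pool <- vector("list", nT)
    for (t in seq_len(nT)) {
      cls_t <- currentClasses(protocol, t)
      total_t <- sum(counts[imgTask == t])
      need_t <- cfg$minInstancesPerClass * length(cls_t)
      if (total_t < need_t)
        stop(sprintf(
          "cannot guarantee %d instances per class: task %d holds %d slots for %d classes",
          cfg$minInstancesPerClass, t, total_t, length(cls_t)))
      pool[[t]] <- sample(c(rep(cls_t, cfg$minInstancesPerClass),
                            sample(rep(cls_t, 2), total_t - need_t,
                                   replace = TRUE)))
    }
    slotAt <- integer(nT)
    images <- vector("list", nImages)
    inst_rows <- vector("list", nImages)
    img_ids <- sprintf("img_%04d", seq_len(nImages))
    margin <- cfg$radiusRange[2] + 1
    for (i in seq_len(nImages)) {
      t <- imgTask[i]
      cls <- pool[[t]][slotAt[t] + seq_len(counts[i])]
      slotAt[t] <- slotAt[t] + counts[i]
      rx <- stats::runif(counts[i], cfg$radiusRange[1], cfg$radiusRange[2])
      ry <- rx * appearance$axisRatio[cls]
      cx <- stats::runif(counts[i], margin, size - margin)
      cy <- stats::runif(counts[i], margin, size - margin)
      lesions <- data.frame(class_id = cls, cx = cx, cy = cy, rx = rx, ry = ry,
                            phase = stats::runif(counts[i], 0, 2 * pi))
      images[[i]] <- renderScene(size, speciesTag(protocol, t), lesions,
                                 appearance, cfg$jitter)
      inst_rows[[i]] <- data.frame(
        instance_id = sprintf("%s_a%02d", img_ids[i], seq_len(counts[i])),
        image_id = img_ids[i],
        x1 = cx - rx, y1 = cy - ry, x2 = cx + rx, y2 = cy + ry,
        class_id = as.integer(cls), stringsAsFactors = FALSE)
    }
    names(images) <- img_ids
    gt <- structure(list(
      instances = do.call(rbind, inst_rows),
      images = data.frame(image_id = img_ids, width = size, height = size,
                          file_name = NA_character_, stringsAsFactors = FALSE),
      categories = data.frame(id = seq_len(nC),
                              name = unname(classRegistry(protocol)),
                              stringsAsFactors = FALSE)),
      class = "cocoGroundTruth")
    structure(list(images = images, gt = gt, config = cfg),
              class = "syntheticBenchmark")
  })
}

#' Write benchmark images as PNG files
#'
#' @param bench a \code{"syntheticBenchmark"}
#' @param dir output directory (created if needed)
#' @return data.frame of image_id, path, invisibly
#' @export
writeBenchmarkImages <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(bench$images), function(id) {
    p <- file.path(dir, paste0(id, ".png"))
    png::writePNG(bench$images[[id]], p)
    p
  }, character(1))
  invisible(data.frame(image_id = names(bench$images), path = unname(paths),
                       stringsAsFactors = FALSE))
}

#' Detection noise model
#'
#' A controllable simulator of detector behavior with closed-form metric
#' expectations, used to test the evaluation stack without training anything:
#' each ground-truth instance is detected with probability
#' \code{1 - missRate}; a detected unknown-class instance leaks a known label
#' with probability \code{opensetLeakRate} (else it is emitted as
#' \code{unknown}); detected known-class instances are relabeled by the
#' confusion matrix; boxes are jittered with Gaussian noise; spurious known
#' detections arrive as a per-image Poisson stream. Under this model
#' \code{E[U-R] = (1-missRate)(1-opensetLeakRate)} and
#' \code{E[A-OSE] = nUnknownGT (1-missRate) opensetLeakRate}.
#'
#' @param locJitterSD box-corner jitter SD in pixels
#' @param missRate per-instance miss probability
#' @param falsePositiveRate expected spurious detections per image
#' @param confusion known-class confusion matrix (rows sum to 1; identity if
#'   NULL) with rownames/colnames the known class ids
#' @param opensetLeakRate probability a detected unknown instance is emitted
#'   under a known label
#' @param scoreModel list: \code{tpBeta} (Beta parameters for true-detection
#'   scores; NULL means score 1.0) and \code{fpBeta} (for spurious scores)
#' @return list of class \code{"DetectionNoiseModel"}
#' @export
detectionNoiseModel <- function(locJitterSD = 0, missRate = 0,
                                falsePositiveRate = 0, confusion = NULL,
                                opensetLeakRate = 0,
                                scoreModel = list(tpBeta = NULL, fpBeta = c(2, 5))) {
  for (p in c(missRate, opensetLeakRate))
    if (p < 0 || p > 1) stop("rates must lie in [0,1]")
  if (falsePositiveRate < 0 || locJitterSD < 0)
    stop("falsePositiveRate and locJitterSD must be nonnegative")
  if (!is.null(confusion)) {
    if (any(abs(rowSums(confusion) - 1) > 1e-8))
      stop("confusion matrix rows must sum to 1")
  }
  structure(list(locJitterSD = locJitterSD, missRate = missRate,
                 falsePositiveRate = falsePositiveRate, confusion = confusion,
                 opensetLeakRate = opensetLeakRate, scoreModel = scoreModel),
            class = "DetectionNoiseModel")
}

#' Simulate detections from ground truth under a noise model
#'
#' With all noise terms zero the output reproduces the ground truth exactly,
#' with score 1.0 per instance and the correct known/unknown label, so the
#' downstream metrics evaluate to their ideal values (mAP 100, A-OSE 0,
#' U-R 1).
#'
#' @param gt a \code{"cocoGroundTruth"}
#' @param noise a \code{\link{detectionNoiseModel}}
#' @param knownClasses integer ids treated as known; all other ground-truth
#'   classes are unknown-world objects
#' @param seed integer seed
#' @return detection data.frame sorted by (image_id, descending score)
#' @export
simulateDetections <- function(gt, noise, knownClasses, seed = 1) {
  inst <- gt$instances
  sizes <- stats::setNames(gt$images$width, gt$images$image_id)
  withSeed(seed, {
    keep <- stats::runif(nrow(inst)) >= noise$missRate
    inst <- inst[keep, , drop = FALSE]
    n <- nrow(inst)
    lab <- integer(n); score <- numeric(n)
    tpBeta <- noise$scoreModel$tpBeta
    for (i in seq_len(n)) {
      cl <- inst$class_id[i]
      if (cl %in% knownClasses) {
        if (is.null(noise$confusion)) lab[i] <- cl
        else {
          row <- noise$confusion[as.character(cl), ]
          lab[i] <- as.integer(sample(colnames(noise$confusion), 1, prob = row))
        }
      } else {
        lab[i] <- if (stats::runif(1) < noise$opensetLeakRate)
          (if (length(knownClasses)) sample(rep(knownClasses, 2), 1) else UNKNOWN_CLASS)
        else UNKNOWN_CLASS
      }
      score[i] <- if (is.null(tpBeta)) 1.0 else stats::rbeta(1, tpBeta[1], tpBeta[2])
    }
    box <- as.matrix(inst[, c("x1", "y1", "x2", "y2")])
    if (noise$locJitterSD > 0 && n > 0) {
      box <- box + matrix(stats::rnorm(4 * n, 0, noise$locJitterSD), n, 4)
      sz <- sizes[inst$image_id]
      box[, 1] <- pmin(pmax(box[, 1], 0), sz - 1)
      box[, 2] <- pmin(pmax(box[, 2], 0), sz - 1)
      box[, 3] <- pmax(pmin(box[, 3], sz), box[, 1] + 0.5)
      box[, 4] <- pmax(pmin(box[, 4], sz), box[, 2] + 0.5)
    }
    det <- data.frame(image_id = inst$image_id,
                      x1 = box[, 1], y1 = box[, 2],
                      x2 = box[, 3], y2 = box[, 4],
                      label = lab, score = score, stringsAsFactors = FALSE)
    if (noise$falsePositiveRate > 0 && length(knownClasses)) {
      fp_rows <- lapply(gt$images$image_id, function(id) {
        k <- stats::rpois(1, noise$falsePositiveRate)
        if (k == 0) return(NULL)
        sz <- sizes[[id]]
        w <- stats::runif(k, 8, 20); h <- stats::runif(k, 8, 20)
        x1 <- stats::runif(k, 0, sz - w); y1 <- stats::runif(k, 0, sz - h)
        data.frame(image_id = id, x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h,
                   label = sample(rep(knownClasses, 2), k, replace = TRUE),
                   score = stats::rbeta(k, noise$scoreModel$fpBeta[1],
                                        noise$scoreModel$fpBeta[2]),
                   stringsAsFactors = FALSE)
      })
      det <- rbind(det, do.call(rbind, fp_rows))
    }
    det$logits <- I(vector("list", nrow(det)))
    orderDetections(det)
  })
}
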