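#' @include toy_detector.R openworld_metrics.R replay_memory.R
NULL

#' Default end-to-end run configuration
#'
#' @param nTasks,classesPerTask protocol shape (default the 4-task x 5-class
#'   schedule)
#' @param nImages benchmark size
#' @param seed root seed; every stage derives its own seed from it
#' @param ... overrides: \code{scene} (list of \code{\link{sceneConfig}}
#'   overrides), \code{detector} (list of \code{\link{toyConfig}} overrides),
#'   \code{valFrac}, \code{testFrac}, \code{replay}, \code{nMin},
#'   \code{order}
#' @return named list accepted by \code{\link{runBenchmark}}
#' @export
defaultRunConfig <- function(nTasks = 4, classesPerTask = 5, nImages = 80,
                             seed = 1, ...) {
  cfg <- list(protocol = defaultProtocolConfig(nTasks, classesPerTask),
              nImages = nImages, seed = seed,
              scene = list(), detector = list(),
              valFrac = 0.2, testFrac = 0.2,
              replay = TRUE, nMin = 25L, order = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

## md5 digest of a data.frame, for the run manifest
tableDigest <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full open-world benchmark cycle
#'
#' Wires protocol -> synthetic scenes -> split -> per-task training with
#' unknown pseudo-labeling -> balanced replay fine-tuning -> validation-set
#' energy fitting -> inference with energy relabeling -> open-world
#' evaluation, in the configured task order (reversed orders supported), and
#' emits one \linkS4class{MetricReport} per task plus a manifest capturing
#' the config, derived per-stage seeds and data digests. All randomness
#' flows from the single root seed.
#'
#' @param config list from \code{\link{defaultRunConfig}} or a path to a
#'   YAML file with the same structure
#' @return list of class \code{"owRun"}: \code{reports} (per task),
#'   \code{manifest}, \code{model}, \code{protocol}, \code{bench},
#'   \code{split}, \code{energyModels}, \code{detections} (per-task test
#'   detections)
#' @export
runBenchmark <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seeds <- list(scene = deriveSeed(config$seed, 1),
                split = deriveSeed(config$seed, 2),
                train = deriveSeed(config$seed, 3),
                replay = deriveSeed(config$seed, 4))
  stage <- "protocol"
  result <- tryCatch({
    protocol <- buildProtocol(config$protocol, order = config$order)
    stage <- "synthetic_scenes"
    sceneArgs <- config$scene
    sceneArgs$seed <- seeds$scene
    bench <- generateBenchmark(protocol, config$nImages,
                               do.call(sceneConfig, sceneArgs))
    stage <- "split"
    split <- splitDataset(bench$gt, protocol, config$valFrac,
                          config$testFrac, seeds$split)
    stage <- "train"
    detArgs <- config$detector
    detArgs$seed <- seeds$train
    model <- toyDetector(do.call(toyConfig, detArgs))
    registry <- as.integer(names(classRegistry(protocol)))
    reports <- list(); energyModels <- list(); detections <- list()
    for (t in seq_len(nTasks(protocol))) {
      stage <- sprintf("train_task_%d", t)
      model <- trainTask(model, protocol, t, bench, split,
                         seed = deriveSeed(seeds$train, t))
      if (isTRUE(config$replay) && t >= 2L) {
        stage <- sprintf("replay_task_%d", t)
        seen <- do.call(rbind, lapply(seq_len(t), function(s)
          trainView(bench$gt, split, s)))
        store <- buildReplaySet(seen, knownAfter(protocol, t), registry,
                                nMin = config$nMin,
                                seed = deriveSeed(seeds$replay, t))
        pool <- finetunePool(store, trainView(bench$gt, split, t), seen)
        ## train on every known annotation of the pooled images, so co-hosted
        ## instances that were not sampled as exemplars are never presented
        ## as background
        pool <- seen[seen$image_id %in% unique(pool$image_id), , drop = FALSE]
        model <- finetuneReplay(model, pool, bench,
                                seed = deriveSeed(seeds$replay, 100 + t))
      }
      stage <- sprintf("energy_task_%d", t)
      energyModels[t] <- list(fitEnergyFromValidation(model, bench, split,
                                                      protocol, t))
      stage <- sprintf("eval_task_%d", t)
      dets <- inferDetections(model, bench$images[split$test_images],
                              energyModel = energyModels[[t]])
      detections[[t]] <- dets
      testGt <- bench$gt$instances
      testGt <- testGt[testGt$image_id %in% split$test_images, , drop = FALSE]
      reports[[t]] <- suppressWarnings(evaluateTask(dets, testGt, protocol, t))
    }
    manifest <- list(config = config, seeds = seeds,
                     gt_digest = tableDigest(bench$gt$instances),
                     split_digest = tableDigest(
                       data.frame(id = c(split$val_images, split$test_images))),
                     n_images = config$nImages,
                     task_order = if (is.null(config$order))
                       seq_len(nTasks(protocol)) else config$order)
    structure(list(reports = reports, manifest = manifest, model = model,
                   protocol = protocol, bench = bench, split = split,
                   energyModels = energyModels, detections = detections),
              class = "owRun")
  }, error = function(e) {
    stop("benchmark run failed in stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  result
}

#' Summarize a benchmark run as a table
#' @param run an \code{"owRun"} from \code{\link{runBenchmark}}
#' @return data.frame with one row per task (columns task, P, C, K, A_OSE, U_R)
#' @export
runSummary <- function(run) {
  do.call(rbind, lapply(run$reports, reportAsRow))
}
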