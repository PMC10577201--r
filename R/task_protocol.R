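#' @include AllClasses.R AllGenerics.R
NULL

#' Build an open-world task protocol
#'
#' Constructs the class schedule: an ordered list of tasks, each contributing
#' a disjoint set of class names (optionally tagged with a species), from
#' which the known/unknown partition at every point of the sequence follows.
#' The registry assigns consecutive integer ids in the order classes first
#' appear.
#'
#' @param config either a path to a YAML/JSON protocol file or a list with an
#'   element \code{tasks}: a list of \code{list(classes = <character>,
#'   species = <character scalar>)}.
#' @param order optional permutation of task indices; the protocol is built
#'   with tasks in this order (the order-sensitivity experiment is a
#'   configuration, not a code change). Ids are still assigned from the
#'   original listing so the registry is order-invariant.
#' @return a \linkS4class{TaskProtocol}
#' @examples
#' p <- buildProtocol(defaultProtocolConfig())
#' length(knownAfter(p, 4))   # 20
#' length(unknownAt(p, 1))    # 15
#' @export
buildProtocol <- function(config, order = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::fromJSON(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  tasks_cfg <- config$tasks
  if (is.null(tasks_cfg) || !length(tasks_cfg))
    stop("protocol config needs a nonempty 'tasks' list")
  all_names <- unlist(lapply(tasks_cfg, function(t) as.character(t$classes)))
  if (anyDuplicated(all_names))
    stop("class '", all_names[duplicated(all_names)][1],
         "' appears in more than one task")
  registry <- all_names                      # id i -> name, fixed listing order
  if (is.null(order)) order <- seq_along(tasks_cfg)
  if (!setequal(order, seq_along(tasks_cfg)))
    stop("'order' must be a permutation of the task indices")
  tasks <- lapply(seq_along(order), function(pos) {
    t <- tasks_cfg[[order[pos]]]
    list(task_index = pos,
         class_ids = match(as.character(t$classes), registry),
         species_tag = if (is.null(t$species)) "default" else as.character(t$species))
  })
  new("TaskProtocol", tasks = tasks, classNames = registry)
}

#' Default 4-task x 5-class protocol configuration
#'
#' The study condition the synthetic benchmark emulates: three tasks of five
#' tomato-style disease classes followed by a cross-species task of five
#' paprika-style classes, giving cumulative known counts 5/10/15/20 and
#' residual unknown counts 15/10/5/0 along the sequence.
#'
#' @param nTasks number of tasks (default 4)
#' @param classesPerTask classes introduced per task (default 5)
#' @return a config list accepted by \code{\link{buildProtocol}}
#' @export
defaultProtocolConfig <- function(nTasks = 4, classesPerTask = 5) {
  tasks <- lapply(seq_len(nTasks), function(t) {
    list(classes = sprintf("disease_t%d_%02d", t, seq_len(classesPerTask)),
         species = if (t == nTasks && nTasks > 1) "paprika" else "tomato")
  })
  list(tasks = tasks)
}

setMethod("nTasks", "TaskProtocol", function(x) length(x@tasks))

setMethod("knownAfter", "TaskProtocol", function(x, taskIndex) {
  stopifnot(taskIndex >= 0, taskIndex <= length(x@tasks))
  if (taskIndex == 0L) return(integer())
  sort(unlist(lapply(x@tasks[seq_len(taskIndex)], `[[`, "class_ids")))
})

setMethod("unknownAt", "TaskProtocol", function(x, taskIndex) {
  setdiff(seq_along(x@classNames), knownAfter(x, taskIndex))
})

setMethod("currentClasses", "TaskProtocol", function(x, taskIndex) {
  stopifnot(taskIndex >= 1, taskIndex <= length(x@tasks))
  sort(x@tasks[[taskIndex]]$class_ids)
})

setMethod("previousClasses", "TaskProtocol", function(x, taskIndex) {
  knownAfter(x, taskIndex - 1L)
})

setMethod("classRegistry", "TaskProtocol", function(x) {
  stats::setNames(x@classNames, seq_along(x@classNames))
})

setMethod("show", "TaskProtocol", function(object) {
  cat(sprintf("TaskProtocol: %d tasks, %d classes\n",
              length(object@tasks), length(object@classNames)))
  for (t in object@tasks)
    cat(sprintf("  task %d [%s]: %d classes (known after: %d, unknown: %d)\n",
                t$task_index, t$species_tag, length(t$class_ids),
                length(knownAfter(object, t$task_index)),
                length(unknownAt(object, t$task_index))))
})

#' Species tag of one task
#' @param x a \linkS4class{TaskProtocol}
#' @param taskIndex task position
#' @return character scalar
#' @export
speciesTag <- function(x, taskIndex) x@tasks[[taskIndex]]$species_tag

#' Split a benchmark into train/validation/test at the image level
#'
#' Draws one shared validation set and one shared test set (default 20% each
#' of the integrated image pool) used across all tasks; the remainder is the
#' training pool. Splitting at the image level prevents an image from leaking
#' across splits. Each pool image is then assigned to exactly one task's
#' training view: the latest task among its annotated classes, i.e. the
#' first point in the sequence at which every object in the image has a
#' label. Per-task training image sets are therefore disjoint, and no
#' training view ever contains an annotation of a class still unknown at its
#' task -- earlier-task objects appearing in a later task's images stay
#' annotated (they are known by then), while a not-yet-known object can only
#' occur in an image assigned to a later task, where it is stripped from
#' this task's view. Validation and test keep all annotations (unknown
#' ground truth is needed there for energy fitting and for U-R/A-OSE).
#'
#' @param gt a \code{"cocoGroundTruth"} object
#' @param protocol a \linkS4class{TaskProtocol}
#' @param valFrac,testFrac split fractions (defaults 0.20/0.20)
#' @param seed integer; the partition is deterministic given the seed
#' @return a list of class \code{"DatasetSplit"}: \code{train_images},
#'   \code{val_images}, \code{test_images} (character vectors of image ids),
#'   \code{train_by_task} (list of per-task instance-id vectors after
#'   stripping), \code{val_instances}, \code{test_instances}
#' @export
splitDataset <- function(gt, protocol, valFrac = 0.2, testFrac = 0.2, seed = 1) {
  stopifnot(valFrac + testFrac > 0, valFrac + testFrac < 1)
  ids <- gt$images$image_id
  nVal <- round(length(ids) * valFrac)
  nTest <- round(length(ids) * testFrac)
  if (nVal < 1 || nTest < 1 || length(ids) - nVal - nTest < 1)
    stop("too few images for nonempty train/val/test splits")
  perm <- withSeed(seed, sample(ids))
  val <- sort(perm[seq_len(nVal)])
  test <- sort(perm[nVal + seq_len(nTest)])
  train <- sort(perm[-seq_len(nVal + nTest)])
  inst <- gt$instances
  taskOf <- integer(length(classRegistry(protocol)))
  for (t in seq_len(nTasks(protocol)))
    taskOf[currentClasses(protocol, t)] <- t
  onTrain <- inst[inst$image_id %in% train, , drop = FALSE]
  imgTask <- tapply(taskOf[onTrain$class_id], onTrain$image_id, max)
  train_by_task <- lapply(seq_len(nTasks(protocol)), function(t) {
    imgs <- names(imgTask)[imgTask == t]
    known <- knownAfter(protocol, t)
    view <- onTrain[onTrain$image_id %in% imgs &
                    onTrain$class_id %in% known, , drop = FALSE]
    view$instance_id
  })
  structure(list(train_images = train, val_images = val, test_images = test,
                 train_by_task = train_by_task,
                 val_instances = inst$instance_id[inst$image_id %in% val],
                 test_instances = inst$instance_id[inst$image_id %in% test],
                 seed = as.integer(seed)),
            class = "DatasetSplit")
}

#' Extract a task's training view as an instance table
#'
#' @param gt a \code{"cocoGroundTruth"} object
#' @param split a \code{"DatasetSplit"}
#' @param taskIndex task position
#' @return instance data.frame restricted to the task's training view
#' @export
trainView <- function(gt, split, taskIndex) {
  gt$instances[gt$instances$instance_id %in% split$train_by_task[[taskIndex]], ,
               drop = FALSE]
}
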