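#' @include AllClasses.R
NULL

#' Build a balanced exemplar replay store
#'
#' After each incremental step a balanced set of training samples is stored
#' at random and later used to fine-tune the model against catastrophic
#' forgetting. The store guarantees a minimum of \code{nMin} instances per
#' known class (default 25) whenever that many are available; classes with
#' fewer contribute all of them and are reported in the store's shortfall.
#' Selection is uniform without replacement per class and deterministic under
#' the seed. The exemplar unit is the instance (with its host image retained
#' through the instance table); an image can host exemplars of several
#' classes.
#'
#' @param instances instance data.frame pooling the training views of all
#'   tasks seen so far
#' @param knownClasses integer ids to store exemplars for; every id must be
#'   registered in \code{registry}
#' @param registry integer vector of all valid class ids (e.g.
#'   \code{as.integer(names(classRegistry(protocol)))})
#' @param nMin guaranteed per-class minimum (default 25)
#' @param seed integer seed
#' @return a \linkS4class{ReplayStore}
#' @export
buildReplaySet <- function(instances, knownClasses, registry, nMin = 25L,
                           seed = 1L) {
  stopifnot(nMin >= 1L)
  bad <- setdiff(knownClasses, registry)
  if (length(bad)) stop("unknown class id in replay request: ", bad[1])
  withSeed(seed, {
    exemplars <- list(); shortfall <- integer()
    for (cl in knownClasses) {
      avail <- instances$instance_id[instances$class_id == cl]
      if (length(avail) <= nMin) {
        chosen <- avail
        if (length(avail) < nMin)
          shortfall[as.character(cl)] <- length(avail)
      } else chosen <- sample(avail, nMin)
      exemplars[[as.character(cl)]] <- sort(chosen)
    }
    new("ReplayStore", exemplars = exemplars, nMin = as.integer(nMin),
        shortfall = shortfall, seed = as.integer(seed))
  })
}

#' Number of exemplars held per class
#' @param store a \linkS4class{ReplayStore}
#' @return named integer vector
#' @export
exemplarCounts <- function(store) {
  vapply(store@exemplars, length, integer(1))
}

setMethod("show", "ReplayStore", function(object) {
  cat(sprintf("ReplayStore: %d classes, nMin = %d, %d exemplars total\n",
              length(object@exemplars), object@nMin,
              sum(exemplarCounts(object))))
  if (length(object@shortfall))
    cat("  shortfall:", paste(names(object@shortfall), object@shortfall,
                              sep = ":", collapse = " "), "\n")
})

#' Assemble the fine-tuning pool
#'
#' The union of the stored exemplars and the current task's instances, with
#' duplicates removed by instance id. At the first task the store is empty
#' and the pool is just the current instances.
#'
#' @param store a \linkS4class{ReplayStore} (may hold no classes)
#' @param currentInstances instance data.frame of the current task
#' @param allInstances instance table to resolve exemplar ids against
#'   (defaults to \code{currentInstances}, sufficient only at the first task)
#' @return instance data.frame, one row per unique instance id
#' @export
finetunePool <- function(store, currentInstances, allInstances = currentInstances) {
  ids <- unique(c(unlist(store@exemplars, use.names = FALSE),
                  currentInstances$instance_id))
  pool <- allInstances[allInstances$instance_id %in% ids, , drop = FALSE]
  missing <- setdiff(ids, pool$instance_id)
  if (length(missing))
    stop("exemplar instance ", missing[1], " cannot be resolved")
  pool[!duplicated(pool$instance_id), , drop = FALSE]
}

#' Write a replay store manifest to JSON
#' @param store a \linkS4class{ReplayStore}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeReplayManifest <- function(store, path) {
  jsonlite::write_json(list(n_min = store@nMin, seed = store@seed,
                            shortfall = as.list(store@shortfall),
                            exemplars = store@exemplars),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
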