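#' @include AllClasses.R
NULL

#' Number of tasks in a protocol
#' @param x a \linkS4class{TaskProtocol}
#' @return integer scalar
#' @export
setGeneric("nTasks", function(x) standardGeneric("nTasks"))

#' Class ids known after completing a task
#'
#' The cumulative known set: the union of the class sets of tasks
#' \code{1..taskIndex} in the protocol's configured order. \code{taskIndex = 0}
#' gives the empty set.
#'
#' @param x a \linkS4class{TaskProtocol}
#' @param taskIndex integer in \code{0..nTasks(x)}
#' @return sorted integer vector of class ids
#' @export
setGeneric("knownAfter", function(x, taskIndex) standardGeneric("knownAfter"))

#' Class ids still unknown at a task
#'
#' The registry complement of \code{knownAfter(x, taskIndex)}: classes present
#' in the world but not yet annotated for training. Empty at the final task of
#' a complete schedule.
#'
#' @inheritParams knownAfter
#' @return sorted integer vector of class ids (possibly empty)
#' @export
setGeneric("unknownAt", function(x, taskIndex) standardGeneric("unknownAt"))

#' Class ids introduced by one task
#' @inheritParams knownAfter
#' @return sorted integer vector of class ids
#' @export
setGeneric("currentClasses", function(x, taskIndex) standardGeneric("currentClasses"))

#' Class ids known before a task starts
#' @inheritParams knownAfter
#' @return sorted integer vector (empty at the first task)
#' @export
setGeneric("previousClasses", function(x, taskIndex) standardGeneric("previousClasses"))

#' Global class registry of a protocol
#' @param x a \linkS4class{TaskProtocol}
#' @return named character vector: names are class ids, values class names
#' @export
setGeneric("classRegistry", function(x) standardGeneric("classRegistry"))
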