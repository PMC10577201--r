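#' @import methods
NULL

#' Sentinel class id for the `unknown` label
#'
#' Detections and pseudo-ground-truth whose category is not (yet) part of the
#' known set carry this reserved id. On disk it is serialized as a dedicated
#' category named \code{"unknown"} so files stay valid COCO for third-party
#' viewers.
#'
#' @export
UNKNOWN_CLASS <- -1L

#' TaskProtocol: the open-world class schedule
#'
#' An ordered sequence of tasks, each introducing a disjoint set of disease
#' classes. At any point \code{t} in the sequence the world is partitioned
#' into known classes (union of tasks 1..t) and unknown classes (the rest of
#' the registry). Task order is configurable, which makes order-sensitivity
#' experiments a feature of the protocol rather than a separate code path.
#'
#' @slot tasks list of per-task descriptors: \code{task_index}, \code{class_ids}
#'   (integer), \code{species_tag} (character scalar).
#' @slot classNames character vector; position \code{i} names class id \code{i}.
#'
#' @exportClass TaskProtocol
setClass("TaskProtocol",
  representation(tasks = "list", classNames = "character"),
  validity = function(object) {
    msgs <- character()
    all_ids <- unlist(lapply(object@tasks, `[[`, "class_ids"))
    if (anyDuplicated(all_ids))
      msgs <- c(msgs, "task class sets must be pairwise disjoint")
    if (any(vapply(object@tasks, function(t) length(t$class_ids) == 0L, logical(1))))
      msgs <- c(msgs, "every task needs a nonempty class set")
    if (!all(all_ids %in% seq_along(object@classNames)))
      msgs <- c(msgs, "class ids must index into the class registry")
    if (length(msgs)) msgs else TRUE
  }
)

#' EnergyModel: fitted known/unknown energy densities
#'
#' Holds maximum-likelihood density fits of the energy score
#' \eqn{E = -T \log \sum_c \exp(l_c / T)} for detections matched to known
#' versus unknown ground truth on a held-out validation split, plus the
#' likelihood-ratio decision rule used to relabel over-confident known
#' predictions as unknown.
#'
#' @slot family "gaussian" or "weibull" (three-parameter, location-shifted).
#' @slot knownPar,unknownPar named numeric parameter vectors
#'   (gaussian: mean, sd; weibull: shape, scale, loc).
#' @slot temperature positive scalar T of the energy score.
#' @slot priorKnown prior weight on the known hypothesis in the decision rule.
#' @slot nKnown,nUnknown sample sizes behind the two fits.
#'
#' @exportClass EnergyModel
setClass("EnergyModel",
  representation(family = "character", knownPar = "numeric",
                 unknownPar = "numeric", temperature = "numeric",
                 priorKnown = "numeric", nKnown = "integer",
                 nUnknown = "integer"),
  validity = function(object) {
    msgs <- character()
    if (!object@family %in% c("gaussian", "weibull"))
      msgs <- c(msgs, "family must be 'gaussian' or 'weibull'")
    if (object@temperature <= 0) msgs <- c(msgs, "temperature must be > 0")
    if (object@priorKnown < 0 || object@priorKnown > 1)
      msgs <- c(msgs, "priorKnown must lie in [0,1]")
    if (object@family == "gaussian") {
      for (p in list(object@knownPar, object@unknownPar))
        if (!all(c("mean", "sd") %in% names(p)) || p[["sd"]] <= 0)
          msgs <- c(msgs, "gaussian parameters need mean and positive sd")
    } else {
      for (p in list(object@knownPar, object@unknownPar))
        if (!all(c("shape", "scale", "loc") %in% names(p)) ||
            p[["shape"]] <= 0 || p[["scale"]] <= 0)
          msgs <- c(msgs, "weibull parameters need positive shape/scale and a loc")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' ReplayStore: balanced exemplar memory
#'
#' Per-class exemplar instances retained after each incremental step, with a
#' guaranteed minimum of \code{nMin} instances per class whenever availability
#' permits; classes with fewer available contribute all of them and are listed
#' in \code{shortfall}. The store grows at most linearly in the number of
#' known classes.
#'
#' @slot exemplars named list: class id (as character) -> character vector of
#'   instance ids.
#' @slot nMin guaranteed per-class minimum (25 by default at construction).
#' @slot shortfall named integer vector of available counts for classes that
#'   could not reach \code{nMin}.
#' @slot seed integer seed the selection was drawn under.
#'
#' @exportClass ReplayStore
setClass("ReplayStore",
  representation(exemplars = "list", nMin = "integer",
                 shortfall = "integer", seed = "integer"),
  validity = function(object) {
    if (object@nMin < 1L) return("nMin must be >= 1")
    short <- names(object@shortfall)
    for (cl in names(object@exemplars)) {
      n <- length(object@exemplars[[cl]])
      if (n < object@nMin && !(cl %in% short))
        return(sprintf("class %s holds %d < nMin exemplars but is not flagged short", cl, n))
    }
    TRUE
  }
)

#' MetricReport: one open-world evaluation pass
#'
#' Holds per-class 11-point AP at IoU 0.5 plus the Table-style summaries:
#' previous-task mAP (P), current-task mAP (C), known mAP (K) -- all on the
#' 0-100 percent scale -- Unknown Recall (unit interval) and the Absolute
#' Open-Set Error count. P is NA at the first task; U-R and A-OSE are NA when
#' no unknown ground truth exists (the final task of a completed schedule).
#'
#' @slot classAP named numeric, AP in [0,1] per evaluated class id.
#' @slot prevMAP,currMAP,knownMAP mAP summaries (the P/C/K columns) on the
#'   percent scale; NA when the class set is empty.
#' @slot uRecall Unknown Recall in [0,1], or NA when no unknown GT exists.
#' @slot aose Absolute Open-Set Error count, or NA when no unknown GT exists.
#' @slot taskIndex position in the task sequence this report evaluates.
#'
#' @exportClass MetricReport
setClass("MetricReport",
  representation(classAP = "numeric", prevMAP = "numeric", currMAP = "numeric",
                 knownMAP = "numeric", uRecall = "numeric", aose = "numeric",
                 taskIndex = "integer"),
  validity = function(object) {
    ap <- object@classAP
    if (length(ap) && (any(ap < -1e-12) || any(ap > 1 + 1e-12)))
      return("per-class AP must lie in [0,1]")
    if (length(object@uRecall) == 1 && !is.na(object@uRecall) &&
        (object@uRecall < 0 || object@uRecall > 1))
      return("uRecall must lie in [0,1]")
    if (length(object@aose) == 1 && !is.na(object@aose) && object@aose < 0)
      return("aose must be nonnegative")
    TRUE
  }
)

#' ToyDetector: a CPU-scale two-stage detector analogue
#'
#' A miniature stand-in for the Faster-RCNN-with-FPN architecture that the
#' full-scale paradigm runs on: a fixed window descriptor replaces the deep
#' backbone, a linear objectness scorer replaces the RPN, a linear projection
#' plus multinomial head (known classes + unknown + background) replaces the
#' classification branch, and a single class-agnostic linear regressor emits
#' one box refinement per proposal regardless of class.
#'
#' @slot knownClasses integer class ids the head currently covers, in
#'   acquisition order.
#' @slot Wobj numeric vector, linear objectness scorer over the descriptor
#'   (+ bias).
#' @slot Wf matrix, descriptor -> embedding projection (+ bias column).
#' @slot Wc matrix, embedding -> logits over known classes, then the unknown
#'   slot, then background (+ bias column).
#' @slot Wr 4-row matrix, the class-agnostic box-delta regressor (+ bias
#'   column); its output dimension is 4 regardless of how many classes are
#'   known, and head extension never touches it.
#' @slot prototypes matrix of per-class embedding prototypes (running means)
#'   for the contrastive clustering loss; rownames are class ids.
#' @slot config training/inference configuration list.
#'
#' @exportClass ToyDetector
setClass("ToyDetector",
  representation(knownClasses = "integer", Wobj = "numeric", Wf = "matrix",
                 Wc = "matrix", Wr = "matrix", prototypes = "matrix",
                 config = "list"),
  validity = function(object) {
    k <- length(object@knownClasses)
    if (nrow(object@Wc) != k + 2L)
      return("classifier must have one row per known class plus unknown plus background")
    if (nrow(object@Wr) != 4L)
      return("the box regressor is class-agnostic: exactly 4 outputs")
    TRUE
  }
)
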