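#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, runs \code{expr}, and restores the caller's RNG state,
#' so every seeded stage is deterministic without clobbering the session
#' stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of \code{expr}
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## derive a per-stage seed from a root seed, kept inside 32-bit range
deriveSeed <- function(rootSeed, offset) {
  as.integer((as.numeric(rootSeed) * 7919 + offset * 104729) %% 2147483647)
}

#' Empty detection table
#'
#' Detections are plain data.frames with columns \code{image_id} (character),
#' \code{x1,y1,x2,y2} (numeric, strictly positive extent), \code{label}
#' (integer class id or \code{\link{UNKNOWN_CLASS}}), \code{score} in [0,1],
#' and a list-column \code{logits} holding a numeric vector over known classes
#' (or NULL when absent).
#'
#' @return zero-row detection data.frame with the canonical columns
#' @export
emptyDetections <- function() {
  data.frame(image_id = character(), x1 = numeric(), y1 = numeric(),
             x2 = numeric(), y2 = numeric(), label = integer(),
             score = numeric(), logits = I(list()),
             stringsAsFactors = FALSE)
}

#' Empty ground-truth instance table
#'
#' Ground-truth instances are data.frames with columns \code{instance_id},
#' \code{image_id} (character), \code{x1,y1,x2,y2} (numeric) and
#' \code{class_id} (integer).
#'
#' @return zero-row instance data.frame
#' @export
emptyInstances <- function() {
  data.frame(instance_id = character(), image_id = character(),
             x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
             class_id = integer(), stringsAsFactors = FALSE)
}

## stable order by image then descending score (ties keep input order)
orderDetections <- function(det) {
  det[order(det$image_id, -det$score, seq_len(nrow(det))), , drop = FALSE]
}
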