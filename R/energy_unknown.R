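#' @include AllClasses.R
NULL

#' Energy score of a logit vector
#'
#' \eqn{E(x) = -T \log \sum_c \exp(l_c / T)} over the known-class logits.
#' Lower energies correspond to confident in-distribution predictions; the
#' score is monotone decreasing in every single logit, and for C equal logits
#' l it reduces to \eqn{-l - T \log C}. Computed with the usual max-shift for
#' numerical stability.
#'
#' @param logits numeric vector over known classes, or a matrix with one row
#'   per detection
#' @param temperature positive scalar T (default 1)
#' @return numeric scalar (or vector for matrix input)
#' @export
energyScore <- function(logits, temperature = 1) {
  stopifnot(temperature > 0)
  if (is.matrix(logits)) return(apply(logits, 1, energyScore, temperature))
  if (!length(logits)) stop("energy score needs at least one logit")
  z <- logits / temperature
  m <- max(z)
  -temperature * (m + log(sum(exp(z - m))))
}

## negative log-likelihood driven MLE of a location-shifted Weibull:
## x - loc ~ Weibull(shape, scale), loc < min(x). Parameterized as
## (log shape, log scale, log(min(x) - loc)) so the support constraint holds
## throughout the optimization.
fitShiftedWeibull <- function(x) {
  mn <- min(x)
  nll <- function(par) {
    k <- exp(par[1]); lam <- exp(par[2]); loc <- mn - exp(par[3])
    -sum(stats::dweibull(x - loc, shape = k, scale = lam, log = TRUE))
  }
  s <- stats::sd(x)
  init <- c(log(1.5), log(max(s, 1e-3)), log(max(0.5 * s, 1e-3)))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  c(shape = exp(fit$par[1]), scale = exp(fit$par[2]),
    loc = mn - exp(fit$par[3]))
}

densityAt <- function(par, family, e) {
  if (family == "gaussian")
    stats::dnorm(e, par[["mean"]], par[["sd"]])
  else
    stats::dweibull(pmax(e - par[["loc"]], 0), par[["shape"]], par[["scale"]])
}

#' Fit known/unknown energy densities on validation energies
#'
#' Maximum-likelihood fit, within the chosen family, of the energy
#' distribution of validation detections matched to known ground truth and
#' of those matched to unknown ground truth. The default family is the
#' location-shifted Weibull customary in open-world detectors, with a
#' Gaussian alternative;
#' the decision rule is a likelihood ratio with a configurable prior weight
#' on the known hypothesis (equal priors by default).
#'
#' @param knownEnergies,unknownEnergies numeric vectors of energy values
#' @param family "weibull" (shifted, three-parameter) or "gaussian"
#' @param temperature the temperature the energies were computed at
#' @param minSamples minimum sample size per fit (default 20)
#' @param priorKnown prior weight on the known hypothesis in [0,1]
#' @return an \linkS4class{EnergyModel}
#' @export
fitEnergyModel <- function(knownEnergies, unknownEnergies,
                           family = c("weibull", "gaussian"),
                           temperature = 1, minSamples = 20,
                           priorKnown = 0.5) {
  family <- match.arg(family)
  for (v in list(knownEnergies, unknownEnergies)) {
    if (length(v) < minSamples)
      stop("energy fit needs >= ", minSamples, " samples per group; got ",
           length(v), " -- fall back to scoring without relabeling")
    if (stats::sd(v) == 0)
      stop("degenerate zero-variance energy sample; cannot fit a density")
  }
  fit1 <- function(x) {
    if (family == "gaussian") c(mean = mean(x), sd = stats::sd(x))
    else fitShiftedWeibull(x)
  }
  new("EnergyModel", family = family,
      knownPar = fit1(knownEnergies), unknownPar = fit1(unknownEnergies),
      temperature = temperature, priorKnown = priorKnown,
      nKnown = length(knownEnergies), nUnknown = length(unknownEnergies))
}

setMethod("show", "EnergyModel", function(object) {
  cat(sprintf("EnergyModel (%s, T = %g, prior known = %g)\n", object@family,
              object@temperature, object@priorKnown))
  cat("  known  (n =", object@nKnown, "):",
      paste(names(object@knownPar), signif(object@knownPar, 4),
            sep = "=", collapse = " "), "\n")
  cat("  unknown(n =", object@nUnknown, "):",
      paste(names(object@unknownPar), signif(object@unknownPar, 4),
            sep = "=", collapse = " "), "\n")
})

#' Relabel over-confident known detections as unknown
#'
#' A detection with a known label is flipped to the \code{unknown} sentinel
#' iff its energy is more likely under the fitted unknown density than under
#' the known density (prior-weighted likelihood ratio; ties keep the known
#' label). Geometry and scores are preserved; labels only ever move
#' known -> unknown, never the reverse; detections without logits pass
#' through unchanged.
#'
#' @param detections detection data.frame with a \code{logits} list-column
#' @param model an \linkS4class{EnergyModel}
#' @return the detection data.frame with updated labels
#' @export
relabelUnknown <- function(detections, model) {
  if (NROW(detections) == 0L) return(detections)
  for (i in seq_len(nrow(detections))) {
    if (detections$label[i] == UNKNOWN_CLASS) next
    lg <- detections$logits[[i]]
    if (is.null(lg) || !length(lg)) next
    e <- energyScore(lg, model@temperature)
    lrKnown <- model@priorKnown * densityAt(model@knownPar, model@family, e)
    lrUnknown <- (1 - model@priorKnown) * densityAt(model@unknownPar, model@family, e)
    if (lrUnknown > lrKnown) detections$label[i] <- UNKNOWN_CLASS
  }
  detections
}

#' Serialize an energy model to JSON
#' @param model an \linkS4class{EnergyModel}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeEnergyModel <- function(model, path) {
  jsonlite::write_json(list(family = model@family,
                            known = as.list(model@knownPar),
                            unknown = as.list(model@unknownPar),
                            temperature = model@temperature,
                            priorKnown = model@priorKnown,
                            nKnown = model@nKnown, nUnknown = model@nUnknown),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an energy model from JSON
#' @param path path written by \code{\link{writeEnergyModel}}
#' @return an \linkS4class{EnergyModel}
#' @export
readEnergyModel <- function(path) {
  d <- jsonlite::fromJSON(path)
  new("EnergyModel", family = d$family,
      knownPar = unlist(d$known), unknownPar = unlist(d$unknown),
      temperature = d$temperature, priorKnown = d$priorKnown,
      nKnown = as.integer(d$nKnown), nUnknown = as.integer(d$nUnknown))
}
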