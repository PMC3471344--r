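#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @rdname accessors
#' @export
setGeneric("uBar", function(x) standardGeneric("uBar"))

#' @rdname accessors
#' @export
setGeneric("vBar", function(x) standardGeneric("vBar"))

#' @rdname accessors
#' @export
setGeneric("runCount", function(x) standardGeneric("runCount"))

#' @rdname accessors
#' @export
setGeneric("runRanges", function(x) standardGeneric("runRanges"))

#' @rdname accessors
#' @export
setGeneric("piDist", function(x) standardGeneric("piDist"))

#' @rdname accessors
#' @export
setGeneric("tauDist", function(x) standardGeneric("tauDist"))

#' @rdname accessors
#' @export
setGeneric("runLengthDist", function(x) standardGeneric("runLengthDist"))

#' Accessors
#'
#' \code{theta} returns the duplicate proportion; \code{uBar} and
#' \code{vBar} the mean single-copy and duplicate run lengths;
#' \code{runCount} the number of single-copy runs; \code{runRanges} the runs
#' as an \link[IRanges]{IRanges}; \code{piDist} the distribution of deletion
#' events per run; \code{tauDist} the proportion of r-event runs with
#' both-chromosome content; \code{runLengthDist} the empirical frequency of
#' single-copy run lengths.
#'
#' @param x a \linkS4class{GenomePair}, \linkS4class{RunStatistics} or
#'   \linkS4class{RecurrenceState}.
#' @return numeric scalar or vector; an IRanges for \code{runRanges}.
#' @name accessors
#' @aliases theta,GenomePair-method theta,RunStatistics-method
#'   theta,RecurrenceState-method uBar,RunStatistics-method
#'   uBar,RecurrenceState-method vBar,RunStatistics-method
#'   vBar,RecurrenceState-method runCount,RunStatistics-method
#'   runRanges,RunStatistics-method piDist,RunStatistics-method
#'   piDist,RecurrenceState-method tauDist,RunStatistics-method
#'   tauDist,RecurrenceState-method runLengthDist,RunStatistics-method
NULL

setMethod("theta", "GenomePair",
          function(x) mean(x@g + x@h == 2L))
setMethod("theta", "RunStatistics", function(x) x@theta)
setMethod("theta", "RecurrenceState", function(x) x@theta)
setMethod("uBar", "RunStatistics", function(x) x@uBar)
setMethod("uBar", "RecurrenceState", function(x) x@uBar)
setMethod("vBar", "RunStatistics", function(x) x@vBar)
setMethod("vBar", "RecurrenceState", function(x) x@vBar)
setMethod("runCount", "RunStatistics", function(x) x@runCount)
setMethod("runRanges", "RunStatistics", function(x) x@runs)
setMethod("piDist", "RunStatistics", function(x) x@piHat)
setMethod("piDist", "RecurrenceState", function(x) x@pi)
setMethod("tauDist", "RunStatistics", function(x) x@tauHat)
setMethod("tauDist", "RecurrenceState", function(x) x@tau)
setMethod("runLengthDist", "RunStatistics", function(x) {
  w <- IRanges::width(x@runs)
  if (length(w) == 0L) return(numeric(0))
  tabulate(w) / length(w)
})

setMethod("show", "GenomePair", function(object) {
  n <- length(object@g)
  cat(sprintf("GenomePair of length %d (positions %d..%d)\n",
              n, object@offset, object@offset + n - 1L))
  cat(sprintf("  theta = %.4f (%d duplicate, %d single-copy positions)\n",
              theta(object), sum(object@g + object@h == 2L),
              sum(object@g + object@h == 1L)))
})

setMethod("show", "DeletionModel", function(object) {
  cat(sprintf("DeletionModel: mu = %g, phi = %g\n", object@mu, object@phi))
})

setMethod("show", "RunStatistics", function(object) {
  cat(sprintf("RunStatistics: %d single-copy runs, theta = %.4f\n",
              object@runCount, object@theta))
  cat(sprintf("  uBar = %.4g, vBar = %.4g\n", object@uBar, object@vBar))
  if (length(object@piHat) && !anyNA(object@piHat)) {
    k <- min(5L, length(object@piHat))
    cat("  pi(1..", k, ") = ", paste(signif(object@piHat[seq_len(k)], 3),
                                     collapse = " "), "\n", sep = "")
  }
})

setMethod("show", "RecurrenceState", function(object) {
  cat(sprintf(
    "RecurrenceState: theta = %.4f, uBar = %.4g, vBar = %.4g, R = %.4g\n",
    object@theta, object@uBar, object@vBar, object@R))
})

setMethod("show", "EventRates", function(object) {
  cat("EventRates at theta-state (tau =", signif(object@tau, 3), "):\n")
  print(signif(object@p, 4))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s): muHat = %.3g, phiHat = %.3g\n",
              object@method, object@muHat, object@phiHat))
  if (!anyNA(object@ciMu))
    cat(sprintf("  mu 90%% CI [%.3g, %.3g]; phi 90%% CI [%.3g, %.3g]\n",
                object@ciMu[1], object@ciMu[2],
                object@ciPhi[1], object@ciPhi[2]))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport:", nrow(object@table), "checkpoints\n")
  cat("  max |recurrence - simulation| per event type:\n")
  print(signif(object@maxDeviation, 3))
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d checkpoints, %d events (mu = %g, phi = %g)\n",
              nrow(object@trajectory), object@eventsTotal,
              object@model@mu, object@model@phi))
})

setMethod("show", "RecurrenceResult", function(object) {
  cat(sprintf("RecurrenceResult: %d steps, theta %.3f -> %.3f\n",
              nrow(object@trajectory),
              object@trajectory$theta[1L], object@finalState@theta))
})
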