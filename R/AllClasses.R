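#' GenomePair: presence/absence of a duplicated gene complement
#'
#' A pair of binary sequences \code{g} and \code{h} over an interval of gene
#' positions, recording which copy of each post-WGD duplicate survives on
#' each homeologous chromosome. The defining constraint is
#' \code{g(i) + h(i) >= 1}: both copies of a gene are never deleted.
#' Per-position event logs record, for every deleted position, the
#' identifier of the deletion event responsible, which is how the number of
#' events \code{r} composing a single-copy run is tracked.
#'
#' Positions carry user-facing labels \code{offset, offset+1, ...} so that
#' worked examples indexed on negative coordinates can be
#' reproduced verbatim.
#'
#' @slot g,h integer vectors of 0/1, one element per gene position.
#' @slot eventG,eventH integer event identifiers (0 = position not deleted).
#' @slot offset integer label of the first position.
#' @export
setClass("GenomePair",
  representation(g = "integer", h = "integer",
                 eventG = "integer", eventH = "integer",
                 offset = "integer"))

setValidity("GenomePair", function(object) {
  n <- length(object@g)
  if (length(object@h) != n ||
      length(object@eventG) != n || length(object@eventH) != n)
    return("g, h and event logs must have equal length")
  if (length(object@offset) != 1L) return("offset must be a single integer")
  if (n == 0L) return("empty interval")
  if (!all(object@g %in% c(0L, 1L)) || !all(object@h %in% c(0L, 1L)))
    return("g and h must be binary")
  bad <- which(object@g + object@h < 1L)
  if (length(bad))
    return(sprintf("g(i) + h(i) >= 1 violated at position %d",
                   object@offset + bad[1L] - 1L))
  TRUE
})

#' DeletionModel: parameters of the excision process
#'
#' @slot mu mean of the geometric deletion-length distribution
#'   \eqn{\gamma(a) = (1/\mu)(1 - 1/\mu)^{a-1}}, \eqn{\mu \ge 1}.
#' @slot phi fractionation bias: probability that a deletion event falls on
#'   chromosome 1 (chromosome 2 receives \code{1 - phi}).
#' @export
setClass("DeletionModel",
  representation(mu = "numeric", phi = "numeric"))

setValidity("DeletionModel", function(object) {
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu < 1)
    return("mu must be a single number >= 1")
  if (length(object@phi) != 1L || !is.finite(object@phi) ||
      object@phi < 0 || object@phi > 1)
    return("phi must lie in [0, 1]")
  TRUE
})

#' DeletionEvent: one realized deletion
#'
#' @slot eventId integer identifier.
#' @slot chromosome 1 (sequence G) or 2 (sequence H).
#' @slot anchor anchor position (label coordinates).
#' @slot drawnLength the geometric draw \code{a}.
#' @slot deletedPositions positions actually converted 1 to 0 (labels).
#' @slot blocked TRUE if terminated by a deletion on the other homeolog.
#' @slot skippedCount positions skipped over (already 0 on the same homeolog).
#' @slot clipped TRUE if truncated by the right end of the interval.
#' @export
setClass("DeletionEvent",
  representation(eventId = "integer", chromosome = "integer",
                 anchor = "integer", drawnLength = "integer",
                 deletedPositions = "integer", blocked = "logical",
                 skippedCount = "integer", clipped = "logical"))

#' RunStatistics: consolidated run summary of a GenomePair
#'
#' Maximal segments where exactly one copy survives (single-copy runs)
#' alternate with segments where both survive (duplicate runs). This class
#' carries the runs themselves (as an \link[IRanges]{IRanges} with metadata
#' columns \code{r}, \code{both}, \code{sideLeft}, \code{sideRight}) and the
#' derived statistics: the duplicate proportion theta, the empirical
#' distribution pi(r) of deletion events per run, tau(r) (proportion of
#' r-event runs with deletions from both homeologs), and the mean
#' single-copy and duplicate run lengths uBar and vBar, which satisfy the
#' accounting identity vBar = theta/(1-theta) * uBar up to boundary-run
#' slack.
#'
#' @slot runs IRanges of single-copy runs (starts in label coordinates).
#' @slot dupRunLengths integer lengths of duplicate runs.
#' @slot theta proportion of positions retaining both copies.
#' @slot uBar,vBar mean single-copy / duplicate run lengths.
#' @slot runCount number of single-copy runs.
#' @slot piHat,tauHat empirical pi(r) and tau(r), indexed r = 1.. (NA when
#'   the input carried no event log).
#' @slot nDeletedG,nDeletedH single-copy positions deleted from G / from H.
#' @export
setClass("RunStatistics",
  representation(runs = "ANY", dupRunLengths = "integer",
                 theta = "numeric", uBar = "numeric", vBar = "numeric",
                 runCount = "integer", piHat = "numeric", tauHat = "numeric",
                 nDeletedG = "integer", nDeletedH = "integer"))

#' EventRates: event-type probabilities and mean-length contributions
#'
#' Probabilities that the next deletion event is of each type, given the
#' current recurrence state: A creates a new run; B extends the run to the
#' left of the anchor; C reaches the run to the right; D reaches over the
#' right-hand run and merges it with the next one; E touches the left run
#' and reaches the right run, merging the two. Subscripts i (event
#' chromosome) and f (chromosome content of the touched run(s)) follow the
#' two-homeolog labelling. \code{pOther} is the residual probability of
#' merging three or more runs, reported but never fed back into the
#' recurrence. muX are the corresponding contributions to the mean number of
#' genes deleted per event.
#'
#' @slot pA,pCii,pDiii,pEiii numeric length-2 (i = 1, 2).
#' @slot pB 2x2 matrix indexed (i, f).
#' @slot pCif,pDiif,pEiif,pEifi,pEiff numeric length-2, order (1,2), (2,1).
#' @slot p aggregate probabilities named A, B, C, D, E, other.
#' @slot muX prefactor-weighted mean-length contributions named A, B, Cii,
#'   Cif, Diii, Diif, Eiii, Eiif, Eifi, Eiff.
#' @slot tau,vBar,mu,phi the state at which the rates were evaluated.
#' @export
setClass("EventRates",
  representation(pA = "numeric", pB = "matrix", pCii = "numeric",
                 pCif = "numeric", pDiii = "numeric", pDiif = "numeric",
                 pEiii = "numeric", pEiif = "numeric", pEifi = "numeric",
                 pEiff = "numeric", p = "numeric", muX = "numeric",
                 tau = "numeric", vBar = "numeric", mu = "numeric",
                 phi = "numeric"))

#' RecurrenceState: the deterministic recurrence state
#'
#' @slot pi distribution of deletion events per run, r = 1..rMax.
#' @slot tau proportion of r-event runs with both-chromosome content.
#' @slot uBar,vBar mean single-copy / duplicate run lengths.
#' @slot theta duplicate proportion, always vBar / (uBar + vBar).
#' @slot R run count (real-valued normalization carrier).
#' @export
setClass("RecurrenceState",
  representation(pi = "numeric", tau = "numeric", uBar = "numeric",
                 vBar = "numeric", theta = "numeric", R = "numeric"))

setValidity("RecurrenceState", function(object) {
  if (length(object@pi) != length(object@tau))
    return("pi and tau must have the same length")
  if (object@R <= 0) return("R must be positive")
  if (object@uBar < 1 || object@vBar <= 0) return("invalid mean run lengths")
  TRUE
})

#' ObservedSample: observable run statistics for inference
#'
#' @slot runLengths lengths of the observed single-copy runs.
#' @slot theta observed duplicate proportion.
#' @slot deletedFrom1,deletedFrom2 counts of single-copy genes deleted from
#'   chromosome 1 / chromosome 2 (NA when chromosome sides are unknown).
#' @export
setClass("ObservedSample",
  representation(runLengths = "integer", theta = "numeric",
                 deletedFrom1 = "integer", deletedFrom2 = "integer"))

setValidity("ObservedSample", function(object) {
  if (length(object@runLengths) == 0L) return("no runs")
  if (any(object@runLengths < 1L)) return("run lengths must be >= 1")
  if (object@theta <= 0 || object@theta >= 1)
    return("theta must lie strictly between 0 and 1")
  c1 <- object@deletedFrom1; c2 <- object@deletedFrom2
  if (!is.na(c1) && !is.na(c2) &&
      c1 + c2 != sum(object@runLengths))
    return("deletedFrom1 + deletedFrom2 must equal the total run length")
  TRUE
})

#' FitResult: estimates of mu and phi with bootstrap intervals
#'
#' @slot muHat,phiHat point estimates (phiHat reported on [0.5, 1]).
#' @slot phiSide which chromosome the bias favours (1 or 2; NA if unknown).
#' @slot ciMu,ciPhi bootstrap percentile intervals (NA when bootstrap = 0).
#' @slot surface data.frame of the objective over the (mu, phi) grid.
#' @slot method,replicates,seed fit settings.
#' @export
setClass("FitResult",
  representation(muHat = "numeric", phiHat = "numeric", phiSide = "integer",
                 ciMu = "numeric", ciPhi = "numeric", surface = "data.frame",
                 method = "character", replicates = "integer",
                 seed = "ANY"))

#' ComparisonReport: recurrence vs simulation event-type trajectories
#'
#' @slot table per-checkpoint simulator means/SEs and recurrence values of
#'   each event-type proportion, aligned on 1 - theta.
#' @slot maxDeviation named maximum absolute deviations per event type.
#' @slot scenario the scenario parameters used.
#' @export
setClass("ComparisonReport",
  representation(table = "data.frame", maxDeviation = "numeric",
                 scenario = "list"))

#' SimulationResult: one simulated fractionation trajectory
#'
#' @slot trajectory per-checkpoint data.frame: theta, uBar, vBar, runCount,
#'   window event-type proportions.
#' @slot checkpointStats list of \linkS4class{RunStatistics}, one per
#'   checkpoint.
#' @slot pair the final \linkS4class{GenomePair} (NULL unless kept).
#' @slot model the \linkS4class{DeletionModel} used.
#' @slot saturated TRUE if the simulation ran out of duplicate positions.
#' @slot eventsTotal number of deletion events applied.
#' @export
setClass("SimulationResult",
  representation(trajectory = "data.frame", checkpointStats = "list",
                 pair = "ANY", model = "DeletionModel",
                 saturated = "logical", eventsTotal = "integer"))

#' RecurrenceResult: a recurrence trajectory
#'
#' @slot trajectory per-step data.frame: theta, uBar, vBar, R and the
#'   aggregate event-type probabilities.
#' @slot snapshots list of \linkS4class{RecurrenceState} at the requested
#'   checkpoints.
#' @slot finalState the last \linkS4class{RecurrenceState}.
#' @slot config the configuration used.
#' @export
setClass("RecurrenceResult",
  representation(trajectory = "data.frame", snapshots = "list",
                 finalState = "RecurrenceState", config = "list"))
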