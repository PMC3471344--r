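#' Create a GenomePair
#'
#' Either an all-duplicate interval of a given length, or a pair built from
#' explicit binary vectors. Event logs (needed to track how many deletion
#' events compose a run) start empty; they are filled in by
#' \code{\link{applyDeletion}} and the simulator.
#'
#' @param length number of gene positions (ignored when \code{g} is given).
#' @param g,h optional binary vectors of equal length.
#' @param offset label of the first position (default 0).
#' @param eventG,eventH optional per-position event identifiers
#'   (0 = not deleted).
#' @return a \linkS4class{GenomePair}.
#' @examples
#' gp <- GenomePair(16, offset = -7L)
#' theta(gp)
#' @export
GenomePair <- function(length = NULL, g = NULL, h = NULL, offset = 0L,
                       eventG = NULL, eventH = NULL) {
  if (is.null(g)) {
    stopifnot(is.numeric(length), length >= 1)
    n <- as.integer(length)
    g <- rep(1L, n); h <- rep(1L, n)
  } else {
    g <- as.integer(g); h <- as.integer(h)
    n <- base::length(g)
  }
  if (is.null(eventG)) eventG <- integer(n) else eventG <- as.integer(eventG)
  if (is.null(eventH)) eventH <- integer(n) else eventH <- as.integer(eventH)
  new("GenomePair", g = g, h = h, eventG = eventG, eventH = eventH,
      offset = as.integer(offset))
}

#' Extract consolidated single-copy runs and their statistics
#'
#' Consolidates the two homeologs: maximal segments where exactly one copy
#' survives become runs, each annotated with its length, the number
#' \code{r} of distinct deletion events that produced it (from the event
#' log), whether it contains deletions from both chromosomes, and the
#' chromosome of its leftmost/rightmost deleted term. Aggregate statistics
#' (theta, uBar, vBar, empirical pi and tau) are returned alongside.
#'
#' When the pair carries no event log (e.g. it was read from a
#' presence/absence table), \code{r} and the pi/tau histograms are NA.
#'
#' @param pair a \linkS4class{GenomePair}.
#' @return a \linkS4class{RunStatistics}.
#' @examples
#' res <- replayEvents(GenomePair(16, offset = -7L), table1Script())
#' extractRuns(res$pair)
#' @export
extractRuns <- function(pair) {
  stopifnot(is(pair, "GenomePair"))
  validObject(pair)
  st <- cpp_state_stats(pair@g, pair@h, pair@eventG, pair@eventH)
  hasLog <- any(pair@eventG > 0L | pair@eventH > 0L) ||
    all(pair@g == 1L & pair@h == 1L)
  nRuns <- length(st$run_start)
  r <- if (hasLog) st$run_r else rep(NA_integer_, nRuns)
  runs <- IRanges::IRanges(start = st$run_start + pair@offset,
                           width = st$run_length)
  S4Vectors::mcols(runs) <- S4Vectors::DataFrame(
    r = r, both = as.logical(st$run_both),
    sideLeft = st$side_left, sideRight = st$side_right)
  if (nRuns > 0L && hasLog) {
    piHat <- tabulate(st$run_r) / nRuns
    tauHat <- vapply(seq_along(piHat), function(rr) {
      sel <- st$run_r == rr
      if (any(sel)) mean(st$run_both[sel]) else 0
    }, numeric(1))
  } else if (nRuns > 0L) {
    piHat <- NA_real_; tauHat <- NA_real_
  } else {
    piHat <- numeric(0); tauHat <- numeric(0)
  }
  new("RunStatistics",
      runs = runs, dupRunLengths = as.integer(st$dup_run_lengths),
      theta = st$theta,
      uBar = if (nRuns) mean(st$run_length) else NA_real_,
      vBar = if (length(st$dup_run_lengths)) mean(st$dup_run_lengths)
             else NA_real_,
      runCount = nRuns, piHat = piHat, tauHat = tauHat,
      nDeletedG = st$n_deleted_g, nDeletedH = st$n_deleted_h)
}

#' Check the run-length accounting identity
#'
#' Alternation of single-copy and duplicate runs forces
#' \eqn{\bar v = \theta/(1-\theta)\,\bar u} on an infinite interval; on a
#' finite interval the deviation is bounded by the contribution of the (at
#' most two) boundary runs. Returns the residual
#' \eqn{\bar v - \theta/(1-\theta)\,\bar u}.
#'
#' @param stats a \linkS4class{RunStatistics}, or a list/object with
#'   elements theta, uBar, vBar.
#' @return the residual (numeric scalar).
#' @examples
#' verifyAccounting(list(theta = 0.9, uBar = 2, vBar = 18))  # 0
#' @export
verifyAccounting <- function(stats) {
  th <- if (is(stats, "RunStatistics")) stats@theta else stats$theta
  ub <- if (is(stats, "RunStatistics")) stats@uBar else stats$uBar
  vb <- if (is(stats, "RunStatistics")) stats@vBar else stats$vBar
  if (!is.finite(th) || th <= 0 || th >= 1)
    stop("theta must lie strictly between 0 and 1 (undefined ratio)")
  vb - th / (1 - th) * ub
}

#' Read / write presence-absence tables
#'
#' Tab-separated, with header columns \code{position}, \code{g}, \code{h}
#' (0/1). Positions must be contiguous; the smallest becomes the offset.
#'
#' @param file path to a TSV file.
#' @return \code{readPresenceAbsence}: a \linkS4class{GenomePair}.
#' @export
readPresenceAbsence <- function(file) {
  d <- read.delim(file, header = TRUE, sep = "\t")
  stopifnot(all(c("position", "g", "h") %in% names(d)))
  d <- d[order(d$position), ]
  if (!all(diff(d$position) == 1L))
    stop("positions must be contiguous")
  GenomePair(g = d$g, h = d$h, offset = min(d$position))
}

#' @rdname readPresenceAbsence
#' @param pair a \linkS4class{GenomePair} to write.
#' @export
writePresenceAbsence <- function(pair, file) {
  stopifnot(is(pair, "GenomePair"))
  d <- data.frame(position = pair@offset + seq_along(pair@g) - 1L,
                  g = pair@g, h = pair@h)
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write run statistics to TSV (+ optional JSON summary)
#'
#' The TSV has one row per single-copy run with columns \code{start},
#' \code{length}, \code{r}, \code{both_chromosomes}. The JSON summary holds
#' theta, uBar, vBar, the run count and the pi/tau histograms.
#'
#' @param stats a \linkS4class{RunStatistics}.
#' @param file output TSV path.
#' @param jsonFile optional output path for the JSON summary.
#' @export
writeRunStatistics <- function(stats, file, jsonFile = NULL) {
  stopifnot(is(stats, "RunStatistics"))
  mc <- S4Vectors::mcols(stats@runs)
  d <- data.frame(start = IRanges::start(stats@runs),
                  length = IRanges::width(stats@runs),
                  r = mc$r, both_chromosomes = mc$both)
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonFile)) {
    jsonlite::write_json(
      list(theta = stats@theta, u_bar = stats@uBar, v_bar = stats@vBar,
           run_count = stats@runCount, pi = stats@piHat,
           tau = stats@tauHat),
      jsonFile, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Build an ObservedSample from run statistics
#'
#' @param stats a \linkS4class{RunStatistics}.
#' @return an \linkS4class{ObservedSample} carrying the run lengths, theta
#'   and the per-homeolog counts of deleted genes.
#' @export
asObservedSample <- function(stats) {
  stopifnot(is(stats, "RunStatistics"))
  new("ObservedSample",
      runLengths = IRanges::width(stats@runs), theta = stats@theta,
      deletedFrom1 = stats@nDeletedG, deletedFrom2 = stats@nDeletedH)
}
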