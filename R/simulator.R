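#' Construct a DeletionModel
#'
#' @param mu mean deletion length, >= 1 (mu = 1 is the gene-by-gene limit).
#' @param phi fractionation bias in [0, 1]: probability a deletion falls on
#'   chromosome 1.
#' @return a \linkS4class{DeletionModel}.
#' @export
DeletionModel <- function(mu, phi = 0.5) {
  new("DeletionModel", mu = as.numeric(mu), phi = as.numeric(phi))
}

#' Draw deletion lengths from the geometric distribution
#'
#' Lengths follow \eqn{\gamma(a) = (1/\mu)(1-1/\mu)^{a-1}}, \eqn{a \ge 1},
#' with mean mu.
#'
#' @param model a \linkS4class{DeletionModel} (or a single numeric mu).
#' @param n number of draws.
#' @return integer vector of lengths >= 1.
#' @export
drawDeletionLength <- function(model, n = 1L) {
  mu <- if (is(model, "DeletionModel")) model@mu else as.numeric(model)
  if (!is.finite(mu) || mu < 1) stop("mu must be >= 1")
  rgeom(n, prob = 1 / mu) + 1L
}

#' Choose a deletion anchor uniformly among duplicate positions
#'
#' Anchors are positions where both copies survive (g = h = 1).
#'
#' @param pair a \linkS4class{GenomePair}.
#' @return a position in label coordinates.
#' @export
chooseAnchor <- function(pair) {
  stopifnot(is(pair, "GenomePair"))
  dup <- which(pair@g == 1L & pair@h == 1L)
  if (length(dup) == 0L)
    stop("saturated: no duplicate positions remain")
  idx <- if (length(dup) == 1L) dup else dup[sample.int(length(dup), 1L)]
  idx + pair@offset - 1L
}

#' Apply one deletion event
#'
#' Scans rightward from the anchor on the chosen chromosome: positions
#' already deleted on that chromosome are skipped without counting toward
#' the drawn length \code{a}; the first position whose copy on the other
#' chromosome is deleted blocks the event (nothing at or beyond it is
#' touched); otherwise positions are converted 1 to 0 until \code{a}
#' conversions or the end of the interval.
#'
#' @param pair a \linkS4class{GenomePair}.
#' @param chromosome 1/"G" or 2/"H".
#' @param anchor anchor position in label coordinates; must be a duplicate
#'   position.
#' @param a drawn deletion length (>= 1).
#' @param eventId identifier to log; defaults to max existing id + 1.
#' @return list with elements \code{pair} (the updated GenomePair) and
#'   \code{event} (a \linkS4class{DeletionEvent}).
#' @examples
#' gp <- GenomePair(10)
#' out <- applyDeletion(gp, "G", anchor = 3, a = 3)
#' out$event
#' @export
applyDeletion <- function(pair, chromosome, anchor, a, eventId = NULL) {
  stopifnot(is(pair, "GenomePair"))
  chrom <- normalizeChromosome(chromosome)
  a <- as.integer(a)
  if (a < 1) stop("a must be >= 1")
  idx0 <- as.integer(anchor) - pair@offset           # 0-based index
  if (idx0 < 0L || idx0 >= length(pair@g))
    stop("anchor outside the interval")
  if (pair@g[idx0 + 1L] != 1L || pair@h[idx0 + 1L] != 1L)
    stop(sprintf("anchor %d is not a duplicate position", anchor))
  if (is.null(eventId))
    eventId <- max(pair@eventG, pair@eventH) + 1L
  res <- cpp_apply_deletion(pair@g, pair@h, pair@eventG, pair@eventH,
                            chrom, idx0, a, as.integer(eventId))
  newPair <- new("GenomePair", g = res$g, h = res$h, eventG = res$eg,
                 eventH = res$eh, offset = pair@offset)
  ev <- new("DeletionEvent", eventId = as.integer(eventId),
            chromosome = chrom, anchor = as.integer(anchor),
            drawnLength = a,
            deletedPositions = as.integer(res$deleted + pair@offset),
            blocked = res$blocked, skippedCount = res$skipped,
            clipped = res$clipped)
  list(pair = newPair, event = ev)
}

normalizeChromosome <- function(chromosome) {
  if (is.character(chromosome)) {
    chrom <- match(toupper(chromosome), c("G", "H"))
    if (is.na(chrom)) stop("chromosome must be \"G\"/\"H\" or 1/2")
    return(as.integer(chrom))
  }
  chrom <- as.integer(chromosome)
  if (!chrom %in% c(1L, 2L)) stop("chromosome must be \"G\"/\"H\" or 1/2")
  chrom
}

#' Replay a scripted list of deletion events
#'
#' Deterministic harness: applies the scripted events in order and returns
#' the final pair, the realized events, and the consolidated run
#' statistics. Scripts are data.frames (or lists of lists) with fields
#' \code{chromosome}, \code{anchor}, \code{a}.
#'
#' @param pair the starting \linkS4class{GenomePair}.
#' @param script event script; see \code{\link{readEventScript}} and
#'   \code{\link{table1Script}}.
#' @return list(pair, events, stats).
#' @examples
#' res <- replayEvents(GenomePair(16, offset = -7L), table1Script())
#' runRanges(res$stats)
#' @export
replayEvents <- function(pair, script) {
  script <- as.data.frame(script)
  events <- vector("list", nrow(script))
  for (i in seq_len(nrow(script))) {
    out <- tryCatch(
      applyDeletion(pair, script$chromosome[i], script$anchor[i],
                    script$a[i], eventId = i),
      error = function(e)
        stop(sprintf("replay failed at event %d: %s", i, conditionMessage(e)),
             call. = FALSE))
    pair <- out$pair
    events[[i]] <- out$event
  }
  list(pair = pair, events = events, stats = extractRuns(pair))
}

#' Read / write event scripts
#'
#' JSON format: an object with an integer \code{offset}, an interval
#' \code{length}, and \code{events}, a list of objects
#' \code{{chromosome: "G"|"H", anchor: int, a: int}} with anchors in label
#' coordinates.
#'
#' @param file path to a JSON script.
#' @return \code{readEventScript}: a data.frame of events with attributes
#'   \code{offset} and \code{length}.
#' @export
readEventScript <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  ev <- as.data.frame(j$events)
  attr(ev, "offset") <- as.integer(j$offset)
  attr(ev, "length") <- as.integer(j$length)
  ev
}

#' @rdname readEventScript
#' @param script event script data.frame with attributes offset and length.
#' @export
writeEventScript <- function(script, file) {
  jsonlite::write_json(
    list(offset = attr(script, "offset"), length = attr(script, "length"),
         events = as.data.frame(script)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' The five-event worked example
#'
#' A compact worked example of skipping and blocking: five deletion
#' events on an interval labelled -7..8 whose final state consolidates into
#' two single-copy runs, one of length 7 built by 3 events (with deletions
#' from both homeologs, the last event blocked at position -1), one of
#' length 4 built by 2 events (G only, with one skip at position 5).
#'
#' @return the event script as a data.frame (attributes offset, length).
#' @export
table1Script <- function() {
  ev <- data.frame(
    chromosome = c("G", "H", "G", "G", "H"),
    anchor = c(-1L, -4L, 5L, 4L, -5L),
    a = c(3L, 1L, 1L, 3L, 4L))
  attr(ev, "offset") <- -7L
  attr(ev, "length") <- 16L
  ev
}

#' Simulate the fractionation process
#'
#' Discrete-time event loop on an interval of given length: each event
#' draws a chromosome (Bernoulli phi), an anchor (uniform among duplicate
#' positions) and a geometric length, then applies the skip/block deletion
#' scan. Run statistics and the tally of event types (A, B, C, D, E, other,
#' classified by how many pre-existing single-copy runs the event absorbed)
#' are recorded at each theta checkpoint; the simulation stops at
#' \code{stopTheta}.
#'
#' @param model a \linkS4class{DeletionModel}.
#' @param length interval size (>= 1000).
#' @param stopTheta target duplicate proportion in (0, 1).
#' @param checkpoints decreasing theta values at which statistics are
#'   recorded; \code{stopTheta} is always appended. Default: just
#'   \code{stopTheta}.
#' @param seed optional RNG seed (\code{set.seed}).
#' @param keepState keep the final \linkS4class{GenomePair} (memory: 4
#'   integer vectors of \code{length}).
#' @return a \linkS4class{SimulationResult}.
#' @examples
#' sim <- runSimulation(DeletionModel(2, 0.5), length = 5000,
#'                      stopTheta = 0.5, seed = 1)
#' sim@trajectory
#' @export
runSimulation <- function(model, length = 100000L, stopTheta = 0.5,
                          checkpoints = NULL, seed = NULL,
                          keepState = FALSE) {
  stopifnot(is(model, "DeletionModel"))
  validObject(model)
  length <- as.integer(length)
  if (length < 1000L) stop("interval length must be >= 1000")
  if (stopTheta <= 0 || stopTheta >= 1)
    stop("stopTheta must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  cps <- sort(unique(c(checkpoints, stopTheta)), decreasing = TRUE)
  if (any(cps >= 1) || any(cps < stopTheta))
    stop("checkpoints must lie in [stopTheta, 1)")
  raw <- cpp_simulate(length, model@mu, model@phi, stopTheta, cps,
                      keepState)
  recs <- raw$records[seq_len(raw$n_checkpoints_done)]
  traj <- do.call(rbind, lapply(recs, function(st) {
    we <- st$window_events
    tal <- c(A = st$tally_A, B = st$tally_B, C = st$tally_C,
             D = st$tally_D, E = st$tally_E, other = st$tally_other)
    props <- if (we > 0) tal / we else tal * NA_real_
    data.frame(checkpoint = st$checkpoint, theta = st$theta,
               uBar = if (length(st$run_length)) mean(st$run_length)
                      else NA_real_,
               vBar = if (length(st$dup_run_lengths))
                        mean(st$dup_run_lengths) else NA_real_,
               runCount = length(st$run_length),
               eventsTotal = st$events_total,
               windowEvents = we,
               pA = props[["A"]], pB = props[["B"]], pC = props[["C"]],
               pD = props[["D"]], pE = props[["E"]],
               pOther = props[["other"]])
  }))
  stats <- lapply(recs, statsFromRecord)
  pair <- NULL
  if (keepState)
    pair <- new("GenomePair", g = raw$g, h = raw$h, eventG = raw$eg,
                eventH = raw$eh, offset = 0L)
  if (raw$saturated)
    warning("simulation saturated before reaching stopTheta")
  new("SimulationResult", trajectory = traj, checkpointStats = stats,
      pair = pair, model = model, saturated = raw$saturated,
      eventsTotal = as.integer(raw$events_total))
}

# Build a RunStatistics from a C++ checkpoint record.
statsFromRecord <- function(st) {
  nRuns <- length(st$run_start)
  runs <- IRanges::IRanges(start = st$run_start, width = st$run_length)
  S4Vectors::mcols(runs) <- S4Vectors::DataFrame(
    r = st$run_r, both = as.logical(st$run_both),
    sideLeft = st$side_left, sideRight = st$side_right)
  if (nRuns > 0L) {
    piHat <- tabulate(st$run_r) / nRuns
    tauHat <- vapply(seq_along(piHat), function(rr) {
      sel <- st$run_r == rr
      if (any(sel)) mean(st$run_both[sel]) else 0
    }, numeric(1))
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
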