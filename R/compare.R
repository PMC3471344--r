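#' Compare the recurrence with stochastic simulation
#'
#' Runs \code{replicates} simulations and one recurrence trajectory at the
#' same (mu, phi), aligns them on 1 - theta, and reports the deviation of
#' the recurrence's event-type probabilities from the pooled simulated
#' event-type proportions. Simulated proportions are tallied in the windows
#' between consecutive checkpoints and attributed to the window midpoint;
#' the recurrence is interpolated linearly there.
#'
#' @param mu,phi deletion model parameters.
#' @param length interval size per replicate.
#' @param replicates number of simulation replicates.
#' @param oneMinusTheta increasing grid of deleted proportions delimiting
#'   the tally windows.
#' @param seed RNG seed for the simulations.
#' @param conservationMode,typos recurrence options (see
#'   \code{\link{runRecurrence}}).
#' @param flagOtherAbove flag checkpoints where the simulated proportion of
#'   unmodelled (3+ run) mergers exceeds this value.
#' @return a \linkS4class{ComparisonReport}. Its table has, per window:
#'   the simulator mean and standard error of each event-type proportion,
#'   the recurrence values, and the absolute deviations.
#' @export
compareRecurrenceToSimulation <- function(mu, phi, length = 100000L,
                                          replicates = 100L,
                                          oneMinusTheta = seq(0.05, 0.7,
                                                              by = 0.05),
                                          seed = 1L,
                                          conservationMode = "corrected",
                                          typos = "repaired",
                                          flagOtherAbove = 0.05) {
  oneMinusTheta <- sort(oneMinusTheta)
  cps <- 1 - oneMinusTheta
  stopTheta <- min(cps)
  types <- c("A", "B", "C", "D", "E", "other")
  counts <- matrix(0, nrow = length(cps), ncol = 6,
                   dimnames = list(NULL, types))
  events <- numeric(length(cps))
  set.seed(seed)
  model <- DeletionModel(mu, phi)
  for (rep in seq_len(replicates)) {
    sim <- runSimulation(model, length = length, stopTheta = stopTheta,
                         checkpoints = cps)
    tr <- sim@trajectory
    props <- as.matrix(tr[, c("pA", "pB", "pC", "pD", "pE", "pOther")])
    we <- tr$windowEvents
    props[is.na(props)] <- 0
    counts <- counts + props * we
    events <- events + we
  }
  simMean <- counts / pmax(events, 1)
  simSE <- sqrt(simMean * (1 - simMean) / pmax(events, 1))
  # window midpoints on the 1 - theta axis
  lower <- c(0, head(oneMinusTheta, -1))
  mids <- (lower + oneMinusTheta) / 2

  rec <- runRecurrence(mu, phi, thetaStop = stopTheta,
                       conservationMode = conservationMode, typos = typos)
  rtr <- rec@trajectory
  recAt <- function(col) approx(1 - rtr$theta, rtr[[col]], xout = mids,
                                rule = 2)$y
  recP <- cbind(A = recAt("pA"), B = recAt("pB"), C = recAt("pC"),
                D = recAt("pD"), E = recAt("pE"), other = recAt("pOther"))

  tab <- data.frame(oneMinusTheta = oneMinusTheta, mid = mids)
  for (t in types) {
    tab[[paste0("sim", t)]] <- simMean[, t]
    tab[[paste0("se", t)]] <- simSE[, t]
    tab[[paste0("rec", t)]] <- recP[, t]
    tab[[paste0("dev", t)]] <- abs(recP[, t] - simMean[, t])
  }
  tab$simBC <- tab$simB + tab$simC
  tab$recBC <- tab$recB + tab$recC
  tab$devBC <- abs(tab$recBC - tab$simBC)
  tab$simDE <- tab$simD + tab$simE
  tab$recDE <- tab$recD + tab$recE
  tab$devDE <- abs(tab$recDE - tab$simDE)
  tab$flagOther <- tab$simother > flagOtherAbove
  maxDev <- c(A = max(tab$devA), B = max(tab$devB), C = max(tab$devC),
              D = max(tab$devD), E = max(tab$devE),
              other = max(tab$devother),
              BC = max(tab$devBC), DE = max(tab$devDE))
  new("ComparisonReport", table = tab, maxDeviation = maxDev,
      scenario = list(mu = mu, phi = phi, length = length,
                      replicates = replicates, seed = seed,
                      conservationMode = conservationMode))
}

#' Write the bundled fixtures
#'
#' Writes the five-event worked-example script (\code{table1.json}) and
#' three scenario files covering (mu, phi) = (2, 0.5), (11, 0.5) and
#' (11, 1.0) with fixed seeds. Regeneration is byte-identical.
#'
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
generateFixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(outdir, "table1.json")
  writeEventScript(table1Script(), p)
  paths <- c(paths, p)
  scen <- list(list(name = "small-unbiased", mu = 2, phi = 0.5, seed = 101L),
               list(name = "large-unbiased", mu = 11, phi = 0.5,
                    seed = 102L),
               list(name = "large-biased", mu = 11, phi = 1.0, seed = 103L))
  for (s in scen) {
    sp <- file.path(outdir, paste0("scenario-", s$name, ".json"))
    writeScenario(c(s, list(length = 100000L, stopTheta = 0.3,
                            replicates = 100L)), sp)
    paths <- c(paths, sp)
  }
  invisible(paths)
}

#' Read / write scenario files
#'
#' JSON files holding a named list of simulation scenario parameters:
#' name, mu, phi, length, stopTheta, replicates, seed.
#'
#' @param file path to a scenario JSON file.
#' @return \code{readScenario}: the scenario as a named list.
#' @export
readScenario <- function(file) {
  s <- jsonlite::read_json(file, simplifyVector = TRUE)
  s$length <- as.integer(s$length)
  s$replicates <- as.integer(s$replicates)
  s$seed <- as.integer(s$seed)
  s
}

#' @rdname readScenario
#' @param scenario named list of scenario parameters.
#' @export
writeScenario <- function(scenario, file) {
  keep <- c("name", "mu", "phi", "length", "stopTheta", "replicates",
            "seed")
  jsonlite::write_json(scenario[intersect(keep, names(scenario))], file,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
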