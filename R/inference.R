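#' Construct an ObservedSample
#'
#' The observable quantities inference is based on: the lengths of the
#' single-copy runs, the overall duplicate proportion theta, and (when
#' chromosome sides are known) the counts of single-copy genes deleted from
#' each homeolog.
#'
#' @param runLengths integer run lengths.
#' @param theta duplicate proportion in (0, 1).
#' @param deletedFrom1,deletedFrom2 counts of single-copy genes deleted
#'   from chromosome 1 / 2 (NA when unknown).
#' @return an \linkS4class{ObservedSample}.
#' @export
ObservedSample <- function(runLengths, theta, deletedFrom1 = NA_integer_,
                           deletedFrom2 = NA_integer_) {
  new("ObservedSample", runLengths = as.integer(runLengths),
      theta = as.numeric(theta),
      deletedFrom1 = as.integer(deletedFrom1),
      deletedFrom2 = as.integer(deletedFrom2))
}

#' Direct estimator of the fractionation bias
#'
#' phi is estimated from the proportion of single-copy genes deleted from
#' each homeolog. Since the data cannot distinguish (phi, 1 - phi) without
#' a chromosome-labelling convention, the estimate is reported on [0.5, 1]
#' together with the dominant chromosome.
#'
#' @param sample an \linkS4class{ObservedSample} with known sides, or a
#'   \linkS4class{RunStatistics}.
#' @return list(phiHat, side): the estimate and the chromosome (1 or 2)
#'   deletions favour.
#' @export
estimatePhiDirect <- function(sample) {
  if (is(sample, "RunStatistics")) sample <- asObservedSample(sample)
  stopifnot(is(sample, "ObservedSample"))
  c1 <- sample@deletedFrom1; c2 <- sample@deletedFrom2
  if (is.na(c1) || is.na(c2))
    stop("chromosome sides are unknown; cannot estimate phi directly")
  if (c1 + c2 == 0L) stop("no single-copy genes: no signal for phi")
  list(phiHat = max(c1, c2) / (c1 + c2),
       side = if (c1 >= c2) 1L else 2L)
}

#' Forward-model grid of run-length distributions
#'
#' Simulates the fractionation process at each (mu, phi) grid point down to
#' the target theta, pooling \code{replicates} interval replicates, and
#' stores the pooled run-length histogram and mean run length. The grid is
#' the forward model for \code{\link{fitMuPhi}}; building it once and
#' passing it to several fits amortizes the simulation cost.
#'
#' @param theta target duplicate proportion at which the model is matched.
#' @param muGrid,phiGrid grid values.
#' @param length interval size per replicate.
#' @param replicates simulation replicates pooled per grid point.
#' @param seed RNG seed.
#' @param maxLen histogram bound (longer runs pooled into the last bin).
#' @return an object of class \code{fractorunGrid}.
#' @export
buildModelGrid <- function(theta, muGrid = c(2, 3, 4, 6, 8, 11),
                           phiGrid = seq(0.5, 1, by = 0.1),
                           length = 100000L, replicates = 5L, seed = 1L,
                           maxLen = 200L) {
  set.seed(seed)
  cells <- expand.grid(mu = muGrid, phi = phiGrid)
  hists <- vector("list", nrow(cells))
  means <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    lens <- integer(0)
    for (rep in seq_len(replicates)) {
      sim <- runSimulation(DeletionModel(cells$mu[i], cells$phi[i]),
                           length = length, stopTheta = theta)
      st <- sim@checkpointStats[[base::length(sim@checkpointStats)]]
      lens <- c(lens, IRanges::width(st@runs))
    }
    means[i] <- mean(lens)
    hists[[i]] <- tabulate(pmin(lens, maxLen), nbins = maxLen)
  }
  structure(list(cells = cells, hists = hists, means = means,
                 muGrid = sort(unique(muGrid)),
                 phiGrid = sort(unique(phiGrid)),
                 theta = theta, length = length, replicates = replicates,
                 maxLen = maxLen, seed = seed),
            class = "fractorunGrid")
}

# chi-square distance between an observed histogram and model proportions,
# on bins pooled so that every model bin holds at least minP mass.
chisqDistance <- function(obsCounts, modCounts, minExp = 5) {
  modP <- modCounts / sum(modCounts)
  n <- sum(obsCounts)
  # pool the upper tail where model expected counts fall below minExp
  dense <- which(modP * n >= minExp)
  cut <- if (length(dense)) min(max(dense) + 1L, length(modP)) else 2L
  if (cut < 2L) cut <- 2L
  ob <- c(obsCounts[seq_len(cut - 1)], sum(obsCounts[cut:length(obsCounts)]))
  mp <- c(modP[seq_len(cut - 1)], sum(modP[cut:length(modP)]))
  sel <- mp > 0
  sum((ob[sel] / n - mp[sel])^2 / mp[sel])
}

# interpolate model summaries at an off-grid phi (linear between columns)
gridAtPhi <- function(grid, phi) {
  pg <- grid$phiGrid
  phi <- min(max(phi, min(pg)), max(pg))
  j <- findInterval(phi, pg, all.inside = TRUE)
  w <- if (pg[j + 1] > pg[j]) (phi - pg[j]) / (pg[j + 1] - pg[j]) else 0
  lapply(grid$muGrid, function(m) {
    i1 <- which(grid$cells$mu == m & grid$cells$phi == pg[j])
    i2 <- which(grid$cells$mu == m & grid$cells$phi == pg[j + 1])
    list(mu = m,
         hist = (1 - w) * grid$hists[[i1]] + w * grid$hists[[i2]],
         mean = (1 - w) * grid$means[i1] + w * grid$means[i2])
  })
}

# mean-curve inversion: the model mean run length is strictly increasing
# in mu at fixed (phi, theta), so the estimate is read off by monotone
# interpolation of log(mu) against the model means
invertMeanCurve <- function(muGrid, modelMeans, obsMean) {
  o <- order(modelMeans)
  exp(approx(modelMeans[o], log(muGrid)[o], xout = obsMean, rule = 2)$y)
}

# parabolic refinement of the objective minimum on the log-mu axis
refineMu <- function(muGrid, obj) {
  i <- which.min(obj)
  if (i == 1L || i == length(muGrid)) return(muGrid[i])
  x <- log(muGrid[(i - 1):(i + 1)])
  y <- obj[(i - 1):(i + 1)]
  denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
  a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
          x[1] * (y[3] - y[2])) / denom
  b <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
          x[1]^2 * (y[2] - y[3])) / denom
  if (a <= 0) return(muGrid[i])
  xm <- -b / (2 * a)
  xm <- min(max(xm, x[1]), x[3])
  exp(xm)
}

#' Estimate mu and phi from observed run statistics
#'
#' The forward model is the stochastic simulator evaluated over a (mu, phi)
#' grid at the observed theta. With \code{method = "distribution"} the
#' objective is a chi-square distance between the observed run-length
#' histogram and the model histogram; with \code{method = "mean_curve"} it
#' matches the observed mean run length. When the sample carries the
#' per-homeolog split of single-copy genes, phi is estimated directly from
#' that split and mu is fitted conditional on it (interpolating the model
#' between the neighbouring phi columns); otherwise (mu, phi) are fitted
#' jointly over the grid. The grid minimum is refined by a parabola on the
#' log-mu axis. Bootstrap intervals resample runs with replacement (theta
#' held fixed) and re-fit against the same grid.
#'
#' @param sample an \linkS4class{ObservedSample} or
#'   \linkS4class{RunStatistics}.
#' @param method "distribution" or "mean_curve".
#' @param grid optional prebuilt \code{\link{buildModelGrid}} object; built
#'   on the fly (at the observed theta) when absent.
#' @param bootstrap number of bootstrap resamples (0 = no intervals).
#' @param level confidence level for the percentile intervals.
#' @param seed RNG seed (grid building and bootstrap).
#' @param ... passed to \code{\link{buildModelGrid}} when building.
#' @return a \linkS4class{FitResult}.
#' @export
fitMuPhi <- function(sample, method = c("distribution", "mean_curve"),
                     grid = NULL, bootstrap = 0L, level = 0.9,
                     seed = 1L, ...) {
  method <- match.arg(method)
  if (is(sample, "RunStatistics")) sample <- asObservedSample(sample)
  stopifnot(is(sample, "ObservedSample"))
  validObject(sample)
  set.seed(seed)
  if (is.null(grid))
    grid <- buildModelGrid(theta = sample@theta, seed = seed, ...)
  if (abs(grid$theta - sample@theta) > 0.05)
    stop("observed theta is outside the model grid coverage")
  lens <- sample@runLengths
  obsHist <- tabulate(pmin(lens, grid$maxLen), nbins = grid$maxLen)

  haveSides <- !is.na(sample@deletedFrom1) && !is.na(sample@deletedFrom2)
  if (haveSides) {
    direct <- estimatePhiDirect(sample)
    phiHat <- direct$phiHat
    phiSide <- direct$side
    cols <- gridAtPhi(grid, phiHat)
    obj <- objectiveOverMu(cols, obsHist, mean(lens), method)
    muHat <- estimateMu(grid$muGrid, cols, obsHist, mean(lens), method)
    surface <- data.frame(mu = grid$muGrid, phi = phiHat, objective = obj)
  } else {
    surf <- lapply(grid$phiGrid, function(ph) {
      cols <- gridAtPhi(grid, ph)
      data.frame(mu = grid$muGrid, phi = ph,
                 objective = objectiveOverMu(cols, obsHist, mean(lens),
                                             method))
    })
    surface <- do.call(rbind, surf)
    best <- surface[which.min(surface$objective), ]
    phiHat <- best$phi
    phiSide <- NA_integer_
    cols <- gridAtPhi(grid, phiHat)
    obj <- objectiveOverMu(cols, obsHist, mean(lens), method)
    muHat <- estimateMu(grid$muGrid, cols, obsHist, mean(lens), method)
  }
  if (max(obj) - min(obj) < 1e-12)
    warning("objective surface is flat; mu is unidentifiable here")

  ciMu <- c(NA_real_, NA_real_); ciPhi <- c(NA_real_, NA_real_)
  if (bootstrap > 0L) {
    nRuns <- length(lens)
    cTot <- if (haveSides) sample@deletedFrom1 + sample@deletedFrom2 else NA
    muB <- numeric(bootstrap); phiB <- numeric(bootstrap)
    for (b in seq_len(bootstrap)) {
      bl <- lens[sample.int(nRuns, nRuns, replace = TRUE)]
      bh <- tabulate(pmin(bl, grid$maxLen), nbins = grid$maxLen)
      muB[b] <- estimateMu(grid$muGrid, cols, bh, mean(bl), method)
      phiB[b] <- if (haveSides) {
        c1 <- rbinom(1L, cTot, max(sample@deletedFrom1,
                                   sample@deletedFrom2) / cTot)
        max(c1, cTot - c1) / cTot
      } else phiHat
    }
    alpha <- (1 - level) / 2
    ciMu <- unname(quantile(muB, c(alpha, 1 - alpha)))
    ciPhi <- unname(quantile(phiB, c(alpha, 1 - alpha)))
  }
  new("FitResult", muHat = muHat, phiHat = phiHat, phiSide = phiSide,
      ciMu = ciMu, ciPhi = ciPhi, surface = surface, method = method,
      replicates = as.integer(grid$replicates), seed = seed)
}

objectiveOverMu <- function(cols, obsHist, obsMean, method) {
  vapply(cols, function(cell) {
    if (method == "distribution") chisqDistance(obsHist, cell$hist)
    else (obsMean - cell$mean)^2
  }, numeric(1))
}

# point estimate of mu given the model columns at the working phi:
# chi-square minimum refined by a log-mu parabola for "distribution",
# direct inversion of the monotone mean curve for "mean_curve"
estimateMu <- function(muGrid, cols, obsHist, obsMean, method) {
  if (method == "mean_curve") {
    means <- vapply(cols, `[[`, numeric(1), "mean")
    invertMeanCurve(muGrid, means, obsMean)
  } else {
    refineMu(muGrid, objectiveOverMu(cols, obsHist, obsMean, method))
  }
}
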