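#' Goodness-of-fit tests used to validate the model's distributional claims
#'
#' \code{geometricGofTest} tests whether positive integer lengths follow a
#' geometric distribution with unknown mean (estimated by the sample mean):
#' a chi-square test on bins pooled so every expected count is at least
#' \code{minExp}, with one degree of freedom charged for the estimated
#' parameter. Used to check the modelling assumption that duplicate-run
#' lengths are geometric.
#'
#' \code{ksGeometricTest} is a one-sample Kolmogorov-Smirnov test against a
#' geometric distribution with \emph{known} mean; since the distribution is
#' discrete, the null distribution of the statistic is obtained by Monte
#' Carlo. Used to check that at theta near 1 single-copy run lengths are
#' indistinguishable from the deletion-length distribution gamma.
#'
#' \code{convolutionGofTest} tests run lengths of r-event runs against the
#' convolution of r independent geometric draws (a shifted negative
#' binomial): the distribution the run lengths would follow if the
#' per-event lengths composing a run were independent. The model predicts
#' rejection: events with large deletions cluster into the same runs.
#'
#' @param x positive integer lengths.
#' @param minExp minimum expected count per chi-square bin.
#' @return a list with statistic, df (where applicable) and p.value.
#' @export
geometricGofTest <- function(x, minExp = 5) {
  stopifnot(length(x) > 1, all(x >= 1))
  vb <- mean(x)
  if (vb <= 1) return(list(statistic = 0, df = 0L, p.value = 1))
  p <- 1 / vb
  n <- length(x)
  mx <- max(x)
  probs <- c(p * (1 - p)^(0:(mx - 1)))
  probs <- c(probs, max(1 - sum(probs), 0))          # lengths 1..mx, > mx
  obs <- c(tabulate(x, nbins = mx), 0)
  res <- pooledChisq(obs, probs * n, dfLost = 2L, minExp = minExp)
  res
}

#' @rdname geometricGofTest
#' @param mu known mean of the geometric null distribution.
#' @param nsim Monte Carlo replicates for the null distribution.
#' @export
ksGeometricTest <- function(x, mu, nsim = 500L) {
  stopifnot(all(x >= 1), mu >= 1)
  n <- length(x)
  p <- 1 / mu
  ksStat <- function(v) {
    mx <- max(v)
    emp <- cumsum(tabulate(v, nbins = mx)) / length(v)
    thr <- 1 - (1 - p)^(seq_len(mx))
    max(abs(emp - thr))
  }
  d0 <- ksStat(x)
  dNull <- vapply(seq_len(nsim), function(i)
    ksStat(rgeom(n, p) + 1L), numeric(1))
  list(statistic = d0,
       p.value = (1 + sum(dNull >= d0)) / (nsim + 1))
}

#' @rdname geometricGofTest
#' @param r number of deletion events per run under test.
#' @export
convolutionGofTest <- function(x, r, mu, minExp = 5) {
  stopifnot(all(x >= r), mu > 1, r >= 1)
  p <- 1 / mu
  n <- length(x)
  mx <- max(x)
  l <- seq_len(mx)
  probs <- ifelse(l >= r, choose(l - 1, r - 1) * p^r * (1 - p)^(l - r), 0)
  probs <- c(probs, max(1 - sum(probs), 0))
  obs <- c(tabulate(x, nbins = mx), 0)
  pooledChisq(obs, probs * n, dfLost = 1L, minExp = minExp)
}

# chi-square with tail pooling; dfLost = 1 (fixed null) or 2 (one
# estimated parameter)
pooledChisq <- function(obs, expd, dfLost, minExp) {
  keep <- expd >= minExp
  if (!any(keep)) stop("too few observations for a chi-square test")
  cut <- max(which(keep))
  if (cut >= length(expd)) cut <- length(expd) - 1L
  if (cut < 1L) cut <- 1L
  obs2 <- c(obs[seq_len(cut)], sum(obs[-seq_len(cut)]))
  exp2 <- c(expd[seq_len(cut)], sum(expd[-seq_len(cut)]))
  sel <- exp2 > 0
  X2 <- sum((obs2[sel] - exp2[sel])^2 / exp2[sel])
  df <- max(sum(sel) - dfLost, 1L)
  list(statistic = X2, df = df,
       p.value = pchisq(X2, df, lower.tail = FALSE))
}
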