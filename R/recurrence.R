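#' Truncated geometric distribution of duplicate-run lengths
#'
#' The lengths of duplicate (undeleted) runs are modelled as geometric with
#' mean \code{vBar}; the recurrence evaluates it on a finite support
#' \code{1..lMax} chosen so the truncated tail mass is below
#' \code{tailEpsilon}, and renormalizes.
#'
#' @param vBar mean duplicate-run length (>= 1).
#' @param tailEpsilon tail mass below which the support is truncated.
#' @param lMax optional explicit support bound (overrides tailEpsilon).
#' @param renormalize renormalize to sum 1 over the truncated support.
#' @return list(rho, ERho, lMax): the probabilities, their mean, and the
#'   support bound.
#' @examples
#' geometricRho(4)$rho[1:2]  # 0.25, 0.1875 (up to renormalization)
#' @export
geometricRho <- function(vBar, tailEpsilon = 1e-10, lMax = NULL,
                         renormalize = TRUE) {
  if (!is.finite(vBar) || vBar < 1) stop("vBar must be >= 1")
  if (vBar == 1) {
    rho <- if (is.null(lMax)) 1 else c(1, numeric(lMax - 1L))
    return(list(rho = rho, ERho = 1, lMax = length(rho)))
  }
  s <- 1 - 1 / vBar
  if (is.null(lMax))
    lMax <- max(2L, as.integer(ceiling(log(tailEpsilon) / log(s))))
  l <- seq_len(lMax)
  rho <- (1 / vBar) * s^(l - 1)
  if (renormalize) rho <- rho / sum(rho)
  list(rho = rho, ERho = sum(l * rho), lMax = lMax)
}

# Partial sums of the geometric deletion-length distribution gamma:
# P0(x) = sum_{a<=x} gamma(a), P1(x) = sum a*gamma, P2(x) = sum a^2*gamma,
# clamped beyond xMax where the remaining mass is negligible. Tails
# sum_{a>=x} gamma(a) = q^(x-1) are always taken in closed form.
gammaPartials <- function(mu, tailEpsilon) {
  q <- 1 - 1 / mu
  xMax <- if (q == 0) 4L else
    max(8L, as.integer(ceiling(3 * log(tailEpsilon) / log(q))) + 8L)
  a <- seq_len(xMax)
  gam <- (1 / mu) * q^(a - 1)
  P1c <- cumsum(a * gam)
  P2c <- cumsum(a^2 * gam)
  list(q = q, xMax = xMax,
       P0 = function(x) 1 - q^pmax(x, 0),
       P1 = function(x) ifelse(x <= 0, 0, P1c[pmin(pmax(x, 1), xMax)]),
       P2 = function(x) ifelse(x <= 0, 0, P2c[pmin(pmax(x, 1), xMax)]))
}

#' Event-type probabilities and mean-length contributions
#'
#' Evaluates, at a recurrence state summarized by (tau, vBar), the
#' probabilities that the next deletion event is of type A, B, C, D or E
#' (with all chromosome-subscripted variants) and the corresponding
#' contributions to the mean number of genes deleted per event. The scalar
#' \code{tau} entering the rate prefactors is the overall proportion of
#' single-copy runs with content from both homeologs.
#'
#' Three evaluation methods are provided. \code{"separable"} (default, used
#' by the recurrence) collapses the anchor-position and length summations
#' analytically using the closed-form geometric tails, leaving sums that
#' factor over the run-length distribution; it is exact up to the stated
#' truncations. \code{"collected"} and \code{"naive"} implement the
#' collected-term and fully nested (as-printed) forms of the rate formulas for
#' types A, C-same-chromosome and D-same-chromosome on an explicitly
#' truncated support; they exist as mutual cross-checks and only fill those
#' three families.
#'
#' @param mu,phi deletion model parameters.
#' @param tau scalar both-chromosome proportion at the current state.
#' @param vBar mean duplicate-run length at the current state.
#' @param tailEpsilon truncation tolerance for the gamma and rho tails.
#' @param method "separable", "collected" or "naive".
#' @param lMax explicit rho support bound (used by the cross-check methods).
#' @return an \linkS4class{EventRates}.
#' @export
computeRates <- function(mu, phi, tau, vBar, tailEpsilon = 1e-10,
                         method = c("separable", "collected", "naive"),
                         lMax = NULL) {
  method <- match.arg(method)
  if (mu < 1) stop("mu must be >= 1")
  if (phi < 0 || phi > 1) stop("phi must lie in [0, 1]")
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  if (method != "separable")
    return(ratesTruncatedForms(mu, phi, tau, vBar, method,
                               lMax = if (is.null(lMax)) 12L else lMax,
                               tailEpsilon = tailEpsilon))

  rr <- geometricRho(vBar, tailEpsilon, lMax = lMax)
  rho <- rr$rho; ERho <- rr$ERho; L <- rr$lMax
  gp <- gammaPartials(mu, tailEpsilon)
  q <- gp$q; P0 <- gp$P0; P1 <- gp$P1; P2 <- gp$P2

  lv <- seq_len(L)
  # tail sums of rho: Rt[x] = sum_{l >= x} rho(l), RtF clamps outside 1..L
  Rt <- rev(cumsum(rev(rho)))
  RtF <- function(x) ifelse(x <= 1, 1, ifelse(x > L, 0, Rt[pmax(x, 1)]))

  # grid for distances m = l - j (anchor to end of run) where gamma decays
  M <- if (q == 0) 4L else
    max(8L, as.integer(ceiling(log(tailEpsilon) / log(q))) + 8L)
  mg <- 0:M
  RtM <- RtF(mg + 2L)                    # sum_{l >= m+2} rho(l)

  qlm1 <- q^(lv - 1)                     # q^(l-1)
  Sl0 <- sum(rho[-1] * (1 - qlm1[-1]))   # sum_{l>=2} rho (1 - q^(l-1))
  Sk0 <- sum(rho * (1 - q^lv))           # sum_k rho (1 - q^k)
  Skq <- sum(rho * q^lv)                 # sum_k rho q^k
  Slq1 <- sum(rho * qlm1)                # sum_l rho q^(l-1)
  one_q <- if (q == 0) 1 else 1 - q

  # --- type A: new run strictly inside an undeleted run
  lA <- lv[lv >= 3]
  bA <- sum(rho[lA] * ((lA - 1) * P0(lA - 2) - P1(lA - 2))) / ERho
  mA <- sum(rho[lA] * ((lA - 1) * P1(lA - 2) - P2(lA - 2))) / ERho

  # --- type B: touches only the run on the left (anchor at j = 1)
  lB <- lv[lv >= 2]
  bB <- sum(rho[lB] * P0(lB - 1)) / ERho
  mB <- sum(rho[lB] * P1(lB - 1)) / ERho

  # --- type C, right-hand run entirely on the event's chromosome:
  # skips through it into the next undeleted run (length k)
  bCii <- Sl0 * Sk0 / (one_q * ERho)
  # mean-length contribution: sum_m sum_k rho(k) [P1(m+k)-P1(m)] Rt(m+2)
  W1 <- outer(mg, seq_len(min(M, L)),
              function(m, k) P1(m + k) - P1(m))
  Vk <- as.numeric(crossprod(RtM, W1))          # sum over m for each k
  Vinf <- sum((mu - P1(mg)) * RtM)              # k beyond the m-grid
  mCii <- (sum(rho[seq_len(min(M, L))] * Vk) + RtF(M + 1L) * Vinf) / ERho

  # --- type C, right-hand run with other-chromosome content: blocked there
  bCif <- Sl0 / (one_q * ERho)
  mCif <- sum((mg + 1) * q^mg * RtM) / ERho

  # --- type D: skips through the right-hand run and reaches the one beyond
  bDiii <- Skq * Sk0 * Sl0 / (one_q * ERho)
  bDiif <- Skq * Sl0 / (one_q * ERho)
  # C(n) = sum_{k<=n} rho(k) Rt(n-k+2): run-length convolution for n = m+k
  Ncap <- 2L * M + 2L
  ng <- seq_len(Ncap)
  Cn <- vapply(ng, function(n) {
    k <- seq_len(min(n, L))
    sum(rho[k] * RtF(n - k + 2L))
  }, numeric(1))
  W1n <- outer(seq_len(M), seq_len(min(M, L)),
               function(n, k) P1(n + k) - P1(n))
  mDiii <- (sum(rho[seq_len(min(M, L))] *
                  as.numeric(crossprod(Cn[seq_len(M)], W1n))) +
            RtF(M + 1L) * sum((mu - P1(seq_len(M))) * Cn[seq_len(M)])) / ERho
  mDiif <- sum((ng + 1) * q^ng * Cn) / ERho

  # --- type E: touches the left run (j = 1) and reaches the right run
  bEiii <- Slq1 * Sk0 / ERho
  lM <- lv[lv <= M + 1L]
  WE <- outer(lM - 1L, seq_len(min(M, L)),
              function(l1, k) P1(l1 + k) - P1(l1))
  mEiii <- (sum(rho[lM] * (as.numeric(WE %*% rho[seq_len(min(M, L))]) +
                             RtF(M + 1L) * (mu - P1(lM - 1L))))) / ERho
  bEiif <- Slq1 / ERho
  mEiif <- sum(rho * lv * qlm1) / ERho
  bEifi <- bEiii; mEifi <- mEiii
  bEiff <- bEiif; mEiff <- mEiif

  assembleRates(mu, phi, tau, vBar, bA, mA, bB, mB, bCii, mCii, bCif, mCif,
                bDiii, mDiii, bDiif, mDiif, bEiii, mEiii, bEiif, mEiif,
                bEifi, mEifi, bEiff, mEiff)
}

# Apply the chromosome prefactors and build the EventRates object from the
# base integrals (which exclude all phi and tau factors except where noted).
assembleRates <- function(mu, phi, tau, vBar, bA, mA, bB, mB, bCii, mCii,
                          bCif, mCif, bDiii, mDiii, bDiif, mDiif,
                          bEiii, mEiii, bEiif, mEiif, bEifi, mEifi,
                          bEiff, mEiff) {
  f1 <- phi; f2 <- 1 - phi
  s2 <- f1^2 + f2^2; s3 <- f1^3 + f2^3; x12 <- f1 * f2
  pA <- c(f1, f2) * bA
  pB <- outer(c(f1, f2), c(f1, f2)) * bB
  pCii <- c(f1^2, f2^2) * (1 - tau) * bCii
  pCif <- c(f1 * tau + f1 * f2 * (1 - tau),
            f2 * tau + f2 * f1 * (1 - tau)) * bCif
  pDiii <- c(f1^3, f2^3) * (1 - tau)^2 * bDiii
  pDiif <- c(f1^2 * (1 - tau) * tau + f1^2 * f2 * (1 - tau)^2,
             f2^2 * (1 - tau) * tau + f2^2 * f1 * (1 - tau)^2) * bDiif
  pEiii <- c(f1^3, f2^3) * (1 - tau) * bEiii
  pEiif <- c(f1^2 * tau + f1^2 * f2 * (1 - tau),
             f2^2 * tau + f2^2 * f1 * (1 - tau)) * bEiif
  pEifi <- c(f1^2 * f2, f2^2 * f1) * (1 - tau) * bEifi
  pEiff <- c(f1 * f2 * tau + f1 * f2^2 * (1 - tau),
             f2 * f1 * tau + f2 * f1^2 * (1 - tau)) * bEiff
  agg <- c(A = sum(pA), B = sum(pB),
           C = sum(pCii) + sum(pCif),
           D = sum(pDiii) + sum(pDiif),
           E = sum(pEiii) + sum(pEiif) + sum(pEifi) + sum(pEiff))
  agg <- c(agg, other = max(0, 1 - sum(agg)))
  muX <- c(A = mA, B = mB,
           Cii = s2 * (1 - tau) * mCii,
           Cif = (tau + 2 * x12 * (1 - tau)) * mCif,
           Diii = s3 * (1 - tau)^2 * mDiii,
           Diif = (s2 * (1 - tau) * tau + x12 * (1 - tau)^2) * mDiif,
           Eiii = s3 * (1 - tau) * mEiii,
           Eiif = (s2 * tau + x12 * (1 - tau)) * mEiif,
           Eifi = x12 * (1 - tau) * mEifi,
           Eiff = (2 * x12 * tau + x12 * (1 - tau)) * mEiff)
  dimnames(pB) <- list(i = c("1", "2"), f = c("1", "2"))
  new("EventRates", pA = setNames(pA, c("1", "2")), pB = pB,
      pCii = setNames(pCii, c("1", "2")),
      pCif = setNames(pCif, c("12", "21")),
      pDiii = setNames(pDiii, c("1", "2")),
      pDiif = setNames(pDiif, c("12", "21")),
      pEiii = setNames(pEiii, c("1", "2")),
      pEiif = setNames(pEiif, c("12", "21")),
      pEifi = setNames(pEifi, c("12", "21")),
      pEiff = setNames(pEiff, c("12", "21")),
      p = agg, muX = muX, tau = tau, vBar = vBar, mu = mu, phi = phi)
}

# Collected-term and naive nested-sum forms of the A, C-same and D-same
# probabilities on an explicitly truncated support (cross-check methods).
# Other families are evaluated with the separable forms restricted to the
# same support so that the returned object is complete.
ratesTruncatedForms <- function(mu, phi, tau, vBar, method, lMax,
                                tailEpsilon) {
  q <- 1 - 1 / mu
  gam <- function(a) ifelse(a >= 1, (1 / mu) * q^(a - 1), 0)
  rr <- geometricRho(vBar, tailEpsilon, lMax = lMax)
  rho <- rr$rho; ERho <- rr$ERho; L <- rr$lMax
  gsum <- function(from, to) {      # sum of gamma over an integer range
    if (to < from) return(0)
    sum(gam(seq(from, to)))
  }
  gsumW <- function(from, to, w) {  # weighted by a function of a
    if (to < from) return(0)
    a <- seq(from, to)
    sum(w(a) * gam(a))
  }

  if (method == "naive") {
    bA <- 0
    for (l in seq_len(L)[-(1:2)])
      for (j in 2:(l - 1))
        bA <- bA + rho[l] * gsum(1, l - j)
    bCii <- 0
    for (l in seq_len(L)[-1])
      for (k in seq_len(L))
        for (j in 2:l)
          bCii <- bCii + rho[l] * rho[k] * gsum(l - j + 1, l - j + k)
    bDiii <- 0
    for (l in seq_len(L)[-1])
      for (k in seq_len(L))
        for (h in seq_len(L))
          for (j in 2:l)
            bDiii <- bDiii +
              rho[l] * rho[k] * rho[h] * gsum(l - j + k + 1, l - j + k + h)
  } else {  # collected
    bA <- 0
    for (l in seq_len(L)[-(1:2)])
      bA <- bA + rho[l] * gsumW(1, l - 2, function(a) l - a - 1)
    bCii <- 0
    for (l in seq_len(L)[-1])
      for (k in seq_len(L)) {
        lo <- min(l - 1, k); hi <- max(l - 1, k)
        bCii <- bCii + rho[l] * rho[k] *
          (gsumW(1, min(l - 2, k - 1), function(a) a) +
           gsumW(lo, hi, function(a) rep(lo, length(a))) +
           gsumW(max(l, k + 1), l + k - 2, function(a) l + k - a - 1))
      }
    bDiii <- 0
    for (l in seq_len(L)[-1])
      for (k in seq_len(L))
        for (h in seq_len(L)) {
          lo <- min(l + k - 1, k + h); hi <- max(l + k - 1, k + h)
          cm <- min(l - 1, h)
          bDiii <- bDiii + rho[l] * rho[k] * rho[h] *
            (gsumW(k + 1, min(l + k - 2, h + k - 1), function(a) a - k) +
             gsumW(lo, hi, function(a) rep(cm, length(a))) +
             gsumW(max(l + k, k + h + 1), l + k + h - 2,
                   function(a) l + k + h - a - 1))
        }
  }
  bA <- bA / ERho; bCii <- bCii / ERho; bDiii <- bDiii / ERho

  # remaining families via the separable forms on the same support
  sep <- computeRates(mu, phi, tau, vBar, tailEpsilon,
                      method = "separable", lMax = L)
  f1 <- phi; f2 <- 1 - phi
  pA <- c(f1, f2) * bA
  pCii <- c(f1^2, f2^2) * (1 - tau) * bCii
  pDiii <- c(f1^3, f2^3) * (1 - tau)^2 * bDiii
  out <- sep
  out@pA <- setNames(pA, c("1", "2"))
  out@pCii <- setNames(pCii, c("1", "2"))
  out@pDiii <- setNames(pDiii, c("1", "2"))
  agg <- c(A = sum(pA), B = sum(out@pB),
           C = sum(pCii) + sum(out@pCif),
           D = sum(pDiii) + sum(out@pDiif),
           E = sum(out@pEiii) + sum(out@pEiif) + sum(out@pEifi) +
             sum(out@pEiff))
  out@p <- c(agg, other = max(0, 1 - sum(agg)))
  out
}

#' Per-event change in the run-count distribution pi(r)
#'
#' A-type events create runs with r = 1; B/C events promote a run from
#' r - 1 to r; D/E events merge runs of s and r - s - 1 events into one of
#' r. In \code{conservationMode = "corrected"} (default) the merger gain
#' carries coefficient (pD + pE), so that the total change in run count is
#' pA - (pD + pE), one net run lost per merger; \code{"as_printed"} keeps
#' the as-printed coefficient 2(pD + pE) on the gain term.
#'
#' @param rates an \linkS4class{EventRates}.
#' @param pi current pi vector (sums to 1).
#' @param conservationMode "corrected" or "as_printed".
#' @return delta-pi vector of the same length.
#' @export
deltaPi <- function(rates, pi,
                    conservationMode = c("corrected", "as_printed")) {
  conservationMode <- match.arg(conservationMode)
  p <- rates@p
  pBC <- p[["B"]] + p[["C"]]
  pDE <- p[["D"]] + p[["E"]]
  gain <- if (conservationMode == "corrected") pDE else 2 * pDE
  loss <- pBC + 2 * pDE
  rMax <- length(pi)
  d <- numeric(rMax)
  conv <- convolveSelf(pi)
  d[1] <- p[["A"]] - loss * pi[1]
  if (rMax >= 2) {
    r <- 2:rMax
    d[r] <- pBC * pi[r - 1] + gain * conv[r] - loss * pi[r]
  }
  d
}

# conv[r] = sum_{s=1}^{r-2} pi(s) pi(r-s-1); zero for r <= 2.
# convolve(x, rev(y), "open")[k] = sum_{s+u=k+1} x(s) y(u), so index r - 2.
convolveSelf <- function(pi) convolvePair(pi, pi)

convolvePair <- function(x, y) {
  rMax <- length(x)
  out <- numeric(rMax)
  if (rMax >= 3) {
    full <- convolve(x, rev(y), type = "open")
    out[3:rMax] <- full[(3:rMax) - 2]
  }
  out
}

#' Per-event change in the both-chromosome run counts
#'
#' tau(r) tracks the proportion of r-event runs containing deletions from
#' both homeologs. Runs become mixed through cross-chromosome B/C
#' extensions and through most mergers; delta-tau(1) = 0 always, since a
#' one-event run lies on a single chromosome.
#'
#' Two misprints in the as-printed update system are repaired by default (\code{typos =
#' "repaired"}): the duplicated term "pB12 + pB12" is read as pB12 + pB21,
#' and the factor "(1 - r(r-1))" as (1 - tau(r-1)). \code{typos =
#' "as_printed"} implements the printed expressions literally, for audit.
#'
#' @param rates an \linkS4class{EventRates}.
#' @param pi,tau current distributions.
#' @param conservationMode as in \code{\link{deltaPi}}.
#' @param typos "repaired" or "as_printed".
#' @return delta-tau vector (changes in both-chromosome run counts per
#'   event, not yet divided by run counts).
#' @export
deltaTau <- function(rates, pi, tau,
                     conservationMode = c("corrected", "as_printed"),
                     typos = c("repaired", "as_printed")) {
  conservationMode <- match.arg(conservationMode)
  typos <- match.arg(typos)
  p <- rates@p
  pBC <- p[["B"]] + p[["C"]]
  pDE <- p[["D"]] + p[["E"]]
  gain <- if (conservationMode == "corrected") pDE else 2 * pDE
  loss <- pBC + 2 * pDE
  f1 <- rates@phi; f2 <- 1 - rates@phi
  cross <- if (typos == "repaired")
    rates@pB["1", "2"] + rates@pB["2", "1"] + sum(rates@pCif)
  else
    2 * rates@pB["1", "2"] + sum(rates@pCif)
  rMax <- length(pi)
  d <- numeric(rMax)
  if (rMax < 2) return(d)
  r <- 2:rMax
  tprev <- if (typos == "repaired") tau[r - 1] else {
    tp <- r * (r - 1)   # the printed, dimensionally inconsistent factor
    tp[r == 2] <- 0     # the printed r = 2 equation carries no such factor
    tp
  }
  # mergers: mixed unless both runs and the event share one chromosome
  sameChrom <- f1^3 + f2^3
  convAll <- convolveSelf(pi)
  A <- pi * (1 - tau)
  convSame <- convolvePair(A, A)
  mixedConv <- convAll - sameChrom * convSame
  d[r] <- pBC * pi[r - 1] * tau[r - 1] +
    cross * pi[r - 1] * (1 - tprev) +
    gain * mixedConv[r] -
    loss * tau[r] * pi[r]
  d[1] <- 0
  d
}

#' Advance the recurrence state by one macro-step
#'
#' Applies Lambda times the per-event changes: updates the run count R, the
#' pi and tau distributions, the mean run lengths uBar/vBar and theta. The
#' total gene count R (uBar + vBar) is conserved exactly by construction,
#' and theta' = vBar' / (uBar' + vBar').
#'
#' @param state a \linkS4class{RecurrenceState}.
#' @param rates the \linkS4class{EventRates} at that state.
#' @param dPi,dTau per-event changes from \code{\link{deltaPi}} and
#'   \code{\link{deltaTau}}.
#' @param lambda macro-step size (number of events applied).
#' @param conservationMode as in \code{\link{deltaPi}} (used for the
#'   analytic total run-count change, which is robust to truncation).
#' @return the advanced \linkS4class{RecurrenceState}.
#' @export
advanceState <- function(state, rates, dPi, dTau, lambda,
                         conservationMode = c("corrected", "as_printed")) {
  conservationMode <- match.arg(conservationMode)
  if (lambda <= 0) stop("lambda must be positive")
  p <- rates@p
  pDE <- p[["D"]] + p[["E"]]
  sumDPi <- if (conservationMode == "corrected") p[["A"]] - pDE
            else p[["A"]]
  R <- state@R
  Rn <- R + lambda * sumDPi
  if (Rn <= 0)
    stop("run count would become non-positive; use a smaller lambda")
  piCounts <- R * state@pi + lambda * dPi   # unnormalized run counts
  piCounts[piCounts < 0] <- 0
  piNew <- piCounts / sum(piCounts)
  muTotal <- sum(rates@muX)
  uNew <- (R * state@uBar + lambda * muTotal) / Rn
  vNew <- (R / Rn) * (state@uBar + state@vBar) - uNew
  if (vNew <= 0 || uNew < 1)
    stop("mean run lengths left their domain; use a smaller lambda")
  Tn <- R * state@pi * state@tau + lambda * dTau
  tauNew <- ifelse(piCounts > 0, pmin(pmax(Tn / pmax(piCounts, 1e-300), 0),
                                      1), 0)
  tauNew[1] <- 0
  new("RecurrenceState", pi = piNew, tau = tauNew, uBar = uNew,
      vBar = vNew, theta = vNew / (uNew + vNew), R = Rn)
}

#' Run the deterministic recurrence for pi(r)
#'
#' Iterates compute-rates / delta / advance from an initial state near
#' theta = 1 down to \code{thetaStop}. The recurrence cannot start at
#' theta = 1 (there are no runs); it is initialized at \code{thetaStart}
#' with pi = (1, 0, ...), tau = 0, uBar = mu (the regime where essentially
#' every event is of type A) and vBar from the accounting identity. The
#' run-count carrier R starts at 1 and cancels from every reported
#' proportion.
#'
#' @param mu,phi deletion model parameters.
#' @param thetaStop stop when theta falls to this value.
#' @param thetaStart initial duplicate proportion (default 0.99).
#' @param lambda macro-step size: "auto" (default) targets a relative
#'   change in R of at most 1 percent per step, or a fixed number of events.
#' @param tailEpsilon truncation tolerance for the gamma and rho tails.
#' @param conservationMode "corrected" (default) or "as_printed"; see
#'   \code{\link{deltaPi}}.
#' @param typos "repaired" (default) or "as_printed"; see
#'   \code{\link{deltaTau}}.
#' @param checkpoints optional decreasing theta values at which full states
#'   are snapshotted.
#' @param rMax initial truncation of the pi support (grown on demand).
#' @param maxSteps safety bound on the number of macro-steps.
#' @return a \linkS4class{RecurrenceResult}.
#' @examples
#' rec <- runRecurrence(2, 0.5, thetaStop = 0.8)
#' tail(rec@trajectory, 2)
#' @export
runRecurrence <- function(mu, phi, thetaStop, thetaStart = 0.99,
                          lambda = "auto", tailEpsilon = 1e-10,
                          conservationMode = c("corrected", "as_printed"),
                          typos = c("repaired", "as_printed"),
                          checkpoints = NULL, rMax = 100L,
                          maxSteps = 200000L) {
  conservationMode <- match.arg(conservationMode)
  typos <- match.arg(typos)
  if (thetaStop <= 0 || thetaStop >= thetaStart || thetaStart >= 1)
    stop("need 0 < thetaStop < thetaStart < 1")
  pi0 <- c(1, numeric(rMax - 1L))
  state <- new("RecurrenceState", pi = pi0, tau = numeric(rMax),
               uBar = mu, vBar = thetaStart / (1 - thetaStart) * mu,
               theta = thetaStart, R = 1)
  cps <- sort(unique(checkpoints), decreasing = TRUE)
  cps <- cps[cps <= thetaStart & cps >= thetaStop]
  snapshots <- list()
  cpIdx <- 1L
  rows <- vector("list", 2048L)
  nRow <- 0L
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > maxSteps) stop("recurrence did not reach thetaStop")
    tauTot <- sum(state@tau * state@pi)
    rates <- computeRates(mu, phi, tauTot, state@vBar, tailEpsilon)
    dPi <- deltaPi(rates, state@pi, conservationMode)
    dTau <- deltaTau(rates, state@pi, state@tau, conservationMode, typos)
    p <- rates@p
    sumDPi <- if (conservationMode == "corrected")
      p[["A"]] - p[["D"]] - p[["E"]] else p[["A"]]
    lam <- if (identical(lambda, "auto")) {
      act <- max(abs(sumDPi),
                 0.5 * (p[["A"]] + p[["B"]] + p[["C"]] +
                          2 * (p[["D"]] + p[["E"]])))
      0.01 * state@R / max(act, 1e-12)
    } else as.numeric(lambda)
    nRow <- nRow + 1L
    if (nRow > length(rows)) rows <- c(rows, vector("list", length(rows)))
    rows[[nRow]] <- data.frame(
      step = step, theta = state@theta, uBar = state@uBar,
      vBar = state@vBar, R = state@R, tauTotal = tauTot,
      pA = p[["A"]], pB = p[["B"]], pC = p[["C"]], pD = p[["D"]],
      pE = p[["E"]], pOther = p[["other"]], lambda = lam)
    newState <- advanceState(state, rates, dPi, dTau, lam,
                             conservationMode)
    if (newState@theta >= state@theta)
      stop("theta is non-monotone; use a smaller lambda")
    # grow the pi support if mass accumulates near the truncation bound
    nr <- length(newState@pi)
    if (newState@pi[nr] > 1e-9 && nr < 4000L) {
      grow <- numeric(nr)
      newState@pi <- c(newState@pi, grow)
      newState@tau <- c(newState@tau, grow)
    }
    while (cpIdx <= length(cps) && newState@theta <= cps[cpIdx]) {
      snapshots[[as.character(cps[cpIdx])]] <- newState
      cpIdx <- cpIdx + 1L
    }
    state <- newState
    if (state@theta <= thetaStop) break
  }
  traj <- do.call(rbind, rows[seq_len(nRow)])
  new("RecurrenceResult", trajectory = traj, snapshots = snapshots,
      finalState = state,
      config = list(mu = mu, phi = phi, thetaStart = thetaStart,
                    thetaStop = thetaStop, lambda = lambda,
                    tailEpsilon = tailEpsilon,
                    conservationMode = conservationMode, typos = typos))
}
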