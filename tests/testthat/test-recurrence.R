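test_that("the duplicate-run length distribution rho is geometric", {
  expect_equal(geometricRho(1)$rho, 1)
  r4 <- geometricRho(4, renormalize = FALSE)
  expect_equal(r4$rho[1:2], c(0.25, 0.1875))
  for (vb in c(1.5, 4, 30, 500)) {
    r <- geometricRho(vb, tailEpsilon = 1e-10)
    expect_equal(sum(r$rho), 1)
    expect_lt(abs(r$ERho - vb), 1e-10 * r$lMax + 1e-8)
  }
  expect_error(geometricRho(0.8), "vBar")
})

test_that("collected-term rate forms equal the naive nested sums", {
  for (mu in c(1.5, 2, 6, 11)) for (vb in c(2, 5, 9)) {
    col <- computeRates(mu, 0.6, 0.2, vb, method = "collected", lMax = 12L)
    nai <- computeRates(mu, 0.6, 0.2, vb, method = "naive", lMax = 12L)
    expect_lt(max(abs(col@pA - nai@pA)), 1e-12)
    expect_lt(max(abs(col@pCii - nai@pCii)), 1e-12)
    expect_lt(max(abs(col@pDiii - nai@pDiii)), 1e-12)
    sep <- computeRates(mu, 0.6, 0.2, vb, method = "separable", lMax = 12L)
    expect_lt(max(abs(sep@pA - nai@pA)), 1e-9)
    expect_lt(max(abs(sep@pCii - nai@pCii)), 1e-9)
    expect_lt(max(abs(sep@pDiii - nai@pDiii)), 1e-9)
  }
})

test_that("rates vanish and symmetrize as the chromosome labels demand", {
  # phi = 1: everything multiplied by phi2 vanishes
  r <- computeRates(4, 1, 0.3, 10)
  expect_equal(r@pA[["2"]], 0)
  expect_equal(unname(r@pB["1", "2"]), 0)
  expect_equal(unname(r@pB["2", "1"]), 0)
  expect_equal(unname(r@pB["2", "2"]), 0)
  expect_equal(r@pCii[["2"]], 0)
  expect_equal(r@pCif[["21"]], 0)
  expect_equal(r@pDiii[["2"]], 0)
  expect_equal(r@pEifi, c("12" = 0, "21" = 0))
  # the tau channel of pCif survives phi = 1 (blocked by mixed runs)
  expect_gt(r@pCif[["12"]], 0)
  # tau = 0, phi = 0.5: symmetry under chromosome relabelling
  s <- computeRates(4, 0.5, 0, 10)
  expect_equal(s@pCii[["1"]], s@pCii[["2"]])
  expect_equal(s@pCif[["12"]], s@pCif[["21"]])
  expect_equal(unname(s@pB["1", "2"]), unname(s@pB["2", "1"]))
  expect_equal(s@pA[["1"]], s@pA[["2"]])
  # probabilities are non-negative and close to 1
  expect_true(all(r@p >= 0))
  expect_equal(sum(s@p), 1, tolerance = 1e-9)
})

# minimal EventRates with prescribed aggregates, for the delta algebra
mkRates <- function(pA = 0, pB = 0, pC = 0, pD = 0, pE = 0, phi = 0.5,
                    pB12 = pB / 4, pB21 = pB / 4, pCif = c(0, 0)) {
  pBm <- matrix(c(pB / 2 - pB12, pB21, pB12, pB / 2 - pB21), 2, 2,
                dimnames = list(i = c("1", "2"), f = c("1", "2")))
  new("EventRates", pA = c("1" = pA / 2, "2" = pA / 2), pB = pBm,
      pCii = c("1" = 0, "2" = 0), pCif = setNames(pCif, c("12", "21")),
      pDiii = c("1" = pD / 2, "2" = pD / 2),
      pDiif = c("12" = 0, "21" = 0),
      pEiii = c("1" = pE / 2, "2" = pE / 2),
      pEiif = c("12" = 0, "21" = 0), pEifi = c("12" = 0, "21" = 0),
      pEiff = c("12" = 0, "21" = 0),
      p = c(A = pA, B = pB, C = pC, D = pD, E = pE,
            other = max(0, 1 - pA - pB - pC - pD - pE)),
      muX = c(A = 0, B = 0, Cii = 0, Cif = 0, Diii = 0, Diif = 0,
              Eiii = 0, Eiif = 0, Eifi = 0, Eiff = 0),
      tau = 0, vBar = 10, mu = 2, phi = phi)
}

test_that("delta-pi follows the birth/extension/merger accounting", {
  pi0 <- c(1, numeric(9))
  r <- mkRates(pA = 0.6, pB = 0.1, pC = 0.2)
  d <- deltaPi(r, pi0)
  expect_equal(d[1], 0.6 - 0.3)
  expect_equal(d[2], 0.3)
  expect_true(all(d[3:10] == 0))
  expect_equal(deltaPi(mkRates(), pi0), numeric(10))
  # total run-count change: pA - (pD + pE) corrected, pA as printed
  set.seed(8)
  pi1 <- c(prop.table(runif(12)), numeric(40))   # support well inside rMax
  r2 <- mkRates(pA = 0.3, pB = 0.1, pC = 0.2, pD = 0.05, pE = 0.15)
  expect_equal(sum(deltaPi(r2, pi1, "corrected")), 0.3 - 0.2,
               tolerance = 1e-12)
  expect_equal(sum(deltaPi(r2, pi1, "as_printed")), 0.3, tolerance = 1e-12)
})

test_that("delta-tau creates mixed runs only through cross-chromosome paths", {
  pi0 <- c(1, numeric(9))
  tau0 <- numeric(10)
  # phi = 1 and tau = 0: no cross rates, mergers all same-chromosome
  r1 <- mkRates(pA = 0.5, pB = 0.2, pC = 0.1, pD = 0.1, pE = 0.1, phi = 1,
                pB12 = 0, pB21 = 0)
  expect_equal(deltaTau(r1, pi0, tau0), numeric(10))
  expect_equal(deltaTau(r1, pi0, tau0)[1], 0)
  # symmetric state: delta-tau(2) = (pB12 + pB21 + pC12 + pC21) pi(1)
  r2 <- mkRates(pA = 0.5, pB = 0.2, pC = 0.2, phi = 0.5,
                pB12 = 0.05, pB21 = 0.05, pCif = c(0.08, 0.08))
  d <- deltaTau(r2, pi0, tau0)
  expect_equal(d[2], (0.05 + 0.05 + 0.08 + 0.08) * 1)
  expect_equal(d[1], 0)
})

test_that("advancing conserves genes and fixes the accounting identity", {
  st <- new("RecurrenceState", pi = c(0.6, 0.3, 0.1, 0), tau = numeric(4),
            uBar = 2.5, vBar = 10, theta = 0.8, R = 5)
  r <- computeRates(2, 0.5, 0, 10)
  dP <- deltaPi(r, st@pi)
  dT <- deltaTau(r, st@pi, st@tau)
  st2 <- advanceState(st, r, dP, dT, lambda = 0.05)
  expect_equal(st2@R * (st2@uBar + st2@vBar), st@R * (st@uBar + st@vBar),
               tolerance = 1e-12)
  expect_equal(st2@theta, st2@vBar / (st2@uBar + st2@vBar))
  expect_equal(st2@vBar, st2@theta / (1 - st2@theta) * st2@uBar,
               tolerance = 1e-10)
  expect_equal(sum(st2@pi), 1)
  expect_equal(st2@tau[1], 0)
  # zero deltas leave the state at a fixed point (R included)
  zero <- mkRates()
  st3 <- advanceState(st, zero, numeric(4), numeric(4), lambda = 1)
  expect_equal(st3@R, st@R)
  expect_equal(st3@pi, st@pi)
  expect_equal(st3@uBar, st@uBar)
})

test_that("the recurrence trajectory is sane and conservative", {
  rec <- runRecurrence(2, 0.5, thetaStop = 0.5, checkpoints = c(0.9, 0.6))
  tr <- rec@trajectory
  expect_true(all(diff(tr$theta) < 0))
  # pA decreases monotonically as deletion proceeds
  expect_true(all(diff(tr$pA) < 1e-12))
  # probability closure at every step
  tot <- tr$pA + tr$pB + tr$pC + tr$pD + tr$pE + tr$pOther
  expect_true(all(abs(tot - 1) < 1e-8))
  # total gene count R (uBar + vBar) conserved to relative 1e-10
  genes <- tr$R * (tr$uBar + tr$vBar)
  expect_lt(diff(range(genes)) / genes[1], 1e-10)
  # near theta = 1, pi(1) is essentially 1 and pi is non-increasing
  early <- rec@snapshots[["0.9"]]
  expect_gt(piDist(early)[1], 0.8)
  expect_true(all(diff(piDist(early)[1:10]) <= 1e-12))
  expect_equal(sum(piDist(early)), 1)
  expect_equal(tauDist(early)[1], 0)
})

test_that("biased large-deletion fractionation delays mergers", {
  recBig <- runRecurrence(11, 1, thetaStop = 0.55)
  recSmall <- runRecurrence(2, 0.5, thetaStop = 0.55)
  atX <- function(rec, x) {
    tr <- rec@trajectory
    approx(1 - tr$theta, tr$pD + tr$pE, xout = x, rule = 2)$y
  }
  # the ordering emerges once enough runs exist to merge; very early both
  # proportions are near zero, so compare where growth is under way
  for (x in c(0.3, 0.35, 0.4, 0.45))
    expect_lt(atX(recBig, x), atX(recSmall, x))
})

test_that("invalid recurrence configurations fail loudly", {
  expect_error(runRecurrence(2, 0.5, thetaStop = 0.999), "thetaStop")
  expect_error(computeRates(0.5, 0.5, 0, 5), "mu")
  expect_error(computeRates(2, 0.5, 1.2, 5), "tau")
  st <- new("RecurrenceState", pi = 1, tau = 0, uBar = 2, vBar = 8,
            theta = 0.8, R = 0.01)
  r <- mkRates(pA = 0, pB = 0, pC = 0, pD = 0.5, pE = 0.5)
  expect_error(advanceState(st, r, deltaPi(r, 1), 0, lambda = 1),
               "smaller lambda")
})
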