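test_that("the direct phi estimator reads the per-homeolog split", {
  s <- ObservedSample(runLengths = rep(1L, 1000), theta = 0.5,
                      deletedFrom1 = 500L, deletedFrom2 = 500L)
  expect_equal(estimatePhiDirect(s)$phiHat, 0.5)
  s2 <- ObservedSample(runLengths = rep(2L, 500), theta = 0.5,
                       deletedFrom1 = 1000L, deletedFrom2 = 0L)
  d2 <- estimatePhiDirect(s2)
  expect_equal(d2$phiHat, 1.0)
  expect_equal(d2$side, 1L)
  expect_error(
    estimatePhiDirect(ObservedSample(1L, 0.5, NA, NA)), "unknown")
})

test_that("the direct phi estimator recovers a known bias", {
  phis <- vapply(1:20, function(s) {
    st <- simFinalStats(6, 0.75, length = 30000L, stopTheta = 0.5,
                        seed = 500 + s)
    estimatePhiDirect(st)$phiHat
  }, numeric(1))
  expect_lt(abs(mean(phis) - 0.75), 0.02)
})

test_that("relabelling the chromosomes leaves the estimates invariant", {
  st <- simFinalStats(4, 0.8, length = 30000L, stopTheta = 0.5, seed = 42)
  s <- asObservedSample(st)
  sSwap <- ObservedSample(s@runLengths, s@theta,
                          deletedFrom1 = s@deletedFrom2,
                          deletedFrom2 = s@deletedFrom1)
  grid <- buildModelGrid(theta = theta(st), muGrid = c(2, 4, 8),
                         phiGrid = c(0.5, 0.75, 1), length = 10000L,
                         replicates = 2L, seed = 2)
  f1 <- fitMuPhi(s, grid = grid, seed = 3)
  f2 <- fitMuPhi(sSwap, grid = grid, seed = 3)
  expect_equal(f1@muHat, f2@muHat)
  expect_equal(f1@phiHat, f2@phiHat)
  expect_true(f1@phiHat >= 0.5 && f1@phiHat <= 1)
  expect_equal(f1@phiSide + f2@phiSide, 3L)  # sides swap, 1 <-> 2
})

test_that("model mean run length increases with mu at fixed phi and theta", {
  grid <- buildModelGrid(theta = 0.5, muGrid = c(2, 3, 4, 6, 8, 11),
                         phiGrid = c(0.5, 1), length = 20000L,
                         replicates = 3L, seed = 7)
  for (ph in c(0.5, 1)) {
    sel <- grid$cells$phi == ph
    m <- grid$means[sel][order(grid$cells$mu[sel])]
    expect_true(all(diff(m) > 0))
  }
})

test_that("fits are deterministic and recover mu in a scaled setting", {
  grid <- buildModelGrid(theta = 0.5, muGrid = c(2, 3, 4, 6, 8, 11),
                         phiGrid = seq(0.5, 1, 0.25), length = 30000L,
                         replicates = 3L, seed = 11)
  st <- simFinalStats(6, 0.5, length = 100000L, stopTheta = 0.5, seed = 600)
  f1 <- fitMuPhi(st, method = "distribution", grid = grid, seed = 5)
  f2 <- fitMuPhi(st, method = "distribution", grid = grid, seed = 5)
  expect_identical(f1@muHat, f2@muHat)
  expect_identical(f1@ciMu, f2@ciMu)
  expect_lt(abs(f1@muHat - 6) / 6, 0.15)
  fm <- fitMuPhi(st, method = "mean_curve", grid = grid, seed = 5)
  expect_lt(abs(fm@muHat - 6) / 6, 0.2)
})

test_that("a gene-by-gene sample drives mu to the grid lower bound", {
  grid <- buildModelGrid(theta = 0.6, muGrid = c(2, 3, 4, 6, 8, 11),
                         phiGrid = c(0.5, 0.75), length = 20000L,
                         replicates = 3L, seed = 13)
  st <- simFinalStats(1, 0.5, length = 50000L, stopTheta = 0.6, seed = 700)
  f <- fitMuPhi(st, method = "distribution", grid = grid)
  expect_equal(f@muHat, 2)            # lower bound of the grid
  obj <- f@surface$objective
  expect_equal(which.min(obj), 1L)
  expect_gt(obj[length(obj)], obj[1])
})

test_that("bootstrap intervals bracket the point estimate and cover", {
  grid <- buildModelGrid(theta = 0.5, muGrid = c(2, 3, 4, 6, 8, 11),
                         phiGrid = c(0.7, 0.8), length = 30000L,
                         replicates = 6L, seed = 17)
  cover <- 0L
  nData <- 30L
  for (i in seq_len(nData)) {
    st <- simFinalStats(6, 0.75, length = 30000L, stopTheta = 0.5,
                        seed = 800 + i)
    f <- fitMuPhi(st, method = "mean_curve", grid = grid,
                  bootstrap = 100L, level = 0.9, seed = i)
    expect_lte(f@ciMu[1], f@ciMu[2])
    if (f@ciMu[1] <= 6 && f@ciMu[2] >= 6) cover <- cover + 1L
  }
  expect_gte(cover, round(0.8 * nData))
})
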