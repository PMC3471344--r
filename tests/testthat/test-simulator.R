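test_that("deletion lengths follow the geometric law", {
  expect_true(all(drawDeletionLength(DeletionModel(1), 500L) == 1L))
  set.seed(42)
  a <- drawDeletionLength(DeletionModel(2), 2e5L)
  p1 <- mean(a == 1)
  expect_lt(abs(p1 - 0.5), 3 * sqrt(0.25 / 2e5))
  expect_lt(abs(mean(a == 2) - 0.25), 3 * sqrt(0.25 * 0.75 / 2e5))
  a11 <- drawDeletionLength(11, 1e6L)
  se <- sqrt(11 * 10 / 1e6)          # geometric variance mu(mu-1)
  expect_lt(abs(mean(a11) - 11), 3 * se)
  expect_error(drawDeletionLength(0.5), "mu")
})

test_that("anchors are uniform over the remaining duplicate positions", {
  gp <- applyDeletion(GenomePair(40), "G", anchor = 10, a = 8)$pair
  dup <- which(gp@g == 1L & gp@h == 1L) - 1L
  set.seed(9)
  draws <- replicate(20000L, chooseAnchor(gp))
  expect_true(all(draws %in% dup))
  cs <- chisq.test(table(factor(draws, levels = dup)))
  expect_gt(cs$p.value, 0.01)
  # one duplicate left: that position with probability 1
  gp2 <- pairFromStrings("0011", "1101")  # only position 3 is duplicate
  expect_equal(chooseAnchor(gp2), 3L)
  gp3 <- pairFromStrings("0011", "1100")
  expect_error(chooseAnchor(gp3), "saturated")
})

test_that("the deletion scan respects skip and block semantics", {
  out <- applyDeletion(GenomePair(10), "G", anchor = 2, a = 3)
  expect_equal(out$event@deletedPositions, c(2L, 3L, 4L))
  expect_equal(out$event@skippedCount, 0L)
  expect_false(out$event@blocked)
  # conversions never exceed a; equality iff neither blocked nor clipped
  set.seed(21)
  gp <- GenomePair(60)
  for (i in 1:40) {
    dup <- which(gp@g == 1L & gp@h == 1L)
    if (!length(dup)) break
    anc <- dup[sample.int(length(dup), 1L)] - 1L
    a <- drawDeletionLength(3)
    out <- applyDeletion(gp, sample(c("G", "H"), 1L), anc, a)
    ev <- out$event
    expect_lte(length(ev@deletedPositions), ev@drawnLength)
    expect_equal(length(ev@deletedPositions) == ev@drawnLength,
                 !ev@blocked && !ev@clipped)
    expect_true(ev@anchor %in% ev@deletedPositions)
    gp <- out$pair
    expect_true(validObject(gp))
  }
  expect_error(applyDeletion(gp, "G",
                             which(gp@g == 0L)[1] - 1L, 2),
               "not a duplicate")
})

test_that("replay handles empty, simple and invalid scripts", {
  empty <- replayEvents(GenomePair(12), data.frame())
  expect_equal(runCount(empty$stats), 0L)
  expect_equal(theta(empty$pair), 1)

  one <- replayEvents(GenomePair(12),
                      data.frame(chromosome = "G", anchor = 0, a = 2))
  expect_equal(runWidths(one$stats), 2L)
  expect_equal(runR(one$stats), 1L)

  bad <- data.frame(chromosome = c("G", "H"), anchor = c(0, 0), a = c(2, 1))
  expect_error(replayEvents(GenomePair(12), bad), "event 2")
})

test_that("event scripts round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  writeEventScript(table1Script(), f)
  back <- readEventScript(f)
  expect_equal(attr(back, "offset"), -7L)
  expect_equal(attr(back, "length"), 16L)
  expect_equal(back$anchor, table1Script()$anchor)
  res <- replayEvents(GenomePair(attr(back, "length"),
                                 offset = attr(back, "offset")), back)
  expect_equal(runWidths(res$stats), c(7L, 4L))
})

test_that("degenerate parameters give the expected trajectories", {
  sim <- runSimulation(DeletionModel(1, 1), length = 20000L,
                       stopTheta = 0.95, seed = 5, keepState = TRUE)
  # every event deletes exactly one gene, always on chromosome 1
  expect_equal(sim@eventsTotal, sum(sim@pair@g == 0L))
  expect_true(all(sim@pair@h == 1L))
  st <- sim@checkpointStats[[1]]
  expect_true(all(runWidths(st) == runR(st)))  # gene-by-gene runs
})

test_that("chromosome choice is Bernoulli(phi)", {
  sim <- runSimulation(DeletionModel(3, 0.5), length = 100000L,
                       stopTheta = 0.5, seed = 13, keepState = TRUE)
  onG <- length(unique(sim@pair@eventG[sim@pair@eventG > 0L]))
  onH <- length(unique(sim@pair@eventH[sim@pair@eventH > 0L]))
  n <- onG + onH
  expect_lt(abs(onG / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("larger mu gives longer single-copy runs at matched theta", {
  u2 <- vapply(1:8, function(s)
    uBar(simFinalStats(2, 0.5, length = 20000L, seed = s)), numeric(1))
  u11 <- vapply(1:8, function(s)
    uBar(simFinalStats(11, 0.5, length = 20000L, seed = 100 + s)),
    numeric(1))
  expect_true(all(u11 > u2))
})

test_that("simulation is reproducible from its seed", {
  s1 <- runSimulation(DeletionModel(5, 0.8), length = 20000L,
                      stopTheta = 0.6, seed = 77)
  s2 <- runSimulation(DeletionModel(5, 0.8), length = 20000L,
                      stopTheta = 0.6, seed = 77)
  expect_identical(s1@trajectory, s2@trajectory)
})

test_that("early-time run lengths are indistinguishable from gamma", {
  # at theta >= 0.99 nearly every event is type A, so single-copy run
  # lengths should follow the deletion-length distribution itself
  lens <- integer(0)
  for (s in 1:5) {
    st <- simFinalStats(6, 0.5, length = 100000L, stopTheta = 0.99,
                        seed = 300 + s)
    lens <- c(lens, runWidths(st))
  }
  set.seed(1)
  ks <- ksGeometricTest(lens, mu = 6)
  expect_gt(ks$p.value, 0.01)
})

test_that("duplicate-run lengths stay geometric at theta = 0.5", {
  st <- simFinalStats(2, 0.5, length = 100000L, stopTheta = 0.5, seed = 31)
  expect_gt(geometricGofTest(st@dupRunLengths)$p.value, 0.01)
})

test_that("per-event lengths composing a run are not independent", {
  # under independence, r = 2 run lengths would be the convolution of two
  # geometric draws; large deletions cluster, so the test must reject
  lens <- integer(0)
  for (s in 1:5) {
    st <- simFinalStats(6, 0.5, length = 100000L, stopTheta = 0.5,
                        seed = 400 + s)
    sel <- runR(st) == 2L
    lens <- c(lens, runWidths(st)[sel])
  }
  gof <- convolutionGofTest(lens, r = 2L, mu = 6)
  expect_lt(gof$p.value, 1e-4)
  expect_lt(mean(lens), 12)   # shorter than the independent sum's mean 2*mu
})
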