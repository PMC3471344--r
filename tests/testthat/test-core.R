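test_that("the five-event worked example consolidates into the expected runs", {
  res <- replayEvents(GenomePair(16, offset = -7L), table1Script())
  st <- res$stats
  expect_equal(runCount(st), 2L)
  expect_equal(IRanges::start(runRanges(st)), c(-5L, 4L))
  expect_equal(runWidths(st), c(7L, 4L))
  expect_equal(runR(st), c(3L, 2L))
  expect_equal(runBoth(st), c(TRUE, FALSE))
  # event 4 skips the pre-existing 0 at position 5; event 5 skips -4 and is
  # blocked at -1, realizing 3 of its 4 drawn conversions
  ev4 <- res$events[[4]]
  expect_equal(ev4@deletedPositions, c(4L, 6L, 7L))
  expect_equal(ev4@skippedCount, 1L)
  expect_false(ev4@blocked)
  ev5 <- res$events[[5]]
  expect_equal(ev5@deletedPositions, c(-5L, -3L, -2L))
  expect_true(ev5@blocked)
  expect_equal(ev5@skippedCount, 1L)
  # empirical pi and tau from the two runs
  expect_equal(piDist(st), c(0, 0.5, 0.5))
  expect_equal(tauDist(st), c(0, 0, 1))
})

test_that("degenerate pairs extract correctly", {
  allOnes <- GenomePair(50)
  st <- extractRuns(allOnes)
  expect_equal(runCount(st), 0L)
  expect_equal(theta(st), 1)
  expect_length(piDist(st), 0)

  one <- applyDeletion(GenomePair(20), "G", anchor = 5, a = 5)
  st1 <- extractRuns(one$pair)
  expect_equal(runCount(st1), 1L)
  expect_equal(runWidths(st1), 5L)
  expect_equal(runR(st1), 1L)
  expect_false(runBoth(st1))
})

test_that("the g + h >= 1 constraint is enforced, naming the position", {
  expect_error(GenomePair(g = c(1L, 0L, 1L), h = c(1L, 0L, 1L),
                          offset = 10L),
               "position 11")
})

test_that("runs without an event log get NA event counts", {
  gp <- pairFromStrings("101101", "111111")
  st <- extractRuns(gp)
  expect_equal(runCount(st), 2L)
  expect_true(all(is.na(runR(st))))
  expect_true(all(is.na(piDist(st))))
})

test_that("the accounting identity residual behaves as the identity demands", {
  expect_equal(verifyAccounting(list(theta = 0.5, uBar = 3, vBar = 3)), 0)
  expect_equal(verifyAccounting(list(theta = 0.9, uBar = 2, vBar = 18)), 0)
  expect_error(verifyAccounting(list(theta = 1, uBar = 2, vBar = 2)),
               "undefined")
  st <- simFinalStats(6, 0.5, length = 100000L, stopTheta = 0.4, seed = 7)
  expect_lt(abs(verifyAccounting(st)),
            2 * max(uBar(st), vBar(st)) / runCount(st))
})

test_that("run extraction partitions the interval and alternates", {
  sim <- runSimulation(DeletionModel(3, 0.7), length = 20000L,
                       stopTheta = 0.45, seed = 11, keepState = TRUE)
  st <- extractRuns(sim@pair)
  singles <- sum(runWidths(st))
  dups <- sum(st@dupRunLengths)
  expect_equal(singles + dups, 20000L)
  expect_equal(sum(runWidths(st)), runCount(st) * uBar(st))
  # alternation: counts differ by at most 1
  expect_lte(abs(runCount(st) - length(st@dupRunLengths)), 1L)
  # single-copy composition splits over the two homeologs
  expect_equal(st@nDeletedG + st@nDeletedH, singles)
})

test_that("checkpoint statistics agree with R-level run extraction", {
  sim <- runSimulation(DeletionModel(4, 0.6), length = 20000L,
                       stopTheta = 0.5, seed = 3, keepState = TRUE)
  cp <- sim@checkpointStats[[length(sim@checkpointStats)]]
  st <- extractRuns(sim@pair)
  expect_equal(theta(cp), theta(st))
  expect_equal(uBar(cp), uBar(st))
  expect_equal(runCount(cp), runCount(st))
  expect_equal(piDist(cp), piDist(st))
  expect_equal(tauDist(cp), tauDist(st))
})

test_that("presence/absence tables and run statistics round-trip", {
  res <- replayEvents(GenomePair(16, offset = -7L), table1Script())
  tsv <- tempfile(fileext = ".tsv")
  writePresenceAbsence(res$pair, tsv)
  back <- readPresenceAbsence(tsv)
  expect_equal(back@g, res$pair@g)
  expect_equal(back@h, res$pair@h)
  expect_equal(back@offset, -7L)

  runsTsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  writeRunStatistics(res$stats, runsTsv, js)
  d <- read.delim(runsTsv)
  expect_equal(names(d), c("start", "length", "r", "both_chromosomes"))
  expect_equal(d$start, c(-5L, 4L))
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$run_count, 2L)
  expect_equal(summ$pi, c(0, 0.5, 0.5))
})
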