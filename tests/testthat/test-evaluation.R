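# Train/test splitting, PR by states/bins/raw scores/element sets, score
# binning with proportional tie splitting, and top-fraction sets.

test_that("train/test split halves the slices deterministically", {
  part4 <- GenomePartition(c(chr1 = 4000), sliceLength = 1000)
  sp4 <- splitTrainTest(part4, seed = 1)
  expect_length(sp4$train, 2L)
  expect_length(sp4$test, 2L)
  part5 <- GenomePartition(c(chr1 = 5000), sliceLength = 1000)
  sp5 <- splitTrainTest(part5, seed = 1)
  expect_equal(sort(c(length(sp5$train), length(sp5$test))), c(2L, 3L))
  # disjoint, union = all slices
  expect_equal(sum(width(sp5$train)) + sum(width(sp5$test)), 5000)
  expect_length(GenomicRanges::intersect(sp5$train, sp5$test), 0L)
  sp5b <- splitTrainTest(part5, seed = 1)
  expect_identical(start(sp5$train), start(sp5b$train))
  expect_false(identical(start(sp5$train),
                         start(splitTrainTest(part5, seed = 2)$train)))
})

test_that("pr_by_states matches exhaustive counting on a 30-base toy", {
  labels <- rep(c(1, 2, 3), each = 10)
  seg <- segmentationFromLabels(list(chr1 = labels))
  part <- GenomePartition(c(chr1 = 30), sliceLength = 15)
  train <- part@slices[1]  # bases 1..15
  test <- part@slices[2]   # bases 16..30
  target <- gr("chr1", c(5, 25), c(14, 28))  # 10 bases train-ish + 4 test
  pr <- prByStates(seg, target, train, test)
  pts <- prPoints(pr)
  # train folds: st1 5/10 ann bases? direct oracle on test side:
  # test bases: st2 16..20 (5), st3 21..30 (10); target in test: 25..28 (4)
  # train enrichment: st1 (5/10)/(10/15), st2 (5/10)/(5/15), st3 0/...
  # order: st2, st1, st3
  expect_equal(pts$unit, c("state2", "state1", "state3"))
  expect_equal(pts$precision, c(0 / 5, 0 / 5, 4 / 15))
  expect_equal(pts$recall, c(0, 0, 1))
  # single state containing all target bases
  seg1 <- segmentationFromLabels(list(chr1 = rep(1, 30)))
  pr1 <- prByStates(seg1, target, train, test)
  expect_equal(prPoints(pr1)$recall, 1)
  expect_equal(prPoints(pr1)$precision, 4 / 15)
  # target = whole genome: precision 1 at every (nonempty) step
  prAll <- prByStates(seg, gr("chr1", 1, 30), train, test)
  expect_true(all(na.omit(prPoints(prAll)$precision) == 1))
})

test_that("bin_score conserves bases and equalizes non-missing bins", {
  uni <- gr("chr1", 1, 399)
  sc <- GRanges("chr1", IRanges(1:399, 1:399), score = rnorm(399))
  binned <- binScore(sc, uni, nBins = 400, seed = 1)
  runs <- stateRuns(binned)
  expect_equal(sum(width(runs)), 399)
  cnt <- vapply(1:400, function(k)
    sum(width(runs[mcols(runs)$state == k])), numeric(1))
  expect_equal(cnt[1], 0)           # no undefined bases
  expect_true(all(cnt[2:400] == 1)) # one base per non-missing bin
  # all bases share one score: bins equal within one base
  sc2 <- GRanges("chr1", IRanges(1, 1000), score = 5)
  b2 <- binScore(sc2, gr("chr1", 1, 1000), nBins = 5, seed = 2)
  runs2 <- stateRuns(b2)
  cnt2 <- vapply(1:5, function(k)
    sum(width(runs2[mcols(runs2)$state == k])), numeric(1))
  expect_equal(cnt2, c(0, 250, 250, 250, 250))
})

test_that("tied score plateaus are split proportionally across bins", {
  # 1000 bases: 350 distinct high scores, a 300-base tied plateau, 250
  # distinct low scores, 100 undefined
  uni <- gr("chr1", 1, 1000)
  sc <- c(
    GRanges("chr1", IRanges(1:350, 1:350), score = 2000 - (1:350)),
    GRanges("chr1", IRanges(351, 650), score = 100),
    GRanges("chr1", IRanges(651:900, 651:900), score = 50 - (651:900) / 100))
  binned <- binScore(sc, uni, nBins = 10, seed = 3)
  runs <- stateRuns(binned)
  cnt <- vapply(1:10, function(k)
    sum(width(runs[mcols(runs)$state == k])), numeric(1))
  expect_equal(cnt[1], 100)  # undefined bin
  expect_equal(sum(cnt), 1000)
  expect_equal(cnt[2:10], rep(100, 9))
  # fractional allocation oracle: 900 defined bases over 9 bins of 100;
  # plateau of 300 bases occupies score ranks 351..650, i.e. bins 4..7:
  # 50 bases in bin 4, 100 in 5, 100 in 6, 50 in 7 -- as counted from
  # within the plateau's genomic interval
  plateau <- runs[start(runs) >= 351 & end(runs) <= 650]
  pc <- vapply(1:10, function(k)
    sum(width(plateau[mcols(plateau)$state == k])), numeric(1))
  expect_equal(pc[c(5, 6, 7, 8)], c(50, 100, 100, 50))
})

test_that("pr_by_bins and pr_by_raw_score agree with counting oracles", {
  part <- GenomePartition(c(chr1 = 30), sliceLength = 15)
  train <- part@slices[1]
  test <- part@slices[2]
  target <- gr("chr1", 21, 26)
  # score: descending with position; defined on 1..24 only
  sc <- GRanges("chr1", IRanges(1:24, 1:24), score = 24:1)
  pr <- prByRawScore(sc, target, test)
  pts <- prPoints(pr)
  # test bases 16..30; defined among them: 16..24 with scores 9..1
  # thresholds add one base at a time from base 16 downward
  expect_equal(nrow(pts), 10L)  # 9 distinct scores on test + undefined
  # cumulative tp after threshold passes base 21 (score 4)
  i <- which(pts$unit == "score>=4")
  expect_equal(pts$precision[i], 1 / 6)
  expect_equal(pts$recall[i], 1 / 6)  # target in test has 6 bases
  last <- nrow(pts)
  expect_equal(pts$recall[last], 1)
  expect_equal(pts$precision[last], 6 / 15)
  # binning the same score and ranking bins by train enrichment
  binned <- binScore(sc, gr("chr1", 1, 30), nBins = 4, seed = 1)
  prb <- prByBins(binned, target, train, test)
  expect_s4_class(prb, "PRCurve")
  expect_equal(max(prPoints(prb)$recall), 1)
})

test_that("element-set PR points count overlap on the test half", {
  part <- GenomePartition(c(chr1 = 20), sliceLength = 10)
  test <- part@slices[2]  # bases 11..20
  target <- gr("chr1", 13, 18)
  expect_equal(unlist(prPoints(prPointElements(target, target, test))[
    , c("precision", "recall")], use.names = FALSE), c(1, 1))
  disj <- gr("chr1", 11, 12)
  expect_equal(prPoints(prPointElements(disj, target, test))$recall, 0)
  half <- gr("chr1", 16, 20)  # 5 bases, 3 in target
  pt <- prPoints(prPointElements(half, target, test))
  expect_equal(pt$precision, 3 / 5)
  expect_equal(pt$recall, 3 / 6)
})

test_that("concatenated multi-sample targets match the pooled oracle", {
  labels <- rep(c(1, 2), each = 10)
  seg <- segmentationFromLabels(list(chr1 = labels))
  t1 <- gr("chr1", 1, 6)    # sample A: 6 bases in state 1
  t2 <- gr("chr1", 11, 14)  # sample B: 4 bases in state 2
  cat2 <- concatTargets(list(A = t1, B = t2))
  expect_equal(as.character(seqnames(cat2)), c("chr1#A", "chr1#B"))
  segR <- replicateAcrossSamples(seg, c("A", "B"))
  expect_equal(countSegments(segR), 4L)
  et <- overlapEnrichment(segR, cat2)
  # pooled: 10 target bases over 40; state1 6/10 vs 20/40
  expect_equal(unname(folds(et)[, 1]), c((6 / 10) / (20 / 40),
                                         (4 / 10) / (20 / 40)))
  # identical samples give the same PR as a single sample
  part <- GenomePartition(c(chr1 = 20), sliceLength = 10)
  split1 <- splitTrainTest(part, seed = 3)
  prOne <- prByStates(seg, t1, split1$train, split1$test)
  segDup <- replicateAcrossSamples(seg, c("A", "B"))
  prTwo <- prByStates(segDup, concatTargets(list(A = t1, B = t1)),
                      replicateAcrossSamples(split1$train, c("A", "B")),
                      replicateAcrossSamples(split1$test, c("A", "B")))
  expect_equal(prPoints(prTwo)$precision, prPoints(prOne)$precision)
  expect_equal(prPoints(prTwo)$recall, prPoints(prOne)$recall)
})

test_that("top-fraction sets pick the closest threshold and nest", {
  uni <- gr("chr1", 1, 100)
  sc <- GRanges("chr1", IRanges(1:100, 1:100), score = 100:1)
  top10 <- topFractionSet(sc, 0.10, uni)
  expect_equal(sum(width(top10)), 10)
  expect_equal(start(reduce(top10)), 1)
  # monotone nesting over fractions
  fr <- c(0.01, 0.05, 0.10, 0.5)
  sets <- lapply(fr, function(p) topFractionSet(sc, p, uni))
  for (i in seq_len(length(fr) - 1)) {
    extra <- GenomicRanges::setdiff(sets[[i]], sets[[i + 1]])
    expect_length(extra, 0L)
  }
  # all-tied scores: whole universe or empty, whichever closer
  scT <- GRanges("chr1", IRanges(1, 100), score = 7)
  expect_equal(sum(width(topFractionSet(scT, 0.4, uni))), 0)
  expect_equal(sum(width(topFractionSet(scT, 0.6, uni))), 100)
  # undefined bases count toward the universe but rank lowest
  scU <- GRanges("chr1", IRanges(1:50, 1:50), score = 50:1)
  top50 <- topFractionSet(scU, 0.5, uni)  # 50% of 100 = 50 bases
  expect_equal(sum(width(top50)), 50)
  expect_true(all(end(top50) <= 50))
})
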