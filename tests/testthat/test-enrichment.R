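# Fold enrichment: overlap, background-restricted, positional, and the
# promoter-proximal gene ranking — all against per-base counting oracles.

test_that("overlap enrichment follows the fold formula on a 100 b toy", {
  # genome 100 b; state 1 covers 20 b; annotation 10 b with 5 in state 1
  labels <- rep(c(1, 2), c(20, 80))
  seg <- segmentationFromLabels(list(chr1 = labels))
  ann <- gr("chr1", 16, 25)
  et <- overlapEnrichment(seg, ann)
  expect_equal(unname(folds(et)[, 1]), c((5 / 10) / (20 / 100),
                                         (5 / 10) / (80 / 100)))
  # annotation = universe -> every state fold 1
  et2 <- overlapEnrichment(seg, gr("chr1", 1, 100))
  expect_equal(unname(folds(et2)[, 1]), c(1, 1))
  # empty annotation -> missing values
  et3 <- overlapEnrichment(seg, GRanges())
  expect_true(all(is.na(folds(et3))))
})

test_that("overlap enrichment equals the per-base counting oracle", {
  set.seed(5)
  labels <- sample(4, 300, replace = TRUE)
  seg <- segmentationFromLabels(list(chr1 = labels))
  annMask <- rep(FALSE, 300)
  annMask[sample(300, 60)] <- TRUE
  idx <- which(annMask)
  ann <- reduce(gr("chr1", idx, idx))
  et <- overlapEnrichment(seg, ann)
  expect_equal(unname(folds(et)[, 1]), countingEnrichment(labels, annMask))
  # conservation of annotation bases across states
  stateAnn <- vapply(1:4, function(k)
    sum(labels[idx] == k), numeric(1))
  expect_equal(sum(stateAnn), 60)
  # invariance under splitting annotation intervals
  split1 <- gr("chr1", idx, idx)  # fully split, one interval per base
  expect_equal(folds(overlapEnrichment(seg, split1)), folds(et))
})

test_that("restricting the universe gives background-relative folds", {
  set.seed(6)
  labels <- sample(3, 200, replace = TRUE)
  seg <- segmentationFromLabels(list(chr1 = labels))
  uniMask <- rep(FALSE, 200)
  uniMask[30:170] <- TRUE
  annMask <- rep(FALSE, 200)
  annMask[sample(30:170, 40)] <- TRUE
  uni <- gr("chr1", 30, 170)
  idx <- which(annMask)
  et <- overlapEnrichment(seg, reduce(gr("chr1", idx, idx)), universe = uni)
  expect_equal(unname(folds(et)[, 1]),
               countingEnrichment(labels, annMask, uniMask))
  # annotation bases outside the universe are clipped with a warning
  expect_warning(overlapEnrichment(seg, gr("chr1", 1, 50), universe = uni),
                 "clipped")
})

test_that("relative enrichment divides foreground by background folds", {
  expect_equal(relativeEnrichment(c(2, 4, 1), c(2, 2, 0.5)), c(1, 2, 2))
  expect_true(is.na(relativeEnrichment(1, 0)))
  # background = whole genome is the identity
  labels <- rep(c(1, 2), c(50, 50))
  seg <- segmentationFromLabels(list(chr1 = labels))
  fg <- folds(overlapEnrichment(seg, gr("chr1", 1, 30)))[, 1]
  wg <- folds(overlapEnrichment(seg, gr("chr1", 1, 100)))[, 1]
  expect_equal(relativeEnrichment(fg, wg), fg)
})

test_that("neighborhood enrichment matches direct counting and strands", {
  labels <- c(rep(1, 10), rep(2, 10), rep(3, 10))
  seg <- segmentationFromLabels(list(chr1 = labels))
  gf <- stateFractions(seg)
  anchors <- GRanges("chr1", IRanges(c(10, 15, 21), width = 1),
                     strand = c("+", "+", "-"))
  ne <- neighborhoodEnrichment(seg, anchors, left = 2, right = 2)
  expect_equal(dim(ne), c(5L, 3L))
  # direct counting at offset -2: bases 8 (st1), 13 (st2), 23 (st3)
  expect_equal(unname(ne["-2", ]), (c(1, 1, 1) / 3) / gf)
  # offset +1: base 11 (st2), 16 (st2), 20 (st2, mirrored for '-')
  expect_equal(unname(ne["1", ]), c(0, (3 / 3) / gf[2], 0))
  # anchors all in one state at offset 0
  a0 <- GRanges("chr1", IRanges(c(3, 5, 7), width = 1))
  ne0 <- neighborhoodEnrichment(seg, a0, 0, 0)
  expect_equal(unname(ne0["0", 1]), 1 / gf[1])
  # window-0 single anchor equals overlap enrichment of that base
  one <- neighborhoodEnrichment(seg, GRanges("chr1", IRanges(12, 12)), 0, 0)
  ov <- folds(overlapEnrichment(seg, gr("chr1", 12, 12)))[, 1]
  expect_equal(unname(one["0", ]), unname(ifelse(is.na(ov), NA, ov)))
  expect_error(neighborhoodEnrichment(seg, GRanges(), 1, 1), "zero anchors")
})

test_that("out-of-range offsets are skipped per anchor", {
  labels <- rep(1:2, each = 5)
  seg <- segmentationFromLabels(list(chr1 = labels))
  ne <- neighborhoodEnrichment(seg, GRanges("chr1", IRanges(1, 1)),
                               left = 2, right = 1)
  expect_true(all(is.na(ne["-2", ])))
  expect_equal(unname(ne["0", ]), c(1 / 0.5, 0))
})

test_that("gene ranking counts in-state promoter-window bases", {
  # state 1 on bases 1..4001 exactly covers gene A's +/-2 kb window
  labels <- c(rep(1, 4001), rep(2, 8000))
  seg <- segmentationFromLabels(list(chr1 = labels))
  tss <- GRanges("chr1", IRanges(c(2001, 8000, 9000), width = 1),
                 gene = c("geneA", "geneB", "geneC"))
  rk <- rankGenesByState(seg, tss, window = 2000, topFraction = 1 / 3)
  expect_equal(unname(rk$counts["geneA", ]), c(4001L, 0L))
  expect_equal(unname(rk$counts["geneB", ]), c(0L, 4001L))
  expect_equal(rk$ranking$state1, c("geneA", "geneB", "geneC"))
  # state absent near all genes: all counts zero, tie-break by gene id
  expect_equal(rk$ranking$state2[1], "geneB")  # 4001 > geneC 4001? check below
  # geneB window 6000..10000 all state2 (4001), geneC window 7000..11000
  expect_equal(unname(rk$counts["geneC", "state2"]), 4001L)
  # tie between geneB and geneC on state2 resolved lexicographically
  expect_equal(rk$ranking$state2[1:2], c("geneB", "geneC"))
  expect_length(rk$topGenes$state1, 1L)
  expect_equal(rk$topGenes$state1, "geneA")
})
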