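test_that("sensitivity formula reproduces the printed full-set value", {
  ## 161 positive genomes of which exactly one has zero predictions
  labels <- data.frame(genome_id = sprintf("g%03d", 1:161),
                       lineage = "mixed", sec_positive = TRUE)
  preds <- data.frame(genome_id = sprintf("g%03d", 2:161),
                      locus_id = "L1")
  r <- evaluateBenchmark(preds, labels, byLineage = FALSE)
  expect_equal(r$sn, 99.4)
  expect_true(is.na(r$sp))   # no negative genomes in this set
})

test_that("perfect predictions give 100/100 and hand arithmetic checks out", {
  labels <- data.frame(genome_id = c(paste0("p", 1:3), paste0("n", 1:3)),
                       lineage = "x",
                       sec_positive = rep(c(TRUE, FALSE), each = 3))
  preds <- data.frame(genome_id = paste0("p", 1:3), locus_id = "a")
  r <- evaluateBenchmark(preds, labels, byLineage = FALSE)
  expect_equal(c(r$sn, r$sp), c(100, 100))
  ## 4 positives {2,0,1,3}, 4 negatives {0,0,1,0}
  labels2 <- data.frame(genome_id = c(paste0("p", 1:4), paste0("n", 1:4)),
                        lineage = "x",
                        sec_positive = rep(c(TRUE, FALSE), each = 4))
  preds2 <- data.frame(
    genome_id = c("p1", "p1", "p3", "p4", "p4", "p4", "n3"),
    locus_id = c("a", "b", "a", "a", "b", "c", "a"))
  r2 <- evaluateBenchmark(preds2, labels2, byLineage = FALSE)
  expect_equal(r2$sn, 75.0)
  expect_equal(r2$sp, 75.0)
  expect_equal(r2$Nplus, 1.5)
  expect_equal(r2$Nminus, 0.3)  # 0.25 rounded half-up to one decimal
})

test_that("evaluation ignores row order and duplicated locus rows", {
  labels <- data.frame(genome_id = c("a", "b", "c"), lineage = "x",
                       sec_positive = c(TRUE, TRUE, FALSE))
  preds <- data.frame(genome_id = c("a", "a", "b"),
                      locus_id = c("l1", "l1", "l2"))
  r1 <- evaluateBenchmark(preds, labels, byLineage = FALSE)
  r2 <- evaluateBenchmark(preds[c(3, 1, 2), ], labels[c(2, 3, 1), ],
                          byLineage = FALSE)
  expect_equal(r1, r2)
  expect_equal(r1$Nplus, 1)    # the duplicate row counts once
  expect_error(evaluateBenchmark(data.frame(genome_id = "zz",
                                            locus_id = "l"), labels),
               "unknown genome id")
})

test_that("column conservation is the modal non-gap frequency", {
  aln <- new("SeedAlignment", ids = c("a", "b"),
             seqs = c("GGAAAUUCCC", "GGAAAUUCCC"),
             ssCons = "<<<....>>>", positionLabels = character(0),
             domainTag = "eukaryota")
  st <- columnStats(aln)
  expect_true(all(st$perColumn == 1))
  ## column {A,A,G,A} -> 75%
  rows <- c("AGGAAUUCCU", "AGGAAUUCCU", "GGGAAUUCCU", "AGGAAUUCCU")
  aln2 <- new("SeedAlignment", ids = paste0("s", 1:4), seqs = rows,
              ssCons = ".<<....>>.", positionLabels = character(0),
              domainTag = "eukaryota")
  expect_equal(columnStats(aln2)$perColumn[1], 0.75)
  expect_error(columnStats(new("SeedAlignment", ids = "a", seqs = "AAAAAAAAAA",
                               ssCons = "..........",
                               positionLabels = character(0),
                               domainTag = "eukaryota")),
               ">= 2")
})

test_that("stems vary compensatorily, loops stay conserved, in bundled seeds", {
  st <- columnStats(bundledSeed("eukaryota"))
  expect_gt(st$unpairedMean, st$pairedMean)
  ## the universally conserved anchors are 100% columns
  expect_true(all(c("18", "19", "33", "34", "35", "36", "55", "61")
                  %in% st$fullyConserved))
})
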