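test_that("Laplace arithmetic: 2 sequences with {A,G} at a column give 2/6", {
  ## toy alignment with a free loop column where the two rows disagree
  ss <-   "<<..<<....>>.<<....>>.<<....>>.<<....>>..>>"
  base <- "GGAACCGAAAGGUGCGAAAGCACGGAAACGAGGGAAACCCAUU"
  row2 <- base
  substr(row2, 8, 8) <- "G"   # column 8 (D-loop): row1 A, row2 G
  aln <- new("SeedAlignment", ids = c("a", "b"), seqs = c(base, row2),
             ssCons = ss, positionLabels = character(0),
             domainTag = "eukaryota")
  m <- buildModel(aln, pseudocount = 1)
  ## find the ML state emitting match column 8
  v <- which(m@params$stType == "ML" & m@params$emitLcol == 8L)
  pr <- m@params$eprS[v, ]
  expect_equal(pr[1], 2 / 6)  # A: (1 + 1) / (2 + 4)
  expect_equal(pr[3], 2 / 6)  # G
  expect_equal(pr[2], 1 / 6)  # C: pseudocount only
})

test_that("a single-sequence model scores its training sequence highest", {
  aln <- toyAlignment()
  single <- new("SeedAlignment", ids = "a", seqs = aln@seqs[1],
                ssCons = aln@ssCons, positionLabels = character(0),
                domainTag = "eukaryota")
  m <- buildModel(single, pseudocount = 1e-3, transitionPseudocount = 1e-6)
  sq <- single@seqs[1]
  self <- scoreSequence(m, sq)$score
  chars <- strsplit(sq, "")[[1]]
  for (i in seq_along(chars)) {
    for (b in setdiff(c("A", "C", "G", "U"), chars[i])) {
      mut <- chars; mut[i] <- b
      expect_lt(scoreSequence(m, paste(mut, collapse = ""))$score, self)
    }
  }
})

test_that("bundled model consensus lengths match tRNA-Sec lengths", {
  ## tRNA-Sec is the longest tRNA, 90-101 nt
  for (dom in c("eukaryota", "bacteria", "archaea")) {
    cl <- consensusLength(bundledModel(dom))
    expect_gte(cl, 90L)
    expect_lte(cl, 101L)
  }
})

test_that("CYK maximum equals exhaustive parse enumeration", {
  m <- toyModel()
  ## all short sequences over a two-letter alphabet
  for (n in 2:4) {
    combos <- expand.grid(rep(list(c("G", "C")), n), stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      s <- paste(unlist(combos[r, ]), collapse = "")
      expect_equal(scoreSequence(m, s)$score, oracleScore(m, s),
                   tolerance = 1e-6)
    }
  }
  ## random four-letter sequences up to length 10
  set.seed(7)
  for (r in 1:60) {
    n <- sample(4:10, 1)
    s <- randSeq(n, seed = 7000 + r)
    expect_equal(scoreSequence(m, s)$score, oracleScore(m, s),
                 tolerance = 1e-6)
  }
})

test_that("the consensus sequence beats all its point mutants", {
  m <- toyModel()
  cons <- modelConsensusSeq(m)
  self <- scoreSequence(m, cons)$score
  chars <- strsplit(cons, "")[[1]]
  for (i in seq_along(chars)) {
    for (b in setdiff(c("A", "C", "G", "U"), chars[i])) {
      mut <- chars; mut[i] <- b
      expect_gte(self, scoreSequence(m, paste(mut, collapse = ""))$score)
    }
  }
})

test_that("model-sampled sequences score above the reporting threshold", {
  m <- bundledModel("eukaryota")
  s <- sampleTrna(m, seed = 1)
  expect_gt(scoreSequence(m, s$seq)$score, 40)
})

test_that("scores are invariant under T/U substitution", {
  m <- toyModel()
  s <- "GGAACCGAAAGGUGCGAAAGCACGGAAACGAGGGAAACCCAUU"
  expect_identical(scoreSequence(m, s)$score,
                   scoreSequence(m, chartr("U", "T", s))$score)
})

test_that("iid null sequences have negative mean bit score", {
  m <- bundledModel("bacteria")
  sc <- vapply(1:200, function(k)
    scoreSequence(m, randSeq(consensusLength(m), seed = 20000 + k))$score,
    numeric(1))
  expect_lt(mean(sc), 0)
})

test_that("serialization round-trips with bit-exact scores", {
  m <- bundledModel("archaea")
  tmp <- tempfile(fileext = ".json")
  writeModel(m, tmp)
  m2 <- readModel(tmp)
  probes <- c(sampleTrna(m, 3)$seq, sampleTrna(m, 4)$seq,
              randSeq(92, seed = 99))
  for (s in probes)
    expect_identical(scoreSequence(m, s)$score, scoreSequence(m2, s)$score)
})

test_that("degenerate inputs are rejected", {
  m <- toyModel()
  expect_error(scoreSequence(m, ""), "empty")
  expect_error(scoreSequence(m, "ACGX"), "characters")
  expect_error(new("SeedAlignment", ids = character(0), seqs = character(0),
                   ssCons = "<.>", positionLabels = character(0),
                   domainTag = "eukaryota"),
               ">= 1 sequence")
  expect_error(buildModel(toyAlignment(), pseudocount = 0), "positive")
})
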