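## one planted genome per domain, annotated through the full pipeline
annotatedFor <- function(domain, seed, len = 2000L, strand = "+", ...) {
  g <- makeGenome(list(contigs = c(chr = len), seed = seed,
                       planted = list(list(model = domain, strand = strand,
                                           at = as.integer(len / 3), ...))))
  list(genome = g, cands = searchTrnaSec(g$genome))
}

test_that("error-free samples realize the domain folds", {
  euk <- annotatedFor("eukaryota", 41L)
  expect_equal(mcols(euk$cands)$fold, "9/4")
  ap <- mcols(euk$cands)$armPairs[[1]]
  expect_equal(unname(ap[c("A-stem", "T-stem")]), c(9L, 4L))
  expect_equal(mcols(euk$cands)$atTotal, 13L)
  bac <- annotatedFor("bacteria", 42L)
  expect_equal(mcols(bac$cands)$fold, "8/5")
  ap <- mcols(bac$cands)$armPairs[[1]]
  expect_equal(unname(ap[c("A-stem", "T-stem")]), c(8L, 5L))
})

test_that("a deleted acceptor-stem pair reduces the realized pair count", {
  m <- bundledModel("eukaryota")
  s <- sampleTrna(m, seed = 5)
  ## delete both bases of the 3rd acceptor pair
  i5 <- match(3L, s$colOfBase)                 # base at match column 3
  mp <- m@matchPair[3L]
  i3 <- match(mp, s$colOfBase)
  chars <- strsplit(s$seq, "")[[1]][-c(i5, i3)]
  mut <- paste(chars, collapse = "")
  r <- scoreSequence(m, mut)
  arms <- parseArms(r$parse, m)
  expect_equal(unname(arms$pairs["A-stem"]), 8L)
})

test_that("anticodon extraction reports UCA, variants, and deletions", {
  euk <- annotatedFor("eukaryota", 43L)
  expect_equal(mcols(euk$cands)$anticodon, "UCA")
  ## CUA variant (as in Geodermatophilaceae): substitute the anticodon
  m <- bundledModel("bacteria")
  s <- sampleTrna(m, seed = 6)
  ac <- match(c("34", "35", "36"), positionMap(m))
  pos <- match(ac, s$colOfBase)
  chars <- strsplit(s$seq, "")[[1]]
  expect_equal(paste(chars[pos], collapse = ""), "UCA")
  chars[pos] <- c("C", "U", "A")
  r <- scoreSequence(m, paste(chars, collapse = ""))
  expect_equal(extractAnticodon(r$parse, m, paste(chars, collapse = "")),
               "CUA")
  ## deletion rule, on a parse with position 35 deleted
  r2 <- scoreSequence(m, s$seq)
  r2$parse$colPos[ac[2]] <- NA
  expect_true(is.na(extractAnticodon(r2$parse, m, s$seq)))
})

test_that("anticodon-dependent thresholds follow the 40/55 rule", {
  cands <- c(fakeCandidate(score = 47.0, anticodon = "UCA"),
             fakeCandidate(start = 301, end = 390, score = 47.0,
                           anticodon = "CUA"),
             fakeCandidate(start = 501, end = 590, score = 60.2,
                           anticodon = "CUA"),
             fakeCandidate(start = 701, end = 790, score = 47.0,
                           anticodon = NA_character_))
  out <- applyThresholds(cands, threshold = 40, stringent = 55)
  expect_equal(start(out), c(101L, 501L))
  expect_error(applyThresholds(cands, threshold = 60, stringent = 55),
               "configuration")
})

test_that("the arm filter keeps clean candidates and drops truncated ones", {
  for (dom in c("eukaryota", "bacteria", "archaea")) {
    res <- annotatedFor(dom, 44L)
    expect_equal(length(res$cands), 1L, info = dom)
  }
  ## synthetic truncations, injected at the annotation level
  res <- annotatedFor("eukaryota", 45L)
  cand <- res$cands
  ap <- mcols(cand)$armPairs[[1]]
  ap["D-stem"] <- 2L                       # D-stem reduced to 2 pairs
  mcols(cand)$armPairs[[1]] <- ap
  expect_equal(length(filterArms(cand)), 0L)
  ap["D-stem"] <- 6L; ap["V-stem"] <- 0L   # missing V-arm
  mcols(cand)$armPairs[[1]] <- ap
  expect_equal(length(filterArms(cand)), 0L)
})

test_that("the discriminator is the 14th base 3' of position 61 and G73 holds", {
  res <- annotatedFor("eukaryota", 46L)
  cand <- res$cands
  expect_true(mcols(cand)$g73)
  expect_equal(mcols(cand)$discriminator, "G")
  m <- bundledModel("eukaryota")
  p61 <- mcols(cand)$parse[[1]]$colPos[match("61", positionMap(m))]
  g61 <- start(cand) + p61 - 1L
  expect_equal(mcols(cand)$discPos - g61, 14L)
  ## and on the minus strand the offset is 14 towards lower coordinates
  resM <- annotatedFor("bacteria", 47L, strand = "-")
  candM <- resM$cands
  expect_true(mcols(candM)$g73)
  p61 <- mcols(candM)$parse[[1]]$colPos[match("61",
                                              positionMap(bundledModel("bacteria")))]
  g61 <- end(candM) - p61 + 1L
  expect_equal(g61 - mcols(candM)$discPos, 14L)
})

test_that("a hit truncated at the contig end has an undefined discriminator", {
  m <- bundledModel("eukaryota")
  s <- sampleTrna(m, seed = 9)
  set.seed(100)
  bg <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  genome <- c(ctg = paste0(bg, chartr("U", "T", s$seq)))  # gene ends the contig
  hits <- scanGenome(genome)
  cands <- annotateCandidates(hits, genome)
  expect_true(is.na(mcols(cands)$discriminator[1]))
  expect_false(mcols(cands)$g73[1])
  expect_false(mcols(cands)$cca[1])
})

test_that("the 13-bp AT-stem assumption misplaces the discriminator on 7/5 folds", {
  ## a 12-bp AT-stem (7/5) tRNA with genomic G73 + CCA: the fixed 14-residue
  ## rule overshoots the true discriminator by one, landing on the first C
  can <- bundledModel("canonical")
  s <- sampleTrna(can, seed = 12)
  set.seed(200)
  bg <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  genome <- c(ctg = paste0(substr(bg, 1, 600),
                           chartr("U", "T", s$seq), "GCCA",
                           substr(bg, 601, 1200)))
  hits <- scanGenome(genome, models = list(can))
  expect_gte(length(hits), 1L)
  cands <- annotateCandidates(hits, genome, models = list(can))
  expect_equal(mcols(cands)$fold[1], "7/5")      # the flag for this case
  expect_equal(mcols(cands)$discriminator[1], "C")
  expect_false(mcols(cands)$g73[1])
})

test_that("genomic CCA is detected in bacteria and absent in eukaryotes", {
  bac <- annotatedFor("bacteria", 48L)
  expect_true(mcols(bac$cands)$cca)
  euk <- annotatedFor("eukaryota", 48L)
  expect_false(mcols(euk$cands)$cca)
  expect_warning(detectCCA(euk$cands, 1L,
                           secScan:::asContigs(euk$genome$genome), NULL),
                 "undefined")
})

test_that("C-loop introns are detected at the canonical point and spliced", {
  for (ilen in c(16L, 25L)) {
    res <- annotatedFor("eukaryota", 49L + ilen, intronLen = ilen)
    cand <- res$cands
    expect_equal(length(cand), 1L)
    expect_equal(mcols(cand)$intronLen, ilen)
    ## insertion point: one base 3' of the anticodon (after position 37)
    m <- bundledModel("eukaryota")
    p37 <- mcols(cand)$parse[[1]]$colPos[match("37", positionMap(m))]
    expect_equal(mcols(cand)$intronFrom, p37 + 1L)
    ## splicing: mature sequence scores at least as well as the unspliced hit
    expect_gte(scoreSequence(m, mcols(cand)$matureSeq)$score,
               scoreSequence(m, mcols(cand)$matchedSeq)$score)
    expect_equal(nchar(mcols(cand)$matchedSeq) - ilen,
                 nchar(mcols(cand)$matureSeq))
  }
  clean <- annotatedFor("eukaryota", 50L)
  expect_equal(mcols(clean$cands)$intronLen, 0L)
})

test_that("fold classification covers the named classes and the fallthrough", {
  expect_equal(classifyFold(9, 4)$label, "9/4")
  expect_equal(classifyFold(9, 4)$atTotal, 13)
  expect_equal(classifyFold(8, 5)$label, "8/5")
  expect_equal(classifyFold(7, 5)$label, "7/5")
  expect_equal(classifyFold(7, 5)$atTotal, 12)
  expect_equal(classifyFold(6, 4)$label, "other")
})
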