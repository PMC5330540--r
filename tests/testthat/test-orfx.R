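## toy genome builder: codons spliced into a background with a CDS record
aaToCodon <- function(aa) {
  gc11 <- Biostrings::getGeneticCode("11")
  vapply(aa, function(a) names(gc11)[gc11 == a][1], character(1))
}

## an annotated gene: ATG ... [TGA] ... TAA with known codon layout
toyOrfGenome <- function(codons, strand = "+", lead = 90L, tail = 90L) {
  set.seed(404)
  bg1 <- paste(sample(c("A", "C", "G", "T"), lead, TRUE), collapse = "")
  bg2 <- paste(sample(c("A", "C", "G", "T"), tail, TRUE), collapse = "")
  ## a bounding upstream in-frame stop so the 5' extension is well defined
  gene <- paste(codons, collapse = "")
  oriented <- paste0(bg1, "TAA", gene, bg2)
  contig <- if (strand == "+") oriented else secScan:::revComp(oriented)
  cdsStart <- lead + 4L            # 1-based, after the TAA
  cdsEnd <- lead + 3L + nchar(gene)
  L <- nchar(oriented)
  gr <- GRanges("ctg", IRanges(
    ifelse(strand == "+", cdsStart, L - cdsEnd + 1L),
    ifelse(strand == "+", cdsEnd, L - cdsStart + 1L)), strand = strand)
  mcols(gr)$type <- "CDS"
  list(genome = c(ctg = contig), cds = gr)
}

test_that("genes are extended through in-frame TGA to the next hard stop", {
  ## annotated CDS stops at the TGA; extension must read through to TAA
  cod <- c("ATG", "GAA", "CTG", "AAA", "TGA", "GGC", "GAT", "TAA")
  tg <- toyOrfGenome(cod)
  cdsOnly <- tg$cds
  end(cdsOnly) <- start(cdsOnly) + 3L * 4L - 1L   # annotate up to before TGA
  orfs <- extendOrfs(tg$genome, cdsOnly)
  expect_equal(length(orfs), 1L)
  expect_equal(mcols(orfs)$nTga, 1L)
  expect_equal(mcols(orfs)$tgaCodons[[1]], 5L)
  expect_equal(mcols(orfs)$terminalStop, "TAA")
  expect_equal(substr(mcols(orfs)$protein, 5, 5), "U")
})

test_that("genes without in-frame TGA are dropped; consecutive TGAs counted", {
  cod <- c("ATG", "GAA", "CTG", "AAA", "TAA")
  tg <- toyOrfGenome(cod)
  end(tg$cds) <- end(tg$cds) - 3L
  expect_equal(length(extendOrfs(tg$genome, tg$cds)), 0L)
  cod2 <- c("ATG", "GAA", "TGA", "TGA", "GGC", "TAG")
  tg2 <- toyOrfGenome(cod2)
  end(tg2$cds) <- start(tg2$cds) + 3L * 2L - 1L
  orfs <- extendOrfs(tg2$genome, tg2$cds)
  expect_equal(mcols(orfs)$nTga, 2L)
  expect_equal(mcols(orfs)$tgaCodons[[1]], c(3L, 4L))
  ## reverse strand gives the same protein (CDS = first two codons, i.e.
  ## the high end of the forward-strand interval)
  tg2m <- toyOrfGenome(cod2, strand = "-")
  start(tg2m$cds) <- end(tg2m$cds) - 3L * 2L + 1L
  orfsM <- extendOrfs(tg2m$genome, tg2m$cds)
  expect_equal(mcols(orfsM)$protein, mcols(orfs)$protein)
  ## frame errors are rejected
  bad <- tg2$cds; end(bad) <- end(bad) - 1L
  expect_error(extendOrfs(tg2$genome, bad), "frame")
})

test_that("U positions in the translation round-trip to TGA codon indices", {
  cod <- c("ATG", "TGA", "GAA", "TGA", "GGC", "TAA")
  tg <- toyOrfGenome(cod)
  end(tg$cds) <- end(tg$cds) - 3L
  orfs <- extendOrfs(tg$genome, tg$cds)
  uPos <- which(strsplit(mcols(orfs)$protein, "")[[1]] == "U")
  expect_equal(uPos, mcols(orfs)$tgaCodons[[1]])
})

test_that("local alignment finds TGA/Cys pairs and matches a DP oracle", {
  prot <- "MKVLUGGEIDRATLLKQWFE"     # U at position 5 (a Cys site)
  subj <- c(cys1 = "MKVLCGGEIDRATLLKQWFE",
            cys2 = "AKVLCGGEIDRATILKQWYE",
            rand = "PPPPQQQQWWWWHHHHNNNN")
  hits <- alignHomologs(prot, subj, minScore = 40)
  expect_true(all(c("cys1", "cys2") %in% hits$subject))
  expect_false("rand" %in% hits$subject)
  for (r in which(hits$subject %in% c("cys1", "cys2"))) {
    up <- hits$uPairs[[r]]
    expect_true(any(up$queryPos == 5L & up$subjectResidue == "C"))
  }
  ## independent affine-gap Smith-Waterman oracle on short peptides
  data(BLOSUM62, package = "Biostrings", envir = environment())
  swOracle <- function(a, b, open = 11, ext = 1) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    M <- matrix(-Inf, n + 1, m + 1); X <- M; Y <- M
    M[1, ] <- 0; M[, 1] <- 0
    best <- 0
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      sc <- BLOSUM62[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      best <- max(best, M[i, j])
    }
    best
  }
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (r in 1:6) {
    q <- paste(sample(aas, 15, TRUE), collapse = "")
    s <- paste(sample(aas, 18, TRUE), collapse = "")
    got <- alignHomologs(q, c(x = s), minScore = -1000)
    expect_equal(got$score[1], swOracle(q, s), info = paste(q, s))
  }
})

test_that("selection needs >= 3 distinct Cys-pairing subjects and is monotone", {
  orfs <- GRanges("c", IRanges(c(1, 100, 200), width = 30),
                  strand = "+")
  mcols(orfs)$orfId <- c("o1", "o2", "o3")
  mkHit <- function(subj, res) data.frame(
    subject = subj, score = 50,
    uPairs = I(list(data.frame(queryPos = 1L, subjectResidue = res))))
  hits <- list(
    do.call(rbind, lapply(c("s1", "s2", "s3"), mkHit, res = "C")),
    do.call(rbind, lapply(c("s1", "s2"), mkHit, res = "C")),
    do.call(rbind, lapply(paste0("s", 1:5), mkHit, res = "W")))
  sel <- selectCandidates(orfs, hits, minCysHits = 3L)
  expect_equal(mcols(sel)$selected, c(TRUE, FALSE, FALSE))
  expect_equal(mcols(sel)$nCysHits, c(3L, 2L, 0L))
  ## monotone in the threshold
  sel2 <- selectCandidates(orfs, hits, minCysHits = 2L)
  expect_true(all(mcols(sel)$selected <= mcols(sel2)$selected))
})

test_that("a Brachyspira-like gene cluster yields exactly the planted candidate", {
  ## one Sec gene (TGA at the conserved site) and one Cys paralogue sharing
  ## the domain, plus Cys homologues from other species in the database
  core <- "MSKEVLXGGEIDRATLLKQWFEDHPEVLREWGITREQLEAGK"
  secGene <- sub("X", "U", core)
  cysGene <- sub("X", "C", core)
  codSec <- unname(aaToCodon(strsplit(sub("U", "*", secGene), "")[[1]]))
  codSec[codSec == "TAA"] <- "TGA"   # the Sec codon
  codCys <- unname(aaToCodon(strsplit(cysGene, "")[[1]]))
  set.seed(77)
  spacer <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  geneA <- paste(c(codSec, "TAA"), collapse = "")
  geneB <- paste(c(codCys, "TAA"), collapse = "")
  lead <- paste(sample(c("A", "C", "G", "T"), 90, TRUE), collapse = "")
  contig <- paste0(lead, "TAA", geneA, spacer, "TAA", geneB, spacer)
  aSt <- nchar(lead) + 4L
  bSt <- nchar(lead) + 3L + nchar(geneA) + nchar(spacer) + 4L
  cds <- GRanges("ctg", IRanges(c(aSt, bSt),
                                c(aSt + nchar(geneA) - 4L,
                                  bSt + nchar(geneB) - 4L)), strand = "+")
  mcols(cds)$type <- "CDS"
  homologs <- c(h1 = cysGene, h2 = sub("LLKQ", "ILKQ", cysGene),
                h3 = sub("EDHP", "EDNP", cysGene))
  res <- orfScreen(c(ctg = contig), cds, homologs)
  expect_equal(length(res), 1L)              # the Cys gene has no TGA
  expect_true(mcols(res)$selected)
  expect_equal(mcols(res)$nCysHits, 3L)
})
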