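mkGenome <- function(...) makeGenome(list(...))

test_that("a planted gene is recovered at exact coordinates", {
  g <- mkGenome(contigs = c(chr = 6000L), seed = 21L,
                planted = list(list(model = "eukaryota", strand = "+",
                                    at = 2500L)))
  hits <- scanGenome(g$genome)
  expect_equal(length(hits), 1L)
  expect_equal(start(hits), g$truth$start + 1L)  # truth is 0-based half-open
  expect_equal(end(hits), g$truth$end)
  expect_equal(as.character(strand(hits)), "+")
  expect_equal(mcols(hits)$domain, "eukaryota")
  ## coordinates round-trip: the extracted genomic sequence is the matched
  ## sequence
  sq <- substr(g$genome[["chr"]], start(hits), end(hits))
  expect_identical(chartr("T", "U", sq), mcols(hits)$matchedSeq[1])
})

test_that("a reverse-strand gene maps to the same locus with strand minus", {
  g <- mkGenome(contigs = c(chr = 4000L), seed = 22L,
                planted = list(list(model = "bacteria", strand = "-",
                                    at = 1500L)))
  hits <- scanGenome(g$genome)
  expect_equal(length(hits), 1L)
  expect_equal(as.character(strand(hits)), "-")
  expect_equal(start(hits), g$truth$start + 1L)
  expect_equal(end(hits), g$truth$end)
  sq <- secScan:::revComp(substr(g$genome[["chr"]], start(hits), end(hits)))
  expect_identical(chartr("T", "U", sq), mcols(hits)$matchedSeq[1])
})

test_that("a signal-free random genome yields no hits at the default threshold", {
  g <- mkGenome(contigs = c(c1 = 50000L), seed = 7L, planted = list())
  hits <- scanGenome(g$genome)
  expect_equal(length(hits), 0L)
})

test_that("threshold raising is monotone and never adds hits", {
  g <- mkGenome(contigs = c(chr = 3000L), seed = 23L,
                planted = list(list(model = "archaea", strand = "+",
                                    at = 1200L)))
  h40 <- scanGenome(g$genome, config = ScanConfig(threshold = 40))
  h60 <- scanGenome(g$genome, config = ScanConfig(threshold = 60,
                                                  stringentThreshold = 60))
  h999 <- scanGenome(g$genome, config = ScanConfig(threshold = 500,
                                                   stringentThreshold = 500))
  expect_true(all(paste(start(h60), end(h60)) %in% paste(start(h40), end(h40))))
  expect_equal(length(h999), 0L)
})

test_that("scanning a concatenation equals the union of per-contig scans", {
  g <- mkGenome(contigs = c(a = 2000L, b = 2000L), seed = 24L,
                planted = list(list(model = "eukaryota", contig = 1L,
                                    strand = "+", at = 700L),
                               list(model = "bacteria", contig = 2L,
                                    strand = "-", at = 900L)))
  joint <- scanGenome(g$genome)
  sep <- suppressWarnings(   # combining GRanges with disjoint seqlevels
    c(scanGenome(g$genome["a"]), scanGenome(g$genome["b"])))
  expect_equal(length(joint), length(sep))
  expect_equal(sort(paste(seqnames(joint), start(joint), end(joint))),
               sort(paste(seqnames(sep), start(sep), end(sep))))
})

test_that("overlap resolution keeps the maximum-score hit per locus", {
  gr <- GRanges("c", IRanges(c(100, 150), c(200, 260)), strand = "+",
                score = c(62.1, 55.0), domain = c("eukaryota", "bacteria"))
  out <- resolveOverlaps(gr)
  expect_equal(length(out), 1L)
  expect_equal(mcols(out)$score, 62.1)
  ## opposite strands at the same coordinates both survive
  gr2 <- GRanges("c", IRanges(c(100, 100), c(200, 200)), strand = c("+", "-"),
                 score = c(50, 45), domain = c("eukaryota", "eukaryota"))
  expect_equal(length(resolveOverlaps(gr2)), 2L)
})

test_that("score ties break by length, then domain order, then start", {
  gr <- GRanges("c", IRanges(c(100, 100), c(200, 190)), strand = "+",
                score = c(50, 50), domain = c("bacteria", "eukaryota"))
  expect_equal(width(resolveOverlaps(gr)), 101L)  # longer wins
  gr2 <- GRanges("c", IRanges(c(100, 100), c(200, 200)), strand = "+",
                 score = c(50, 50), domain = c("archaea", "eukaryota"))
  expect_equal(mcols(resolveOverlaps(gr2))$domain, "eukaryota")
  gr3 <- GRanges("c", IRanges(c(102, 100), c(201, 199)), strand = "+",
                 score = c(50, 50), domain = c("eukaryota", "eukaryota"))
  expect_equal(start(resolveOverlaps(gr3)), 100L)
})

test_that("cluster domain assignment is the argmax and identity on singletons", {
  gr <- GRanges("c", IRanges(c(1, 1), c(90, 90)), strand = "+",
                score = c(71.2, 58.9), domain = c("eukaryota", "bacteria"))
  expect_equal(assignDomain(gr), "eukaryota")
  expect_equal(assignDomain(gr[2]), "bacteria")
  expect_error(assignDomain(gr[0]), "empty")
})

test_that("genomes sampled from one model are tagged with that domain", {
  ok <- vapply(1:50, function(s) {
    g <- mkGenome(contigs = c(x = 320L), seed = 3000L + s,
                  planted = list(list(model = "bacteria", strand = "+")))
    hits <- scanGenome(g$genome)
    length(hits) >= 1L && mcols(hits)$domain[which.max(mcols(hits)$score)] ==
      "bacteria"
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("short contigs are skipped with a warning, empty genomes error", {
  tiny <- c(stub = paste(rep("ACGT", 10), collapse = ""))
  w <- capture_warnings(scanGenome(tiny))
  expect_true(length(w) >= 1 && all(grepl("skipped", w)))
  expect_error(scanGenome(character(0)), "genome")
  expect_error(scanGenome(c(a = "ACGT", a = "ACGT")), "duplicate")
})
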