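test_that("FASTA files round-trip across wrapping and case", {
  seqs <- c(c1 = strrep("ACGTACGTAA", 20), c2 = strrep("GGGTTTACCA", 15),
            c3 = "ACGTN")
  fa <- tempfile(fileext = ".fa")
  writeFastaFile(seqs, fa, width = 17)
  expect_identical(readFastaFile(fa), seqs)
  writeLines(c(">a", "acgTT", ">a", "ACGTT"), fa)
  expect_error(readFastaFile(fa), "duplicate")
})

test_that("coordinate conventions: truth BED vs GFF3 vs BED6 output", {
  spec <- list(contigs = c(ctg = 1800L), seed = 88L,
               planted = list(list(model = "bacteria", strand = "+",
                                   at = 600L)))
  out <- tempfile()
  res <- cliSimulate(spec, out)
  expect_true(all(file.exists(file.path(out, c("genome.fa", "truth.bed",
                                               "truth.tsv")))))
  cands <- suppressMessages(
    cliSearch(file.path(out, "genome.fa"), out))
  expect_equal(length(cands), 1L)
  gff <- readLines(file.path(out, "trnasec.gff3"))
  expect_equal(gff[1], "##gff-version 3")
  f <- strsplit(gff[2], "\t")[[1]]
  bed <- strsplit(readLines(file.path(out, "trnasec.bed"))[1], "\t")[[1]]
  truth <- read.delim(file.path(out, "truth.tsv"))
  ## GFF3 is 1-based inclusive; BED and the truth table are 0-based
  expect_equal(as.integer(f[4]), truth$start + 1L)
  expect_equal(as.integer(f[5]), truth$end)
  expect_equal(as.integer(bed[2]), as.integer(f[4]) - 1L)
  expect_equal(as.integer(bed[3]), as.integer(f[5]))
  expect_match(f[9], "g73=true")
  expect_match(f[9], "anticodon=UCA")
  expect_match(f[9], "cca=true")      # bacterial gene: genomic CCA
  ## TSV summary has one row per candidate
  tsv <- read.delim(file.path(out, "trnasec.tsv"))
  expect_equal(nrow(tsv), 1L)
  expect_equal(tsv$fold, "8/5")
})

test_that("the -T semantics remove borderline candidates", {
  ## construct a degraded gene scoring between 40 and 55 bits with an
  ## intact UCA anticodon, then verify it disappears at T = 55
  m <- bundledModel("eukaryota")
  found <- NULL
  for (s in 1:40) {
    smp <- sampleTrna(m, seed = 500 + s)
    mut <- mutateSeq(smp$seq, subRate = 0.18, seed = 600 + s, mode = "random")
    sc <- scoreSequence(m, mut)$score
    if (sc > 42 && sc < 53) {
      r <- scoreSequence(m, mut)
      if (identical(extractAnticodon(r$parse, m, mut), "UCA")) {
        found <- mut; break
      }
    }
  }
  expect_false(is.null(found))
  set.seed(999)
  bg <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  genome <- c(ctg = paste0(substr(bg, 1, 600), chartr("U", "T", found), "G",
                           substr(bg, 601, 1200)))
  out1 <- tempfile(); out2 <- tempfile()
  fa <- tempfile(fileext = ".fa")
  writeFastaFile(genome, fa)
  c1 <- suppressMessages(cliSearch(fa, out1))
  expect_equal(length(c1), 1L)
  c2 <- suppressMessages(cliSearch(fa, out2, threshold = 55))
  expect_equal(length(c2), 0L)
  expect_equal(length(readLines(file.path(out2, "trnasec.gff3"))), 1L)
})

test_that("cloverleaf rendering is deterministic and marks the motifs", {
  g <- makeGenome(list(contigs = c(chr = 1500L), seed = 91L,
                       planted = list(list(model = "eukaryota",
                                           strand = "+", at = 500L))))
  cands <- searchTrnaSec(g$genome)
  m <- bundledModel("eukaryota")
  txt1 <- renderCloverleaf(cands[1], m)
  txt2 <- renderCloverleaf(cands[1], m)
  expect_identical(txt1, txt2)                  # byte-identical across runs
  expect_true(any(grepl("\\[U C A\\]", txt1))) # anticodon bracketed
  expect_true(any(grepl("discriminator: \\(G\\) = G73", txt1)))
  expect_true(any(grepl("^A-stem", txt1)))
  svg <- tempfile(fileext = ".svg")
  renderCloverleaf(cands[1], m, svgPath = svg)
  doc <- readLines(svg)
  expect_match(doc[1], "<svg")
  ## five arm colour groups present
  for (col in unique(secScan:::ARM_COLORS[c("A-stem", "D-stem", "C-stem",
                                            "V-stem", "T-stem")]))
    expect_true(any(grepl(col, doc, fixed = TRUE)))
  ## anticodon (3 circles) + discriminator circled
  expect_gte(sum(grepl('stroke="black" stroke-width="2"', doc)), 4L)
})

test_that("the --plot flag writes one SVG per candidate", {
  g <- makeGenome(list(contigs = c(chr = 1500L), seed = 92L,
                       planted = list(list(model = "archaea",
                                           strand = "-", at = 400L))))
  fa <- tempfile(fileext = ".fa")
  writeFastaFile(g$genome, fa)
  out <- tempfile()
  cands <- suppressMessages(cliSearch(fa, out, plot = TRUE))
  svgs <- list.files(out, pattern = "\\.svg$")
  expect_equal(length(svgs), length(cands))
})
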