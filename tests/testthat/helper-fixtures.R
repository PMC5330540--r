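suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## small cloverleaf toy alignment: 4 stems of 2 bp inside a 2-bp acceptor
## stem -- the smallest topology the structure annotator accepts
toyAlignment <- function() {
  ss <- "<<..<<....>>.<<....>>.<<....>>.<<....>>..>>"
  rows <- c("GGAACCGAAAGGUGCGAAAGCACGGAAACGAGGGAAACCCAUU",
            "GGAACCGUAAGGUGCGAUAGCACGGAUACGAGGGAUACCCAUU",
            "GGUACCGAAAGGUGCGAAAGCACGGAAACGAGGGAAACCCAUA",
            "GGAACCGAUAGGUGCGAAAGCACGGACACGAGGGAAACCCAUU")
  new("SeedAlignment", ids = sprintf("t%d", seq_along(rows)), seqs = rows,
      ssCons = ss, positionLabels = character(0), domainTag = "eukaryota")
}

.toyModelCache <- new.env()
toyModel <- function() {
  if (is.null(.toyModelCache$m)) .toyModelCache$m <- buildModel(toyAlignment())
  .toyModelCache$m
}

## independent maximum-parse oracle: plain recursion over the model's states
## and log-odds (memoised), structurally unrelated to the C++ DP
oracleScore <- function(model, seq) {
  p <- model@params
  x <- secScan:::encodeSeqString(seq)
  memo <- new.env(hash = TRUE)
  esS <- function(v, b) if (b >= 4) 0 else p$escS[v, b + 1]
  esP <- function(v, a, b) if (a >= 4 || b >= 4) 0 else p$escP[v, a * 4 + b + 1]
  nodesDF <- model@nodes
  bifChildren <- function(v) {
    nd <- p$stNode[v]
    row <- which(nodesDF$id == nd)
    c(which(p$stNode == nodesDF$child1[row] & p$stType == "S"),
      which(p$stNode == nodesDF$child2[row] & p$stType == "S"))
  }
  rec <- function(v, i, j) {
    key <- paste(v, i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    tp <- p$stType[v]
    d <- j - i + 1
    val <- -Inf
    if (tp == "E") {
      val <- if (d <= 0) 0 else -Inf
    } else if (tp == "B") {
      bc <- bifChildren(v)
      for (k in (i - 1):j)
        val <- max(val, rec(bc[1], i, k) + rec(bc[2], k + 1, j))
    } else if (tp %in% c("S", "D")) {
      for (ci in seq_along(p$children[[v]]))
        val <- max(val, p$tSc[[v]][ci] + rec(p$children[[v]][ci], i, j))
    } else if (tp %in% c("ML", "IL")) {
      if (d >= 1)
        for (ci in seq_along(p$children[[v]]))
          val <- max(val, esS(v, x[i]) + p$tSc[[v]][ci] +
                       rec(p$children[[v]][ci], i + 1, j))
    } else if (tp %in% c("MR", "IR")) {
      if (d >= 1)
        for (ci in seq_along(p$children[[v]]))
          val <- max(val, esS(v, x[j]) + p$tSc[[v]][ci] +
                       rec(p$children[[v]][ci], i, j - 1))
    } else if (tp == "MP") {
      if (d >= 2)
        for (ci in seq_along(p$children[[v]]))
          val <- max(val, esP(v, x[i], x[j]) + p$tSc[[v]][ci] +
                       rec(p$children[[v]][ci], i + 1, j - 1))
    }
    memo[[key]] <- val
    val
  }
  rec(1L, 1L, length(x))
}

## brute-force maximum base-pair count (independent of foldSequence)
bruteMaxPairs <- function(seq, minLoop = 3L) {
  x <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i >= j || j - i <= minLoop) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i + 1L, j)
    for (k in (i + minLoop + 1L):j) {
      if (basesPair(x[i], x[k]))
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, length(x))
}

## consensus (most probable match emissions) sequence of a model
modelConsensusSeq <- function(model) {
  p <- model@params
  K <- model@consensusLength
  bases <- character(K)
  ntype <- model@nodes$type[match(model@states$node, model@nodes$id)]
  for (v in seq_along(p$stType)) {
    if (p$stType[v] == "MP") {
      cell <- which.max(p$eprP[v, ]) - 1L
      bases[p$emitLcol[v]] <- secScan:::NUC[cell %/% 4L + 1L]
      bases[p$emitRcol[v]] <- secScan:::NUC[cell %% 4L + 1L]
    } else if (p$stType[v] == "ML" && ntype[v] == "MATL") {
      bases[p$emitLcol[v]] <- secScan:::NUC[which.max(p$eprS[v, ])]
    } else if (p$stType[v] == "MR" && ntype[v] == "MATR") {
      bases[p$emitRcol[v]] <- secScan:::NUC[which.max(p$eprS[v, ])]
    }
  }
  paste(bases, collapse = "")
}

## random iid sequence
randSeq <- function(n, seed, alphabet = c("A", "C", "G", "U")) {
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## a minimal annotated candidate GRanges row for unit tests
fakeCandidate <- function(contig = "c1", start = 101, end = 190,
                          strand = "+", score = 60, domain = "eukaryota",
                          anticodon = "UCA", matureSeq = NULL) {
  gr <- GRanges(contig, IRanges(start, end), strand = strand)
  mcols(gr)$score <- score
  mcols(gr)$domain <- domain
  mcols(gr)$anticodon <- anticodon
  if (!is.null(matureSeq)) mcols(gr)$matureSeq <- matureSeq
  gr
}
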