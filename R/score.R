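TYPE_CODE <- c(S = 0L, D = 1L, E = 2L, ML = 3L, MR = 4L, MP = 5L,
               IL = 6L, IR = 7L, B = 8L)

## flatten model parameters for the C++ kernel (0-based indices)
flatCM <- function(model) {
  p <- model@params
  S <- length(p$stType)
  cN <- vapply(p$children, length, integer(1))
  cOff <- c(0L, cumsum(cN))[seq_len(S)]
  cIdx <- as.integer(unlist(p$children, use.names = FALSE)) - 1L
  if (is.null(cIdx)) cIdx <- integer(0)
  cSc <- as.numeric(unlist(p$tSc, use.names = FALSE))
  if (is.null(cSc)) cSc <- numeric(0)
  bL <- rep(-1L, S); bR <- rep(-1L, S)
  bifs <- which(p$stType == "B")
  for (s in bifs) {
    nd <- p$stNode[s]
    row <- which(model@nodes$id == nd)
    beglS <- which(p$stNode == model@nodes$child1[row] & p$stType == "S")
    begrS <- which(p$stNode == model@nodes$child2[row] & p$stType == "S")
    bL[s] <- beglS - 1L; bR[s] <- begrS - 1L
  }
  list(type = unname(TYPE_CODE[p$stType]), cOff = cOff, cN = cN, cIdx = cIdx,
       cSc = cSc, escS = as.numeric(t(p$escS)), escP = as.numeric(t(p$escP)),
       bL = bL, bR = bR, consSpan = p$consSpan)
}

## Per-state parse-length bands: consensus subtree span +/- slack. The wide
## insert slack (bandIns, intron-sized) is only needed for states whose
## subtree contains the canonical intron point (position 37); elsewhere a
## small slack covers ordinary bulges and the V-arm insert region.
cmBands <- function(model, flat, bandDel, bandIns, W, smallIns = 12L) {
  p <- model@params
  S <- length(flat$type)
  c37 <- match("37", model@positionMap)
  wide <- if (is.na(c37)) rep(TRUE, S) else
    p$subtreeLo <= c37 & p$subtreeHi >= c37
  ins <- ifelse(wide, as.integer(bandIns), as.integer(smallIns))
  dmin <- pmax(0L, flat$consSpan - as.integer(bandDel))
  dmax <- pmin(flat$consSpan + ins, as.integer(W))
  e <- flat$type == TYPE_CODE[["E"]]
  dmin[e] <- 0L; dmax[e] <- 0L
  list(dmin = as.integer(dmin), dmax = as.integer(dmax))
}

encodeSeqString <- function(seq) {
  chars <- strsplit(toupper(chartr("Tt", "Uu", seq)), "")[[1]]
  code <- encodeNuc(chars)
  if (anyNA(code)) stop("sequence contains characters outside A,C,G,T/U,N")
  code
}

#' Score a sequence against a covariance model
#'
#' Computes the maximum-score CYK parse of the full sequence against the
#' model (global in the model) and returns the bit score with the traceback
#' parse. T and U are equivalent; N emits at the null (0 bits).
#'
#' @param model a \linkS4class{CovarianceModel}.
#' @param seq a nucleotide string (or \code{Biostrings} XString).
#' @return list with elements \code{score} (bits) and \code{parse}; the parse
#'   has \code{colPos} (1-based sequence position emitted at each match
#'   column, NA when deleted), \code{pairUsed} (logical per match column:
#'   emitted by a pair-match state), and \code{inserts}
#'   (data.frame afterCol/pos: insertions anchored 3' of a consensus column,
#'   0 = before the first column).
#' @export
scoreSequence <- function(model, seq) {
  seq <- as.character(seq)
  if (!nzchar(seq)) stop("empty sequence")
  x <- encodeSeqString(seq)
  flat <- flatCM(model)
  n <- length(x)
  S <- length(flat$type)
  dmin <- rep(0L, S); dmax <- rep(n, S)
  e <- flat$type == TYPE_CODE[["E"]]
  dmin[e] <- 0L; dmax[e] <- 0L
  res <- .cm_align(flat$type, flat$cOff, flat$cN, flat$cIdx, flat$cSc,
                   flat$escS, flat$escP, flat$bL, flat$bR,
                   dmin, dmax, as.integer(x))
  parse <- interpretTrace(model, res)
  list(score = res$score, parse = parse)
}

## convert a C++ traceback into match-column positions and insert records
interpretTrace <- function(model, res) {
  p <- model@params
  K <- model@consensusLength
  colPos <- rep(NA_integer_, K)
  pairUsed <- rep(FALSE, K)
  insAfter <- integer(0); insPos <- integer(0)
  st <- res$state
  for (k in seq_along(st)) {
    v <- st[k]; tp <- p$stType[v]
    if (tp == "MP") {
      lc <- p$emitLcol[v]; rc <- p$emitRcol[v]
      colPos[lc] <- res$i[k]; colPos[rc] <- res$j[k]
      pairUsed[lc] <- TRUE; pairUsed[rc] <- TRUE
    } else if (tp == "ML") {
      colPos[p$emitLcol[v]] <- res$i[k]
    } else if (tp == "MR") {
      colPos[p$emitRcol[v]] <- res$j[k]
    } else if (tp == "IL") {
      insAfter <- c(insAfter, p$insAfterCol[v]); insPos <- c(insPos, res$i[k])
    } else if (tp == "IR") {
      insAfter <- c(insAfter, p$insAfterCol[v]); insPos <- c(insPos, res$j[k])
    }
  }
  ord <- order(insPos)
  list(colPos = colPos, pairUsed = pairUsed,
       inserts = data.frame(afterCol = insAfter[ord], pos = insPos[ord]))
}

## raw banded scan of one sequence chunk: per-start best parse >= thresh
cmScanChunk <- function(model, x, config) {
  flat <- flatCM(model)
  W <- model@consensusLength + config@windowPad
  b <- cmBands(model, flat, config@bandDel, config@bandIns, W)
  .cm_scan(flat$type, flat$cOff, flat$cN, flat$cIdx, flat$cSc,
           flat$escS, flat$escP, flat$bL, flat$bR, b$dmin, b$dmax,
           as.integer(x), config@threshold)
}
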