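#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps
#' @importFrom IRanges IRanges
NULL

## accept named character, DNAStringSet, or FASTA path
asContigs <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readFastaFile(genome)
  if (methods::is(genome, "DNAStringSet") || methods::is(genome, "RNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector, DNAStringSet or FASTA path")
  if (!length(genome)) stop("empty genome")
  if (anyDuplicated(names(genome))) stop("duplicate contig ids")
  toupper(genome)
}

#' Scan a genome with tRNA-Sec covariance models
#'
#' Evaluates every start position on both strands of every contig with each
#' model (banded CYK, maximum parse length = consensus length + window pad)
#' and reports hits whose bit score reaches the threshold. Reverse-strand
#' hits are mapped back to forward coordinates. With \code{resolve = TRUE}
#' (the default) overlapping hits are collapsed per locus to the single
#' highest-scoring one and each surviving hit is re-aligned to its model to
#' attach the parse.
#'
#' Softmasked (lowercase) sequence is uppercased; N runs are scanned and
#' score 0 bits per N.
#'
#' @param genome named character vector of contigs, a
#'   \code{Biostrings::DNAStringSet}, or a FASTA path.
#' @param models list of \linkS4class{CovarianceModel}s (default: the three
#'   bundled domain models).
#' @param config a \linkS4class{ScanConfig}.
#' @param resolve collapse overlapping hits and attach parses.
#' @param chunkSize DP chunk length (memory/speed trade-off; results are
#'   independent of chunking).
#' @return A \code{GRanges} with mcols \code{score}, \code{domain}, and when
#'   resolved \code{matchedSeq} (hit-orientation RNA) and \code{parse}.
#' @export
scanGenome <- function(genome, models = bundledSearchModels(),
                       config = ScanConfig(), resolve = TRUE,
                       chunkSize = 1000L) {
  contigs <- asContigs(genome)
  if (!length(models)) stop("at least one model required")
  if (is.null(names(models)))
    names(models) <- vapply(models, domainTag, character(1))
  out <- list()
  for (cn in names(contigs)) {
    cseq <- contigs[[cn]]
    L <- nchar(cseq)
    for (mi in seq_along(models)) {
      model <- models[[mi]]
      minParse <- max(1L, model@consensusLength - config@bandDel)
      if (L < minParse) {
        warning("contig ", cn, " shorter than the minimum parse of model ",
                domainTag(model), "; skipped")
        next
      }
      W <- model@consensusLength + config@windowPad
      for (str in config@strands) {
        s <- if (str == "+") cseq else revComp(cseq)
        x <- encodeSeqString(s)
        hits <- scanSeqChunked(model, x, config, chunkSize, W)
        if (!nrow(hits)) next
        ## map back to forward-strand coordinates (1-based inclusive)
        if (str == "-") {
          st <- L - hits$end + 1L
          en <- L - hits$start + 1L
          hits$start <- st; hits$end <- en
        }
        out[[length(out) + 1L]] <- data.frame(
          contig = cn, start = hits$start, end = hits$end, strand = str,
          score = hits$score, domain = domainTag(model))
      }
    }
  }
  if (!length(out)) {
    gr <- GRanges()
    mcols(gr)$score <- numeric(0); mcols(gr)$domain <- character(0)
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GRanges(df$contig, IRanges(df$start, df$end), strand = df$strand,
                score = df$score, domain = df$domain)
  gr <- gr[order(as.character(seqnames(gr)), start(gr),
                 as.character(strand(gr)), -mcols(gr)$score)]
  if (resolve) {
    gr <- resolveOverlaps(gr)
    gr <- attachParses(gr, contigs, models)
  }
  gr
}

scanSeqChunked <- function(model, x, config, chunkSize, W) {
  L <- length(x)
  C <- max(as.integer(chunkSize), 3L * W)
  step <- C - (W - 1L)
  res <- list()
  s0 <- 1L
  repeat {
    e0 <- min(L, s0 + C - 1L)
    h <- cmScanChunk(model, x[s0:e0], config)
    if (nrow(h)) {
      keep <- h$start <= step | e0 == L
      h <- h[keep, , drop = FALSE]
      h$start <- h$start + s0 - 1L
      h$end <- h$end + s0 - 1L
      res[[length(res) + 1L]] <- h
    }
    if (e0 == L) break
    s0 <- s0 + step
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  out <- do.call(rbind, res)
  out[!duplicated(out$start), , drop = FALSE]
}

DOMAIN_ORDER <- c(eukaryota = 1L, bacteria = 2L, archaea = 3L, canonical = 4L)

#' Resolve overlapping hits, keeping the best per locus
#'
#' Clusters of hits that overlap by at least one nucleotide on the same
#' strand are collapsed to their maximum-score member. Ties are broken by
#' longer interval, then domain order (eukaryota < bacteria < archaea), then
#' leftmost start.
#'
#' @param hits a \code{GRanges} with mcols \code{score} and \code{domain}.
#' @return the surviving \code{GRanges} subset.
#' @export
resolveOverlaps <- function(hits) {
  if (!length(hits)) return(hits)
  ov <- findOverlaps(hits, hits, minoverlap = 1L, ignore.strand = FALSE)
  ## connected components
  comp <- seq_along(hits)
  repeat {
    newComp <- comp
    for (k in seq_along(ov)) {
      a <- S4Vectors::queryHits(ov)[k]; b <- S4Vectors::subjectHits(ov)[k]
      m <- min(newComp[a], newComp[b])
      newComp[a] <- m; newComp[b] <- m
    }
    if (identical(newComp, comp)) break
    comp <- newComp
  }
  keep <- vapply(split(seq_along(hits), comp), function(idx) {
    sc <- mcols(hits)$score[idx]
    w <- width(hits)[idx]
    dord <- DOMAIN_ORDER[mcols(hits)$domain[idx]]
    st <- start(hits)[idx]
    idx[order(-sc, -w, dord, st)][1]
  }, integer(1))
  sort(hits[sort(unname(keep))])
}

#' Domain label of an overlap cluster
#'
#' The domain of a locus hit by several models is that of the
#' maximum-score member.
#'
#' @param cluster a non-empty \code{GRanges} with mcols \code{score},
#'   \code{domain}.
#' @return character(1) domain tag.
#' @export
assignDomain <- function(cluster) {
  if (!length(cluster)) stop("empty cluster")
  mcols(cluster)$domain[which.max(mcols(cluster)$score)]
}

## re-align resolved hits to their models to obtain parses
attachParses <- function(gr, contigs, models) {
  byTag <- stats::setNames(models, vapply(models, domainTag, character(1)))
  seqs <- character(length(gr)); parses <- vector("list", length(gr))
  scores <- numeric(length(gr))
  for (k in seq_along(gr)) {
    cn <- as.character(seqnames(gr))[k]
    sq <- substr(contigs[[cn]], start(gr)[k], end(gr)[k])
    if (as.character(strand(gr))[k] == "-") sq <- revComp(sq)
    sq <- chartr("T", "U", sq)
    mdl <- byTag[[mcols(gr)$domain[k]]]
    r <- scoreSequence(mdl, sq)
    seqs[k] <- sq
    parses[[k]] <- r$parse
    scores[k] <- r$score
  }
  mcols(gr)$score <- scores
  mcols(gr)$matchedSeq <- seqs
  mcols(gr)$parse <- I(parses)
  gr
}
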