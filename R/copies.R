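## Classification of additional tRNA-Sec gene copies against the top-scoring
## candidate of the same genome: assembly-artifact duplicates (identical
## including flanks), neutral copies, copies with compensatory pair
## mutations, and copies with structure-disrupting mutations.

extractWithFlanks <- function(gr, k, contigs, flank) {
  cn <- as.character(seqnames(gr))[k]
  L <- nchar(contigs[[cn]])
  a <- max(1L, start(gr)[k] - flank)
  b <- min(L, end(gr)[k] + flank)
  sq <- substr(contigs[[cn]], a, b)
  if (as.character(strand(gr))[k] == "-") sq <- revComp(sq)
  chartr("T", "U", toupper(sq))
}

pairBasesFromParse <- function(model, parse, seq) {
  mp <- model@matchPair
  i5 <- which(!is.na(mp) & mp > seq_along(mp))
  chars <- strsplit(chartr("T", "U", seq), "")[[1]]
  baseAt <- function(col) {
    p <- parse$colPos[col]
    if (is.na(p)) NA_character_ else chars[p]
  }
  data.frame(col5 = i5, col3 = mp[i5],
             b5 = vapply(i5, baseAt, character(1)),
             b3 = vapply(mp[i5], baseAt, character(1)))
}

#' Classify a tRNA-Sec gene copy against the top-scoring candidate
#'
#' Both candidates are aligned to the same model; each consensus pair is
#' classified: \emph{compensatory} when both copies form a Watson-Crick/GU
#' pair but both partner bases differ; \emph{disrupted} when the pairing
#' status differs between the two copies (or neither pairs, or a partner is
#' deleted); \emph{equivalent} otherwise. The per-pair classes are symmetric
#' in the two candidates. Overall: \code{identical} when the sequences match
#' exactly including \code{flank} nucleotides of genomic context;
#' \code{disrupted} when at least one pair is disrupted; \code{compensatory}
#' when at least one pair is compensatory and none disrupted; otherwise
#' \code{equivalent}.
#'
#' @param copy,top single-row annotated candidate \code{GRanges} (with
#'   \code{matureSeq} and \code{parse} mcols) from the same genome.
#' @param model the \linkS4class{CovarianceModel} both are aligned to.
#' @param genome the genome both candidates live in.
#' @param flank flanking nucleotides for the identity test (default 100).
#' @return list: \code{class}, \code{perPair} (data.frame col5, col3,
#'   topBases, copyBases, class).
#' @export
classifyCopy <- function(copy, top, model, genome, flank = 100L) {
  contigs <- asContigs(genome)
  for (gr in list(copy, top)) {
    cn <- as.character(seqnames(gr))[1]
    if (!cn %in% names(contigs))
      stop("candidates from different genomes: contig ", cn, " not found")
  }
  idTop <- extractWithFlanks(top, 1L, contigs, flank)
  idCopy <- extractWithFlanks(copy, 1L, contigs, flank)
  alTop <- scoreSequence(model, mcols(top)$matureSeq[1])
  alCopy <- scoreSequence(model, mcols(copy)$matureSeq[1])
  pt <- pairBasesFromParse(model, alTop$parse, mcols(top)$matureSeq[1])
  pc <- pairBasesFromParse(model, alCopy$parse, mcols(copy)$matureSeq[1])
  perPair <- data.frame(col5 = pt$col5, col3 = pt$col3,
                        topBases = paste0(pt$b5, pt$b3),
                        copyBases = paste0(pc$b5, pc$b3))
  cls <- character(nrow(perPair))
  for (r in seq_len(nrow(perPair))) {
    t5 <- pt$b5[r]; t3 <- pt$b3[r]; c5 <- pc$b5[r]; c3 <- pc$b3[r]
    if (anyNA(c(t5, t3, c5, c3))) { cls[r] <- "disrupted"; next }
    if (t5 == c5 && t3 == c3) { cls[r] <- "equivalent"; next }
    pT <- basesPair(t5, t3); pC <- basesPair(c5, c3)
    cls[r] <- if (pT && pC) {
      if (c5 != t5 && c3 != t3) "compensatory" else "equivalent"
    } else "disrupted"   # pairing lost, gained, or absent in both yet changed
  }
  perPair$class <- cls
  overall <- if (identical(idTop, idCopy)) "identical"
    else if (any(cls == "disrupted")) "disrupted"
    else if (any(cls == "compensatory")) "compensatory"
    else "equivalent"
  list(class = overall, perPair = perPair)
}
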