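## Candidate annotation: arm architecture, anticodon, thresholds,
## discriminator base, CCA tail, fold class, introns.

STEMS <- c("A-stem", "D-stem", "C-stem", "V-stem", "T-stem")

#' Arm architecture realized by a hit's parse
#'
#' Counts, per stem, the consensus pairs actually emitted as pairs by the
#' parse, realized loop lengths, and insertions inside stems (bulges),
#' labelled with the tRNA position of the consensus column they follow.
#'
#' @param parse a parse as returned by \code{\link{scoreSequence}}.
#' @param model the \linkS4class{CovarianceModel} the parse was made with.
#' @return list: \code{pairs} (named integer, realized pairs per stem),
#'   \code{loops} (named integer, realized loop lengths), \code{atTotal}
#'   (A-stem + T-stem pairs), \code{bulges} (data.frame label/afterCol/n).
#' @export
parseArms <- function(parse, model) {
  arm <- model@matchArm
  mp <- model@matchPair
  pairs <- vapply(STEMS, function(s) {
    i5 <- which(arm == s & !is.na(mp) & mp > seq_along(mp))
    sum(parse$pairUsed[i5])
  }, integer(1))
  loops <- vapply(c("D-loop", "C-loop", "V-loop", "T-loop"), function(s) {
    sum(!is.na(parse$colPos[arm == s]))
  }, integer(1))
  ins <- parse$inserts
  bulges <- data.frame(label = character(0), afterCol = integer(0),
                       n = integer(0))
  if (nrow(ins)) {
    byCol <- table(ins$afterCol)
    ac <- as.integer(names(byCol))
    inStem <- ac >= 1 & ac < length(arm) &
      arm[pmax(ac, 1)] %in% STEMS & arm[pmin(ac + 1L, length(arm))] ==
      arm[pmax(ac, 1)]
    if (any(inStem)) {
      lab <- paste0(model@positionMap[ac[inStem]], "a")
      bulges <- data.frame(label = lab, afterCol = ac[inStem],
                           n = as.integer(byCol[inStem]))
    }
  }
  list(pairs = pairs, loops = loops,
       atTotal = unname(pairs["A-stem"] + pairs["T-stem"]), bulges = bulges)
}

#' Anticodon triplet of a parse
#'
#' The bases aligned to the consensus columns with position labels 34-36,
#' reported in the RNA alphabet; undefined (NA) when any of the three is
#' deleted in the parse.
#'
#' @param parse,model as in \code{\link{parseArms}}.
#' @param seq the matched sequence (hit orientation).
#' @return character(1) 3-mer or NA.
#' @export
extractAnticodon <- function(parse, model, seq) {
  ac <- match(c("34", "35", "36"), model@positionMap)
  if (anyNA(ac)) return(NA_character_)
  pos <- parse$colPos[ac]
  if (anyNA(pos)) return(NA_character_)
  paste(strsplit(chartr("T", "U", seq), "")[[1]][pos], collapse = "")
}

#' Fold class from arm pair counts
#'
#' @param aPairs,tPairs realized (or consensus) acceptor and T-stem pair
#'   counts.
#' @return list: \code{label} in \{"9/4","8/5","7/5","other"\} and
#'   \code{atTotal}.
#' @export
classifyFold <- function(aPairs, tPairs) {
  label <- if (aPairs == 9 && tPairs == 4) "9/4"
    else if (aPairs == 8 && tPairs == 5) "8/5"
    else if (aPairs == 7 && tPairs == 5) "7/5"
    else "other"
  list(label = label, atTotal = aPairs + tPairs)
}

## genomic position (1-based, forward strand) of the k-th residue 3' of a
## hit-oriented position p (offset 0 = that residue)
genomicOffset <- function(gr, k, p, offset) {
  if (as.character(strand(gr))[k] == "+") start(gr)[k] + p - 1L + offset
  else end(gr)[k] - p + 1L - offset
}

readGenomeBase <- function(contigs, cn, gpos, strandChar) {
  if (gpos < 1L || gpos > nchar(contigs[[cn]])) return(NA_character_)
  b <- toupper(substr(contigs[[cn]], gpos, gpos))
  if (strandChar == "-") b <- chartr("ACGTU", "TGCAA", b)
  chartr("T", "U", b)
}

#' Locate the discriminator base (position 73)
#'
#' The discriminator is not a model column. Following the 13-bp AT-stem
#' geometry, it is found as the 14th genomic residue 3' of the residue
#' aligned to tRNA position 61, read from the genome in hit orientation --
#' independent of the number of acceptor-stem pairs realized by the parse.
#' Undefined when position 61 is deleted or the contig ends first. For 7/5
#' (12-bp AT-stem) folds this fixed offset lands one base 3' of the
#' structurally correct discriminator; such candidates are flagged via their
#' fold label.
#'
#' @param gr annotated hits \code{GRanges} (with parse mcols).
#' @param k hit index.
#' @param contigs named character contigs.
#' @param model the hit's model.
#' @return list \code{base}, \code{gpos} or NULL when undefined.
#' @export
findDiscriminator <- function(gr, k, contigs, model) {
  c61 <- match("61", model@positionMap)
  if (is.na(c61)) return(NULL)
  p61 <- mcols(gr)$parse[[k]]$colPos[c61]
  if (is.na(p61)) return(NULL)
  cn <- as.character(seqnames(gr))[k]
  gpos <- genomicOffset(gr, k, p61, 14L)
  b <- readGenomeBase(contigs, cn, gpos, as.character(strand(gr))[k])
  if (is.na(b)) return(NULL)
  list(base = b, gpos = gpos)
}

#' Is the CCA tail genomically encoded?
#'
#' TRUE iff the three residues immediately 3' of the discriminator (hit
#' orientation, read from the genome) are C, C, A. FALSE (with a warning)
#' when the discriminator is undefined; FALSE when the contig ends.
#'
#' @inheritParams findDiscriminator
#' @param disc result of \code{\link{findDiscriminator}}.
#' @return logical(1).
#' @export
detectCCA <- function(gr, k, contigs, disc) {
  if (is.null(disc)) {
    warning("discriminator undefined; CCA reported as FALSE")
    return(FALSE)
  }
  cn <- as.character(seqnames(gr))[k]
  str <- as.character(strand(gr))[k]
  step <- if (str == "+") 1L else -1L
  b <- vapply(1:3, function(o)
    readGenomeBase(contigs, cn, disc$gpos + step * o, str), character(1))
  !anyNA(b) && paste(b, collapse = "") == "CCA"
}

#' Detect a C-loop intron
#'
#' An insertion of at least \code{minLen} residues whose insertion point is
#' one base 3' of the anticodon (i.e. following the consensus column at
#' position 37) is reported as an intron.
#'
#' @param parse,model as in \code{\link{parseArms}}.
#' @param seq matched sequence (hit orientation).
#' @param minLen minimum intron length (default 8).
#' @return NULL, or list \code{from}, \code{to} (1-based positions within the
#'   hit), \code{len}, \code{mature} (spliced sequence).
#' @export
detectIntron <- function(parse, model, seq, minLen = 8L) {
  c37 <- match("37", model@positionMap)
  if (is.na(c37)) return(NULL)
  pos <- parse$inserts$pos[parse$inserts$afterCol == c37]
  if (length(pos) < minLen) return(NULL)
  pos <- sort(pos)
  mature <- paste0(substr(seq, 1, pos[1] - 1L),
                   substr(seq, pos[length(pos)] + 1L, nchar(seq)))
  list(from = pos[1], to = pos[length(pos)], len = length(pos),
       mature = chartr("T", "U", mature))
}

#' Annotate resolved hits into tRNA-Sec candidates
#'
#' Computes, for every hit: arm architecture and fold class, anticodon,
#' discriminator base and G73 flag, genomic CCA tail, C-loop intron and
#' mature sequence. The result carries one metadata column per feature.
#'
#' @param hits resolved \code{GRanges} from \code{\link{scanGenome}} (with
#'   parses attached).
#' @param genome the scanned genome (same object or path).
#' @param models the models used in the scan.
#' @param intronMinLen minimum intron length.
#' @return the \code{GRanges} with added mcols: \code{anticodon},
#'   \code{discriminator}, \code{discPos}, \code{g73}, \code{cca},
#'   \code{fold}, \code{atTotal}, \code{armPairs} (list), \code{armLoops}
#'   (list), \code{bulges} (list), \code{intronLen}, \code{intronFrom},
#'   \code{matureSeq}.
#' @export
annotateCandidates <- function(hits, genome, models = bundledSearchModels(),
                               intronMinLen = 8L) {
  contigs <- asContigs(genome)
  if (is.null(names(models)))
    names(models) <- vapply(models, domainTag, character(1))
  byTag <- stats::setNames(models, vapply(models, domainTag, character(1)))
  n <- length(hits)
  anticodon <- character(n); disc <- character(n); discPos <- integer(n)
  g73 <- logical(n); cca <- logical(n); fold <- character(n)
  atTot <- integer(n); intronLen <- integer(n); intronFrom <- integer(n)
  mature <- character(n)
  armPairs <- vector("list", n); armLoops <- vector("list", n)
  bulges <- vector("list", n)
  for (k in seq_len(n)) {
    mdl <- byTag[[mcols(hits)$domain[k]]]
    parse <- mcols(hits)$parse[[k]]
    sq <- mcols(hits)$matchedSeq[k]
    arms <- parseArms(parse, mdl)
    armPairs[[k]] <- arms$pairs; armLoops[[k]] <- arms$loops
    bulges[[k]] <- arms$bulges
    f <- classifyFold(arms$pairs[["A-stem"]], arms$pairs[["T-stem"]])
    fold[k] <- f$label; atTot[k] <- f$atTotal
    anticodon[k] <- extractAnticodon(parse, mdl, sq)
    d <- findDiscriminator(hits, k, contigs, mdl)
    if (is.null(d)) {
      disc[k] <- NA_character_; discPos[k] <- NA_integer_; g73[k] <- FALSE
      cca[k] <- suppressWarnings(detectCCA(hits, k, contigs, NULL))
    } else {
      disc[k] <- d$base; discPos[k] <- d$gpos
      g73[k] <- identical(d$base, "G")
      cca[k] <- detectCCA(hits, k, contigs, d)
    }
    intr <- detectIntron(parse, mdl, sq, minLen = intronMinLen)
    if (is.null(intr)) {
      intronLen[k] <- 0L; intronFrom[k] <- NA_integer_
      mature[k] <- chartr("T", "U", sq)
    } else {
      intronLen[k] <- intr$len; intronFrom[k] <- intr$from
      mature[k] <- intr$mature
    }
  }
  mcols(hits)$anticodon <- anticodon
  mcols(hits)$discriminator <- disc
  mcols(hits)$discPos <- discPos
  mcols(hits)$g73 <- g73
  mcols(hits)$cca <- cca
  mcols(hits)$fold <- fold
  mcols(hits)$atTotal <- atTot
  mcols(hits)$armPairs <- I(armPairs)
  mcols(hits)$armLoops <- I(armLoops)
  mcols(hits)$bulges <- I(bulges)
  mcols(hits)$intronLen <- intronLen
  mcols(hits)$intronFrom <- intronFrom
  mcols(hits)$matureSeq <- mature
  hits
}

#' Anticodon-dependent score thresholds
#'
#' Candidates with the canonical UCA anticodon are kept at the base
#' threshold; candidates with any other (or undefined) anticodon must reach
#' the stringent threshold.
#'
#' @param cands annotated candidates \code{GRanges}.
#' @param threshold base threshold (default 40).
#' @param stringent stringent threshold for non-UCA candidates (default 55).
#' @return the filtered \code{GRanges}.
#' @export
applyThresholds <- function(cands, threshold = 40, stringent = 55) {
  if (threshold > stringent)
    stop("configuration error: threshold exceeds the stringent threshold")
  if (!length(cands)) return(cands)
  uca <- !is.na(mcols(cands)$anticodon) & mcols(cands)$anticodon == "UCA"
  keep <- (uca & mcols(cands)$score >= threshold) |
          (!uca & mcols(cands)$score >= stringent)
  cands[keep]
}

#' Arm-completeness filter
#'
#' Removes candidates with shorter or missing arms: each stem must realize
#' at least its consensus pair count minus \code{slack} (the V-stem at least
#' \code{vMin}), and all five arms must be present.
#'
#' @param cands annotated candidates \code{GRanges}.
#' @param models models used (for consensus pair counts).
#' @param slack allowed missing pairs per stem (default 2).
#' @param vMin minimum V-stem pairs (default 2).
#' @return the filtered \code{GRanges}.
#' @export
filterArms <- function(cands, models = bundledSearchModels(), slack = 2L,
                       vMin = 2L) {
  if (!length(cands)) return(cands)
  byTag <- stats::setNames(models, vapply(models, domainTag, character(1)))
  keep <- vapply(seq_along(cands), function(k) {
    mdl <- byTag[[mcols(cands)$domain[k]]]
    consPairs <- vapply(STEMS, function(s) {
      i5 <- which(mdl@matchArm == s & !is.na(mdl@matchPair) &
                  mdl@matchPair > seq_along(mdl@matchPair))
      length(i5)
    }, integer(1))
    minima <- pmax(consPairs - slack, 1L)
    minima["V-stem"] <- vMin
    realized <- mcols(cands)$armPairs[[k]]
    all(realized[STEMS] >= minima[STEMS])
  }, logical(1))
  cands[keep]
}

#' Full search pipeline
#'
#' scan -> resolve -> annotate -> anticodon thresholds -> arm filter.
#'
#' @param genome genome input as in \code{\link{scanGenome}}.
#' @param models models (default bundled).
#' @param config a \linkS4class{ScanConfig}.
#' @param verbose log per-stage candidate counts to stderr.
#' @return annotated, filtered candidates \code{GRanges}.
#' @export
searchTrnaSec <- function(genome, models = bundledSearchModels(),
                          config = ScanConfig(), verbose = FALSE) {
  hits <- scanGenome(genome, models, config, resolve = TRUE)
  if (verbose) message(length(hits), " hits after overlap resolution")
  cands <- annotateCandidates(hits, genome, models)
  cands <- applyThresholds(cands, config@threshold,
                           config@stringentThreshold)
  if (verbose) message(length(cands), " after anticodon thresholds")
  cands <- filterArms(cands, models)
  if (verbose) message(length(cands), " after arm-completeness filter")
  cands
}
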