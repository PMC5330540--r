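## Synthetic-data generation: seed alignments, model sampling, decoys,
## planted genomes with truth tables, and targeted mutation modes.

WC_PAIRS <- list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"),
                 c("G", "U"), c("U", "G"))

## arm sizes per bundled domain; a = acceptor pairs, t = T-stem pairs
## (AT-stem = a + t: 13 for the three tRNA-Sec domains, 12 for the
## canonical 7/5 decoy), d = D-stem pairs, v = V-stem pairs
SEED_LAYOUTS <- list(
  eukaryota = list(a = 9, d = 6, dloop = 4, c = 6, cloop = 7, v = 7,
                   vloop = 5, t = 4, tloop = 7),
  archaea   = list(a = 9, d = 7, dloop = 4, c = 6, cloop = 7, v = 7,
                   vloop = 5, t = 4, tloop = 7),
  bacteria  = list(a = 8, d = 6, dloop = 4, c = 6, cloop = 7, v = 7,
                   vloop = 6, t = 5, tloop = 7),
  canonical = list(a = 7, d = 4, dloop = 8, c = 5, cloop = 7, v = 3,
                   vloop = 4, t = 5, tloop = 7))

seedStructureString <- function(ly) {
  paste0(strrep("<", ly$a), "..",
         strrep("<", ly$d), strrep(".", ly$dloop), strrep(">", ly$d), ".",
         strrep("<", ly$c), strrep(".", ly$cloop), strrep(">", ly$c),
         strrep("<", ly$v), strrep(".", ly$vloop), strrep(">", ly$v),
         strrep("<", ly$t), strrep(".", ly$tloop), strrep(">", ly$t),
         strrep(">", ly$a))
}

## invariant positions (by tRNA position label) and their residues; these
## mirror the universally conserved tRNA-Sec anchors: G18/G19 in the D-loop,
## U33 + UCA anticodon, U55 and C61 in the T arm, C66 in the acceptor stem
SEED_ANCHORS <- c("18" = "G", "19" = "G", "33" = "U",
                  "34" = "U", "35" = "C", "36" = "A",
                  "55" = "U", "61" = "C", "66" = "C")

#' Generate a bundled-style seed alignment
#'
#' Builds a structurally annotated alignment for one domain of life with the
#' domain's tRNA-Sec consensus topology (eukaryota/archaea 9/4 fold,
#' bacteria 8/5, both with a 13-bp AT-stem; \code{canonical} gives the
#' 7/5, 12-bp AT-stem decoy architecture of ordinary tRNAs). Sequences are
#' drawn around a seeded random consensus with compensatory (pair-preserving)
#' substitutions in stems and a lower substitution rate in loops; universally
#' conserved anchor residues (G18, G19, U33, anticodon UCA, U55, C61, C66)
#' are held fixed.
#'
#' @param domain one of \code{"eukaryota"}, \code{"bacteria"},
#'   \code{"archaea"}, \code{"canonical"}.
#' @param n number of sequences (default 16).
#' @param seed RNG seed.
#' @param stemRate per-pair compensatory substitution rate.
#' @param loopRate per-column loop substitution rate.
#' @return A \linkS4class{SeedAlignment} with position labels.
#' @export
makeSeedStockholm <- function(domain = c("eukaryota", "bacteria", "archaea",
                                         "canonical"),
                              n = 128L, seed = 101L,
                              stemRate = 0.06, loopRate = 0.03) {
  domain <- match.arg(domain)
  ly <- SEED_LAYOUTS[[domain]]
  ss <- seedStructureString(ly)
  ncol <- nchar(ss)
  partner <- wussPairs(ss)
  ## derive arms + labels from the topology itself
  dummy <- new("SeedAlignment", ids = "d", seqs = strrep("A", ncol),
               ssCons = ss, positionLabels = character(0), domainTag = domain)
  cs <- annotateStructure(dummy)
  labels <- cs@labels
  set.seed(seed)
  cons <- character(ncol)
  opens <- which(!is.na(partner) & partner > seq_len(ncol))
  for (i in opens) {
    pr <- WC_PAIRS[[sample.int(4L, 1L)]]   # consensus pairs are WC
    cons[i] <- pr[1]; cons[partner[i]] <- pr[2]
  }
  unp <- which(is.na(partner))
  cons[unp] <- sample(NUC, length(unp), replace = TRUE)
  anchored <- match(names(SEED_ANCHORS), labels)
  keep <- !is.na(anchored)
  cons[anchored[keep]] <- SEED_ANCHORS[keep]
  ## anchored stem positions force the partner to pair
  for (i in anchored[keep]) {
    if (!is.na(partner[i]))
      cons[partner[i]] <- wcPartner(cons[i])
  }
  seqs <- character(n)
  for (s in seq_len(n)) {
    row <- cons
    for (i in opens) {
      if (i %in% anchored[keep] || partner[i] %in% anchored[keep]) next
      if (stats::runif(1) < stemRate) {
        pr <- WC_PAIRS[[sample.int(6L, 1L)]]
        row[i] <- pr[1]; row[partner[i]] <- pr[2]
      }
    }
    for (i in unp) {
      if (i %in% anchored[keep]) next
      if (stats::runif(1) < loopRate) row[i] <- sample(setdiff(NUC, row[i]), 1L)
    }
    seqs[s] <- paste(row, collapse = "")
  }
  ## length variation lives in the variable arm (as in real tRNA-Sec, the
  ## longest tRNA): a block of minority-occupancy insert columns after the
  ## V-loop, so models carry genuine insert counts and sampled lengths vary
  ## upward from the consensus length
  if (domain != "canonical") {
    nIns <- 6L
    vloopCols <- which(cs@arm == "V-loop")
    at <- vloopCols[length(vloopCols)]     # after the last V-loop column
    kDist <- c(0.55, 0.15, 0.10, 0.08, 0.06, 0.04, 0.02)
    splice <- function(s, block) paste0(substr(s, 1, at), block,
                                        substr(s, at + 1L, nchar(s)))
    for (s in seq_len(n)) {
      k <- sample(0:nIns, 1L, prob = kDist)
      block <- paste0(paste(sample(NUC, k, replace = TRUE), collapse = ""),
                      strrep(".", nIns - k))
      seqs[s] <- splice(seqs[s], block)
    }
    ss <- splice(ss, strrep(".", nIns))
    labels <- append(labels, rep("", nIns), after = at)
  }
  new("SeedAlignment", ids = sprintf("%s_%02d", substr(domain, 1, 3),
                                     seq_len(n)),
      seqs = seqs, ssCons = ss, positionLabels = labels, domainTag = domain)
}

wcPartner <- function(b) c(A = "U", C = "G", G = "C", U = "A")[[b]]

#' Sample a sequence from a covariance model
#'
#' Draws a parse from the model's joint distribution (transition and emission
#' probabilities) and returns the emitted sequence with its true structure.
#'
#' @param model a \linkS4class{CovarianceModel}.
#' @param seed RNG seed (reproducible per seed).
#' @return list: \code{seq} (RNA string), \code{structure} (dot-bracket over
#'   the emitted bases), \code{colOfBase} (match column per base, 0 for
#'   insertions).
#' @export
sampleTrna <- function(model, seed = 1L) {
  set.seed(seed)
  p <- model@params
  nodes <- model@nodes
  sampleEmit <- function(pr) sample.int(length(pr), 1L, prob = pr) - 1L
  gen <- function(v) {
    tp <- p$stType[v]
    if (tp == "E") return(list(b = character(0), col = integer(0)))
    if (tp == "B") {
      nd <- p$stNode[v]
      row <- which(nodes$id == nd)
      lv <- which(p$stNode == nodes$child1[row] & p$stType == "S")
      rv <- which(p$stNode == nodes$child2[row] & p$stType == "S")
      L <- gen(lv); R <- gen(rv)
      return(list(b = c(L$b, R$b), col = c(L$col, R$col)))
    }
    pickChild <- function() {
      ci <- sample(length(p$children[[v]]), 1L, prob = p$tPr[[v]])
      p$children[[v]][ci]
    }
    if (tp %in% c("S", "D")) return(gen(pickChild()))
    if (tp %in% c("ML", "IL")) {
      b <- NUC[sampleEmit(p$eprS[v, ]) + 1L]
      cl <- if (tp == "ML") p$emitLcol[v] else 0L
      sub <- gen(pickChild())
      return(list(b = c(b, sub$b), col = c(cl, sub$col)))
    }
    if (tp %in% c("MR", "IR")) {
      b <- NUC[sampleEmit(p$eprS[v, ]) + 1L]
      cl <- if (tp == "MR") p$emitRcol[v] else 0L
      sub <- gen(pickChild())
      return(list(b = c(sub$b, b), col = c(sub$col, cl)))
    }
    ## MP
    pair <- sampleEmit(p$eprP[v, ])
    bl <- NUC[pair %/% 4L + 1L]; br <- NUC[pair %% 4L + 1L]
    sub <- gen(pickChild())
    list(b = c(bl, sub$b, br),
         col = c(p$emitLcol[v], sub$col, p$emitRcol[v]))
  }
  g <- gen(1L)
  struct <- vapply(seq_along(g$col), function(k) {
    cl <- g$col[k]
    if (cl == 0L || is.na(model@matchPair[cl])) "." else
      if (model@matchPair[cl] > cl) "(" else ")"
  }, character(1))
  ## a sampled pair may have one side deleted: repair unmatched brackets
  pt <- rep(NA_integer_, length(g$col))
  for (k in seq_along(g$col)) {
    cl <- g$col[k]
    if (cl > 0L && !is.na(model@matchPair[cl])) {
      pk <- match(model@matchPair[cl], g$col)
      if (!is.na(pk)) pt[k] <- pk else struct[k] <- "."
    }
  }
  list(seq = paste(g$b, collapse = ""),
       structure = paste(struct, collapse = ""),
       colOfBase = g$col, pairTable = pt)
}

#' Canonical-tRNA decoy sequence
#'
#' Samples a ~75-nt canonical (7/5 fold, 4-bp D-stem, 12-bp AT-stem)
#' tRNA-like sequence from the bundled canonical model. Such sequences are
#' the most common potential false positives for a tRNA-Sec search.
#'
#' @param seed RNG seed.
#' @return list as \code{\link{sampleTrna}}.
#' @export
makeDecoy <- function(seed = 1L) {
  sampleTrna(bundledModel("canonical"), seed = seed)
}

#' Mutate a sequence, optionally structure-aware
#'
#' \code{random} applies iid substitutions at \code{subRate}; with a pair
#' table, \code{compensatory} rewrites whole pairs to a different
#' Watson-Crick/GU pair (both partners change, pairing preserved) and
#' \code{disruptive} mutates one partner so the pair can no longer form.
#'
#' @param seq nucleotide string.
#' @param pairTable integer vector, partner index per position (NA unpaired),
#'   e.g. from \code{\link{sampleTrna}}.
#' @param subRate substitution rate for mode "random" (in [0,1]).
#' @param seed RNG seed.
#' @param mode one of "random", "compensatory", "disruptive".
#' @param nPairs number of pairs to alter in the structure-aware modes.
#' @return mutated sequence string.
#' @export
mutateSeq <- function(seq, pairTable = NULL, subRate = 0.02, seed = 1L,
                      mode = c("random", "compensatory", "disruptive"),
                      nPairs = 1L) {
  mode <- match.arg(mode)
  if (subRate < 0 || subRate > 1) stop("subRate outside [0,1]")
  set.seed(seed)
  x <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  if (mode == "random") {
    hit <- which(stats::runif(length(x)) < subRate)
    for (i in hit) x[i] <- sample(setdiff(NUC, x[i]), 1L)
    return(paste(x, collapse = ""))
  }
  if (is.null(pairTable)) stop("structure-aware modes need a pairTable")
  opens <- which(!is.na(pairTable) & pairTable > seq_along(pairTable))
  ## only intact pairs can be compensatorily rewritten or disrupted
  opens <- opens[vapply(opens, function(i) basesPair(x[i], x[pairTable[i]]),
                        logical(1))]
  if (!length(opens)) stop("no intact pairs in structure")
  sel <- sample(opens, min(nPairs, length(opens)))
  for (i in sel) {
    j <- pairTable[i]
    if (mode == "compensatory") {
      cand <- Filter(function(pr) pr[1] != x[i] && pr[2] != x[j], WC_PAIRS)
      pr <- cand[[sample.int(length(cand), 1L)]]
      x[i] <- pr[1]; x[j] <- pr[2]
    } else {
      bad <- Filter(function(b) !basesPair(b, x[j]), NUC)
      x[i] <- bad[[sample.int(length(bad), 1L)]]
    }
  }
  paste(x, collapse = "")
}

#' Do two bases form a Watson-Crick or GU wobble pair?
#' @param a,b single RNA bases.
#' @return logical.
#' @export
basesPair <- function(a, b) {
  paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
}

#' Build a synthetic genome with planted tRNA genes and decoys
#'
#' Generates iid background sequence at the requested GC content and inserts
#' planted items (model samples or canonical decoys) at recorded coordinates.
#' Mutations and a C-loop intron (inserted one base 3' of the anticodon, iid
#' sequence) can be applied per item. Fully deterministic per seed.
#'
#' @param spec list with elements: \code{contigs} (integer lengths, named or
#'   not), \code{gc} (default 0.5), \code{seed}, and \code{planted}: a list
#'   of items, each a list with \code{model} (a \linkS4class{CovarianceModel}
#'   or a bundled domain tag, or \code{"decoy"}), optional \code{contig}
#'   (index), \code{strand} ("+"/"-"), \code{at} (0-based start; random when
#'   absent), \code{mutate} (list(mode, subRate, nPairs)), \code{intronLen}.
#' @return list: \code{genome} (named character, DNA alphabet), \code{truth}
#'   (data.frame: contig, start, end (0-based half-open), strand, type,
#'   intronLen, intronStart, mutated, seed).
#' @export
makeGenome <- function(spec) {
  lens <- as.integer(spec$contigs)
  if (!length(lens)) stop("spec$contigs required")
  gc <- if (is.null(spec$gc)) 0.5 else spec$gc
  seed <- if (is.null(spec$seed)) 1L else as.integer(spec$seed)
  set.seed(seed)
  nm <- names(spec$contigs)
  if (is.null(nm)) nm <- sprintf("contig%02d", seq_along(lens))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- vapply(lens, function(L)
    paste(sample(names(probs), L, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  names(contigs) <- nm
  truth <- list()
  occupied <- lapply(lens, function(L) integer(0))
  for (it in spec$planted) {
    mdl <- it$model
    type <- NULL
    if (is.character(mdl)) {
      type <- mdl
      mdl <- if (mdl == "decoy") bundledModel("canonical") else bundledModel(mdl)
    } else type <- domainTag(mdl)
    ## planted tRNA-Sec genes are functional: resample until the anticodon
    ## columns (34-36) carry UCA (decoys are exempt)
    smp <- NULL
    ac <- match(c("34", "35", "36"), positionMap(mdl))
    for (try in 1:100) {
      itemSeed <- sample.int(.Machine$integer.max, 1L)
      smp <- sampleTrna(mdl, seed = itemSeed)
      if (type == "decoy" || anyNA(ac)) break
      b <- strsplit(smp$seq, "")[[1]][match(ac, smp$colOfBase)]
      if (!anyNA(b) && paste(b, collapse = "") == "UCA") break
    }
    sq <- smp$seq
    mutated <- FALSE
    if (!is.null(it$mutate)) {
      mu <- it$mutate
      sq <- mutateSeq(sq, pairTable = smp$pairTable,
                      subRate = if (is.null(mu$subRate)) 0.02 else mu$subRate,
                      seed = sample.int(.Machine$integer.max, 1L),
                      mode = mu$mode,
                      nPairs = if (is.null(mu$nPairs)) 1L else mu$nPairs)
      mutated <- TRUE
    }
    intronLen <- if (is.null(it$intronLen)) 0L else as.integer(it$intronLen)
    intronStart <- NA_integer_
    if (intronLen > 0L) {
      c37 <- match("37", positionMap(mdl))
      if (is.na(c37)) stop("model has no position 37; cannot place intron")
      k <- match(c37, smp$colOfBase)   # base index of position 37
      if (is.na(k)) stop("sampled sequence lacks position 37")
      intron <- paste(sample(NUC, intronLen, replace = TRUE), collapse = "")
      sq <- paste0(substr(sq, 1, k), intron, substr(sq, k + 1, nchar(sq)))
      intronStart <- k           # 0-based offset within the planted gene
    }
    ## genomic trailer: the discriminator base G73 is transcribed but not a
    ## model column; the CCA tail is genomically encoded in bacteria only
    trailer <- if (type == "decoy") "" else {
      if (is.null(it$trailer)) {
        if (type == "bacteria") "GCCA" else "G"
      } else it$trailer
    }
    dna <- chartr("U", "T", paste0(sq, trailer))
    wb <- nchar(sq); wt <- nchar(trailer)
    ci <- if (is.null(it$contig)) sample.int(length(lens), 1L) else it$contig
    strand <- if (is.null(it$strand)) "+" else it$strand
    if (strand == "-") dna <- revComp(dna)
    w <- nchar(dna)
    if (w > lens[ci]) stop("planted item longer than contig ", ci)
    if (is.null(it$at)) {
      ok <- FALSE
      for (try in 1:200) {
        at <- sample.int(lens[ci] - w + 1L, 1L) - 1L
        span <- (at + 1L):(at + w)
        if (!any(span %in% occupied[[ci]])) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place item in contig ", ci)
    } else {
      at <- as.integer(it$at)
      span <- (at + 1L):(at + w)
      if (at + w > lens[ci]) stop("planted item exceeds contig capacity")
      if (any(span %in% occupied[[ci]])) stop("planted items overlap")
    }
    occupied[[ci]] <- c(occupied[[ci]], span)
    substr(contigs[ci], at + 1L, at + w) <- dna
    ## truth interval covers the gene body (model columns), not the trailer
    bodyStart <- if (strand == "+") at else at + wt
    truth[[length(truth) + 1L]] <- data.frame(
      contig = nm[ci], start = bodyStart, end = bodyStart + wb,
      strand = strand, type = type, intronLen = intronLen,
      intronStart = intronStart, mutated = mutated, seed = seed)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), type = character(0),
               intronLen = integer(0), intronStart = integer(0),
               mutated = logical(0), seed = integer(0))
  list(genome = contigs, truth = truth)
}

revComp <- function(dna) {
  chartr("ACGTU", "TGCAA", paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
}
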