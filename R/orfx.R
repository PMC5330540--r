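## TGA-readthrough ORF screen for selenoprotein candidates: annotated genes
## are extended through in-frame TGA codons to the next hard stop, and ORFs
## whose TGA aligns to Cys in several homologues are selected.

STOP_HARD <- c("TAA", "TAG")
START_CODONS <- c("ATG", "GTG", "TTG")   # bacterial table 11 starts

codonAt <- function(s, k) substr(s, k, k + 2L)

#' Extend annotated genes through in-frame TGA codons
#'
#' Each single-exon CDS is extended in its reading frame: 3' through any
#' consecutive in-frame TGA codons up to the first TAA/TAG (or the contig
#' boundary), and 5' back to the first upstream in-frame non-TGA stop, then
#' forward to the furthest-upstream start codon (ATG/GTG/TTG). All in-frame
#' TGA codons inside the extension are recorded; ORFs without any in-frame
#' TGA are dropped. The translation uses the bacterial genetic code
#' (table 11) with U at TGA positions.
#'
#' @param genome genome as in \code{\link{scanGenome}}.
#' @param annotations GFF3 path or a \code{GRanges}; features with
#'   \code{type == "CDS"} are used.
#' @return \code{GRanges} (forward coordinates) with mcols: \code{orfId},
#'   \code{nTga}, \code{tgaCodons} (list of codon indices, 1-based),
#'   \code{protein} (with U), \code{terminalStop} (TAA/TAG or NA at a contig
#'   boundary).
#' @export
extendOrfs <- function(genome, annotations) {
  contigs <- asContigs(genome)
  if (is.character(annotations))
    annotations <- rtracklayer::import(annotations)
  cds <- annotations[mcols(annotations)$type == "CDS"]
  out <- list()
  for (k in seq_along(cds)) {
    cn <- as.character(seqnames(cds))[k]
    if (!cn %in% names(contigs)) stop("unknown contig in annotation: ", cn)
    str <- as.character(strand(cds))[k]
    L <- nchar(contigs[[cn]])
    ## oriented coordinates: position 1 = 5' end of the coding strand
    S <- if (str == "+") contigs[[cn]] else revComp(contigs[[cn]])
    a <- if (str == "+") start(cds)[k] else L - end(cds)[k] + 1L
    b <- if (str == "+") end(cds)[k] else L - start(cds)[k] + 1L
    if ((b - a + 1L) %% 3L != 0L)
      stop("CDS frame inconsistent with length at ", cn, ":", start(cds)[k])
    ## 3' extension
    e <- b
    terminalStop <- NA_character_
    repeat {
      if (e + 3L > nchar(S)) break
      cod <- codonAt(S, e + 1L)
      if (cod %in% STOP_HARD) { terminalStop <- cod; break }
      e <- e + 3L
    }
    ## 5' extension: first upstream in-frame hard stop
    s5 <- a
    repeat {
      if (s5 - 3L < 1L) break
      cod <- codonAt(S, s5 - 3L)
      if (cod %in% STOP_HARD) break
      s5 <- s5 - 3L
    }
    ## furthest-upstream start codon between the bounding stop and the
    ## original CDS start
    st <- s5
    while (st < a && !codonAt(S, st) %in% START_CODONS) st <- st + 3L
    if (st > a) st <- a                      # no start found: keep original
    orf <- substr(S, st, e)
    ncod <- nchar(orf) %/% 3L
    codons <- vapply(seq_len(ncod), function(i)
      codonAt(orf, 3L * (i - 1L) + 1L), character(1))
    tga <- which(codons == "TGA")
    if (!length(tga)) next
    prot <- translateWithSec(codons)
    fs <- if (str == "+") st else L - e + 1L
    fe <- if (str == "+") e else L - st + 1L
    g <- GRanges(cn, IRanges(fs, fe), strand = str)
    mcols(g)$orfId <- sprintf("orf_%s_%d_%s", cn, fs, str)
    mcols(g)$nTga <- length(tga)
    mcols(g)$tgaCodons <- I(list(tga))
    mcols(g)$protein <- prot
    mcols(g)$terminalStop <- terminalStop
    out[[length(out) + 1L]] <- g
  }
  if (!length(out)) {
    g <- GRanges()
    mcols(g)$orfId <- character(0); mcols(g)$nTga <- integer(0)
    mcols(g)$tgaCodons <- I(list()); mcols(g)$protein <- character(0)
    mcols(g)$terminalStop <- character(0)
    return(g)
  }
  do.call(c, out)
}

translateWithSec <- function(codons) {
  gc11 <- Biostrings::getGeneticCode("11")
  aa <- gc11[codons]
  aa[codons == "TGA"] <- "U"
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Local alignment of a TGA-readthrough ORF against homologue proteins
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps) of the ORF's
#' translation against each subject; U (selenocysteine) in the query scores
#' as C. For every query U inside the aligned region the paired subject
#' residue is reported.
#'
#' @param protein ORF translation (may contain U).
#' @param subjects named character vector (or AAStringSet) of homologue
#'   protein sequences.
#' @param minScore minimum alignment score to report (default 40).
#' @param gapOpening,gapExtension affine gap penalties (defaults 11, 1).
#' @return data.frame: subject, score, uPairs (list column of data.frames
#'   with queryPos and subjectResidue per query U inside the alignment).
#' @export
alignHomologs <- function(protein, subjects, minScore = 40,
                          gapOpening = 11, gapExtension = 1) {
  if (!length(subjects)) stop("empty protein set")
  if (methods::is(subjects, "AAStringSet"))
    subjects <- stats::setNames(as.character(subjects), names(subjects))
  q <- chartr("U", "C", protein)
  uPos <- which(strsplit(protein, "")[[1]] == "U")
  res <- list()
  for (nm in names(subjects)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(subjects[[nm]]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = gapOpening, gapExtension = gapExtension)
    sc <- Biostrings::score(pa)
    if (sc < minScore) next
    qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    qStart <- IRanges::start(Biostrings::pattern(pa))
    qp <- qStart - 1L
    pairs <- list()
    for (t in seq_along(qa)) {
      if (qa[t] != "-") qp <- qp + 1L
      if (qa[t] != "-" && qp %in% uPos && sa[t] != "-")
        pairs[[length(pairs) + 1L]] <- data.frame(queryPos = qp,
                                                  subjectResidue = sa[t])
    }
    res[[length(res) + 1L]] <- data.frame(
      subject = nm, score = sc,
      uPairs = I(list(if (length(pairs)) do.call(rbind, pairs) else
        data.frame(queryPos = integer(0), subjectResidue = character(0)))))
  }
  if (!length(res))
    return(data.frame(subject = character(0), score = numeric(0),
                      uPairs = I(list())))
  do.call(rbind, res)
}

#' Select selenoprotein-candidate ORFs
#'
#' An ORF is selected when at least \code{minCysHits} distinct subjects
#' align one of its TGA (U) positions to a cysteine.
#'
#' @param orfs \code{GRanges} from \code{\link{extendOrfs}}.
#' @param hitsPerOrf list (parallel to \code{orfs}) of data.frames from
#'   \code{\link{alignHomologs}}.
#' @param minCysHits minimum distinct Cys-pairing subjects (default 3).
#' @return \code{orfs} with added mcols \code{nCysHits} and \code{selected}.
#' @export
selectCandidates <- function(orfs, hitsPerOrf, minCysHits = 3L) {
  nCys <- vapply(seq_along(orfs), function(k) {
    h <- hitsPerOrf[[k]]
    if (!nrow(h)) return(0L)
    hasCys <- vapply(seq_len(nrow(h)), function(r)
      any(h$uPairs[[r]]$subjectResidue == "C"), logical(1))
    length(unique(h$subject[hasCys]))
  }, integer(1))
  mcols(orfs)$nCysHits <- nCys
  mcols(orfs)$selected <- nCys >= minCysHits
  orfs
}

#' Run the full ORF screen
#'
#' @param genome genome input.
#' @param annotations GFF3 CDS annotation.
#' @param proteins homologue protein FASTA path or named character vector.
#' @param minCysHits selection threshold (default 3).
#' @param minScore minimum alignment score (default 40).
#' @return \code{GRanges} of TGA-containing ORFs with selection mcols.
#' @export
orfScreen <- function(genome, annotations, proteins, minCysHits = 3L,
                      minScore = 40) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    aa <- Biostrings::readAAStringSet(proteins)
    proteins <- stats::setNames(as.character(aa), sub("\\s.*", "", names(aa)))
  }
  orfs <- extendOrfs(genome, annotations)
  hits <- lapply(seq_along(orfs), function(k)
    alignHomologs(mcols(orfs)$protein[k], proteins, minScore = minScore))
  selectCandidates(orfs, hits, minCysHits = minCysHits)
}
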