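## File I/O: FASTA, GFF3, BED6, TSV. Genomic coordinates are 1-based
## inclusive GRanges internally; BED output converts to 0-based half-open.

#' Read a (possibly wrapped, mixed-case) FASTA file
#'
#' @param path FASTA path.
#' @return named character vector (uppercase DNA).
#' @export
readFastaFile <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nms <- sub("\\s.*", "", names(x))
  if (anyDuplicated(nms)) stop("duplicate contig ids in ", path)
  stats::setNames(toupper(as.character(x)), nms)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return \code{path}, invisibly.
#' @export
writeFastaFile <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

cleanCandidateGr <- function(cands) {
  gr <- GRanges(seqnames(cands), IRanges(start(cands), end(cands)),
                strand = strand(cands))
  mc <- mcols(cands)
  keep <- c("score", "domain", "anticodon", "discriminator", "g73", "cca",
            "fold", "atTotal", "intronLen", "intronFrom", "copyClass")
  for (cc in intersect(keep, colnames(mc))) mcols(gr)[[cc]] <- mc[[cc]]
  gr
}

#' Write candidates as GFF3
#'
#' Features of type \code{tRNA}, score = bit score, 1-based inclusive
#' coordinates, with attributes \code{domain_model}, \code{anticodon},
#' \code{discriminator}, \code{g73}, \code{cca}, \code{fold} and, when
#' present, \code{intron} (within-hit coordinates) and \code{copy_class}.
#'
#' @param cands annotated candidates \code{GRanges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(cands, path) {
  lines <- "##gff-version 3"
  mc <- mcols(cands)
  for (k in seq_along(cands)) {
    attrs <- c(
      sprintf("ID=trnasec%03d", k),
      sprintf("domain_model=%s", mc$domain[k]),
      sprintf("anticodon=%s",
              ifelse(is.na(mc$anticodon[k]), "undefined", mc$anticodon[k])),
      sprintf("discriminator=%s",
              ifelse(is.na(mc$discriminator[k]), "undefined",
                     mc$discriminator[k])),
      sprintf("g73=%s", tolower(mc$g73[k])),
      sprintf("cca=%s", tolower(mc$cca[k])),
      sprintf("fold=%s", mc$fold[k]))
    if (!is.null(mc$intronLen) && mc$intronLen[k] > 0L)
      attrs <- c(attrs, sprintf("intron=%d-%d", mc$intronFrom[k],
                                mc$intronFrom[k] + mc$intronLen[k] - 1L))
    if (!is.null(mc$copyClass) && !is.na(mc$copyClass[k]))
      attrs <- c(attrs, sprintf("copy_class=%s", mc$copyClass[k]))
    lines <- c(lines, paste(
      as.character(seqnames(cands))[k], "secScan", "tRNA",
      start(cands)[k], end(cands)[k],
      sprintf("%.2f", mc$score[k]), as.character(strand(cands))[k], ".",
      paste(attrs, collapse = ";"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write candidates as BED6
#'
#' BED start is 0-based (GFF3 start minus one).
#'
#' @inheritParams writeGff3
#' @export
writeBed6 <- function(cands, path) {
  mc <- mcols(cands)
  lines <- vapply(seq_along(cands), function(k) {
    paste(as.character(seqnames(cands))[k], start(cands)[k] - 1L,
          end(cands)[k], sprintf("trnasec%03d", k),
          sprintf("%.2f", mc$score[k]), as.character(strand(cands))[k],
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write the per-candidate TSV summary
#'
#' @inheritParams writeGff3
#' @export
writeCandidateTsv <- function(cands, path) {
  df <- as.data.frame(cleanCandidateGr(cands))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
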