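## High-level entry points used by the command-line wrapper
## (inst/scripts/secscan).

#' Run a search and write GFF3/BED/TSV (and optional SVG) outputs
#'
#' Runs the full pipeline (scan, overlap resolution, annotation, anticodon
#' thresholds, arm filter) and writes \code{trnasec.gff3},
#' \code{trnasec.bed}, \code{trnasec.tsv} and, when \code{plot} is TRUE, one
#' SVG per candidate into \code{outDir}. Stage counts are logged to stderr.
#'
#' @param genome FASTA path (or named character / DNAStringSet).
#' @param outDir output directory (created if needed).
#' @param threshold bit-score threshold T (default 40).
#' @param stringent threshold for non-UCA candidates (default 55).
#' @param plot write one cloverleaf SVG per candidate (off by default).
#' @param models models to search with (default bundled).
#' @return the candidates \code{GRanges}, invisibly.
#' @export
cliSearch <- function(genome, outDir, threshold = 40, stringent = 55,
                      plot = FALSE, models = bundledSearchModels()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config <- ScanConfig(threshold = threshold,
                       stringentThreshold = stringent)
  cands <- searchTrnaSec(genome, models, config, verbose = TRUE)
  writeGff3(cands, file.path(outDir, "trnasec.gff3"))
  writeBed6(cands, file.path(outDir, "trnasec.bed"))
  writeCandidateTsv(cands, file.path(outDir, "trnasec.tsv"))
  if (plot && length(cands)) {
    byTag <- stats::setNames(models,
                             vapply(models, domainTag, character(1)))
    for (k in seq_along(cands))
      renderCloverleaf(cands[k], byTag[[mcols(cands)$domain[k]]],
                       svgPath = file.path(outDir,
                                           sprintf("trnasec%03d.svg", k)))
  }
  invisible(cands)
}

#' Generate a synthetic genome and write genome + truth files
#'
#' @param spec simulation spec list (see \code{\link{makeGenome}}) or a YAML
#'   path with the same structure.
#' @param outDir output directory; writes \code{genome.fa},
#'   \code{truth.bed}, \code{truth.tsv}.
#' @return the \code{\link{makeGenome}} result, invisibly.
#' @export
cliSimulate <- function(spec, outDir) {
  if (is.character(spec) && length(spec) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML specs requires the yaml package")
    spec <- yaml::read_yaml(spec)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- makeGenome(spec)
  writeFastaFile(res$genome, file.path(outDir, "genome.fa"))
  tr <- res$truth
  bed <- vapply(seq_len(nrow(tr)), function(k)
    paste(tr$contig[k], tr$start[k], tr$end[k], tr$type[k], 0,
          tr$strand[k], sep = "\t"), character(1))
  writeLines(bed, file.path(outDir, "truth.bed"))
  utils::write.table(tr, file.path(outDir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(res)
}
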