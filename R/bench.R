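## Genome-level benchmark harness. The design exploits the non-universality
## of selenocysteine: a tRNA-Sec prediction in a Sec-devoid genome is
## necessarily a false positive, and absence of predictions in a
## selenoprotein-encoding genome is a false negative -- a benchmark that is
## impossible for tRNAs of the other amino acids.

roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Genome-level sensitivity and specificity of tRNA-Sec predictions
#'
#' Sensitivity is the percentage of Sec-positive genomes with at least one
#' prediction; specificity the percentage of Sec-negative genomes with none.
#' N+ and N- are the mean number of predictions per positive and negative
#' genome. Values are reported to one decimal (half-up); statistics over an
#' empty genome set are NA.
#'
#' @param predictions data.frame with columns \code{genome_id},
#'   \code{locus_id} (and optionally \code{score}); duplicate rows for the
#'   same (genome, locus) are counted once. An empty data.frame means no
#'   predictions anywhere.
#' @param labels data.frame with columns \code{genome_id}, \code{lineage},
#'   \code{sec_positive} (logical).
#' @param byLineage also compute per-lineage rows.
#' @return data.frame with columns lineage, nPos, nNeg, sn, sp, Nplus,
#'   Nminus (first row = "all").
#' @export
evaluateBenchmark <- function(predictions, labels, byLineage = TRUE) {
  if (anyDuplicated(labels$genome_id)) stop("duplicate genome ids in labels")
  if (nrow(predictions)) {
    unknown <- setdiff(unique(predictions$genome_id), labels$genome_id)
    if (length(unknown))
      stop("unknown genome id in predictions: ",
           paste(unknown, collapse = ", "))
    predictions <- unique(predictions[c("genome_id", "locus_id")])
  }
  counts <- stats::setNames(rep(0L, nrow(labels)), labels$genome_id)
  if (nrow(predictions)) {
    tb <- table(predictions$genome_id)
    counts[names(tb)] <- as.integer(tb)
  }
  evalSet <- function(lab, lineage) {
    pos <- counts[lab$genome_id[lab$sec_positive]]
    neg <- counts[lab$genome_id[!lab$sec_positive]]
    data.frame(
      lineage = lineage, nPos = length(pos), nNeg = length(neg),
      sn = if (length(pos)) roundHalfUp(100 * mean(pos >= 1L)) else NA_real_,
      sp = if (length(neg)) roundHalfUp(100 * mean(neg == 0L)) else NA_real_,
      Nplus = if (length(pos)) roundHalfUp(mean(pos)) else NA_real_,
      Nminus = if (length(neg)) roundHalfUp(mean(neg)) else NA_real_)
  }
  out <- evalSet(labels, "all")
  if (byLineage && length(unique(labels$lineage)) > 1L) {
    for (lin in unique(labels$lineage))
      out <- rbind(out, evalSet(labels[labels$lineage == lin, ], lin))
  }
  rownames(out) <- NULL
  out
}

#' Per-column conservation of a seed alignment
#'
#' Conservation of a column is the frequency of its modal non-gap residue
#' among the non-gap rows. Means are reported separately for paired and
#' unpaired columns; the means cover the consensus positions (columns
#' occupied in at least half of the rows -- minority-occupancy insert
#' columns are not tRNA positions), and all-gap columns are undefined.
#' Columns conserved in every row are listed by tRNA position label when
#' labels are available.
#'
#' @param aln a \linkS4class{SeedAlignment} with >= 2 sequences.
#' @return list: \code{perColumn} (numeric), \code{pairedMean},
#'   \code{unpairedMean}, \code{fullyConserved} (labels or column indices).
#' @export
columnStats <- function(aln) {
  if (length(aln@seqs) < 2L) stop("need >= 2 sequences")
  m <- do.call(rbind, strsplit(aln@seqs, ""))
  isGap <- m == "-" | m == "."
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[!isGap[, j], j]
    if (!length(col)) return(NA_real_)
    max(table(col)) / length(col)
  }, numeric(1))
  partner <- wussPairs(aln@ssCons)
  paired <- !is.na(partner)
  ok <- !is.na(cons) & colMeans(!isGap) >= 0.5
  full <- which(!is.na(cons) & cons == 1 &
                colSums(!isGap) == nrow(m))
  labels <- if (length(aln@positionLabels)) {
    l <- aln@positionLabels[full]
    l[l == ""] <- as.character(full[l == ""])
    l
  } else as.character(full)
  list(perColumn = cons,
       pairedMean = mean(cons[paired & ok]),
       unpairedMean = mean(cons[!paired & ok]),
       fullyConserved = labels)
}

#' Read / write benchmark tables
#'
#' Labels TSV: \code{genome_id lineage sec_positive}; predictions TSV:
#' \code{genome_id locus_id score}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readLabelsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$sec_positive <- as.logical(df$sec_positive)
  df
}

#' @rdname readLabelsTsv
#' @export
readPredictionsTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readLabelsTsv
#' @param x data.frame to write.
#' @export
writeBenchmarkTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
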