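#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

DOMAIN_TAGS <- c("eukaryota", "bacteria", "archaea", "canonical")
ARM_LABELS <- c("A-stem", "D-stem", "D-loop", "C-stem", "C-loop",
                "V-stem", "V-loop", "T-stem", "T-loop", "linker")

#' SeedAlignment: a structurally annotated training alignment
#'
#' Holds a multiple alignment of tRNA-Sec (or canonical tRNA) sequences
#' together with a consensus secondary structure in WUSS bracket notation and,
#' optionally, a per-column tRNA position label line. Gaps are \code{-} or
#' \code{.}; \code{T} and \code{U} are equivalent on input and stored as RNA.
#'
#' @slot ids character, one id per row.
#' @slot seqs character, aligned rows (RNA alphabet plus gaps), equal widths.
#' @slot ssCons character(1), consensus structure, same width as the rows.
#' @slot positionLabels character, per-column tRNA position labels (\code{""}
#'   for unlabeled columns) or \code{character(0)} when absent.
#' @slot domainTag character(1), one of eukaryota/bacteria/archaea/canonical.
#' @exportClass SeedAlignment
setClass("SeedAlignment",
  representation(ids = "character", seqs = "character", ssCons = "character",
                 positionLabels = "character", domainTag = "character"))

setValidity("SeedAlignment", function(object) {
  msg <- character()
  if (length(object@seqs) < 1L) msg <- c(msg, "alignment needs >= 1 sequence")
  w <- unique(nchar(object@seqs))
  if (length(w) > 1L) msg <- c(msg, "rows have differing lengths")
  if (length(w) == 1L && nchar(object@ssCons) != w)
    msg <- c(msg, "structure line length differs from row length")
  if (length(object@positionLabels) &&
      length(object@positionLabels) != nchar(object@ssCons))
    msg <- c(msg, "position label line has wrong length")
  bad <- grepl("[^ACGUN.-]", object@seqs)
  if (any(bad)) msg <- c(msg, "alphabet must be A,C,G,U/T,N,-,.")
  if (!object@domainTag %in% DOMAIN_TAGS)
    msg <- c(msg, "unknown domain tag")
  p <- tryCatch(wussPairs(object@ssCons), error = function(e) e)
  if (inherits(p, "error")) msg <- c(msg, conditionMessage(p))
  if (length(msg)) msg else TRUE
})

#' ConsensusStructure: per-column pairing and arm assignment
#'
#' @slot pairPartner integer, partner column index per column (NA if unpaired);
#'   a symmetric involution over the paired columns.
#' @slot arm character, per-column arm label (A-stem, D-stem, D-loop, C-stem,
#'   C-loop, V-stem, V-loop, T-stem, T-loop, linker).
#' @slot isMatch logical, per-column match-column flag (occupancy rule:
#'   a column is a match column when fewer than half of the rows are gaps).
#' @slot labels character, per-column tRNA position labels ("" if none).
#' @exportClass ConsensusStructure
setClass("ConsensusStructure",
  representation(pairPartner = "integer", arm = "character",
                 isMatch = "logical", labels = "character"))

setValidity("ConsensusStructure", function(object) {
  msg <- character()
  n <- length(object@pairPartner)
  if (length(object@arm) != n || length(object@isMatch) != n ||
      length(object@labels) != n)
    msg <- c(msg, "slot lengths differ")
  pp <- object@pairPartner
  paired <- which(!is.na(pp))
  if (any(pp[pp[paired]] != paired))
    msg <- c(msg, "pairPartner is not a symmetric involution")
  if (any(!object@arm[paired] %in% c("A-stem", "D-stem", "C-stem",
                                     "V-stem", "T-stem")))
    msg <- c(msg, "paired columns must carry a *-stem arm label")
  if (any(!object@arm %in% ARM_LABELS)) msg <- c(msg, "unknown arm label")
  if (length(msg)) msg else TRUE
})

#' CovarianceModel: a profile SCFG over the tRNA-Sec cloverleaf
#'
#' A covariance model derived deterministically from a \linkS4class{SeedAlignment}:
#' a guide tree of pair-match / left-match / right-match / bifurcation nodes
#' over the consensus match columns, expanded into states carrying emission
#' and transition probabilities (Laplace-smoothed counts) and their bit-score
#' log-odds against an iid null model.
#'
#' @slot nodes data.frame: type, lcol, rcol (match-column index), child ids.
#' @slot states data.frame: one row per state (node, type, emission/children
#'   bookkeeping); probabilities and log-odds live in \code{params}.
#' @slot params list: emission and transition probability and log-odds tables,
#'   flattened for the C++ CYK kernel.
#' @slot consensusLength integer(1), number of match columns.
#' @slot domainTag character(1).
#' @slot positionMap character, tRNA position label per match column.
#' @slot matchArm character, arm label per match column.
#' @slot matchPair integer, partner match column per match column (NA unpaired).
#' @slot nullModel numeric(4), iid nucleotide null (sums to 1).
#' @slot pseudocount numeric(1), the pseudocount the model was built with.
#' @exportClass CovarianceModel
setClass("CovarianceModel",
  representation(nodes = "data.frame", states = "data.frame", params = "list",
                 consensusLength = "integer", domainTag = "character",
                 positionMap = "character", matchArm = "character",
                 matchPair = "integer", nullModel = "numeric",
                 pseudocount = "numeric"))

setValidity("CovarianceModel", function(object) {
  msg <- character()
  if (abs(sum(object@nullModel) - 1) > 1e-9)
    msg <- c(msg, "null model must sum to 1")
  if (object@consensusLength != length(object@positionMap))
    msg <- c(msg, "positionMap length != consensusLength")
  ok <- checkModelNormalization(object, tol = 1e-9)
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (length(msg)) msg else TRUE
})

#' ScanConfig: parameters of the genome scan
#'
#' @slot threshold numeric(1), reporting bit-score threshold T (default 40).
#' @slot stringentThreshold numeric(1), threshold applied downstream to
#'   candidates whose anticodon is not UCA (default 55).
#' @slot windowPad integer(1), maximum parse length is consensusLength +
#'   windowPad (default 30).
#' @slot bandDel integer(1), per-state length-band slack for deletions.
#' @slot bandIns integer(1), per-state length-band slack for insertions.
#' @slot strands character, strands to scan.
#' @exportClass ScanConfig
setClass("ScanConfig",
  representation(threshold = "numeric", stringentThreshold = "numeric",
                 windowPad = "integer", bandDel = "integer",
                 bandIns = "integer", strands = "character"))

setValidity("ScanConfig", function(object) {
  msg <- character()
  if (object@threshold <= 0) msg <- c(msg, "threshold must be positive")
  if (object@threshold > object@stringentThreshold)
    msg <- c(msg, "threshold must not exceed the stringent threshold")
  if (object@windowPad < 0L) msg <- c(msg, "windowPad must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ScanConfig
#'
#' @param threshold reporting bit-score threshold (applies to every hit).
#' @param stringentThreshold threshold for non-UCA-anticodon candidates.
#' @param windowPad maximum parse length above the model consensus length.
#' @param bandDel,bandIns CYK length-band slack (deletions / insertions).
#' @param strands strands to scan, subset of \code{c("+", "-")}.
#' @return A \linkS4class{ScanConfig}.
#' @export
ScanConfig <- function(threshold = 40, stringentThreshold = 55,
                       windowPad = 30L, bandDel = 30L, bandIns = 40L,
                       strands = c("+", "-")) {
  new("ScanConfig", threshold = as.numeric(threshold),
      stringentThreshold = as.numeric(stringentThreshold),
      windowPad = as.integer(windowPad), bandDel = as.integer(bandDel),
      bandIns = as.integer(bandIns), strands = strands)
}

setMethod("show", "SeedAlignment", function(object) {
  cat(sprintf("SeedAlignment (%s): %d sequences x %d columns\n",
              object@domainTag, length(object@seqs), nchar(object@ssCons)))
  cat(sprintf("  consensus pairs: %d\n",
              sum(!is.na(wussPairs(object@ssCons))) %/% 2L))
})

setMethod("show", "CovarianceModel", function(object) {
  np <- sum(!is.na(object@matchPair)) %/% 2L
  cat(sprintf("CovarianceModel (%s): %d match columns, %d consensus pairs, %d states\n",
              object@domainTag, object@consensusLength, np, nrow(object@states)))
})

setMethod("show", "ScanConfig", function(object) {
  cat(sprintf("ScanConfig: T=%g, stringent T=%g, window pad %d, strands %s\n",
              object@threshold, object@stringentThreshold, object@windowPad,
              paste(object@strands, collapse = "/")))
})

#' Accessors
#'
#' \code{domainTag} returns the domain label of a model or alignment;
#' \code{consensusLength} the number of match columns of a model;
#' \code{positionMap} the per-match-column tRNA position labels.
#'
#' @param x a \linkS4class{CovarianceModel} or \linkS4class{SeedAlignment}.
#' @return character or integer scalar / vector as described.
#' @rdname accessors
#' @export
setGeneric("domainTag", function(x) standardGeneric("domainTag"))
#' @rdname accessors
#' @export
setGeneric("consensusLength", function(x) standardGeneric("consensusLength"))
#' @rdname accessors
#' @export
setGeneric("positionMap", function(x) standardGeneric("positionMap"))

#' @rdname accessors
setMethod("domainTag", "CovarianceModel", function(x) x@domainTag)
#' @rdname accessors
setMethod("domainTag", "SeedAlignment", function(x) x@domainTag)
#' @rdname accessors
setMethod("consensusLength", "CovarianceModel", function(x) x@consensusLength)
#' @rdname accessors
setMethod("positionMap", "CovarianceModel", function(x) x@positionMap)
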