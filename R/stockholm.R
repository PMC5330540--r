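WUSS_OPEN  <- c("<", "(", "[", "{")
WUSS_CLOSE <- c(">", ")", "]", "}")
WUSS_SINGLE <- c(".", ",", "_", "-", ":", "~")

#' Pair table of a WUSS structure string
#'
#' Matches each opening bracket with its closing partner (all bracket families
#' are treated as nesting; pseudoknots are not supported). Unpaired characters
#' are \code{. , _ - : ~}.
#'
#' @param ss a WUSS (subset) structure string.
#' @return integer vector, per-position partner index (NA when unpaired).
#' @export
wussPairs <- function(ss) {
  chars <- strsplit(ss, "")[[1]]
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% WUSS_OPEN) {
      stack <- c(stack, i)
    } else if (ch %in% WUSS_CLOSE) {
      if (!length(stack)) stop("unbalanced structure: unmatched '", ch, "'")
      j <- stack[length(stack)]
      if (match(ch, WUSS_CLOSE) != match(chars[j], WUSS_OPEN))
        stop("unbalanced structure: '", chars[j], "' closed by '", ch, "'")
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (!ch %in% WUSS_SINGLE) {
      stop("illegal structure character '", ch, "'")
    }
  }
  if (length(stack)) stop("unbalanced structure: unclosed bracket")
  partner
}

#' Read a single-alignment Stockholm file
#'
#' Supports the subset used by the bundled seeds: sequence rows, one
#' \code{#=GC SS_cons} consensus-structure line (WUSS subset), an optional
#' \code{#=GC RF} line and an optional \code{#=GC POSLBL} line carrying
#' comma-separated per-column tRNA position labels. Wrapped (interleaved)
#' alignments are concatenated. T is converted to U.
#'
#' @param path file path, or a character vector of lines via \code{text=}.
#' @param text optional character vector of lines (overrides \code{path}).
#' @param domainTag domain tag to record; when missing, taken from a
#'   \code{#=GF DOMAIN} line, defaulting to "eukaryota".
#' @return A \linkS4class{SeedAlignment}.
#' @export
readStockholm <- function(path, text = NULL, domainTag = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header)")
  seqs <- list(); ss <- ""; poslbl <- ""; domain <- NULL
  for (ln in lines[-1]) {
    if (ln == "//") break
    if (grepl("^#=GF\\s+DOMAIN\\s+", ln)) {
      domain <- sub("^#=GF\\s+DOMAIN\\s+", "", ln)
    } else if (grepl("^#=GC\\s+SS_cons\\s+", ln)) {
      ss <- paste0(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
    } else if (grepl("^#=GC\\s+POSLBL\\s+", ln)) {
      poslbl <- paste0(poslbl, sub("^#=GC\\s+POSLBL\\s+", "", ln))
    } else if (grepl("^#", ln)) {
      next
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) != 2L) stop("malformed sequence line: ", ln)
      seqs[[f[1]]] <- paste0(if (is.null(seqs[[f[1]]])) "" else seqs[[f[1]]], f[2])
    }
  }
  if (!nzchar(ss)) stop("missing #=GC SS_cons structure line")
  if (!length(seqs)) stop("alignment has no sequences")
  mat <- toupper(chartr("Tt", "Uu", unlist(seqs)))
  if (length(unique(nchar(mat))) != 1L || nchar(mat[1]) != nchar(ss))
    stop("row-length mismatch between sequences and structure line")
  labels <- character(0)
  if (nzchar(poslbl)) {
    labels <- strsplit(poslbl, ",", fixed = TRUE)[[1]]
    if (length(labels) != nchar(ss))
      stop("POSLBL label count differs from column count")
    labels[labels == "."] <- ""
  }
  if (is.null(domainTag)) domainTag <- if (is.null(domain)) "eukaryota" else domain
  aln <- new("SeedAlignment", ids = names(mat), seqs = unname(mat),
             ssCons = ss, positionLabels = labels, domainTag = domainTag)
  validObject(aln)
  aln
}

#' Write a SeedAlignment as Stockholm
#'
#' @param aln a \linkS4class{SeedAlignment}.
#' @param path output file path; when NULL the lines are returned invisibly.
#' @return invisibly, the lines written.
#' @export
writeStockholm <- function(aln, path = NULL) {
  idw <- max(nchar(aln@ids), nchar("#=GC POSLBL"))
  pad <- function(s) formatC(s, width = -idw)
  lines <- c("# STOCKHOLM 1.0",
             paste("#=GF DOMAIN", aln@domainTag),
             paste(pad(aln@ids), aln@seqs),
             paste(pad("#=GC SS_cons"), aln@ssCons))
  if (length(aln@positionLabels)) {
    lbl <- aln@positionLabels
    lbl[lbl == ""] <- "."
    lines <- c(lines, paste(pad("#=GC POSLBL"), paste(lbl, collapse = ",")))
  }
  lines <- c(lines, "//")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Match columns of an alignment (occupancy rule)
#'
#' A column is a match column when fewer than 50% of the rows are gaps.
#'
#' @param aln a \linkS4class{SeedAlignment}.
#' @return logical vector over columns.
#' @export
matchColumns <- function(aln) {
  m <- do.call(rbind, strsplit(aln@seqs, ""))
  colMeans(m == "-" | m == ".") < 0.5
}
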