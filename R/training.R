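## Model refinement: training-set filtering, structure-based folding, and
## the iterative fold-align-rebuild loop.

#' Filter a training set of candidate tRNA-Sec sequences
#'
#' Keeps sequences that look like plausible tRNA-Sec under a bootstrap
#' model (bit score >= \code{minScore}) and whose anticodon is UCA;
#' sequences with any other anticodon are discarded (their count is logged).
#'
#' @param seqs named character vector of unaligned sequences (60-130 nt).
#' @param model bootstrap \linkS4class{CovarianceModel} used to locate the
#'   anticodon.
#' @param minScore structural plausibility threshold in bits (default 0).
#' @return the retained subset of \code{seqs}.
#' @export
filterTraining <- function(seqs, model, minScore = 0) {
  if (!length(seqs)) stop("empty training set")
  lens <- nchar(seqs)
  if (any(lens < 60L | lens > 130L))
    stop("training sequences must be 60-130 nt")
  keep <- vapply(seqs, function(sq) {
    r <- scoreSequence(model, sq)
    if (r$score < minScore) return(FALSE)
    ac <- extractAnticodon(r$parse, model, sq)
    !is.na(ac) && ac == "UCA"
  }, logical(1))
  message(sum(!keep), " of ", length(seqs), " training sequences discarded")
  if (!any(keep)) stop("no training sequences left after filtering")
  seqs[keep]
}

#' Maximum-base-pair folding (Nussinov)
#'
#' Folds a sequence by maximizing the number of Watson-Crick/GU pairs with a
#' minimum hairpin loop of 3 unpaired bases. Ties are broken
#' deterministically in favour of 5'-most pairs (at each subproblem, pairing
#' the leftmost base with its smallest admissible partner is preferred).
#'
#' @param seq nucleotide string (>= 10 nt).
#' @param minLoop minimum hairpin loop length (default 3).
#' @return dot-bracket string.
#' @export
foldSequence <- function(seq, minLoop = 3L) {
  x <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(x)
  if (n < 10L) stop("sequence too short to fold (< 10 nt)")
  N <- matrix(0L, n, n)
  for (d in (minLoop + 1L):(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      best <- N[i + 1L, j]               # i unpaired
      for (k in (i + minLoop + 1L):j) {
        if (basesPair(x[i], x[k])) {
          v <- 1L + (if (k - i >= 2L) N[i + 1L, k - 1L] else 0L) +
            (if (k < j) N[k + 1L, j] else 0L)
          if (v > best) best <- v
        }
      }
      N[i, j] <- best
    }
  }
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i <= minLoop) next
    paired <- FALSE
    for (k in (i + minLoop + 1L):j) {    # 5'-most: pair i, smallest k first
      if (!basesPair(x[i], x[k])) next
      v <- 1L + (if (k - i >= 2L) N[i + 1L, k - 1L] else 0L) +
        (if (k < j) N[k + 1L, j] else 0L)
      if (v == N[i, j]) {
        db[i] <- "("; db[k] <- ")"
        stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  paste(db, collapse = "")
}

## induced alignment of sequences from their parses against one model
induceAlignment <- function(parses, seqs, ids, model) {
  K <- model@consensusLength
  ## insert-slot widths per anchor 0..K
  widths <- rep(0L, K + 1L)
  for (p in parses) {
    if (nrow(p$inserts)) {
      tb <- table(p$inserts$afterCol)
      a <- as.integer(names(tb)) + 1L
      widths[a] <- pmax(widths[a], as.integer(tb))
    }
  }
  nc <- K + sum(widths)
  rows <- character(length(parses))
  for (s in seq_along(parses)) {
    chars <- strsplit(chartr("T", "U", toupper(seqs[s])), "")[[1]]
    p <- parses[[s]]
    out <- character(0)
    insAt <- function(a) {
      pos <- sort(p$inserts$pos[p$inserts$afterCol == a])
      w <- widths[a + 1L]
      c(chars[pos], rep("-", w - length(pos)))
    }
    out <- c(out, insAt(0L))
    for (cc in seq_len(K)) {
      out <- c(out, if (is.na(p$colPos[cc])) "-" else chars[p$colPos[cc]])
      out <- c(out, insAt(cc))
    }
    rows[s] <- paste(out, collapse = "")
  }
  ## structure + labels over the induced columns
  ssc <- character(0); lbl <- character(0)
  mp <- model@matchPair
  ssChar <- ifelse(is.na(mp), ".", ifelse(mp > seq_len(K), "<", ">"))
  addIns <- function(a) {
    w <- widths[a + 1L]
    ssc <<- c(ssc, rep(".", w)); lbl <<- c(lbl, rep("", w))
  }
  addIns(0L)
  for (cc in seq_len(K)) {
    ssc <- c(ssc, ssChar[cc]); lbl <- c(lbl, model@positionMap[cc])
    addIns(cc)
  }
  new("SeedAlignment", ids = ids, seqs = rows,
      ssCons = paste(ssc, collapse = ""), positionLabels = lbl,
      domainTag = model@domainTag)
}

#' Iterative align-and-rebuild model refinement
#'
#' Repeatedly aligns all training sequences to the current model (maximum
#' score CYK parses), induces the implied multiple alignment, and rebuilds
#' the model from it, until the alignment is unchanged between iterations or
#' \code{maxIter} is reached. The summed training bit score is recorded per
#' iteration; note the first entry is scored under the bootstrap model,
#' whose absolute bit level is not comparable to the rebuilt models when its
#' training depth differs (pseudocount dilution). Among the rebuilt
#' iterates, a score decrease (oscillation) stops the loop with a warning,
#' and the returned model is always the best-scoring rebuilt iterate.
#'
#' @param seqs named character vector of unaligned training sequences.
#' @param seedModel bootstrap \linkS4class{CovarianceModel}.
#' @param maxIter maximum iterations (default 10).
#' @return list: \code{alignment} (\linkS4class{SeedAlignment}),
#'   \code{model}, \code{iterations}, \code{totalScores} (per iteration).
#' @export
iterativeAlign <- function(seqs, seedModel, maxIter = 10L) {
  if (!length(seqs)) stop("empty training set")
  ids <- if (is.null(names(seqs))) sprintf("seq%03d", seq_along(seqs)) else
    names(seqs)
  model <- seedModel
  prevRows <- NULL
  best <- NULL      # best among rebuilt iterates (scored from it >= 2)
  scores <- numeric(0)
  aln <- NULL
  for (it in seq_len(maxIter)) {
    res <- lapply(seqs, function(sq) scoreSequence(model, sq))
    total <- sum(vapply(res, function(r) r$score, numeric(1)))
    scores <- c(scores, total)
    aln <- induceAlignment(lapply(res, `[[`, "parse"), seqs, ids, model)
    if (it >= 2L && (is.null(best) || total > best$total))
      best <- list(alignment = aln, model = model, total = total, iter = it)
    if (!is.null(prevRows) && identical(aln@seqs, prevRows)) {
      ## the alignment reached at the previous iteration was already stable
      return(list(alignment = aln, model = model, iterations = it - 1L,
                  totalScores = scores))
    }
    if (it >= 3L && total < scores[it - 1L]) {
      warning("training score decreased at iteration ", it,
              "; returning the best-scoring iteration")
      return(list(alignment = best$alignment, model = best$model,
                  iterations = it, totalScores = scores))
    }
    prevRows <- aln@seqs
    model <- buildModel(aln, pseudocount = seedModel@pseudocount)
  }
  warning("no convergence within ", maxIter,
          " iterations; returning the best-scoring iteration")
  if (is.null(best)) best <- list(alignment = aln, model = model)
  list(alignment = best$alignment, model = best$model, iterations = maxIter,
       totalScores = scores)
}
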