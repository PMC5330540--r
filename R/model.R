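## Covariance model construction.
##
## The guide tree is derived deterministically from the consensus structure
## over the match columns; each node expands into the standard state set
## (pair/left/right match, delete, inserts, bifurcation plumbing). Emission
## and transition probabilities are Laplace-smoothed counts from the seed
## alignment; scores are log2 odds against an iid null.

NUC <- c("A", "C", "G", "U")

## ---- guide tree ----------------------------------------------------------

## mpair: partner vector over match columns (match-index space)
buildGuide <- function(mpair) {
  nodes <- list()
  add <- function(type, l = NA_integer_, r = NA_integer_) {
    nodes[[length(nodes) + 1L]] <<- list(id = length(nodes) + 1L, type = type,
                                         lcol = l, rcol = r,
                                         child1 = NA_integer_,
                                         child2 = NA_integer_)
    length(nodes)
  }
  setChild <- function(id, c1, c2 = NA_integer_) {
    nodes[[id]]$child1 <<- c1
    nodes[[id]]$child2 <<- c2
  }
  rec <- function(i, j) {
    if (i > j) return(add("END"))
    if (is.na(mpair[i])) {
      id <- add("MATL", l = i)
      setChild(id, rec(i + 1L, j))
      return(id)
    }
    if (is.na(mpair[j])) {
      id <- add("MATR", r = j)
      setChild(id, rec(i, j - 1L))
      return(id)
    }
    if (mpair[i] == j) {
      id <- add("MATP", l = i, r = j)
      setChild(id, rec(i + 1L, j - 1L))
      return(id)
    }
    k <- mpair[i]
    id <- add("BIF")
    bl <- add("BEGL")
    setChild(bl, rec(i, k))
    br <- add("BEGR")
    setChild(br, rec(k + 1L, j))
    setChild(id, bl, br)
    id
  }
  root <- add("ROOT")
  setChild(root, rec(1L, length(mpair)))
  do.call(rbind, lapply(nodes, function(n)
    data.frame(id = n$id, type = n$type, lcol = n$lcol, rcol = n$rcol,
               child1 = n$child1, child2 = n$child2)))
}

NODE_STATES <- list(
  ROOT = c("S", "IL", "IR"), MATP = c("MP", "ML", "MR", "D", "IL", "IR"),
  MATL = c("ML", "D", "IL"), MATR = c("MR", "D", "IR"),
  BIF = "B", BEGL = "S", BEGR = c("S", "IL"), END = "E")

SPLIT_STATES <- list(
  MATP = c("MP", "ML", "MR", "D"), MATL = c("ML", "D"), MATR = c("MR", "D"),
  BIF = "B", BEGL = "S", BEGR = "S", END = "E")

## states data.frame + children lists (in state-id space)
makeStates <- function(nodes) {
  st <- list()
  for (k in seq_len(nrow(nodes))) {
    for (tp in NODE_STATES[[nodes$type[k]]]) {
      st[[length(st) + 1L]] <- data.frame(node = nodes$id[k], type = tp)
    }
  }
  states <- do.call(rbind, st)
  states$id <- seq_len(nrow(states))
  stateOf <- function(nodeId, type)
    states$id[states$node == nodeId & states$type == type]
  splitOf <- function(nodeId)
    vapply(SPLIT_STATES[[nodes$type[nodes$id == nodeId]]],
           function(tp) stateOf(nodeId, tp), integer(1))
  children <- vector("list", nrow(states))
  for (s in seq_len(nrow(states))) {
    nd <- states$node[s]
    tp <- states$type[s]
    ntype <- nodes$type[nodes$id == nd]
    ch <- nodes$child1[nodes$id == nd]
    kids <- switch(tp,
      S = if (ntype == "ROOT")
            c(stateOf(nd, "IL"), stateOf(nd, "IR"), splitOf(ch))
          else if (ntype == "BEGR") c(stateOf(nd, "IL"), splitOf(ch))
          else splitOf(ch),
      MP = , ML = , MR = , D = {
        base <- splitOf(ch)
        if (ntype == "MATP") c(stateOf(nd, "IL"), stateOf(nd, "IR"), base)
        else if (ntype == "MATL") c(stateOf(nd, "IL"), base)
        else c(stateOf(nd, "IR"), base)
      },
      IL = {
        if (ntype %in% c("ROOT", "MATP"))
          c(stateOf(nd, "IL"), stateOf(nd, "IR"), splitOf(ch))
        else c(stateOf(nd, "IL"), splitOf(ch))
      },
      IR = c(stateOf(nd, "IR"), splitOf(ch)),
      B = integer(0),
      E = integer(0))
    children[[s]] <- unname(kids)
  }
  list(states = states, children = children,
       stateOf = NULL)
}

## ---- insert-column ownership --------------------------------------------

## Assign each non-match (insert) column to the insert state that emits it.
## Rules (5' preference): a gap after a left emission belongs to that node's
## IL; a gap before a right emission to that node's IR; a gap between a right
## and a left emission to the IL of the BEGR whose subtree starts at the next
## match column; leading/trailing gaps to the ROOT IL/IR.
assignInsertOwners <- function(nodes, states, matchOrig, ncol) {
  stateOf <- function(nodeId, type)
    states$id[states$node == nodeId & states$type == type]
  K <- length(matchOrig)
  evNode <- integer(K); evSide <- character(K); evCol <- integer(K)
  for (k in seq_len(nrow(nodes))) {
    if (!is.na(nodes$lcol[k])) {
      m <- nodes$lcol[k]
      evNode[m] <- nodes$id[k]; evSide[m] <- "L"; evCol[m] <- matchOrig[m]
    }
    if (!is.na(nodes$rcol[k])) {
      m <- nodes$rcol[k]
      evNode[m] <- nodes$id[k]; evSide[m] <- "R"; evCol[m] <- matchOrig[m]
    }
  }
  ord <- order(evCol)
  evNode <- evNode[ord]; evSide <- evSide[ord]; evCol <- evCol[ord]
  ## first match column of each node's subtree
  firstMatch <- rep(NA_integer_, nrow(nodes))
  rec <- function(id) {
    row <- which(nodes$id == id)
    cand <- c(if (!is.na(nodes$lcol[row])) matchOrig[nodes$lcol[row]],
              if (!is.na(nodes$rcol[row])) matchOrig[nodes$rcol[row]])
    for (ch in c(nodes$child1[row], nodes$child2[row])) {
      if (!is.na(ch)) cand <- c(cand, rec(ch))
    }
    firstMatch[row] <<- if (length(cand)) min(cand) else NA_integer_
    firstMatch[row]
  }
  rec(1L)
  rootId <- nodes$id[nodes$type == "ROOT"]
  owner <- rep(NA_integer_, ncol)
  insCols <- setdiff(seq_len(ncol), evCol)
  for (c0 in insCols) {
    prev <- which(evCol < c0)
    nxt <- which(evCol > c0)
    if (!length(prev)) {
      owner[c0] <- stateOf(rootId, "IL")
    } else if (!length(nxt)) {
      owner[c0] <- stateOf(rootId, "IR")
    } else {
      p <- prev[length(prev)]; q <- nxt[1]
      if (evSide[p] == "L") {
        owner[c0] <- stateOf(evNode[p], "IL")
      } else if (evSide[q] == "R") {
        owner[c0] <- stateOf(evNode[q], "IR")
      } else {
        begr <- which(nodes$type == "BEGR" & firstMatch == evCol[q])
        if (!length(begr))
          stop("internal error: no BEGR owns insert column ", c0)
        owner[c0] <- stateOf(nodes$id[begr[1]], "IL")
      }
    }
  }
  owner
}

## ---- parameter estimation ------------------------------------------------

encodeNuc <- function(chars) {
  code <- match(chars, NUC) - 1L
  code[chars == "N"] <- 4L
  code[is.na(code)] <- NA_integer_  # gaps
  code
}

#' Build a covariance model from a seed alignment
#'
#' Derives the consensus structure (see \code{\link{annotateStructure}}),
#' builds the guide tree over the match columns, counts state transitions and
#' emissions over the aligned rows (uniform sequence weights), applies the
#' pseudocount, and converts to bit scores against the null model.
#'
#' When \code{intronCap} is TRUE, the insert state at the canonical tRNA
#' intron point (immediately 3' of position 37, one base 3' of the anticodon)
#' has its self-transition bit score floored at \code{-0.1}, so that C-loop
#' introns of a few tens of nucleotides remain parseable at search time; this
#' affects scoring only, not the sampling probabilities.
#'
#' @param aln a \linkS4class{SeedAlignment} (>= 1 sequence).
#' @param pseudocount positive Laplace pseudocount for emissions (default 1).
#' @param transitionPseudocount positive pseudocount for transitions
#'   (default 1e-4; transitions see far fewer distinct outcomes than
#'   emissions, and a large pseudocount over-weights unobserved indel paths).
#' @param nullModel iid nucleotide null distribution (default uniform).
#' @param intronCap floor the intron-point insert extension penalty.
#' @return A \linkS4class{CovarianceModel}.
#' @export
buildModel <- function(aln, pseudocount = 1, transitionPseudocount = 1e-4,
                       nullModel = rep(0.25, 4), intronCap = TRUE) {
  if (!length(aln@seqs)) stop("empty alignment")
  if (pseudocount <= 0 || transitionPseudocount <= 0)
    stop("pseudocount must be positive")
  cs <- annotateStructure(aln)
  ncol <- length(cs@pairPartner)
  isM <- cs@isMatch
  matchOrig <- which(isM)
  K <- length(matchOrig)
  ## pairing restricted to match columns
  origPartner <- cs@pairPartner
  mpair <- rep(NA_integer_, K)
  for (k in seq_len(K)) {
    p <- origPartner[matchOrig[k]]
    if (!is.na(p) && isM[p]) mpair[k] <- match(p, matchOrig)
  }
  nodes <- buildGuide(mpair)
  ms <- makeStates(nodes)
  states <- ms$states
  children <- ms$children
  S <- nrow(states)
  owner <- assignInsertOwners(nodes, states, matchOrig, ncol)

  tCount <- lapply(children, function(ch) numeric(length(ch)))
  eS <- matrix(0, S, 4); eP <- matrix(0, S, 16)
  stateOf <- function(nodeId, type)
    states$id[states$node == nodeId & states$type == type]
  mainOf <- function(nodeRow, xl, xr) {
    tp <- nodes$type[nodeRow]
    switch(tp,
      MATP = if (!is.na(xl) && !is.na(xr)) "MP"
             else if (!is.na(xl)) "ML" else if (!is.na(xr)) "MR" else "D",
      MATL = if (!is.na(xl)) "ML" else "D",
      MATR = if (!is.na(xr)) "MR" else "D",
      ROOT = "S", BEGL = "S", BEGR = "S", BIF = "B", END = "E")
  }
  addT <- function(from, to) {
    k <- match(to, children[[from]])
    tCount[[from]][k] <<- tCount[[from]][k] + 1
  }
  ownedCols <- split(seq_len(ncol)[!is.na(owner)], owner[!is.na(owner)])

  for (sq in aln@seqs) {
    x <- encodeNuc(strsplit(sq, "")[[1]])
    insCount <- function(stId) {
      cols <- ownedCols[[as.character(stId)]]
      if (is.null(cols)) return(list(n = 0L, bases = integer(0)))
      b <- x[cols]; b <- b[!is.na(b)]
      list(n = length(b), bases = b)
    }
    emit <- function(stId, bases) {
      for (b in bases) if (b < 4L) eS[stId, b + 1L] <<- eS[stId, b + 1L] + 1
    }
    walk <- function(nodeId) {
      row <- which(nodes$id == nodeId)
      tp <- nodes$type[row]
      xl <- if (!is.na(nodes$lcol[row])) x[matchOrig[nodes$lcol[row]]] else NA
      xr <- if (!is.na(nodes$rcol[row])) x[matchOrig[nodes$rcol[row]]] else NA
      mtp <- mainOf(row, xl, xr)
      myMain <- stateOf(nodeId, mtp)
      if (mtp == "MP" && !is.na(xl) && !is.na(xr) && xl < 4L && xr < 4L)
        eP[myMain, xl * 4L + xr + 1L] <<- eP[myMain, xl * 4L + xr + 1L] + 1
      if (mtp == "ML" && !is.na(xl) && xl < 4L)
        eS[myMain, xl + 1L] <<- eS[myMain, xl + 1L] + 1
      if (mtp == "MR" && !is.na(xr) && xr < 4L)
        eS[myMain, xr + 1L] <<- eS[myMain, xr + 1L] + 1
      if (tp == "BIF") {
        walk(nodes$child1[row])
        walk(nodes$child2[row])
        return(myMain)
      }
      if (tp == "END") return(myMain)
      childEntry <- walk(nodes$child1[row])
      cur <- myMain
      ilId <- if ("IL" %in% NODE_STATES[[tp]]) stateOf(nodeId, "IL") else NA
      irId <- if ("IR" %in% NODE_STATES[[tp]]) stateOf(nodeId, "IR") else NA
      if (!is.na(ilId)) {
        ins <- insCount(ilId)
        if (ins$n > 0L) {
          addT(cur, ilId)
          if (ins$n > 1L) for (z in seq_len(ins$n - 1L)) addT(ilId, ilId)
          emit(ilId, ins$bases)
          cur <- ilId
        }
      }
      if (!is.na(irId)) {
        ins <- insCount(irId)
        if (ins$n > 0L) {
          addT(cur, irId)
          if (ins$n > 1L) for (z in seq_len(ins$n - 1L)) addT(irId, irId)
          emit(irId, ins$bases)
          cur <- irId
        }
      }
      addT(cur, childEntry)
      myMain
    }
    walk(nodes$id[nodes$type == "ROOT"])
  }

  ## smooth + normalize + log-odds
  a <- pseudocount
  ta <- transitionPseudocount
  tPr <- vector("list", S); tSc <- vector("list", S)
  for (s in seq_len(S)) {
    if (states$type[s] == "B") { tPr[[s]] <- numeric(0); tSc[[s]] <- numeric(0); next }
    if (!length(children[[s]])) { tPr[[s]] <- numeric(0); tSc[[s]] <- numeric(0); next }
    v <- tCount[[s]] + ta
    tPr[[s]] <- v / sum(v)
    tSc[[s]] <- log2(tPr[[s]])
  }
  eprS <- matrix(0.25, S, 4); escS <- matrix(0, S, 4)
  eprP <- matrix(1 / 16, S, 16); escP <- matrix(0, S, 16)
  nullP <- as.numeric(nullModel)
  for (s in seq_len(S)) {
    tp <- states$type[s]
    if (tp %in% c("ML", "MR", "IL", "IR")) {
      v <- eS[s, ] + a
      eprS[s, ] <- v / sum(v)
      escS[s, ] <- log2(eprS[s, ] / nullP)
    } else if (tp == "MP") {
      v <- eP[s, ] + a
      eprP[s, ] <- v / sum(v)
      escP[s, ] <- log2(eprP[s, ] / as.numeric(outer(nullP, nullP)))
    }
  }

  labels <- cs@labels[matchOrig]
  arm <- cs@arm[matchOrig]
  ## intron-point insert: the IL owning the gap 3' of the column labeled 37
  if (intronCap && "37" %in% labels) {
    c37 <- matchOrig[match("37", labels)]
    m37 <- match(c37, matchOrig)
    nrow37 <- which(!is.na(nodes$lcol) & nodes$lcol == m37)
    if (length(nrow37)) {
      il <- stateOf(nodes$id[nrow37], "IL")
      if (length(il) == 1L && length(tSc[[il]])) {
        self <- match(il, children[[il]])
        if (!is.na(self)) tSc[[il]][self] <- max(tSc[[il]][self], -0.1)
      }
    }
  }

  cons <- consSpanPerState(nodes, states)
  params <- list(version = 1L,
                 stType = states$type, stNode = states$node,
                 children = children, tPr = tPr, tSc = tSc,
                 eprS = eprS, escS = escS, eprP = eprP, escP = escP,
                 consSpan = cons,
                 emitLcol = stateEmitCol(nodes, states, "L"),
                 emitRcol = stateEmitCol(nodes, states, "R"),
                 insAfterCol = insertAnchors(nodes, states, K),
                 subtreeLo = subtreeSpan(nodes, states)$lo,
                 subtreeHi = subtreeSpan(nodes, states)$hi)
  mdl <- new("CovarianceModel", nodes = nodes, states = states,
             params = params, consensusLength = K, domainTag = aln@domainTag,
             positionMap = labels, matchArm = arm, matchPair = mpair,
             nullModel = nullP, pseudocount = as.numeric(a))
  validObject(mdl)
  mdl
}

## number of consensus (match) emissions in the subtree of each state's node
consSpanPerState <- function(nodes, states) {
  span <- rep(0L, nrow(nodes))
  rec <- function(id) {
    row <- which(nodes$id == id)
    s <- sum(!is.na(nodes$lcol[row])) + sum(!is.na(nodes$rcol[row]))
    for (ch in c(nodes$child1[row], nodes$child2[row]))
      if (!is.na(ch)) s <- s + rec(ch)
    span[row] <<- s
    s
  }
  rec(1L)
  span[match(states$node, nodes$id)]
}

## match column emitted on a given side by each state (0 when none)
stateEmitCol <- function(nodes, states, side) {
  col <- if (side == "L") nodes$lcol else nodes$rcol
  out <- integer(nrow(states))
  for (s in seq_len(nrow(states))) {
    row <- which(nodes$id == states$node[s])
    tp <- states$type[s]
    if (side == "L" && tp %in% c("MP", "ML") && !is.na(col[row]))
      out[s] <- col[row]
    if (side == "R" && tp %in% c("MP", "MR") && !is.na(col[row]))
      out[s] <- col[row]
  }
  out
}

## match-column span [lo, hi] of each state's node subtree (0/−1 for END)
subtreeSpan <- function(nodes, states) {
  lo <- rep(NA_integer_, nrow(nodes)); hi <- rep(NA_integer_, nrow(nodes))
  rec <- function(id) {
    row <- which(nodes$id == id)
    cand <- c(nodes$lcol[row], nodes$rcol[row])
    for (ch in c(nodes$child1[row], nodes$child2[row]))
      if (!is.na(ch)) { rec(ch); cand <- c(cand, lo[ch], hi[ch]) }
    cand <- cand[!is.na(cand)]
    lo[row] <<- if (length(cand)) min(cand) else 0L
    hi[row] <<- if (length(cand)) max(cand) else -1L
    invisible(NULL)
  }
  rec(1L)
  idx <- match(states$node, nodes$id)
  list(lo = lo[idx], hi = hi[idx])
}

## consensus (match-space) column immediately 5' of each insert state's
## insertion point; NA for non-insert states
insertAnchors <- function(nodes, states, K) {
  firstMatch <- rep(NA_integer_, nrow(nodes))
  rec <- function(id) {
    row <- which(nodes$id == id)
    cand <- c(nodes$lcol[row], nodes$rcol[row])
    for (ch in c(nodes$child1[row], nodes$child2[row]))
      if (!is.na(ch)) cand <- c(cand, rec(ch))
    cand <- cand[!is.na(cand)]
    firstMatch[row] <<- if (length(cand)) min(cand) else NA_integer_
    firstMatch[row]
  }
  rec(1L)
  out <- rep(NA_integer_, nrow(states))
  for (s in seq_len(nrow(states))) {
    tp <- states$type[s]
    if (!tp %in% c("IL", "IR")) next
    row <- which(nodes$id == states$node[s])
    nt <- nodes$type[row]
    out[s] <- if (tp == "IL") {
      switch(nt, ROOT = 0L, BEGR = firstMatch[row] - 1L, nodes$lcol[row])
    } else {
      switch(nt, ROOT = K, nodes$rcol[row] - 1L)
    }
  }
  out
}

checkModelNormalization <- function(model, tol = 1e-9) {
  p <- model@params
  for (s in seq_along(p$tPr)) {
    if (length(p$tPr[[s]]) && abs(sum(p$tPr[[s]]) - 1) > tol)
      return(sprintf("transition row of state %d does not sum to 1", s))
  }
  tp <- p$stType
  singlet <- tp %in% c("ML", "MR", "IL", "IR")
  if (any(abs(rowSums(p$eprS[singlet, , drop = FALSE]) - 1) > tol))
    return("singlet emission row does not sum to 1")
  pairs <- tp == "MP"
  if (any(abs(rowSums(p$eprP[pairs, , drop = FALSE]) - 1) > tol))
    return("pair emission row does not sum to 1")
  TRUE
}

## ---- serialization -------------------------------------------------------

#' Write / read a covariance model (versioned JSON)
#'
#' The serialization stores probabilities and bit scores at full precision,
#' so a written-and-reread model reproduces scores bit-exactly.
#'
#' @param model a \linkS4class{CovarianceModel}.
#' @param path file path.
#' @return \code{readModel} returns the \linkS4class{CovarianceModel};
#'   \code{writeModel} returns \code{path} invisibly.
#' @export
writeModel <- function(model, path) {
  obj <- list(format = "secScan-cm", version = 1L,
              domainTag = model@domainTag,
              consensusLength = model@consensusLength,
              positionMap = model@positionMap,
              matchArm = model@matchArm,
              matchPair = model@matchPair,
              nullModel = model@nullModel,
              pseudocount = model@pseudocount,
              nodes = model@nodes,
              states = model@states,
              params = model@params[setdiff(names(model@params), "version")])
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "secScan-cm"))
    stop("not a secScan covariance model file")
  p <- obj$params
  p$version <- 1L
  p$children <- lapply(p$children, as.integer)
  p$tPr <- lapply(p$tPr, as.numeric)
  p$tSc <- lapply(p$tSc, as.numeric)
  for (m in c("eprS", "escS", "eprP", "escP")) p[[m]] <- as.matrix(p[[m]])
  p$consSpan <- as.integer(p$consSpan)
  p$emitLcol <- as.integer(p$emitLcol)
  p$emitRcol <- as.integer(p$emitRcol)
  p$insAfterCol <- as.integer(p$insAfterCol)
  p$subtreeLo <- as.integer(p$subtreeLo)
  p$subtreeHi <- as.integer(p$subtreeHi)
  nodes <- as.data.frame(obj$nodes)
  for (cc in c("id", "lcol", "rcol", "child1", "child2"))
    nodes[[cc]] <- as.integer(nodes[[cc]])
  states <- as.data.frame(obj$states)
  states$node <- as.integer(states$node); states$id <- as.integer(states$id)
  mdl <- new("CovarianceModel", nodes = nodes, states = states, params = p,
             consensusLength = as.integer(obj$consensusLength),
             domainTag = obj$domainTag,
             positionMap = as.character(obj$positionMap),
             matchArm = as.character(obj$matchArm),
             matchPair = as.integer(obj$matchPair),
             nullModel = as.numeric(obj$nullModel),
             pseudocount = as.numeric(obj$pseudocount))
  validObject(mdl)
  mdl
}
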