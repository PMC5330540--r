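## Helices = maximal runs of directly nested pairs (i,j),(i+1,j-1).
## Bulged stems therefore split into separate helices; the bundled seeds
## use clean helices, and bulges in genomic hits are insert states, so the
## consensus topology is always a plain cloverleaf plus V-arm.
findHelices <- function(partner) {
  opens <- which(!is.na(partner) & partner > seq_along(partner))
  helices <- list()
  used <- logical(length(partner))
  for (i in opens) {
    if (used[i]) next
    a <- i; b <- partner[i]
    run_i <- integer(0); run_j <- integer(0)
    while (a <= length(partner) && !is.na(partner[a]) && partner[a] == b &&
           b > a) {
      used[a] <- TRUE
      run_i <- c(run_i, a); run_j <- c(run_j, b)
      a <- a + 1L; b <- b - 1L
    }
    helices[[length(helices) + 1L]] <- list(i = run_i, j = run_j)
  }
  helices
}

#' Annotate the cloverleaf architecture of a seed alignment
#'
#' Derives the consensus pairing from the WUSS line, groups pairs into
#' helices, and assigns each column to a tRNA arm. The topology must be a
#' cloverleaf with a variable arm: one outer helix (the acceptor stem) whose
#' multiloop contains exactly four hairpin helices, in 5'->3' order the
#' D, anticodon (C), variable (V) and T arms. Explicit per-column position
#' labels from the alignment are used when present; otherwise canonical
#' tRNA position labels are inferred from the arm layout.
#'
#' @param aln a \linkS4class{SeedAlignment}.
#' @return A \linkS4class{ConsensusStructure}.
#' @export
annotateStructure <- function(aln) {
  partner <- wussPairs(aln@ssCons)
  n <- length(partner)
  helices <- findHelices(partner)
  if (!length(helices)) stop("structure error: no pairs")
  ## outer helix: pairs not nested inside any other pair
  outermost <- vapply(helices, function(h) {
    i <- h$i[1]
    !any(!is.na(partner) & seq_len(n) < i & partner > h$j[1])
  }, logical(1))
  if (sum(outermost) != 1L)
    stop("structure error: expected a single acceptor helix, found ",
         sum(outermost))
  acc <- helices[[which(outermost)]]
  inner_lo <- acc$i[length(acc$i)] + 1L
  inner_hi <- acc$j[length(acc$j)] - 1L
  inner <- helices[!outermost]
  inside <- vapply(inner, function(h) h$i[1] >= inner_lo && h$j[1] <= inner_hi,
                   logical(1))
  if (!all(inside)) stop("structure error: helix outside the acceptor stem")
  ## top-level helices of the multiloop (not nested in another inner helix)
  starts <- vapply(inner, function(h) h$i[1], integer(1))
  ends <- vapply(inner, function(h) h$j[1], integer(1))
  top <- vapply(seq_along(inner), function(k) {
    !any(starts < starts[k] & ends > ends[k])
  }, logical(1))
  if (any(!top)) stop("structure error: nested helix inside an arm")
  o <- order(starts)
  arms4 <- inner[o]
  if (length(arms4) != 4L)
    stop("structure error: expected 4 stems inside the acceptor multiloop, found ",
         length(arms4))
  stem_names <- c("D-stem", "C-stem", "V-stem", "T-stem")
  loop_names <- c("D-loop", "C-loop", "V-loop", "T-loop")
  arm <- rep("linker", n)
  arm[c(acc$i, acc$j)] <- "A-stem"
  for (k in 1:4) {
    h <- arms4[[k]]
    arm[c(h$i, h$j)] <- stem_names[k]
    lo <- h$i[length(h$i)] + 1L; hi <- h$j[length(h$j)] - 1L
    if (lo > hi) stop("structure error: empty ", loop_names[k])
    arm[lo:hi] <- loop_names[k]
  }
  labels <- if (length(aln@positionLabels)) aln@positionLabels else
    inferPositionLabels(arm, partner)
  cs <- new("ConsensusStructure", pairPartner = partner, arm = arm,
            isMatch = matchColumns(aln), labels = labels)
  validObject(cs)
  cs
}

## Canonical tRNA position labels from the arm layout. Anchors required by the
## annotation pipeline: 18/19 (D-loop), 33-36 (anticodon loop), 55 (T-loop),
## 61 (last T-loop column, so that the discriminator is its 14th 3' residue
## when the AT-stem has 13 bp) and 66 (first acceptor 3' column).
inferPositionLabels <- function(arm, partner) {
  n <- length(arm)
  labels <- rep("", n)
  with_suffix <- function(base, k) {
    if (k <= length(base)) return(base[seq_len(k)])
    extra <- paste0(base[length(base)], letters[seq_len(k - length(base))])
    c(base, extra)
  }
  five_prime <- function(cols) cols[partner[cols] > cols]
  asm <- which(arm == "A-stem")
  a5 <- five_prime(asm); a3 <- sort(partner[a5])
  labels[a5] <- with_suffix(as.character(1:7), length(a5))
  labels[a3] <- with_suffix(as.character(66:72), length(a3))
  lk <- which(arm == "linker" & seq_len(n) > max(a5) &
              seq_len(n) < min(which(arm == "D-stem")))
  labels[lk] <- with_suffix(c("8", "9"), length(lk))
  dsm <- which(arm == "D-stem")
  d5 <- five_prime(dsm); d3 <- sort(partner[d5])
  labels[d5] <- with_suffix(as.character(10:13), length(d5))
  labels[d3] <- with_suffix(as.character(22:25), length(d3))
  dl <- which(arm == "D-loop")
  pool <- as.character(14:20)
  labels[dl] <- if (length(dl) <= 7) utils::tail(pool, length(dl)) else
    with_suffix(pool, length(dl))
  lk2 <- which(arm == "linker" & seq_len(n) > max(dsm) &
               seq_len(n) < min(which(arm == "C-stem")))
  labels[lk2] <- with_suffix("26", length(lk2))
  csm <- which(arm == "C-stem")
  c5 <- five_prime(csm); c3 <- sort(partner[c5])
  labels[c5] <- with_suffix(as.character(27:31), length(c5))
  labels[c3] <- with_suffix(as.character(39:43), length(c3))
  cl <- which(arm == "C-loop")
  L <- length(cl)
  mid <- (L - 3L) %/% 2L           # columns 5' of the anticodon triplet
  pre <- rev(utils::head(c("33", "32", "32a", "32b"), mid))
  post <- utils::head(c("37", "38", "38a", "38b"), L - 3L - mid)
  labels[cl] <- c(pre, "34", "35", "36", post)
  vsm <- which(arm == "V-stem")
  v5 <- five_prime(vsm); v3 <- sort(partner[v5])
  labels[v5] <- with_suffix("44", length(v5))
  labels[v3] <- with_suffix("46", length(v3))
  vl <- which(arm == "V-loop")
  labels[vl] <- with_suffix("45", length(vl))
  tsm <- which(arm == "T-stem")
  t5 <- five_prime(tsm); t3 <- sort(partner[t5])
  labels[t5] <- with_suffix(as.character(49:52), length(t5))
  labels[t3] <- with_suffix(as.character(62:65), length(t3))
  tl <- which(arm == "T-loop")
  k <- length(tl)
  labels[tl] <- c(with_suffix(as.character(54:60), k - 1L), "61")
  labels
}

#' Per-arm consensus pair counts
#'
#' @param cs a \linkS4class{ConsensusStructure}.
#' @return named integer vector of pair counts for the five stems.
#' @export
consensusPairCounts <- function(cs) {
  stems <- c("A-stem", "D-stem", "C-stem", "V-stem", "T-stem")
  out <- vapply(stems, function(s) {
    cols <- which(cs@arm == s & !is.na(cs@pairPartner))
    length(cols) %/% 2L
  }, integer(1))
  names(out) <- stems
  out
}
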