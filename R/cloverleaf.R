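## Cloverleaf rendering: a deterministic text diagram and an SVG drawing
## with the arm colour scheme (acceptor red, D yellow, anticodon green,
## variable blue, T purple), wobble pairs faint, anticodon and discriminator
## circled.

ARM_COLORS <- c("A-stem" = "#d62728", "D-stem" = "#e6b817",
                "D-loop" = "#e6b817", "C-stem" = "#2ca02c",
                "C-loop" = "#2ca02c", "V-stem" = "#1f77b4",
                "V-loop" = "#1f77b4", "T-stem" = "#9467bd",
                "T-loop" = "#9467bd", "linker" = "#7f7f7f")

candidateGlyphs <- function(cand, model) {
  parse <- mcols(cand)$parse[[1]]
  sq <- chartr("T", "U", mcols(cand)$matchedSeq[1])
  chars <- strsplit(sq, "")[[1]]
  arm <- model@matchArm
  mp <- model@matchPair
  baseAt <- function(col) {
    p <- parse$colPos[col]
    if (is.na(p)) "-" else chars[p]
  }
  list(parse = parse, chars = chars, arm = arm, mp = mp, baseAt = baseAt)
}

pairGlyph <- function(a, b) {
  if (a == "-" || b == "-" || !basesPair(a, b)) return(".")
  if (paste0(a, b) %in% c("GU", "UG")) ":" else "|"
}

#' Render a candidate as a cloverleaf
#'
#' Text mode prints one block per arm: the 5' strand, a pairing line
#' (\code{|} Watson-Crick, \code{:} wobble GU/UG, \code{.} broken), and the
#' 3' strand, followed by loop sequences; the anticodon is bracketed and the
#' discriminator base parenthesised. Output is deterministic. With
#' \code{svgPath}, an SVG drawing with arm colours is also written: arms are
#' laid out in cloverleaf orientation, wobble pairs drawn faint, and the
#' anticodon and discriminator circled.
#'
#' @param cand a single annotated candidate (\code{GRanges} row) from
#'   \code{\link{annotateCandidates}}.
#' @param model the candidate's model.
#' @param svgPath optional SVG output path.
#' @return character vector of text lines, invisibly when \code{svgPath} is
#'   given.
#' @export
renderCloverleaf <- function(cand, model, svgPath = NULL) {
  g <- candidateGlyphs(cand, model)
  mc <- mcols(cand)
  lines <- c(sprintf("tRNA-Sec cloverleaf  [%s]  score %.1f bits",
                     mc$domain[1], mc$score[1]),
             sprintf("fold %s (AT-stem %d bp)", mc$fold[1], mc$atTotal[1]))
  stems <- list(c("A-stem", NA), c("D-stem", "D-loop"),
                c("C-stem", "C-loop"), c("V-stem", "V-loop"),
                c("T-stem", "T-loop"))
  for (sl in stems) {
    s <- sl[1]
    i5 <- which(g$arm == s & !is.na(g$mp) & g$mp > seq_along(g$mp))
    b5 <- vapply(i5, g$baseAt, character(1))
    b3 <- vapply(g$mp[i5], g$baseAt, character(1))
    bars <- vapply(seq_along(i5), function(t) pairGlyph(b5[t], b3[t]),
                   character(1))
    lines <- c(lines,
               sprintf("%-7s 5' %s 3'", s, paste(b5, collapse = " ")),
               sprintf("%10s %s", "", paste(bars, collapse = " ")),
               sprintf("%7s 3' %s 5'", "", paste(b3, collapse = " ")))
    if (!is.na(sl[2])) {
      lc <- which(g$arm == sl[2])
      lb <- vapply(lc, g$baseAt, character(1))
      if (sl[2] == "C-loop") {
        ac <- match(c("34", "35", "36"), model@positionMap)
        pos <- match(ac, lc)
        if (!anyNA(pos))
          lb[pos] <- c(paste0("[", lb[pos[1]]),
                       lb[pos[2]], paste0(lb[pos[3]], "]"))
      }
      lines <- c(lines, sprintf("%-7s    %s", sl[2], paste(lb, collapse = " ")))
    }
  }
  disc <- mc$discriminator[1]
  lines <- c(lines,
             if (!is.na(disc)) sprintf("discriminator: (%s)%s", disc,
                                       if (isTRUE(mc$g73[1])) " = G73" else "")
             else "discriminator: undefined",
             sprintf("genomic CCA tail: %s", tolower(mc$cca[1])))
  if (!is.null(svgPath)) {
    writeCloverleafSvg(cand, model, svgPath)
    return(invisible(lines))
  }
  lines
}

## SVG layout: stems drawn as two parallel base rows along fixed arm
## directions (acceptor up, D left, anticodon down-left, V down-right,
## T right), loops fanned at the stem tips
writeCloverleafSvg <- function(cand, model, path) {
  g <- candidateGlyphs(cand, model)
  mc <- mcols(cand)
  dirs <- list("A-stem" = c(0, -1), "D-stem" = c(-1, 0),
               "C-stem" = c(-0.45, 0.9), "V-stem" = c(0.45, 0.9),
               "T-stem" = c(1, 0))
  ortho <- function(d) c(-d[2], d[1])
  cx <- 320; cy <- 300; step <- 22; gapw <- 9
  elems <- character(0)
  circle <- function(x, y, base, fill, extra = "") {
    sprintf(paste0('<circle cx="%.1f" cy="%.1f" r="9" fill="%s" %s/>',
                   '<text x="%.1f" y="%.1f" text-anchor="middle" ',
                   'font-size="10" font-family="monospace">%s</text>'),
            x, y, fill, extra, x, y + 3.5, base)
  }
  acCols <- match(c("34", "35", "36"), model@positionMap)
  c61 <- match("61", model@positionMap)
  for (s in names(dirs)) {
    d <- dirs[[s]]; o <- ortho(d)
    i5 <- which(g$arm == s & !is.na(g$mp) & g$mp > seq_along(g$mp))
    if (!length(i5)) next
    loopName <- sub("-stem", "-loop", s)
    col <- ARM_COLORS[[s]]
    for (t in seq_along(i5)) {
      x0 <- cx + d[1] * step * (t + 1); y0 <- cy + d[2] * step * (t + 1)
      b5 <- g$baseAt(i5[t]); b3 <- g$baseAt(g$mp[i5[t]])
      x5 <- x0 - o[1] * gapw; y5 <- y0 - o[2] * gapw
      x3 <- x0 + o[1] * gapw; y3 <- y0 + o[2] * gapw
      faint <- if (paste0(b5, b3) %in% c("GU", "UG")) ' opacity="0.35"' else ""
      if (b5 != "-" && b3 != "-" && basesPair(b5, b3))
        elems <- c(elems, sprintf(
          '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="%s"%s/>',
          x5, y5, x3, y3, col, faint))
      elems <- c(elems, circle(x5, y5, b5, col), circle(x3, y3, b3, col))
    }
    lc <- which(g$arm == loopName)
    if (length(lc)) {
      tipX <- cx + d[1] * step * (length(i5) + 2)
      tipY <- cy + d[2] * step * (length(i5) + 2)
      nl <- length(lc)
      for (t in seq_len(nl)) {
        ang <- atan2(d[2], d[1]) + pi * (t / (nl + 1) - 0.5)
        x <- tipX + cos(ang) * step * 1.4
        y <- tipY + sin(ang) * step * 1.4
        extra <- if (!anyNA(acCols) && lc[t] %in% acCols)
          'stroke="black" stroke-width="2"' else ""
        elems <- c(elems, circle(x, y, g$baseAt(lc[t]),
                                 ARM_COLORS[[loopName]], extra))
      }
    }
  }
  ## discriminator, circled, past the acceptor 3' end
  disc <- mc$discriminator[1]
  if (!is.na(disc))
    elems <- c(elems, circle(cx + 30, cy - 30, disc, "#ffffff",
                             'stroke="black" stroke-width="2"'))
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="640" height="620">'),
           sprintf('<title>tRNA-Sec %s score %.1f</title>',
                   mc$domain[1], mc$score[1]),
           elems, "</svg>")
  writeLines(svg, path)
  invisible(path)
}
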