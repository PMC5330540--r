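#!/usr/bin/env Rscript
## Regenerates the bundled seed alignments under inst/extdata/models.
## Run from the repository root. Deterministic: fixed seeds.
suppressMessages(library(methods))
if (requireNamespace("secScan", quietly = TRUE)) {
  library(secScan)
} else {
  library(Rcpp)
  for (f in list.files("R", full.names = TRUE)) source(f)
  sourceCpp("src/cyk.cpp")
}
dir.create("inst/extdata/models", recursive = TRUE, showWarnings = FALSE)
seeds <- c(eukaryota = 101L, bacteria = 102L, archaea = 103L,
           canonical = 104L)
for (dom in names(seeds)) {
  aln <- makeSeedStockholm(dom, n = 128L, seed = seeds[[dom]])
  writeStockholm(aln, file.path("inst/extdata/models", paste0(dom, ".stk")))
  cat(dom, ":", length(aln@ids), "sequences x", nchar(aln@ssCons),
      "columns\n")
}
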