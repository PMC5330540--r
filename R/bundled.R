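.modelCache <- new.env(parent = emptyenv())

#' Bundled seed alignments and models
#'
#' The package ships four seed alignments under
#' \code{inst/extdata/models}: the three tRNA-Sec domain seeds (eukaryota:
#' 9/4 fold, 6-bp D-stem; bacteria: 8/5 fold, 6-bp D-stem; archaea: 9/4
#' fold, 7-bp D-stem; all with the 13-bp AT-stem) and a canonical 7/5
#' tRNA decoy seed. They are synthetic alignments generated with
#' \code{\link{makeSeedStockholm}}. \code{bundledModel} builds (and caches)
#' the covariance model from a bundled seed.
#'
#' @param domain one of "eukaryota", "bacteria", "archaea", "canonical".
#' @return \code{bundledSeed}: a \linkS4class{SeedAlignment};
#'   \code{bundledModel}: a \linkS4class{CovarianceModel}.
#' @export
bundledSeed <- function(domain = c("eukaryota", "bacteria", "archaea",
                                   "canonical")) {
  domain <- match.arg(domain)
  path <- system.file("extdata", "models", paste0(domain, ".stk"),
                      package = "secScan", mustWork = TRUE)
  readStockholm(path)
}

#' @rdname bundledSeed
#' @export
bundledModel <- function(domain = c("eukaryota", "bacteria", "archaea",
                                    "canonical")) {
  domain <- match.arg(domain)
  if (is.null(.modelCache[[domain]]))
    .modelCache[[domain]] <- buildModel(bundledSeed(domain))
  .modelCache[[domain]]
}

#' The three tRNA-Sec search models
#'
#' @return named list of the eukaryota, bacteria and archaea
#'   \linkS4class{CovarianceModel}s.
#' @export
bundledSearchModels <- function() {
  doms <- c("eukaryota", "bacteria", "archaea")
  stats::setNames(lapply(doms, bundledModel), doms)
}
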