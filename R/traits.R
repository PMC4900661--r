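#' Canonical trait set of the jatropha half-sib trial
#'
#' The three seed traits analysed throughout the package, in the fixed
#' order used by every covariance matrix and genotypic-value matrix:
#' weight of 100 seeds (`W100S`, g), seed oil content (`SOC`, %), and
#' phorbol ester concentration (`PEC`, mg/g). Row/column 1 of any 3x3
#' trait matrix is always W100S, 2 is SOC, 3 is PEC.
#'
#' @return Named character vector of trait units, names are the trait
#'   labels in canonical order.
#' @examples
#' trait_set()
#' @export
trait_set <- function() {
  c(W100S = "g", SOC = "%", PEC = "mg/g")
}

# resolve the trait labels present in a phenotype table against a
# reference ordering: canonical labels keep canonical order, anything
# else keeps first-appearance order
trait_levels <- function(traits) {
  u <- unique(as.character(traits))
  canon <- names(trait_set())
  if (all(u %in% canon)) canon[canon %in% u] else u
}

# check a set of labels against the canonical traits, error on strangers
match_traits <- function(labels, universe = names(trait_set())) {
  labels <- as.character(labels)
  bad <- setdiff(labels, universe)
  if (length(bad)) {
    stop(sprintf("unknown trait label(s): %s (expected among %s)",
                 paste(bad, collapse = ", "),
                 paste(universe, collapse = ", ")), call. = FALSE)
  }
  labels
}
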