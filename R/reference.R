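#' Reference trait covariance matrices from the jatropha half-sib trial
#'
#' Posterior-mean genetic (`G0`) and residual (`R0`) covariance matrices
#' estimated for 179 jatropha half-sib families evaluated in 2 blocks for
#' weight of 100 seeds (W100S, g), seed oil content (SOC, %) and phorbol
#' ester concentration (PEC, mg/g). These published point estimates serve
#' two roles: default dispersion truths for the trial simulator
#' ([sim_config()]) and plug-in inputs for the selection-index and
#' derived-parameter calculations when no chain is at hand.
#'
#' @return List with components `G0` and `R0`, each a named 3x3 symmetric
#'   positive-definite matrix in canonical trait order (see [trait_set()]).
#' @examples
#' ref <- reference_covariances()
#' diag(ref$G0) / diag(ref$G0 + ref$R0)  # heritabilities
#' @export
reference_covariances <- function() {
  tr <- names(trait_set())
  G0 <- matrix(c(15.522,  0.891, -0.319,
                  0.891,  0.359, -0.004,
                 -0.319, -0.004,  0.373),
               3, 3, dimnames = list(tr, tr))
  R0 <- matrix(c( 7.498,  0.008, -0.080,
                  0.008,  2.416,  0.016,
                 -0.080,  0.016,  0.312),
               3, 3, dimnames = list(tr, tr))
  list(G0 = G0, R0 = R0)
}
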