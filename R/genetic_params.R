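# Derived genetic parameters: heritabilities, phenotypic (co)variances,
# genotypic and phenotypic correlations, computed either per posterior
# draw (then summarized) or as plug-in values from posterior-mean
# covariance matrices. The two variants answer different questions and
# need not agree when the posterior is diffuse; both are always reported.

#' Narrow-sense heritability from variance components
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`. Vectorized over draws.
#'
#' @param sigma_g2 Genetic variance(s), non-negative.
#' @param sigma_e2 Residual variance(s), non-negative.
#' @return Heritability in `[0, 1]`.
#' @examples
#' heritability(0.373, 0.312)  # 0.545 for phorbol ester concentration
#' @export
heritability <- function(sigma_g2, sigma_e2) {
  if (any(sigma_g2 < 0) || any(sigma_e2 < 0))
    stop("variance components must be non-negative", call. = FALSE)
  tot <- sigma_g2 + sigma_e2
  if (any(tot == 0))
    stop("sigma_g2 + sigma_e2 must be positive", call. = FALSE)
  sigma_g2 / tot
}

#' Correlation from a covariance and two variances
#'
#' `r = cov / sqrt(var1 * var2)`, clamped to `[-1, 1]` when floating-point
#' rounding of the inputs pushes it marginally outside.
#'
#' @param cov Covariance(s).
#' @param var1,var2 Positive variances.
#' @return Correlation in `[-1, 1]`.
#' @examples
#' correlation_from_cov(-0.319, 15.522, 0.373)
#' @export
correlation_from_cov <- function(cov, var1, var2) {
  if (any(var1 <= 0) || any(var2 <= 0))
    stop("variances must be positive", call. = FALSE)
  pmin(1, pmax(-1, cov / sqrt(var1 * var2)))
}

#' Phenotypic covariance matrix
#'
#' Entrywise sum `P = G0 + R0` of the genetic and residual trait
#' covariance matrices.
#'
#' @param G0,R0 Symmetric positive semi-definite trait covariance
#'   matrices of equal dimension.
#' @return The phenotypic covariance matrix.
#' @examples
#' ref <- reference_covariances()
#' diag(phenotypic_cov(ref$G0, ref$R0))
#' @export
phenotypic_cov <- function(G0, R0) {
  d <- nrow(G0)
  check_psd_named(G0, "G0", d)
  check_psd_named(R0, "R0", nrow(R0))
  if (!all(dim(G0) == dim(R0)))
    stop("G0 and R0 must have the same dimension", call. = FALSE)
  G0 + R0
}

# per-draw derived chains from a fit: h2 and sigma_p2 per trait, r_g and
# r_p per pair; returns a named matrix of chains
derived_chains <- function(fit) {
  stopifnot(inherits(fit, "mt_gibbs"), fit$genetic)
  traits <- fit$traits
  d <- length(traits)
  S <- fit$n_draws
  out <- NULL; labs <- character(0)
  for (i in seq_len(d)) {
    vg <- fit$G0[i, i, ]; ve <- fit$R0[i, i, ]
    out <- cbind(out, vg / (vg + ve), vg + ve)
    labs <- c(labs, sprintf("h2(%s)", traits[i]), sprintf("sigma2_p(%s)", traits[i]))
  }
  if (d > 1L) for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    rg <- fit$G0[i, j, ] / sqrt(fit$G0[i, i, ] * fit$G0[j, j, ])
    pij <- fit$G0[i, j, ] + fit$R0[i, j, ]
    rp <- pij / sqrt((fit$G0[i, i, ] + fit$R0[i, i, ]) *
                     (fit$G0[j, j, ] + fit$R0[j, j, ]))
    out <- cbind(out, rg, rp)
    labs <- c(labs, sprintf("r_g(%s,%s)", traits[i], traits[j]),
              sprintf("r_p(%s,%s)", traits[i], traits[j]))
  }
  colnames(out) <- labs
  out
}

#' Derived genetic parameters from a fitted model
#'
#' Computes heritabilities, phenotypic variances, and genotypic and
#' phenotypic correlations in two clearly separated variants: (i)
#' per-draw values of each derived quantity summarized over the chain
#' (posterior mean, median, mode, SD, HPD bounds, diagnostics), and (ii)
#' plug-in values obtained from the posterior-mean `G0` and `R0`. The
#' variants coincide as the posterior concentrates but can differ for
#' diffuse posteriors of ratio quantities; neither is silently preferred.
#'
#' @param fit An [fit_gibbs()] object with `genetic = TRUE`.
#' @param hpd_mass HPD interval mass for the per-draw summaries.
#' @return Object of class `mt_genetic_params`: list with `per_draw`
#'   (summary `data.frame`, one row per derived parameter),
#'   `per_draw_mean` (named vector of posterior means of the per-draw
#'   values), and `plugin` (list `G0`, `R0`, `P`, `h2`, `sigma_p2`, `r_g`,
#'   `r_p` from posterior-mean matrices).
#' @export
derive_report <- function(fit, hpd_mass = 0.95) {
  ch <- derived_chains(fit)
  per_draw_mean <- colMeans(ch)
  per_draw <- if (fit$n_draws >= 20L) {
    s <- do.call(rbind, lapply(seq_len(ncol(ch)), function(j)
      summarize_chain(ch[, j], hpd_mass = hpd_mass)))
    rownames(s) <- colnames(ch)
    s
  }
  G0bar <- apply(fit$G0, c(1, 2), mean)
  R0bar <- apply(fit$R0, c(1, 2), mean)
  dimnames(G0bar) <- dimnames(R0bar) <- list(fit$traits, fit$traits)
  P <- G0bar + R0bar
  plugin <- list(
    G0 = G0bar, R0 = R0bar, P = P,
    h2 = setNames(diag(G0bar) / diag(P), fit$traits),
    sigma_p2 = setNames(diag(P), fit$traits),
    r_g = stats::cov2cor(G0bar),
    r_p = stats::cov2cor(P)
  )
  structure(list(per_draw = per_draw, per_draw_mean = per_draw_mean,
                 plugin = plugin, traits = fit$traits),
            class = "mt_genetic_params")
}

#' @export
print.mt_genetic_params <- function(x, digits = 3, ...) {
  cat("Derived genetic parameters\n\nPlug-in (posterior-mean G0, R0):\n")
  cat("  heritabilities:\n")
  print(round(x$plugin$h2, digits))
  cat("  phenotypic variances:\n")
  print(round(x$plugin$sigma_p2, digits))
  cat("  genotypic correlations:\n")
  print(round(x$plugin$r_g, digits))
  cat("  phenotypic correlations:\n")
  print(round(x$plugin$r_p, digits))
  if (!is.null(x$per_draw)) {
    cat("\nPer-draw posterior summaries:\n")
    print(round(as.data.frame(x$per_draw)[
      , c("PM", "PMD", "PSD", "HPD_low", "HPD_high")], digits))
  }
  invisible(x)
}

#' Export derived parameters as delimited tables
#'
#' Writes the per-draw posterior summary table (one row per derived
#' parameter, variance-component-report columns) and a correlation table
#' (heritabilities on the diagonal, genotypic correlations above,
#' phenotypic below — plug-in variant).
#'
#' @param report An [derive_report()] object.
#' @param summary_path,correlation_path Output CSV paths (`NULL` skips).
#' @return Invisible `NULL`.
#' @export
write_genetic_params <- function(report, summary_path = NULL, correlation_path = NULL) {
  stopifnot(inherits(report, "mt_genetic_params"))
  if (!is.null(summary_path) && !is.null(report$per_draw)) {
    utils::write.csv(data.frame(parameter = rownames(report$per_draw),
                                report$per_draw, check.names = FALSE),
                     summary_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(correlation_path)) {
    m <- report$plugin$r_g
    m[lower.tri(m)] <- report$plugin$r_p[lower.tri(m)]
    diag(m) <- report$plugin$h2
    utils::write.csv(data.frame(trait = rownames(m), m, check.names = FALSE),
                     correlation_path, row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}
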