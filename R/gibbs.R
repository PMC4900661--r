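# Gibbs sampler for the multi-trait half-sib mixed model
#
#   y_ijk = mu_i + b_ik + g_ij + e_ijk
#
# with g_j ~ N(0, G0) iid across families, record residual vectors
# e ~ N(0, R0) iid across family-by-block records (homogeneous across
# observations, correlated across traits), an improper uniform prior on
# the fixed effects, and inverse-Wishart priors G0 ~ IW(Sigma_g, n),
# R0 ~ IW(Sigma_e, n). Block effects use a corner-point constraint: the
# first block is absorbed into the per-trait intercept.
#
# Update order per cycle (each an exact multivariate-normal or
# inverse-Wishart draw from its full conditional):
#   1. fixed effects B | g, R0        (matrix-normal; OLS mean, R0 x (W'W)^-1 cov)
#   2. family effects g_j | B, G0, R0 (shared conditional covariance
#                                      (n_blocks R0^-1 + G0^-1)^-1 -- the
#                                      design is balanced by construction)
#   3. G0 | g   ~ IW(Sigma_g + g'g, n + n_families)
#   4. R0 | B,g ~ IW(Sigma_e + E'E, n + n_records)

# build the wide record matrix and designs from a long phenotype table,
# erroring on anything incomplete (no silent imputation)
prepare_mt_data <- function(data) {
  need <- c("family_id", "block_id", "trait", "value")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("data must have columns family_id, block_id, trait, value", call. = FALSE)
  if (anyNA(data$value))
    stop("missing phenotype values are not supported; remove or impute upstream explicitly",
         call. = FALSE)
  traits <- trait_levels(data$trait)
  fams <- sort(unique(as.character(data$family_id)))
  blks <- sort(unique(as.character(data$block_id)))
  q <- length(fams); nb <- length(blks); d <- length(traits)
  if (q < 2L) stop("need at least 2 families", call. = FALSE)
  fi <- match(as.character(data$family_id), fams)
  bi <- match(as.character(data$block_id), blks)
  ti <- match(as.character(data$trait), traits)
  cell <- (fi - 1L) * nb + bi              # record index, family-major
  slot <- (ti - 1L) * (q * nb) + cell      # position in the Y matrix
  if (anyDuplicated(slot))
    stop("duplicated family x block x trait records in phenotype table", call. = FALSE)
  if (length(slot) < q * nb * d)
    stop(sprintf(paste("incomplete phenotype table: %d of %d family x block x trait",
                       "cells missing; missing data are not supported"),
                 q * nb * d - length(slot), q * nb * d), call. = FALSE)
  Y <- matrix(NA_real_, q * nb, d, dimnames = list(NULL, traits))
  Y[slot] <- data$value
  fam_idx <- rep(seq_len(q), each = nb)
  blk_idx <- rep(seq_len(nb), times = q)
  W <- cbind(1, outer(blk_idx, seq_len(nb)[-1L], `==`) + 0)
  colnames(W) <- c("(Intercept)", if (nb > 1L) paste0("block", blks[-1L]))
  list(Y = Y, W = W, fam_idx = fam_idx, blk_idx = blk_idx,
       families = fams, blocks = blks, traits = traits,
       q = q, nb = nb, d = d, N = q * nb)
}

#' Fit the multi-trait mixed model by Gibbs sampling
#'
#' Samples the joint posterior of the per-trait fixed effects (intercept
#' plus block deviations), the family (genotypic) effects, and the
#' unstructured genetic and residual trait covariance matrices from a
#' complete randomized-block phenotype table. Fixed effects carry an
#' improper uniform prior; `G0` and `R0` carry inverse-Wishart priors with
#' `prior_df` degrees of freedom. When no prior scale matrices are given,
#' a weakly informative data-scaled default is used:
#' `0.5 * diag(per-trait phenotypic variance) * (prior_df - n_traits - 1)`,
#' which centres each prior on half the phenotypic variance.
#'
#' @param data Long-format `data.frame` with columns `family_id`,
#'   `block_id`, `trait`, `value`; every family x block x trait cell must
#'   be present exactly once (incomplete tables are rejected).
#' @param n_iter Total Gibbs cycles (default 100000).
#' @param burn_in Discarded initial cycles (default 40000).
#' @param thin Sampling interval; `(n_iter - burn_in)` must be a multiple
#'   of `thin`. Defaults retain (100000 - 40000) / 10 = 6000 draws.
#' @param prior_df Inverse-Wishart degrees of freedom for both covariance
#'   priors (default 5; must be at least `n_traits + 1`).
#' @param prior_scale_g,prior_scale_e Optional symmetric positive-definite
#'   prior scale matrices for `G0` and `R0`.
#' @param genetic If `FALSE`, drop the family effect entirely (fixed
#'   effects + residual covariance only); used for conjugate-validation
#'   runs.
#' @param seed Integer seed for an exactly reproducible chain; `NULL`
#'   continues the current RNG stream.
#' @param store_g Keep the per-draw family-effect matrices (needed for
#'   genotypic-value posterior means; default `TRUE`).
#' @param verbose Print progress every 10000 cycles.
#' @return An object of class `mt_gibbs` with retained draws in `G0`
#'   (`d x d x S` array), `R0`, `beta` (`p x d x S`), `g`
#'   (`q x d x S` or `NULL`), plus the model frame metadata. Methods:
#'   [print.mt_gibbs()], [summary.mt_gibbs()], [coef.mt_gibbs()],
#'   [fitted.mt_gibbs()], [residuals.mt_gibbs()], [plot.mt_gibbs()].
#' @examples
#' ph <- simulate_phenotypes(sim_config(n_families = 40, seed = 7))
#' fit <- fit_gibbs(ph, n_iter = 600, burn_in = 100, thin = 5, seed = 7)
#' summary(fit)
#' @export
fit_gibbs <- function(data,
                      n_iter = 100000L, burn_in = 40000L, thin = 10L,
                      prior_df = 5, prior_scale_g = NULL, prior_scale_e = NULL,
                      genetic = TRUE, seed = NULL,
                      store_g = TRUE, verbose = FALSE) {
  md <- prepare_mt_data(data)
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (burn_in < 0L || burn_in >= n_iter)
    stop("burn_in must be non-negative and smaller than n_iter", call. = FALSE)
  if (thin < 1L || (n_iter - burn_in) %% thin != 0L)
    stop("thin must be a positive divisor of (n_iter - burn_in)", call. = FALSE)
  d <- md$d
  if (prior_df < d + 1)
    stop(sprintf("prior_df must be at least n_traits + 1 = %d for a proper inverse-Wishart",
                 d + 1), call. = FALSE)
  v_phen <- apply(md$Y, 2, stats::var)
  if (is.null(prior_scale_g))
    prior_scale_g <- diag(0.5 * v_phen * (prior_df - d - 1), d)
  if (is.null(prior_scale_e))
    prior_scale_e <- diag(0.5 * v_phen * (prior_df - d - 1), d)
  stop_if_not_spd(prior_scale_g, "prior_scale_g")
  stop_if_not_spd(prior_scale_e, "prior_scale_e")

  S_keep <- (n_iter - burn_in) %/% thin
  q <- md$q; nb <- md$nb; N <- md$N
  Y <- md$Y; W <- md$W; fam_idx <- md$fam_idx
  p <- ncol(W)
  WtW <- crossprod(W)
  WtWinv <- chol2inv(chol(WtW))
  A_w <- t(chol(WtWinv))    # lower factor, A_w %*% t(A_w) = (W'W)^-1

  beta_keep <- array(NA_real_, c(p, d, S_keep),
                     dimnames = list(colnames(W), md$traits, NULL))
  R0_keep <- array(NA_real_, c(d, d, S_keep),
                   dimnames = list(md$traits, md$traits, NULL))
  G0_keep <- if (genetic) R0_keep else NULL
  g_keep <- if (genetic && store_g)
    array(NA_real_, c(q, d, S_keep), dimnames = list(md$families, md$traits, NULL))

  with_local_seed(seed, {
    # initial values: per-trait OLS for B, zero family effects, half the
    # phenotypic variance in each covariance matrix
    B <- WtWinv %*% crossprod(W, Y)
    U <- matrix(0, q, d)
    G0 <- diag(v_phen / 2, d)
    R0 <- diag(v_phen / 2, d)
    kept <- 0L
    for (it in seq_len(n_iter)) {
      R0inv <- chol2inv(chol(R0))
      # (1) fixed effects
      Bhat <- WtWinv %*% crossprod(W, Y - U[fam_idx, , drop = FALSE])
      B <- Bhat + A_w %*% matrix(stats::rnorm(p * d), p, d) %*% chol(R0)
      Rres <- Y - W %*% B
      if (genetic) {
        # (2) family effects: shared full-conditional covariance
        G0inv <- chol2inv(chol(G0))
        Om_inv <- chol2inv(chol(nb * R0inv + G0inv))
        M <- rowsum(Rres, fam_idx) %*% R0inv %*% Om_inv
        U <- M + matrix(stats::rnorm(q * d), q, d) %*% chol(Om_inv)
        # (3) genetic covariance
        G0 <- riwish1(prior_df + q, prior_scale_g + crossprod(U))
      }
      # (4) residual covariance
      E <- Rres - U[fam_idx, , drop = FALSE]
      R0 <- riwish1(prior_df + N, prior_scale_e + crossprod(E))
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        kept <- kept + 1L
        beta_keep[, , kept] <- B
        R0_keep[, , kept] <- R0
        if (genetic) {
          G0_keep[, , kept] <- G0
          if (store_g) g_keep[, , kept] <- U
        }
      }
      if (verbose && it %% 10000L == 0L)
        message(sprintf("cycle %d / %d (%d draws retained)", it, n_iter, kept))
    }
  })

  structure(list(G0 = G0_keep, R0 = R0_keep, beta = beta_keep, g = g_keep,
                 traits = md$traits, families = md$families, blocks = md$blocks,
                 n_draws = S_keep, genetic = genetic,
                 config = list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                               prior_df = prior_df,
                               prior_scale_g = prior_scale_g,
                               prior_scale_e = prior_scale_e, seed = seed),
                 model = list(W = W, fam_idx = fam_idx, blk_idx = md$blk_idx,
                              Y = Y, N = N, q = md$q, nb = md$nb)),
            class = "mt_gibbs")
}

# long labels for the distinct covariance entries, lower triangle
cov_labels <- function(traits, prefix) {
  d <- length(traits)
  out <- character(0)
  for (i in seq_len(d)) for (j in i:d) {
    out <- c(out, if (i == j) sprintf("sigma2_%s(%s)", prefix, traits[i])
             else sprintf("sigma_%s(%s,%s)", prefix, traits[i], traits[j]))
  }
  out
}

#' Extract labeled scalar chains from a fit
#'
#' One column per distinct (co)variance entry of `G0` and `R0`, one row
#' per retained draw — the persistence format of the sampler and the
#' input expected by the diagnostics functions.
#'
#' @param fit An [fit_gibbs()] object.
#' @return Numeric matrix `n_draws` x `n_params`, with a leading `draw`
#'   column when written to disk via [write_chain()].
#' @export
chain_matrix <- function(fit) {
  stopifnot(inherits(fit, "mt_gibbs"))
  d <- length(fit$traits)
  idx <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  pull <- function(arr) t(apply(arr, 3, function(m) m[idx]))
  out <- NULL; labs <- character(0)
  if (fit$genetic) {
    out <- pull(fit$G0)
    labs <- cov_labels(fit$traits, "g")
  }
  out <- cbind(out, pull(fit$R0))
  labs <- c(labs, cov_labels(fit$traits, "e"))
  colnames(out) <- labs
  out
}

#' Persist and reload retained covariance chains
#'
#' Comma-separated text, one row per retained draw: a `draw` index column
#' followed by the distinct entries of `G0` and `R0` under their
#' `sigma2_g(...)` / `sigma_g(...,...)` labels, so diagnostics can be run
#' on saved chains.
#'
#' @param fit An [fit_gibbs()] object.
#' @param path File path.
#' @return `write_chain()` returns `path` invisibly; `read_chain()`
#'   returns a `data.frame`.
#' @export
write_chain <- function(fit, path) {
  m <- chain_matrix(fit)
  utils::write.csv(data.frame(draw = seq_len(nrow(m)), m, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Posterior means of the genotypic values
#'
#' @param fit An [fit_gibbs()] object fitted with `store_g = TRUE`.
#' @return `n_families` x `n_traits` matrix of posterior-mean family
#'   effects, rows named by family, columns in canonical trait order —
#'   the selection criterion used by the clustering and ranking stages.
#' @export
genotypic_value_means <- function(fit) {
  stopifnot(inherits(fit, "mt_gibbs"))
  if (is.null(fit$g))
    stop("fit carries no genotypic-value draws (store_g = FALSE or genetic = FALSE)",
         call. = FALSE)
  out <- apply(fit$g, c(1, 2), mean)
  dimnames(out) <- dimnames(fit$g)[1:2]
  out
}

#' @export
print.mt_gibbs <- function(x, ...) {
  cat(sprintf("Multi-trait Gibbs fit: %d traits (%s), %d families, %d blocks\n",
              length(x$traits), paste(x$traits, collapse = ", "),
              length(x$families), length(x$blocks)))
  cat(sprintf("%d cycles, %d burn-in, thin %d -> %d retained draws\n",
              x$config$n_iter, x$config$burn_in, x$config$thin, x$n_draws))
  if (x$genetic) {
    cat("Posterior-mean G0:\n")
    print(round(apply(x$G0, c(1, 2), mean), 4))
  }
  cat("Posterior-mean R0:\n")
  print(round(apply(x$R0, c(1, 2), mean), 4))
  invisible(x)
}

#' Posterior summary table of the variance components
#'
#' One row per distinct entry of `G0` and `R0` plus one per-trait
#' heritability, each summarized with the posterior mean, median, mode,
#' standard deviation, 95% HPD bounds, Geweke Z and effective sample
#' size.
#'
#' @param object An [fit_gibbs()] object.
#' @param hpd_mass HPD interval mass (default 0.95).
#' @param ... Unused.
#' @return `data.frame` with one row per parameter, of class
#'   `summary.mt_gibbs`.
#' @export
summary.mt_gibbs <- function(object, hpd_mass = 0.95, ...) {
  ch <- chain_matrix(object)
  if (object$genetic) {
    d <- length(object$traits)
    for (i in seq_len(d)) {
      h2 <- object$G0[i, i, ] / (object$G0[i, i, ] + object$R0[i, i, ])
      ch <- cbind(ch, h2)
      colnames(ch)[ncol(ch)] <- sprintf("h2(%s)", object$traits[i])
    }
  }
  out <- do.call(rbind, lapply(seq_len(ncol(ch)), function(j)
    summarize_chain(ch[, j], hpd_mass = hpd_mass)))
  rownames(out) <- colnames(ch)
  class(out) <- c("summary.mt_gibbs", class(out))
  attr(out, "hpd_mass") <- hpd_mass
  out
}

#' @export
print.summary.mt_gibbs <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$degenerate <- NULL
  print(round(y, digits))
  invisible(x)
}

#' @export
coef.mt_gibbs <- function(object, ...) {
  apply(object$beta, c(1, 2), mean)
}

#' @export
fitted.mt_gibbs <- function(object, ...) {
  B <- coef(object)
  fit_wide <- object$model$W %*% B
  if (object$genetic && !is.null(object$g))
    fit_wide <- fit_wide + genotypic_value_means(object)[object$model$fam_idx, , drop = FALSE]
  fit_wide
}

#' @export
residuals.mt_gibbs <- function(object, ...) {
  object$model$Y - fitted(object)
}

#' Trace plots of the covariance chains
#'
#' @param x An [fit_gibbs()] object.
#' @param which Labels of chains to plot (default: the per-trait genetic
#'   and residual variances).
#' @param ... Passed to [plot()].
#' @export
plot.mt_gibbs <- function(x, which = NULL, ...) {
  ch <- chain_matrix(x)
  if (is.null(which))
    which <- grep("^sigma2_", colnames(ch), value = TRUE)
  which <- intersect(which, colnames(ch))
  old <- graphics::par(mfrow = c(ceiling(length(which) / 2), 2),
                       mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in which) {
    graphics::plot(ch[, nm], type = "l", xlab = "retained draw",
                   ylab = nm, main = nm, ...)
  }
  invisible(x)
}
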