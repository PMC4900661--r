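#' Configuration for simulating a half-sib trial
#'
#' Assembles the parameters of the generating model
#' `y_ijk = mu_i + b_ik + g_ij + e_ijk` for trait `i`, family `j`, block
#' `k`: family effects `g_j ~ N(0, G0)` iid across families, residuals
#' `e ~ N(0, R0)` iid across family-by-block records, both correlated
#' across traits. Defaults reproduce the structure of the jatropha trial:
#' 179 half-sib families, 2 complete blocks, three seed traits, with the
#' reference posterior-mean covariance matrices
#' ([reference_covariances()]) as dispersion truths. Trait means and block
#' contrasts are not dispersion parameters; the defaults are plausible
#' trait-scale values (60 g, 35 %, 2 mg/g) with a small block contrast,
#' and recovery of `G0`/`R0` does not depend on them.
#'
#' @param n_families Number of half-sib families (default 179).
#' @param n_blocks Number of complete blocks (default 2).
#' @param mu Numeric vector of overall trait means, canonical order.
#' @param block_effects `n_blocks` x `n_traits` matrix of fixed block
#'   deviations; each column must sum to zero (identifiability).
#' @param G0_true Genetic trait covariance matrix (symmetric positive
#'   semi-definite).
#' @param R0_true Residual trait covariance matrix (symmetric positive
#'   semi-definite).
#' @param traits Trait labels; defaults to the canonical set.
#' @param seed Integer seed used by [simulate_phenotypes()]; `NULL` draws
#'   from the current RNG stream.
#' @return Object of class `mt_sim_config`.
#' @seealso [simulate_phenotypes()]
#' @examples
#' cfg <- sim_config(n_families = 20, seed = 1)
#' cfg$G0_true
#' @export
sim_config <- function(n_families = 179L,
                       n_blocks = 2L,
                       mu = c(60, 35, 2),
                       block_effects = NULL,
                       G0_true = reference_covariances()$G0,
                       R0_true = reference_covariances()$R0,
                       traits = names(trait_set()),
                       seed = NULL) {
  n_families <- as.integer(n_families)
  n_blocks <- as.integer(n_blocks)
  if (n_families < 1L) stop("n_families must be a positive integer", call. = FALSE)
  if (n_blocks < 1L) stop("n_blocks must be a positive integer", call. = FALSE)
  d <- length(traits)
  if (length(mu) != d) stop("mu must have one entry per trait", call. = FALSE)
  check_psd_named(G0_true, "G0_true", d)
  check_psd_named(R0_true, "R0_true", d)
  if (is.null(block_effects)) {
    # small centred contrast per trait, scaled to the trait's rough spread
    scale <- 0.05 * pmax(sqrt(diag(G0_true) + diag(R0_true)), 1e-8)
    lev <- seq_len(n_blocks) - (n_blocks + 1) / 2
    block_effects <- outer(lev, scale)
  }
  block_effects <- as.matrix(block_effects)
  if (!all(dim(block_effects) == c(n_blocks, d)))
    stop("block_effects must be n_blocks x n_traits", call. = FALSE)
  if (any(abs(colSums(block_effects)) > 1e-8))
    stop("block_effects columns must sum to zero", call. = FALSE)
  structure(list(n_families = n_families, n_blocks = n_blocks,
                 mu = setNames(as.numeric(mu), traits),
                 block_effects = block_effects,
                 G0_true = unname_to(G0_true, traits),
                 R0_true = unname_to(R0_true, traits),
                 traits = as.character(traits), seed = seed),
            class = "mt_sim_config")
}

# PSD (not strictly PD) is allowed so degenerate zero-variance
# configurations remain simulable; asymmetry or a negative eigenvalue is
# rejected naming the offending matrix
check_psd_named <- function(m, name, d) {
  if (!is.matrix(m) || !all(dim(m) == c(d, d)))
    stop(sprintf("'%s' must be a %dx%d matrix", name, d, d), call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop(sprintf("matrix '%s' must be symmetric", name), call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1)))
    stop(sprintf("matrix '%s' is not positive semi-definite", name), call. = FALSE)
  invisible(m)
}

unname_to <- function(m, traits) {
  dimnames(m) <- list(traits, traits)
  m
}

# matrix square root tolerating semidefinite input
psd_sqrt <- function(m) {
  e <- eigen(symmetrize(m), symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate a complete half-sib phenotype table
#'
#' Draws one family effect vector per family and one residual vector per
#' family-by-block record from the configured covariance matrices and
#' assembles the complete long-format table: one row per
#' family x block x trait. With the default configuration this yields
#' 358 records per trait (179 families x 2 blocks), 1074 rows in total.
#'
#' @param config An [sim_config()] object.
#' @return A `data.frame` with columns `family_id`, `block_id`, `trait`,
#'   `value`, carrying attributes `true_g` (the simulated
#'   `n_families` x `n_traits` matrix of family effects, for recovery
#'   tests) and `config`.
#' @examples
#' ph <- simulate_phenotypes(sim_config(n_families = 10, seed = 42))
#' nrow(ph)       # 10 * 2 * 3
#' head(attr(ph, "true_g"))
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "mt_sim_config"))
  q <- config$n_families
  nb <- config$n_blocks
  d <- length(config$traits)
  with_local_seed(config$seed, {
    Lg <- psd_sqrt(config$G0_true)
    Le <- psd_sqrt(config$R0_true)
    g <- matrix(stats::rnorm(q * d), q, d) %*% Lg
    e <- matrix(stats::rnorm(q * nb * d), q * nb, d) %*% Le
    fam_ids <- sprintf("F%03d", seq_len(q))
    blk_ids <- sprintf("B%d", seq_len(nb))
    fam_idx <- rep(seq_len(q), each = nb)
    blk_idx <- rep(seq_len(nb), times = q)
    # records in family-major, block-minor order; one wide row per record
    Y <- matrix(config$mu, q * nb, d, byrow = TRUE) +
      config$block_effects[blk_idx, , drop = FALSE] +
      g[fam_idx, , drop = FALSE] + e
    out <- data.frame(
      family_id = rep(fam_ids[fam_idx], times = d),
      block_id = rep(blk_ids[blk_idx], times = d),
      trait = rep(config$traits, each = q * nb),
      value = as.vector(Y),
      stringsAsFactors = FALSE
    )
    dimnames(g) <- list(fam_ids, config$traits)
    attr(out, "true_g") <- g
    attr(out, "config") <- config
    out
  })
}

#' Read and write phenotype tables
#'
#' Long-format comma-separated text with header
#' `family_id,block_id,trait,value`, one row per observed
#' family x block x trait cell.
#'
#' @param x Phenotype `data.frame` as returned by [simulate_phenotypes()].
#' @param path File path.
#' @return `read_phenotypes()` returns the `data.frame`;
#'   `write_phenotypes()` returns `path` invisibly.
#' @export
write_phenotypes <- function(x, path) {
  utils::write.csv(x[, c("family_id", "block_id", "trait", "value")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(family_id = "character",
                                        block_id = "character",
                                        trait = "character",
                                        value = "numeric"))
  need <- c("family_id", "block_id", "trait", "value")
  if (!all(need %in% names(out)))
    stop("phenotype file must have columns family_id, block_id, trait, value",
         call. = FALSE)
  out[, need]
}

#' Write the simulation truth sidecar
#'
#' Records the generating parameters (and, optionally, the simulated
#' family effects) of a run of [simulate_phenotypes()] as YAML, so
#' parameter-recovery experiments can be scored after the fact.
#'
#' @param config The [sim_config()] used.
#' @param path Output YAML path.
#' @param true_g Optional matrix of simulated family effects.
#' @return `path`, invisibly. `read_truth()` returns the parsed list with
#'   matrices restored.
#' @export
write_truth <- function(config, path, true_g = NULL) {
  stopifnot(inherits(config, "mt_sim_config"))
  obj <- list(
    n_families = config$n_families, n_blocks = config$n_blocks,
    traits = config$traits, mu = as.numeric(config$mu),
    block_effects = apply(config$block_effects, 1, as.numeric, simplify = FALSE),
    G0_true = apply(config$G0_true, 1, as.numeric, simplify = FALSE),
    R0_true = apply(config$R0_true, 1, as.numeric, simplify = FALSE),
    seed = config$seed
  )
  if (!is.null(true_g))
    obj$true_g <- apply(true_g, 1, as.numeric, simplify = FALSE)
  writeLines(yaml::as.yaml(obj, precision = 12), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
  for (nm in intersect(c("block_effects", "G0_true", "R0_true", "true_g"), names(obj)))
    obj[[nm]] <- to_mat(obj[[nm]])
  for (nm in intersect(c("G0_true", "R0_true"), names(obj)))
    dimnames(obj[[nm]]) <- list(obj$traits, obj$traits)
  obj
}
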