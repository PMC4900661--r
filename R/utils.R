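# shared numerical helpers (internal)

# symmetric positive-definite check via pivoted Cholesky; tol guards
# against matrices that are PD only up to rounding noise
is_spd <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}

stop_if_not_spd <- function(m, name) {
  if (!is_spd(m)) {
    stop(sprintf("matrix '%s' must be symmetric positive-definite", name),
         call. = FALSE)
  }
  invisible(m)
}

# force exact symmetry after linear-algebra round trips
symmetrize <- function(m) (m + t(m)) / 2

# one draw from an inverse-Wishart with degrees of freedom `df` and scale
# matrix `S` (density proportional to |X|^-((df+d+1)/2) exp(-tr(S X^-1)/2)):
# if W ~ Wishart(df, S^-1) then W^-1 ~ IW(df, S)
riwish1 <- function(df, S) {
  d <- nrow(S)
  if (df <= d - 1) stop("inverse-Wishart degrees of freedom too small", call. = FALSE)
  W <- stats::rWishart(1L, df, solve(S))[, , 1L]
  symmetrize(solve(W))
}

# draw an n x d matrix with iid rows ~ N(0, Sigma)
rmvnorm_rows <- function(n, Sigma) {
  d <- nrow(Sigma)
  Z <- matrix(stats::rnorm(n * d), n, d)
  Z %*% chol(Sigma)
}

# evaluate `expr` under a locally seeded RNG stream, restoring (or
# removing) the caller's .Random.seed afterwards; seed = NULL leaves the
# global stream untouched
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
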