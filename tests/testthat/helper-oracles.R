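# shared fixtures and independent oracles used across test files

ref_cov <- reference_covariances()

# index (row, col) pairs of the distinct entries of a 3x3 symmetric
# matrix, in the row-major order used by chain_matrix() labels
ut3 <- cbind(row = c(1, 1, 1, 2, 2, 3), col = c(1, 2, 3, 2, 3, 3))

# random symmetric positive-definite matrix
random_spd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(0.1 * scale, d)
}

# AR(1) chain generator
ar1_chain <- function(n, rho, sd = 1) {
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sd / sqrt(1 - rho^2))
  for (i in 2:n) x[i] <- rho * x[i - 1] + rnorm(1, sd = sd)
  x
}

# brute-force shortest-window HPD: explicit loop over every contiguous
# window of ceiling(mass * n) sorted draws
hpd_bruteforce <- function(x, mass = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- min(n, max(2L, ceiling(mass * n)))
  best <- c(-Inf, Inf)
  for (i in 1:(n - m + 1)) {
    lo <- xs[i]; hi <- xs[i + m - 1]
    if (hi - lo < best[2] - best[1]) best <- c(lo, hi)
  }
  best
}

# brute-force Ward agglomerator: at every step, evaluate the total
# within-cluster SSE (computed directly from cluster means over raw
# points) for every candidate merge and take the smallest increase
ward_bruteforce <- function(X) {
  n <- nrow(X)
  sse_of <- function(members) {
    P <- X[members, , drop = FALSE]
    sum(sweep(P, 2, colMeans(P))^2)
  }
  clusters <- lapply(seq_len(n), identity)
  total_sse <- 0
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_inc <- Inf
    for (a in 1:(length(clusters) - 1)) for (b in (a + 1):length(clusters)) {
      inc <- sse_of(c(clusters[[a]], clusters[[b]])) -
        sse_of(clusters[[a]]) - sse_of(clusters[[b]])
      if (inc < best_inc) { best_inc <- inc; best <- c(a, b) }
    }
    merges[[length(merges) + 1]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_inc)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(member_sets = merges, heights = heights)
}

# recover the member set joined at each step of an hclust-style merge
# matrix (for comparing agglomeration histories across implementations)
merge_member_sets <- function(merge) {
  sets <- vector("list", nrow(merge))
  expand <- function(id) {
    if (id < 0) -id else sets[[id]]
  }
  for (s in seq_len(nrow(merge))) {
    sets[[s]] <- sort(c(expand(merge[s, 1]), expand(merge[s, 2])))
  }
  sets
}

# minimal stand-in posterior object (class mt_gibbs) built from given
# arrays of covariance draws; enough for derive_report() and summaries
fake_fit <- function(G0_draws, R0_draws, traits = names(trait_set())) {
  structure(list(G0 = G0_draws, R0 = R0_draws, beta = NULL, g = NULL,
                 traits = traits, families = NULL, blocks = NULL,
                 n_draws = dim(G0_draws)[3], genetic = TRUE,
                 config = list(), model = list()),
            class = "mt_gibbs")
}

# small complete single-trait phenotype table with known structure
single_trait_table <- function(n_fam, mu = 10, block_eff = c(0.5, -0.5),
                               sigma = 2, seed = 1) {
  set.seed(seed)
  fam <- sprintf("F%02d", seq_len(n_fam))
  out <- expand.grid(family_id = fam, block_id = c("B1", "B2"),
                     stringsAsFactors = FALSE)
  out$trait <- "Y"
  out$value <- mu + block_eff[match(out$block_id, c("B1", "B2"))] +
    rnorm(nrow(out), sd = sigma)
  out
}
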