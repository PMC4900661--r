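test_that("economic weights convert monetary units per genetic SD", {
  w <- economic_weights(c(W100S = 1, SOC = 1, PEC = 1), ref_cov$G0)
  expect_equal(unname(w), c(0.254, 1.669, 1.637), tolerance = 0.001)
  # doubling / quadrupling the monetary units scales the weights
  w3 <- economic_weights(c(W100S = 2, SOC = 4, PEC = 1), ref_cov$G0)
  expect_equal(w3[["SOC"]], 4 * w[["SOC"]])
  expect_equal(w3[["W100S"]], 2 * w[["W100S"]])
  expect_equal(w3[["PEC"]], w[["PEC"]])
  # identity genetic covariance: weights are the monetary units
  I3 <- diag(3); dimnames(I3) <- dimnames(ref_cov$G0)
  expect_equal(unname(economic_weights(c(W100S = 2, SOC = 3, PEC = 4), I3)),
               c(2, 3, 4))
  Z <- ref_cov$G0; Z[2, 2] <- 0
  expect_error(economic_weights(c(W100S = 1, SOC = 1, PEC = 1), Z), "positive")
})

test_that("index matrices P, G, C restrict the covariances correctly", {
  scn1 <- index_scenario("SOC", goal_traits = c("SOC", "W100S", "PEC"))
  m <- build_index_matrices(scn1, ref_cov$G0, ref_cov$R0)
  expect_equal(drop(m$P), 2.775)
  expect_equal(unname(drop(m$G)), c(0.359, 0.891, -0.004))
  # full index: G = C
  scn3 <- index_scenario(c("SOC", "W100S", "PEC"),
                         goal_traits = c("SOC", "W100S", "PEC"))
  m3 <- build_index_matrices(scn3, ref_cov$G0, ref_cov$R0)
  expect_equal(m3$G, m3$C)
  # no residual variance: P = C when index = goal
  m0 <- build_index_matrices(scn3, ref_cov$G0, matrix(0, 3, 3,
                             dimnames = dimnames(ref_cov$R0)))
  expect_equal(m0$P, m0$C)
  expect_error(index_scenario("OIL"), "unknown trait")
})

test_that("solved index reproduces the published scenario accuracies and responses", {
  s1 <- solve_index(index_scenario("SOC"), ref_cov$G0, ref_cov$R0)
  expect_equal(s1$R_IH, 0.2641, tolerance = 0.001)
  # independent oracle: direct linear solve by hand
  w <- 1 / sqrt(diag(ref_cov$G0))
  P <- ref_cov$G0 + ref_cov$R0
  b_hand <- sum(ref_cov$G0["SOC", ] * w) / P["SOC", "SOC"]
  expect_equal(unname(s1$b), b_hand, tolerance = 1e-12)
  # scenario 2: 2x2 solve, coefficients and W100S response
  s2 <- solve_index(index_scenario(c("SOC", "W100S")), ref_cov$G0, ref_cov$R0)
  b2_hand <- solve(P[c("SOC", "W100S"), c("SOC", "W100S")],
                   ref_cov$G0[c("SOC", "W100S"), ] %*% w)
  expect_equal(unname(s2$b), unname(drop(b2_hand)), tolerance = 1e-12)
  expect_equal(unname(s2$b), c(0.229, 0.204), tolerance = 0.005)
  expect_equal(s2$S[["W100S"]], 5.43, tolerance = 0.03)
  # single-trait index on its own goal: R_IH = sqrt(h2), S = i h2 sigma_P
  h2 <- ref_cov$G0["SOC", "SOC"] / P["SOC", "SOC"]
  s0 <- solve_index(index_scenario("SOC", goal_traits = "SOC",
                                   monetary = c(SOC = 1)),
                    ref_cov$G0, ref_cov$R0)
  expect_equal(s0$R_IH, sqrt(h2), tolerance = 1e-12)
  expect_equal(s0$S[["SOC"]], 1.75 * h2 * sqrt(P["SOC", "SOC"]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("scenario table has the published structure", {
  tab <- run_scenarios(ref_cov$G0, ref_cov$R0)
  expect_equal(nrow(tab), 9L)
  # scenario-1 responses are weight-invariant (scalar b cancels)
  s1 <- tab[tab$scenario == "1", c("S_SOC", "S_W100S", "S_PEC")]
  expect_lt(max(abs(s1[1, ] - s1[2, ])), 1e-10)
  expect_lt(max(abs(s1[1, ] - s1[3, ])), 1e-10)
  # accuracy rises as the index gains traits, within every weight set
  for (wset in unique(tab$weight_set)) {
    r <- tab$R_IH[tab$weight_set == wset]
    expect_true(all(diff(r) > 0))
  }
  # no genetic covariance means no correlated response
  Gd <- diag(diag(ref_cov$G0)); dimnames(Gd) <- dimnames(ref_cov$G0)
  res <- solve_index(index_scenario("SOC"), Gd, ref_cov$R0)
  expect_equal(res$S[["W100S"]], 0)
  expect_equal(res$S[["PEC"]], 0)
  expect_gt(res$S[["SOC"]], 0)
})

test_that("index accuracy is a true optimum bounded by one on random instances", {
  set.seed(21)
  tr <- names(trait_set())
  for (rep in 1:10) {
    G0 <- random_spd(3); R0 <- random_spd(3)
    dimnames(G0) <- dimnames(R0) <- list(tr, tr)
    r1 <- solve_index(index_scenario("SOC"), G0, R0)
    r2 <- solve_index(index_scenario(c("SOC", "W100S")), G0, R0)
    r3 <- solve_index(index_scenario(c("SOC", "W100S", "PEC")), G0, R0)
    for (r in list(r1, r2, r3)) {
      expect_gt(r$R_IH, 0)
      expect_lte(r$R_IH, 1 + 1e-12)
      expect_lte(r$sigma_I, r$sigma_H + 1e-12)
      # gain identity: delta_G = i * R_IH * sigma_H = i * sigma_I
      #              = i * sqrt(b'Gw)
      expect_equal(r$delta_G, 1.75 * r$sigma_I, tolerance = 1e-12)
      expect_equal(r$delta_G,
                   1.75 * sqrt(drop(crossprod(r$b, r$matrices$G %*% r$w))),
                   tolerance = 1e-10)
    }
    # monotone in the index trait set
    expect_lte(r1$R_IH, r2$R_IH + 1e-12)
    expect_lte(r2$R_IH, r3$R_IH + 1e-12)
    # optimality of b for the 2-trait index: no direction on a fine grid
    # correlates better with H
    m <- r2$matrices
    corr_of <- function(b) {
      drop(crossprod(b, m$G %*% r2$w)) /
        (sqrt(drop(crossprod(b, m$P %*% b))) * r2$sigma_H)
    }
    theta <- seq(0, pi, by = 0.01)
    grid_best <- max(sapply(theta, function(t) corr_of(c(cos(t), sin(t)))))
    expect_lte(grid_best, r2$R_IH + 1e-9)
  }
})

test_that("family ranking orders by score with deterministic tie-breaks", {
  res3 <- solve_index(index_scenario(c("SOC", "W100S", "PEC")),
                      ref_cov$G0, ref_cov$R0)
  # 179 families at 10% -> 18 selected
  set.seed(31)
  gv <- matrix(rnorm(179 * 3), 179, dimnames = list(sprintf("F%03d", 1:179),
                                                    names(trait_set())))
  rk <- rank_families(gv, res3)
  expect_equal(sum(rk$selected), 18L)
  expect_equal(rk$family_id[1],
               rownames(gv)[which.max(gv[, res3$scenario$index_traits] %*% res3$b)])
  expect_true(all(diff(rk$score) <= 0))
  # weight on one trait only: ranking equals that trait's ranking
  one <- res3
  one$b <- c(SOC = 0, W100S = 1, PEC = 0)[res3$scenario$index_traits]
  rk1 <- rank_families(gv, one)
  expect_equal(rk1$family_id, rownames(gv)[order(-gv[, "W100S"], rownames(gv))])
  # all-equal scores: lexicographic family order
  gv0 <- gv; gv0[, ] <- 1
  rk0 <- rank_families(gv0, res3)
  expect_equal(rk0$family_id, sort(rownames(gv)))
  expect_error(rank_families(gv[, 1:2], res3), "cover")
})
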