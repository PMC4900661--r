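test_that("no-genetic single-trait sampler matches the conjugate closed form", {
  dat <- single_trait_table(n_fam = 40, sigma = 2, seed = 4)
  s0 <- 3; n0 <- 5
  fit <- fit_gibbs(dat, n_iter = 6500, burn_in = 500, thin = 1,
                   prior_df = n0, prior_scale_e = matrix(s0),
                   genetic = FALSE, seed = 11)
  draws <- fit$R0[1, 1, ]
  expect_length(draws, 6000L)
  # oracle: with a flat prior on the p fixed effects and an IW(s0, n0)
  # prior, the marginal posterior of sigma2 is (s0 + RSS) / chisq(n0 + N - p)
  ols <- lm(value ~ block_id, data = dat)
  rss <- sum(resid(ols)^2)
  df_post <- n0 + nrow(dat) - 2
  m_exact <- (s0 + rss) / (df_post - 2)
  q_exact <- (s0 + rss) / qchisq(c(0.975, 0.025), df_post)
  se_mc <- sd(draws) / sqrt(effective_sample_size(draws))
  expect_lt(abs(mean(draws) - m_exact), 4 * se_mc)
  expect_lt(abs(quantile(draws, 0.025) - q_exact[1]) / q_exact[1], 0.04)
  expect_lt(abs(quantile(draws, 0.975) - q_exact[2]) / q_exact[2], 0.04)
})

test_that("in the noise-free limit posterior genotypic values equal family-mean deviations", {
  cfg <- sim_config(n_families = 60, R0_true = diag(1e-8, 3), seed = 21)
  ph <- simulate_phenotypes(cfg)
  fit <- fit_gibbs(ph, n_iter = 1500, burn_in = 500, thin = 2,
                   prior_scale_e = diag(1e-4, 3), seed = 21)
  gpost <- genotypic_value_means(fit)
  # family means of block-corrected records; centred to remove the
  # intercept/family-mean confounding
  w <- matrix(ph$value, ncol = 3)
  blk <- matrix(ph$block_id, ncol = 3)[, 1]
  famdev <- (w[blk == "B1", ] + w[blk == "B2", ]) / 2
  famdev <- sweep(famdev, 2, colMeans(famdev))
  gcent <- sweep(gpost, 2, colMeans(gpost))
  expect_lt(max(abs(gcent - famdev)), 0.05)
  for (j in 1:3) expect_gt(cor(gcent[, j], famdev[, j]), 0.9999)
})

test_that("retained covariance draws are SPD, reproducible, and balanced in g", {
  ph <- simulate_phenotypes(sim_config(n_families = 100, seed = 31))
  fit <- fit_gibbs(ph, n_iter = 900, burn_in = 300, thin = 3, seed = 31)
  expect_equal(fit$n_draws, 200L)
  min_eig <- function(arr) min(apply(arr, 3, function(m) {
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  }))
  expect_gt(min_eig(fit$G0), 0)
  expect_gt(min_eig(fit$R0), 0)
  # posterior mean of g sums to ~0 per trait for balanced data (the flat
  # intercept absorbs the family average up to prior shrinkage)
  gbar <- colMeans(genotypic_value_means(fit))
  expect_lt(max(abs(gbar) / sqrt(diag(ref_cov$G0) / 100)), 3)
  # identical seed -> identical chain; different seed -> different
  fit2 <- fit_gibbs(ph, n_iter = 900, burn_in = 300, thin = 3, seed = 31)
  expect_identical(fit$G0, fit2$G0)
  fit3 <- fit_gibbs(ph, n_iter = 900, burn_in = 300, thin = 3, seed = 32)
  expect_false(identical(fit$G0, fit3$G0))
})

test_that("incomplete, duplicated or malformed inputs are rejected explicitly", {
  ph <- simulate_phenotypes(sim_config(n_families = 10, seed = 41))
  expect_error(fit_gibbs(ph[-5, ], n_iter = 20, burn_in = 0, thin = 1),
               "incomplete")
  expect_error(fit_gibbs(rbind(ph, ph[1, ]), n_iter = 20, burn_in = 0, thin = 1),
               "duplicated")
  ph_na <- ph; ph_na$value[3] <- NA
  expect_error(fit_gibbs(ph_na, n_iter = 20, burn_in = 0, thin = 1),
               "missing")
  expect_error(fit_gibbs(ph, n_iter = 100, burn_in = 10, thin = 7),
               "divisor")
  expect_error(fit_gibbs(ph, n_iter = 100, burn_in = 200, thin = 1),
               "burn_in")
  expect_error(fit_gibbs(ph, n_iter = 100, burn_in = 0, thin = 1, prior_df = 3),
               "prior_df")
  expect_error(fit_gibbs(ph, n_iter = 100, burn_in = 0, thin = 1,
                         prior_scale_g = matrix(-1, 3, 3)),
               "positive-definite")
  one_fam <- ph[ph$family_id == "F001", ]
  expect_error(fit_gibbs(one_fam, n_iter = 20, burn_in = 0, thin = 1),
               "families")
})

test_that("fit accessors are mutually consistent", {
  ph <- simulate_phenotypes(sim_config(n_families = 30, seed = 51))
  fit <- fit_gibbs(ph, n_iter = 600, burn_in = 200, thin = 2, seed = 51)
  # chain_matrix columns agree with the stored arrays
  ch <- chain_matrix(fit)
  expect_equal(ch[, "sigma2_g(W100S)"], fit$G0[1, 1, ], ignore_attr = TRUE)
  expect_equal(ch[, "sigma_e(SOC,PEC)"], fit$R0[2, 3, ], ignore_attr = TRUE)
  # residuals + fitted reproduce the data
  expect_equal(fitted(fit) + residuals(fit), fit$model$Y, tolerance = 1e-12)
  # single retained draw: genotypic means equal that draw verbatim
  f1 <- fit_gibbs(ph, n_iter = 1, burn_in = 0, thin = 1, seed = 5)
  expect_equal(genotypic_value_means(f1), f1$g[, , 1], ignore_attr = TRUE)
  # antisymmetric two-draw set averages to zero
  g2 <- fit$g[, , 1:2]
  g2[, , 2] <- -g2[, , 1]
  f2 <- fit; f2$g <- g2
  expect_true(all(genotypic_value_means(f2) == 0))
  # chain persistence round-trip
  f <- tempfile(fileext = ".csv")
  write_chain(fit, f)
  back <- read_chain(f)
  expect_equal(back[["sigma2_g(W100S)"]], fit$G0[1, 1, ], tolerance = 1e-12)
  unlink(f)
})
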