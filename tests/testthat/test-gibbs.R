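# Henderson's mixed-model equations for a single-trait animal model with
# intercept: the independent oracle for the Gibbs posterior mean of g.
henderson_blup <- function(y, K, sigma_g, sigma_e) {
  J <- length(y)
  lambda <- sigma_e / sigma_g
  C <- rbind(cbind(J, t(rep(1, J))),
             cbind(rep(1, J), diag(J) + lambda * solve(K)))
  solve(C, c(sum(y), y))[-1]
}

test_that("fixed-variance posterior mean of g matches Henderson's BLUP", {
  set.seed(21)
  J <- 25
  K <- diag(J)
  dimnames(K) <- list(sprintf("L%02d", 1:J), sprintf("L%02d", 1:J))
  g_true <- rnorm(J, 0, 1)
  y <- 5 + g_true + rnorm(J, 0, sqrt(0.5))
  ph <- pheno_table(data.frame(line = rownames(K), env = "E1", y = y), "y")
  pr <- prior_spec(1, n_iter = 6000, burn_in = 1000, thin = 1, seed = 11)
  fit <- fit_gibbs(ph, K, prior = pr, include_ge = FALSE,
                   fixed = list(sigma_T = matrix(1), R = matrix(0.5)))
  blup <- henderson_blup(y, K, 1, 0.5)
  expect_lt(max(abs(fit$g_hat[, 1] - blup)), 0.04)
})

test_that("a constant response gives near-zero line effects and the constant mean", {
  ph <- tiny_pheno(nT = 1, I = 2, J = 10, value = 7)
  m <- random_markers(10, 25)
  k <- gaussian_kernel(squared_distance_matrix(m), 0.5)
  pr <- prior_spec(1, n_iter = 2000, burn_in = 500, thin = 1, seed = 3)
  fit <- fit_gibbs(ph, k, prior = pr)
  # with a degenerate response the fitted values reproduce the constant
  # exactly; the split between intercept and shrunken line effects is only
  # weakly identified along the near-constant kernel direction
  expect_equal(unname(fit$y_pred[, 1]), rep(7, 20), tolerance = 1e-3)
  expect_equal(unname(fit$mu_T), 7, tolerance = 0.3)
  expect_lt(max(abs(fit$g_hat)), 0.3)
})

test_that("fits are deterministic given the seed and invariant to row shuffles", {
  sim <- small_sim()
  k <- gaussian_kernel(squared_distance_matrix(sim$markers), 0.5)
  pr <- prior_spec(2, n_iter = 300, burn_in = 100, thin = 1, seed = 17)
  f1 <- fit_gibbs(sim$pheno, k, prior = pr)
  f2 <- fit_gibbs(sim$pheno, k, prior = pr)
  expect_identical(f1$y_pred, f2$y_pred)
  shuffled <- as.data.frame(sim$pheno)[sample(nrow(sim$pheno)), ]
  f3 <- fit_gibbs(pheno_table(shuffled, trait_names(sim$pheno)), k,
                  prior = pr)
  expect_identical(f1$y_pred, f3$y_pred)
  expect_identical(f1$g_hat, f3$g_hat)
})

test_that("retained covariance draws are symmetric positive definite", {
  sim <- small_sim()
  k <- gaussian_kernel(squared_distance_matrix(sim$markers), 0.5)
  pr <- prior_spec(2, n_iter = 200, burn_in = 100, thin = 1, seed = 2)
  fit <- fit_gibbs(sim$pheno, k, prior = pr)
  expect_gt(fit$n_draws, 0)
  for (nm in c("sigma_T", "sigma_T_ge", "R")) {
    for (S in fit$draws[[nm]]) {
      expect_equal(S, t(S))
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("masked cells of a twin line are predicted from its duplicate", {
  # two identical marker rows -> kernel entry 1; noise-free phenotypes
  set.seed(5)
  m <- unclass(random_markers(10, 40))
  m[2, ] <- m[1, ]                      # L02 duplicates L01
  mm <- marker_matrix(m)
  cfg <- synthetic_config(J = 10, I = 2, nT = 1, p = 40,
                          sigma_T_ge_true = matrix(1e-8),
                          R_true = matrix(1e-8), rho_true = 0.5, seed = 8)
  sim <- simulate_phenotypes(mm, cfg)
  k <- gaussian_kernel(squared_distance_matrix(mm), 0.5)
  mask <- data.frame(line = "L02", env = c("E01", "E02"), trait = "T1")
  pr <- prior_spec(1, n_iter = 1500, burn_in = 500, thin = 1, seed = 12)
  fit <- fit_gibbs(sim$pheno, k, prior = pr, mask = mask)
  pred <- predict_masked(fit, mask)
  obs <- sim$pheno[sim$pheno$line == "L02", "T1"]
  expect_lt(max(abs(pred$predicted - obs)), 0.15)
})

test_that("predict_masked handles empty and invalid masks", {
  sim <- small_sim()
  k <- gaussian_kernel(squared_distance_matrix(sim$markers), 0.5)
  pr <- prior_spec(2, n_iter = 150, burn_in = 50, thin = 1, seed = 1)
  fit <- fit_gibbs(sim$pheno, k, prior = pr)
  expect_equal(nrow(predict_masked(fit, NULL)), 0)
  expect_error(predict_masked(fit, data.frame(line = "nope", env = "E01",
                                              trait = "T1")), "absent")
  expect_error(predict_masked(fit, data.frame(line = "L0001", env = "E01",
                                              trait = "bogus")), "trait")
  expect_false(anyNA(fit$y_pred))
})

test_that("posterior credible intervals for trait variances cover the truth", {
  # 12 replicates at a compact size; the 90% interval for diag(sigma_T)
  # should cover the generative value in most replicates
  hits <- 0L; total <- 0L
  for (s in 1:12) {
    cfg <- synthetic_config(J = 120, I = 3, nT = 2, p = 200, rho_true = 0.5,
                            sigma_T_ge_true = matrix(c(.3, .15, .15, .3), 2),
                            signal_fraction = 0.8, seed = s)
    m <- simulate_markers(cfg)
    sim <- simulate_phenotypes(m, cfg)
    k <- gaussian_kernel(squared_distance_matrix(m), 0.5)
    pr <- prior_spec(2, n_iter = 1500, burn_in = 500, thin = 2, seed = 100 + s)
    fit <- fit_gibbs(sim$pheno, k, prior = pr)
    for (t in 1:2) {
      dr <- vapply(fit$draws$sigma_T, function(S) S[t, t], numeric(1))
      ci <- stats::quantile(dr, c(0.05, 0.95))
      total <- total + 1L
      if (ci[1] <= 1 && 1 <= ci[2]) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.7)
})
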