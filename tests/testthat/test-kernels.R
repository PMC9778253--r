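test_that("squared distances are max-scaled with the documented geometry", {
  m <- marker_matrix(matrix(c(0, 0, 2, 2, 1, 1), 3, 2, byrow = TRUE,
                            dimnames = list(c("a", "b", "c"), NULL)))
  d <- squared_distance_matrix(m)
  # raw squared distances 8, 2, 2 scale to 1, 0.25, 0.25
  expect_equal(d$scale_factor, 8)
  expect_equal(d$d2["a", "b"], 1)
  expect_equal(d$d2["a", "c"], 0.25)
  expect_equal(d$d2["b", "c"], 0.25)
  expect_equal(diag(d$d2), c(a = 0, b = 0, c = 0))
  expect_equal(d$d2, t(d$d2))

  all_same <- marker_matrix(matrix(1, 2, 3,
                                   dimnames = list(c("a", "b"), NULL)))
  expect_error(squared_distance_matrix(all_same), "identical")
})

test_that("gaussian kernel equals rho^d2 and the exp(-gamma d2) form", {
  d <- list(d2 = matrix(c(0, 2, 2, 0), 2,
                        dimnames = list(c("a", "b"), c("a", "b"))),
            scale_factor = 1)
  expect_equal(unclass(gaussian_kernel(d, 0.5))["a", "b"], 0.25)
  expect_equal(diag(unclass(gaussian_kernel(d, 0.5))), c(a = 1, b = 1))

  set.seed(1)
  m <- random_markers(5, 12)
  dm <- squared_distance_matrix(m)
  for (rho in c(0.1, 0.37, 0.9)) {
    gamma <- -log(rho)
    expect_equal(unclass(gaussian_kernel(dm, rho)),
                 exp(-gamma * dm$d2), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(gaussian_kernel(dm, 0), "0, 1")
  expect_error(gaussian_kernel(dm, 1), "0, 1")
})

test_that("no-tuning bandwidth is exp(-1), inside the default grid range", {
  expect_equal(nt_rho(), exp(-1))
  g <- make_grid()
  expect_gt(nt_rho(), min(g))
  expect_lt(nt_rho(), max(g))
  m <- random_markers(4, 10)
  dm <- squared_distance_matrix(m)
  expect_equal(unclass(gaussian_kernel(dm, nt_rho())), exp(-dm$d2),
               ignore_attr = TRUE)
})

test_that("gaussian kernel is monotone in rho and tends to all-ones", {
  m <- random_markers(6, 15)
  dm <- squared_distance_matrix(m)
  k1 <- unclass(gaussian_kernel(dm, 0.2))
  k2 <- unclass(gaussian_kernel(dm, 0.6))
  off <- upper.tri(k1)
  expect_true(all(k2[off] > k1[off]))
  # near rho = 1 the kernel is all ones up to the numerical-rescue jitter
  k_lim <- suppressMessages(unclass(gaussian_kernel(dm, 1 - 1e-12)))
  expect_equal(k_lim, matrix(1, 6, 6), tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("gaussian kernel is positive semidefinite on random panels", {
  for (s in 1:5) {
    m <- random_markers(12, 30, seed = s)
    k <- gaussian_kernel(squared_distance_matrix(m), runif(1, 0.05, 0.95))
    ev <- eigen(unclass(k), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("VanRaden GRM matches the hand-computed single-marker case", {
  m <- marker_matrix(matrix(c(0, 1, 2), 3, 1,
                            dimnames = list(c("a", "b", "c"), "M1")))
  G <- unclass(linear_grm(m))
  expect_equal(G, matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3),
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(G)), rep(0, 3))  # centering identity

  mono <- marker_matrix(matrix(c(2, 2, 0, 0), 2, 2,
                               dimnames = list(c("a", "b"), NULL)))
  expect_error(linear_grm(mono), "monomorphic")
})

test_that("GE kernel equals the brute-force (env, line) loop", {
  ph <- tiny_pheno(I = 2, J = 2)
  des <- build_design(ph)
  K <- matrix(c(1, .3, .3, 1), 2, dimnames = list(des$lines, des$lines))
  class(K) <- c("kernel_matrix", class(matrix()))
  KE <- unclass(ge_kernel(K, des))
  expect_equal(KE, rbind(cbind(unclass(K), matrix(0, 2, 2)),
                         cbind(matrix(0, 2, 2), unclass(K))),
               ignore_attr = TRUE)

  # random unbalanced instance vs explicit double loop
  set.seed(4)
  df <- expand.grid(line = sprintf("L%02d", 1:6), env = sprintf("E%d", 1:3),
                    stringsAsFactors = FALSE)
  df <- df[sample(nrow(df), 14), ]
  df$T1 <- rnorm(14, 10)
  ph2 <- pheno_table(df, "T1")
  des2 <- build_design(ph2)
  m <- random_markers(6, 20)
  K2 <- gaussian_kernel(squared_distance_matrix(m), 0.5)
  KE2 <- unclass(ge_kernel(K2, des2))
  brute <- matrix(0, nrow(ph2), nrow(ph2))
  for (a in seq_len(nrow(ph2))) for (b in seq_len(nrow(ph2)))
    if (ph2$env[a] == ph2$env[b])
      brute[a, b] <- unclass(K2)[ph2$line[a], ph2$line[b]]
  expect_equal(KE2, brute, tolerance = 1e-7, ignore_attr = TRUE)

  # identity kernel stays the identity on matched rows
  KI <- diag(6); dimnames(KI) <- list(rownames(m), rownames(m))
  expect_equal(unclass(ge_kernel(KI, des2)), diag(nrow(ph2)),
               tolerance = 1e-7, ignore_attr = TRUE)
})
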