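test_that("nrmse matches direct arithmetic and guards its preconditions", {
  expect_equal(nrmse(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_equal(nrmse(c(1, 3), c(2, 2)), 0.5)   # RMSE 1 over mean 2
  expect_error(nrmse(c(-1, 1), c(0, 0)), "zero")
  expect_error(nrmse(1:3, 1:2), "length")
  # scale covariance: scaling both by c > 0 leaves NRMSE unchanged
  set.seed(2)
  o <- rnorm(20, 5); p <- o + rnorm(20, 0, 0.3)
  expect_equal(nrmse(3.7 * o, 3.7 * p), nrmse(o, p))
  # missing observed values are dropped
  expect_equal(nrmse(c(1, 3, NA), c(2, 2, 99)), 0.5)
})

test_that("relative efficiency is the NRMSE ratio and chains multiplicatively", {
  expect_equal(relative_efficiency(0.5, 0.5), 1)
  expect_equal(relative_efficiency(1.06, 1), 1.06)
  expect_error(relative_efficiency(1, 0), "positive")
  a <- 0.84; b <- 0.71; c <- 0.66
  expect_equal(relative_efficiency(a, b) * relative_efficiency(b, c),
               relative_efficiency(a, c))
})

make_toy_log <- function() {
  set.seed(11)
  g <- expand.grid(strategy = c("NT", "GrS", "BO"), fold = 1:3,
                   trait = c("T1", "T2"), env = c("E1", "E2"),
                   rep = 1:4, stringsAsFactors = FALSE)
  g$line <- sprintf("L%d", g$rep)
  g$observed <- rnorm(nrow(g), 10)
  g$predicted <- g$observed + rnorm(nrow(g), 0,
                                    ifelse(g$strategy == "NT", 1, 0.8))
  g
}

test_that("scored and aggregated metrics match an independent brute-force loop", {
  log <- make_toy_log()
  per_fold <- score_prediction_log(log, global = "pooled")
  # brute force per (strategy, trait, env, fold)
  for (i in sample(nrow(per_fold), 20)) {
    r <- per_fold[i, ]
    sel <- log$strategy == r$strategy & log$trait == r$trait &
      log$fold == r$fold &
      (if (r$environment == "Global") TRUE else log$env == r$environment)
    sub <- log[sel, ]
    expect_equal(r$nrmse,
                 sqrt(mean((sub$observed - sub$predicted)^2)) /
                   mean(sub$observed))
  }
  agg <- aggregate_metrics(per_fold)
  for (i in sample(which(agg$trait != "All"), 10)) {
    r <- agg[i, ]
    vals <- per_fold$nrmse[per_fold$strategy == r$strategy &
                             per_fold$trait == r$trait &
                             per_fold$environment == r$environment]
    expect_equal(r$nrmse, mean(vals))
    expect_equal(r$se, sd(vals) / sqrt(length(vals)))
  }
  # across-trait rows average the trait-level values
  for (i in which(agg$trait == "All")) {
    r <- agg[i, ]
    vals <- agg$nrmse[agg$strategy == r$strategy & agg$trait != "All" &
                        agg$environment == r$environment]
    expect_equal(r$nrmse, mean(vals))
  }
})

test_that("identical per-fold values aggregate to themselves", {
  pf <- data.frame(strategy = "NT", trait = "T1", environment = "E1",
                   fold = 1:7, nrmse = 0.42)
  agg <- aggregate_metrics(pf)
  expect_equal(agg$nrmse[agg$trait == "T1"], 0.42)
  pf2 <- rbind(pf, transform(pf, trait = "T2", nrmse = 0.62))
  agg2 <- aggregate_metrics(pf2)
  expect_equal(agg2$nrmse[agg2$trait == "All"], 0.52)
})

test_that("the relative-efficiency report matches aggregate ratios", {
  log <- make_toy_log()
  agg <- aggregate_metrics(score_prediction_log(log))
  re <- re_report(agg)
  expect_setequal(unique(re$comparison), c("re_grs", "re_bo", "re_grs_bo"))
  i <- which(re$comparison == "re_grs_bo" & re$trait == "T1" &
               re$environment == "Global")
  n_grs <- agg$nrmse[agg$strategy == "GrS" & agg$trait == "T1" &
                       agg$environment == "Global"]
  n_bo <- agg$nrmse[agg$strategy == "BO" & agg$trait == "T1" &
                      agg$environment == "Global"]
  expect_equal(re$re[i], n_grs / n_bo)
})

test_that("pooled and mean-of-environment Global rows differ as documented", {
  log <- make_toy_log()
  pool <- score_prediction_log(log, "pooled")
  avg <- score_prediction_log(log, "mean_of_env")
  gp <- pool[pool$environment == "Global", ]
  ga <- avg[avg$environment == "Global", ]
  expect_equal(nrow(gp), nrow(ga))
  expect_false(isTRUE(all.equal(gp$nrmse, ga$nrmse)))
})
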