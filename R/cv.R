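# Nested cross-validation: 7 outer folds estimate generalization error, 5
# inner folds inside each outer-training set select the kernel bandwidth,
# and the model is refit on the full outer-training set before predicting
# the outer-test cells.  Folds partition observation records, stratified by
# environment; one fold plan is shared by all tuning strategies so the
# relative-efficiency comparisons are paired.

#' Build a nested cross-validation fold plan
#'
#' Outer folds partition the observation records into `k_outer` groups,
#' stratified by environment (each environment's records are spread as
#' evenly as possible over folds, and the extra records of uneven splits
#' are placed on the currently smallest folds so overall fold sizes stay
#' within one of each other).  Within each outer-training set the same
#' scheme assigns `k_inner` inner folds.  Deterministic given `seed`.
#'
#' @param pheno a [pheno_table()].
#' @param k_outer,k_inner number of outer and inner folds.
#' @param seed integer seed.
#' @param unit `"observation"` (default) partitions records, so a line may
#'   train in one environment and test in another; `"line"` partitions
#'   lines, keeping all records of a line in the same fold.
#' @return a `fold_plan`: list with `outer` (length-n fold id per record),
#'   `inner` (per outer fold, a length-n vector with inner fold ids on the
#'   outer-training records and NA on the test records), `k_outer`,
#'   `k_inner`, `seed`, `unit`.
#' @export
make_fold_plan <- function(pheno, k_outer = 7L, k_inner = 5L, seed = 1L,
                           unit = c("observation", "line")) {
  unit <- match.arg(unit)
  n <- nrow(pheno)
  if (n < k_outer) stop("fewer records than outer folds", call. = FALSE)
  set.seed(.substream(seed, "folds"))
  if (unit == "line") {
    lines <- unique(pheno$line)
    if (length(lines) < k_outer)
      stop("fewer lines than outer folds", call. = FALSE)
    lf <- .balanced_assign(list(sample(length(lines))), k_outer)
    outer <- lf[match(pheno$line, lines)]
  } else {
    strata <- lapply(split(seq_len(n), pheno$env), sample)
    short <- vapply(strata, length, integer(1)) < k_outer
    if (any(short))
      stop("environment(s) with fewer records than outer folds: ",
           paste(names(strata)[short], collapse = ", "),
           "; reduce k_outer or merge environments", call. = FALSE)
    outer <- .balanced_assign(strata, k_outer, n)
  }
  inner <- vector("list", k_outer)
  for (f in seq_len(k_outer)) {
    train <- which(outer != f)
    strata <- lapply(split(train, pheno$env[train]), sample)
    asg <- .balanced_assign(strata, k_inner, length(train))
    inner_f <- rep(NA_integer_, n)
    inner_f[unlist(strata, use.names = FALSE)] <- asg
    inner[[f]] <- inner_f
  }
  structure(list(outer = outer, inner = inner, k_outer = as.integer(k_outer),
                 k_inner = as.integer(k_inner), seed = as.integer(seed),
                 unit = unit),
            class = "fold_plan")
}

# Assign fold ids to already-shuffled strata, keeping per-stratum fold
# counts within one of each other and placing remainder records on the
# globally smallest folds.  Returns ids aligned with unlist(strata).
.balanced_assign <- function(strata, k, n_total = sum(lengths(strata))) {
  totals <- numeric(k)
  out <- integer(0)
  for (s in strata) {
    m <- length(s)
    base <- m %/% k; extra <- m %% k
    counts <- rep(base, k)
    if (extra > 0) {
      take <- order(totals, stats::runif(k))[seq_len(extra)]
      counts[take] <- counts[take] + 1L
    }
    ids <- rep.int(seq_len(k), counts)
    out <- c(out, ids[sample(length(ids))][seq_len(m)])
    totals <- totals + counts
  }
  out
}

#' Serialize a fold plan to CSV
#'
#' One row per observation record with its outer fold and, for every outer
#' fold in whose training set it sits, its inner fold id.
#'
#' @param plan a `fold_plan`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fold_plan <- function(plan, path) {
  df <- data.frame(row = seq_along(plan$outer), outer_fold = plan$outer)
  for (f in seq_len(plan$k_outer))
    df[[paste0("inner_fold_", f)]] <- plan$inner[[f]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Mask covering every trait cell of the given records.
.rows_mask <- function(pheno, rows) {
  traits <- trait_names(pheno)
  data.frame(line = rep(pheno$line[rows], each = length(traits)),
             env = rep(pheno$env[rows], each = length(traits)),
             trait = rep(traits, length(rows)),
             stringsAsFactors = FALSE)
}

#' Inner cross-validation objective for a candidate bandwidth
#'
#' For each inner fold of the given outer fold: fit the model on the other
#' inner folds (with both the inner-validation cells and the outer-test
#' cells masked, so no outer-test information leaks into tuning), predict
#' the validation cells, compute the per-trait NRMSE on them and average
#' over traits.  The objective is the mean of the fold values.
#'
#' @param rho candidate bandwidth in (0, 1).
#' @param pheno a [pheno_table()].
#' @param dist output of [squared_distance_matrix()] for the marker panel.
#' @param plan a `fold_plan`.
#' @param outer_fold which outer fold's inner maps to use.
#' @param prior a [prior_spec()] for the inner fits.
#' @param include_ge passed to [fit_gibbs()].
#' @return mean NRMSE across inner folds (lower is better).
#' @export
inner_objective <- function(rho, pheno, dist, plan, outer_fold, prior,
                            include_ge = TRUE) {
  k <- gaussian_kernel(dist, rho)
  traits <- trait_names(pheno)
  outer_test <- which(plan$outer == outer_fold)
  inner_ids <- plan$inner[[outer_fold]]
  fold_vals <- vapply(seq_len(plan$k_inner), function(v) {
    val_rows <- which(inner_ids == v)
    if (!length(val_rows)) return(NA_real_)
    mask <- .rows_mask(pheno, c(outer_test, val_rows))
    fit <- fit_gibbs(pheno, k, prior = prior, include_ge = include_ge,
                     mask = mask)
    pred <- predict_masked(fit, .rows_mask(pheno, val_rows))
    obs <- as.matrix(pheno[val_rows, traits, drop = FALSE])
    per_trait <- vapply(seq_along(traits), function(t) {
      o <- obs[, t]
      p <- pred$predicted[pred$trait == traits[t]]
      if (all(is.na(o))) return(NA_real_)
      nrmse(o, p)
    }, numeric(1))
    mean(per_trait, na.rm = TRUE)
  }, numeric(1))
  mean(fold_vals, na.rm = TRUE)
}

#' Run one tuning strategy through the nested cross-validation
#'
#' For every outer fold: select the bandwidth on the inner folds according
#' to `strategy` (NT uses the fixed rho = exp(-1) with no inner fitting),
#' refit on the full outer-training set with the outer-test cells masked,
#' and record the test-cell predictions.
#'
#' @param pheno a [pheno_table()].
#' @param markers a [marker_matrix()] covering all phenotyped lines.
#' @param strategy one of `"NT"`, `"GrS"`, `"BO"`.
#' @param plan a `fold_plan` (share one plan across strategies so
#'   relative-efficiency comparisons are paired).
#' @param prior a [prior_spec()] for the outer refits.
#' @param inner_prior prior/sampler settings for the inner tuning fits
#'   (defaults to `prior`; shorter chains are usual here).
#' @param grid bandwidth grid for `"GrS"`.
#' @param bo_n_init,bo_n_iter Bayesian-optimization budget for `"BO"`.
#' @param include_ge passed to [fit_gibbs()].
#' @param verbose print one line per fold.
#' @return list with `log` (data.frame: strategy, fold, rho, line, env,
#'   trait, observed, predicted — one row per outer-test cell) and `tuning`
#'   (per-fold `tune_result`s).
#' @export
run_strategy <- function(pheno, markers, strategy = c("NT", "GrS", "BO"),
                         plan, prior, inner_prior = prior,
                         grid = make_grid(), bo_n_init = 6L, bo_n_iter = 14L,
                         include_ge = TRUE, verbose = FALSE) {
  strategy <- match.arg(strategy)
  check_line_match(pheno, markers)
  dist <- squared_distance_matrix(markers)
  traits <- trait_names(pheno)
  logs <- list()
  tuning <- vector("list", plan$k_outer)
  for (f in seq_len(plan$k_outer)) {
    tuning[[f]] <- switch(
      strategy,
      NT = tune_nt(),
      GrS = tune_grid(function(r)
        inner_objective(r, pheno, dist, plan, f, inner_prior, include_ge),
        grid),
      BO = tune_bo(function(r)
        inner_objective(r, pheno, dist, plan, f, inner_prior, include_ge),
        n_init = bo_n_init, n_iter = bo_n_iter,
        seed = .substream(plan$seed, paste0("bo", f))))
    rho_f <- tuning[[f]]$rho_opt
    test_rows <- which(plan$outer == f)
    mask <- .rows_mask(pheno, test_rows)
    fit <- fit_gibbs(pheno, gaussian_kernel(dist, rho_f), prior = prior,
                     include_ge = include_ge, mask = mask)
    pred <- predict_masked(fit, mask)
    obs <- as.matrix(pheno[test_rows, traits, drop = FALSE])
    logs[[f]] <- data.frame(
      strategy = strategy, fold = f, rho = rho_f,
      line = mask$line, env = mask$env, trait = mask$trait,
      observed = as.vector(t(obs)), predicted = pred$predicted,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("[%s] fold %d: rho = %.4f, %d test cells",
                      strategy, f, rho_f, nrow(mask)))
  }
  list(log = do.call(rbind, logs), tuning = tuning)
}

# Deterministic substream seed derived from a master seed and a label.
.substream <- function(seed, name) {
  as.integer((as.numeric(seed) * 7919 + sum(utf8ToInt(name)) * 104729) %%
               2147483399) + 1L
}
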