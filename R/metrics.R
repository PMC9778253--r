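# Prediction-accuracy metrics: normalized root mean squared error (NRMSE)
# at several aggregation levels and relative efficiencies between tuning
# strategies.

#' Normalized root mean squared error
#'
#' `sqrt(mean((observed - predicted)^2)) / mean(observed)`.  Pairs where the
#' observed value is missing are dropped before computing either term; the
#' mean of the observed values must be nonzero.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return a nonnegative scalar (lower is better).
#' @export
nrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  keep <- !is.na(observed)
  observed <- observed[keep]; predicted <- predicted[keep]
  if (length(observed) == 0L)
    stop("no observed values to score", call. = FALSE)
  m <- mean(observed)
  if (abs(m) < .Machine$double.eps * 100)
    stop("mean of observed values is zero; NRMSE is undefined", call. = FALSE)
  sqrt(mean((observed - predicted)^2)) / m
}

#' Relative efficiency of an alternative strategy versus a reference
#'
#' The ratio `nrmse_ref / nrmse_alt`.  Values above 1 mean the alternative
#' predicts better (smaller error) than the reference.
#'
#' @param nrmse_ref NRMSE of the reference strategy (e.g. no tuning).
#' @param nrmse_alt NRMSE of the alternative (e.g. grid search).
#' @return the ratio.
#' @export
relative_efficiency <- function(nrmse_ref, nrmse_alt) {
  if (any(nrmse_alt <= 0))
    stop("alternative NRMSE must be positive", call. = FALSE)
  nrmse_ref / nrmse_alt
}

#' Score a log of cross-validation predictions
#'
#' Takes the raw prediction log of a strategy run (one row per scored test
#' cell) and produces tidy NRMSE rows per (trait, environment, fold), plus
#' "Global" environment rows that pool all environments.
#'
#' @param log data.frame with columns `strategy`, `fold`, `trait`, `env`,
#'   `observed`, `predicted`.
#' @param global how the Global rows pool environments: `"pooled"` computes
#'   one NRMSE from all test cells of the fold (a single pooled normalizing
#'   mean); `"mean_of_env"` averages the per-environment NRMSEs.
#' @return data.frame with columns `strategy`, `trait`, `environment`,
#'   `fold`, `nrmse`.
#' @export
score_prediction_log <- function(log, global = c("pooled", "mean_of_env")) {
  global <- match.arg(global)
  log <- log[!is.na(log$observed), , drop = FALSE]
  out <- list()
  for (key in split(seq_len(nrow(log)),
                    list(log$strategy, log$trait, log$env, log$fold),
                    drop = TRUE)) {
    r <- log[key, ]
    out[[length(out) + 1L]] <- data.frame(
      strategy = r$strategy[1L], trait = r$trait[1L], environment = r$env[1L],
      fold = r$fold[1L], nrmse = nrmse(r$observed, r$predicted))
  }
  for (key in split(seq_len(nrow(log)),
                    list(log$strategy, log$trait, log$fold), drop = TRUE)) {
    r <- log[key, ]
    v <- if (global == "pooled") nrmse(r$observed, r$predicted) else {
      mean(vapply(split(seq_len(nrow(r)), r$env), function(i)
        nrmse(r$observed[i], r$predicted[i]), numeric(1)))
    }
    out[[length(out) + 1L]] <- data.frame(
      strategy = r$strategy[1L], trait = r$trait[1L], environment = "Global",
      fold = r$fold[1L], nrmse = v)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate per-fold NRMSE rows over folds and traits
#'
#' Trait-level NRMSE is the unweighted mean over folds; the across-trait
#' summary (`trait = "All"`) is the unweighted mean over the trait-level
#' values.  A standard error over folds (sd / sqrt(#folds)) accompanies each
#' trait-level row.
#'
#' @param per_fold output of [score_prediction_log()].
#' @return data.frame with columns `strategy`, `trait`, `environment`,
#'   `nrmse`, `se`.
#' @export
aggregate_metrics <- function(per_fold) {
  out <- list()
  for (key in split(seq_len(nrow(per_fold)),
                    list(per_fold$strategy, per_fold$trait,
                         per_fold$environment), drop = TRUE)) {
    r <- per_fold[key, ]
    out[[length(out) + 1L]] <- data.frame(
      strategy = r$strategy[1L], trait = r$trait[1L],
      environment = r$environment[1L], nrmse = mean(r$nrmse),
      se = stats::sd(r$nrmse) / sqrt(nrow(r)))
  }
  agg <- do.call(rbind, out)
  for (key in split(seq_len(nrow(agg)),
                    list(agg$strategy, agg$environment), drop = TRUE)) {
    r <- agg[key, ]
    out[[length(out) + 1L]] <- data.frame(
      strategy = r$strategy[1L], trait = "All",
      environment = r$environment[1L], nrmse = mean(r$nrmse), se = NA_real_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative-efficiency report comparing tuning strategies
#'
#' For every (trait, environment) cell present for both strategies of a
#' comparison, computes `re_grs = NRMSE_NT / NRMSE_GrS`,
#' `re_bo = NRMSE_NT / NRMSE_BO` and `re_grs_bo = NRMSE_GrS / NRMSE_BO`;
#' a ratio above 1 favors the strategy in the denominator.
#'
#' @param agg output of [aggregate_metrics()] (strategies among NT, GrS, BO).
#' @return data.frame with columns `trait`, `environment`, `comparison`,
#'   `re`.
#' @export
re_report <- function(agg) {
  combos <- list(re_grs = c("NT", "GrS"), re_bo = c("NT", "BO"),
                 re_grs_bo = c("GrS", "BO"))
  out <- list()
  for (nm in names(combos)) {
    ref <- agg[agg$strategy == combos[[nm]][1L], ]
    alt <- agg[agg$strategy == combos[[nm]][2L], ]
    if (!nrow(ref) || !nrow(alt)) next
    key_ref <- paste(ref$trait, ref$environment, sep = "\r")
    key_alt <- paste(alt$trait, alt$environment, sep = "\r")
    common <- intersect(key_ref, key_alt)
    for (k in common) {
      i <- match(k, key_ref); j <- match(k, key_alt)
      out[[length(out) + 1L]] <- data.frame(
        trait = ref$trait[i], environment = ref$environment[i],
        comparison = nm,
        re = relative_efficiency(ref$nrmse[i], alt$nrmse[j]))
    }
  }
  if (!length(out))
    return(data.frame(trait = character(), environment = character(),
                      comparison = character(), re = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
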