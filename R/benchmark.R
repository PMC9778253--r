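# Pipeline entry point: run the requested tuning strategies on one shared
# fold plan, score their predictions and write tidy metric files plus a
# reproducibility manifest.  A YAML run configuration drives everything;
# `inst/cli/gkblup` wraps this in a shell command.

#' Read and validate a YAML run configuration
#'
#' Recognized keys (defaults in parentheses): `phenotypes`, `markers`,
#' `traits` — input CSV paths and trait column names; or `preset` +
#' optional `markers_p` to simulate instead; `strategies` (NT, GrS, BO);
#' `k_outer` (7), `k_inner` (5); `grid`: `start` (0.01), `stop` (0.999),
#' `step` (0.04); `bo`: `n_init` (6), `n_iter` (14); `sampler`: `n_iter`
#' (3000), `burn_in` (1000), `thin` (2); `inner_sampler`: same keys for the
#' tuning fits (defaults to shorter chains: 600/200/2); `global`
#' ("pooled" or "mean_of_env"); `include_ge` (true); `seed` (1); `out`.
#'
#' @param path YAML file path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(raw)
}

#' Build a run configuration from a list
#' @param x named list of options, see [read_run_config()].
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(x = list()) {
  dft <- list(phenotypes = NULL, markers = NULL, traits = NULL,
              preset = NULL, markers_p = NULL,
              strategies = c("NT", "GrS", "BO"),
              k_outer = 7L, k_inner = 5L,
              grid = list(start = 0.01, stop = 0.999, step = 0.04),
              bo = list(n_init = 6L, n_iter = 14L),
              sampler = list(n_iter = 3000L, burn_in = 1000L, thin = 2L),
              inner_sampler = list(n_iter = 600L, burn_in = 200L, thin = 2L),
              global = "pooled", include_ge = TRUE, seed = 1L,
              out = "gkblup_run")
  for (nm in names(x)) {
    if (!nm %in% names(dft))
      stop("unknown config key: ", nm, call. = FALSE)
    if (is.list(dft[[nm]]) && !is.null(x[[nm]]))
      dft[[nm]][names(x[[nm]])] <- x[[nm]]
    else dft[[nm]] <- x[[nm]]
  }
  if (!length(dft$strategies) ||
      !all(dft$strategies %in% c("NT", "GrS", "BO")))
    stop("strategies must be a non-empty subset of NT, GrS, BO",
         call. = FALSE)
  if (!dft$global %in% c("pooled", "mean_of_env"))
    stop("global must be 'pooled' or 'mean_of_env'", call. = FALSE)
  if (is.null(dft$preset) &&
      (is.null(dft$phenotypes) || is.null(dft$markers) ||
       is.null(dft$traits)))
    stop("either 'preset' or all of 'phenotypes', 'markers', 'traits' ",
         "must be given", call. = FALSE)
  structure(dft, class = "run_config")
}

#' Run the full tuning benchmark
#'
#' Loads (or simulates) the data, builds one fold plan shared by all
#' requested strategies, runs tune-refit-predict per outer fold, and
#' writes: `fold_metrics.csv` (per-fold NRMSE rows), `metrics.csv`
#' (aggregated), `re_report.json` (relative efficiencies), `fold_plan.csv`
#' and `manifest.json`.
#'
#' @param config a `run_config` (or list coerced by [run_config()]).
#' @return invisibly, a list with `per_fold`, `aggregated`, `re`,
#'   `selected_rho` (strategy x fold) and `plan`.
#' @export
cmd_benchmark <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (!is.null(config$preset)) {
    cfg <- synthetic_preset(config$preset, p = config$markers_p,
                            seed = .substream(config$seed, "simulate"))
    markers <- simulate_markers(cfg)
    pheno <- simulate_phenotypes(markers, cfg)$pheno
  } else {
    pheno <- read_phenotypes(config$phenotypes, config$traits)
    markers <- read_markers(config$markers)
  }
  check_line_match(pheno, markers)
  nT <- length(trait_names(pheno))
  mk_prior <- function(s) prior_spec(nT, n_iter = s$n_iter,
                                     burn_in = s$burn_in, thin = s$thin,
                                     seed = .substream(config$seed, "sampler"))
  prior <- mk_prior(config$sampler)
  inner_prior <- mk_prior(config$inner_sampler)
  plan <- make_fold_plan(pheno, config$k_outer, config$k_inner,
                         seed = config$seed)
  grid <- make_grid(config$grid$start, config$grid$stop, config$grid$step)

  runs <- lapply(config$strategies, function(s)
    run_strategy(pheno, markers, s, plan, prior, inner_prior, grid,
                 bo_n_init = config$bo$n_init, bo_n_iter = config$bo$n_iter,
                 include_ge = config$include_ge))
  names(runs) <- config$strategies
  log <- do.call(rbind, lapply(runs, `[[`, "log"))
  per_fold <- score_prediction_log(log, global = config$global)
  agg <- aggregate_metrics(per_fold)
  re <- re_report(agg)
  selected <- do.call(rbind, lapply(names(runs), function(s)
    data.frame(strategy = s, fold = seq_len(plan$k_outer),
               rho = vapply(runs[[s]]$tuning, `[[`, numeric(1), "rho_opt"))))

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(per_fold, file.path(config$out, "fold_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(agg, file.path(config$out, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(selected, file.path(config$out, "selected_rho.csv"),
                   row.names = FALSE)
  write_fold_plan(plan, file.path(config$out, "fold_plan.csv"))
  jsonlite::write_json(
    list(re = re,
         global_nrmse = agg[agg$trait == "All" & agg$environment == "Global",
                            c("strategy", "nrmse")]),
    file.path(config$out, "re_report.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("gkblup")),
         seed = config$seed, strategies = config$strategies,
         k_outer = config$k_outer, k_inner = config$k_inner,
         grid = config$grid, bo = config$bo, sampler = config$sampler,
         inner_sampler = config$inner_sampler, global = config$global,
         include_ge = config$include_ge),
    file.path(config$out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(per_fold = per_fold, aggregated = agg, re = re,
                 selected_rho = selected, plan = plan, log = log))
}
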