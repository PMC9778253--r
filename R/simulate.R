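# Synthetic multi-environment multi-trait genomic data drawn from the same
# generative model the sampler fits, with known ground truth.  The
# generator emulates the shapes of typical breeding datasets (hundreds of
# lines, a handful of environments, 2-4 traits, thousands of markers,
# balanced or unbalanced line x environment layouts); it makes no attempt
# to match real linkage-disequilibrium structure or trait architectures.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a compact dataset with a strongly nonlinear genetic
#' signal: 150 lines, 3 environments, 2 correlated traits, 300 markers, a
#' generative bandwidth of 0.9 and a per-trait genetic signal fraction of
#' 0.6, with genotype-by-environment variance on the same scale as the
#' main genetic variance.
#'
#' @param J,I,nT,p lines, environments, traits, markers.
#' @param maf_range allele-frequency bounds, inside (0, 0.5].
#' @param rho_true generative Gaussian-kernel bandwidth in (0, 1).
#' @param mu_true length-nT trait intercepts (kept away from zero so NRMSE
#'   is well defined).
#' @param beta_E_true I x nT environment effects, or NULL to draw them
#'   N(0, 0.5^2) from the seed.
#' @param sigma_T_true,sigma_T_ge_true nT x nT genetic and interaction
#'   trait covariances (default: unit variance, 0.5 covariance).
#' @param R_true nT x nT residual covariance, or NULL to derive a diagonal
#'   residual from `signal_fraction` and the realized genetic variance.
#' @param signal_fraction target per-trait share of phenotypic variance
#'   explained by the genetic terms when `R_true` is NULL.
#' @param missing_fraction fraction of line x environment cells removed
#'   entirely (whole records, never individual traits); 0 = balanced.
#' @param env_line_counts optional length-I vector: exact number of lines
#'   present per environment (overrides `missing_fraction`); used by the
#'   unbalanced dataset presets.
#' @param seed integer master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(J = 150L, I = 3L, nT = 2L, p = 300L,
                             maf_range = c(0.05, 0.5), rho_true = 0.9,
                             mu_true = rep(10, nT), beta_E_true = NULL,
                             sigma_T_true = 0.5 + 0.5 * diag(nT),
                             sigma_T_ge_true = 0.5 + 0.5 * diag(nT),
                             R_true = NULL, signal_fraction = 0.6,
                             missing_fraction = 0, env_line_counts = NULL,
                             seed = 1L) {
  stopifnot(J >= 2, I >= 1, nT >= 1, p >= 1,
            maf_range[1L] > 0, maf_range[2L] <= 0.5,
            maf_range[1L] <= maf_range[2L],
            rho_true > 0, rho_true < 1,
            missing_fraction >= 0, missing_fraction < 1,
            signal_fraction > 0, signal_fraction < 1)
  for (S in list(sigma_T_true, sigma_T_ge_true))
    if (!isTRUE(all.equal(S, t(S))) ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("trait covariance matrices must be symmetric positive definite",
           call. = FALSE)
  if (!is.null(env_line_counts) &&
      (length(env_line_counts) != I || any(env_line_counts < 1) ||
       any(env_line_counts > J)))
    stop("env_line_counts must give 1..J lines for each of the I environments",
         call. = FALSE)
  structure(list(J = as.integer(J), I = as.integer(I), nT = as.integer(nT),
                 p = as.integer(p), maf_range = maf_range,
                 rho_true = rho_true, mu_true = mu_true,
                 beta_E_true = beta_E_true, sigma_T_true = sigma_T_true,
                 sigma_T_ge_true = sigma_T_ge_true, R_true = R_true,
                 signal_fraction = signal_fraction,
                 missing_fraction = missing_fraction,
                 env_line_counts = env_line_counts,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Dataset-shape presets for the generator
#'
#' Each preset reproduces the shape (lines, environments, traits, markers,
#' balance) of a published multi-environment breeding dataset: `japonica`
#' (320 rice lines over 5 years with per-year panels of 93/292/316/316/134,
#' 4 traits, 44,598 markers), `indica` (327 rice lines x 3 years, 4 traits,
#' 92,430 markers, balanced), `groundnut` (318 lines x 4 environments,
#' 4 traits, 8,268 markers, balanced), `cotton` (859 lines across 7
#' environments with each line in a single environment, 2 traits, 5,000
#' markers) and `disease` (438 wheat lines x 6 environments, 3 traits,
#' 11,617 post-QC markers).  Only shapes are emulated; all effect sizes
#' come from the generative model.
#'
#' @param name preset name.
#' @param p optional marker-count override (full panels are large; smaller
#'   panels keep the same phenotype layout).
#' @param seed master seed.
#' @return a [synthetic_config()].
#' @export
synthetic_preset <- function(name = c("japonica", "indica", "groundnut",
                                      "cotton", "disease"),
                             p = NULL, seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    japonica = list(J = 320L, I = 5L, nT = 4L, p = 44598L,
                    env_line_counts = c(93L, 292L, 316L, 316L, 134L)),
    indica = list(J = 327L, I = 3L, nT = 4L, p = 92430L),
    groundnut = list(J = 318L, I = 4L, nT = 4L, p = 8268L),
    cotton = list(J = 859L, I = 7L, nT = 2L, p = 5000L,
                  env_line_counts = c(123L, 123L, 123L, 123L, 123L, 123L,
                                      121L)),
    disease = list(J = 438L, I = 6L, nT = 3L, p = 11617L))
  if (!is.null(p)) cfg$p <- as.integer(p)
  do.call(synthetic_config, c(cfg, list(seed = seed)))
}

#' Simulate a post-QC marker panel
#'
#' Each marker draws an allele frequency uniformly from `maf_range`; line
#' dosages are binomial(2, f) draws.  Monomorphic columns are resampled so
#' every marker is polymorphic.
#'
#' @param cfg a [synthetic_config()].
#' @return a [marker_matrix()] with line ids `L0001`, `L0002`, ...
#' @export
simulate_markers <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(.substream(cfg$seed, "markers"))
  J <- cfg$J; p <- cfg$p
  f <- stats::runif(p, cfg$maf_range[1L], cfg$maf_range[2L])
  m <- matrix(stats::rbinom(J * p, 2L, rep(f, each = J)), J, p)
  mono <- which(apply(m, 2L, function(x) length(unique(x)) == 1L))
  while (length(mono)) {
    m[, mono] <- stats::rbinom(J * length(mono), 2L,
                               rep(f[mono], each = J))
    mono <- mono[apply(m[, mono, drop = FALSE], 2L,
                       function(x) length(unique(x)) == 1L)]
  }
  rownames(m) <- sprintf("L%04d", seq_len(J))
  colnames(m) <- sprintf("M%d", seq_len(p))
  marker_matrix(m)
}

#' Simulate multi-environment multi-trait phenotypes with known truth
#'
#' Builds the Gaussian kernel at `rho_true`, draws the line effects from a
#' matrix-variate normal with row covariance K and column covariance
#' `sigma_T_true`, the interaction effects per environment from the same
#' row covariance with column covariance `sigma_T_ge_true`, and iid
#' residual rows.  When `R_true` is NULL the residual variances are set
#' from the realized variance of the genetic terms so each trait's genetic
#' signal fraction equals `signal_fraction`.  Unbalanced layouts remove
#' whole (line, environment) records.
#'
#' @param markers output of [simulate_markers()] (or any marker matrix
#'   whose rows are the J lines).
#' @param cfg the same [synthetic_config()].
#' @return list with `pheno` (a [pheno_table()]) and `truth` (all draws and
#'   parameters: `g`, `gE` on the full grid, `beta_E`, `mu`, covariance
#'   matrices, the kernel, the realized signal fractions and the seed).
#' @export
simulate_phenotypes <- function(markers, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  J <- nrow(markers); I <- cfg$I; nT <- cfg$nT
  if (J != cfg$J) stop("marker matrix and config disagree on J", call. = FALSE)
  set.seed(.substream(cfg$seed, "phenotypes"))
  lines <- rownames(markers)
  envs <- sprintf("E%02d", seq_len(I))
  dist <- squared_distance_matrix(markers)
  K <- gaussian_kernel(dist, cfg$rho_true)
  eK <- eigen(unclass(K), symmetric = TRUE)
  Ksqrt <- eK$vectors %*% (sqrt(pmax(eK$values, 0)) * t(eK$vectors))

  cT <- chol(cfg$sigma_T_true)
  g <- Ksqrt %*% matrix(stats::rnorm(J * nT), J) %*% cT
  cGE <- chol(cfg$sigma_T_ge_true)
  gE <- do.call(rbind, lapply(seq_len(I), function(e)
    Ksqrt %*% matrix(stats::rnorm(J * nT), J) %*% cGE))
  beta_E <- cfg$beta_E_true
  if (is.null(beta_E)) beta_E <- matrix(stats::rnorm(I * nT, 0, 0.5), I, nT)
  dimnames(beta_E) <- list(envs, NULL)

  ei <- rep(seq_len(I), each = J); li <- rep(seq_len(J), I)
  signal <- g[li, , drop = FALSE] + gE
  R <- cfg$R_true
  if (is.null(R)) {
    v_sig <- apply(signal, 2L, stats::var)
    R <- diag(v_sig * (1 - cfg$signal_fraction) / cfg$signal_fraction,
              nT)
  }
  eps <- matrix(stats::rnorm(I * J * nT), I * J) %*% chol(R)
  Y <- matrix(cfg$mu_true, I * J, nT, byrow = TRUE) +
    beta_E[ei, , drop = FALSE] + signal + eps
  realized_sf <- apply(signal, 2L, stats::var) /
    (apply(signal, 2L, stats::var) + diag(as.matrix(R)))

  keep <- rep(TRUE, I * J)
  if (!is.null(cfg$env_line_counts)) {
    for (e in seq_len(I)) {
      idx <- which(ei == e)
      drop_n <- J - cfg$env_line_counts[e]
      if (drop_n > 0) keep[sample(idx, drop_n)] <- FALSE
    }
  } else if (cfg$missing_fraction > 0) {
    keep[sample(I * J, floor(cfg$missing_fraction * I * J))] <- FALSE
  }

  traits <- sprintf("T%d", seq_len(nT))
  df <- data.frame(line = lines[li], env = envs[ei],
                   stringsAsFactors = FALSE)
  df[traits] <- as.data.frame(Y)
  pheno <- pheno_table(df[keep, , drop = FALSE], traits)
  truth <- list(g = g, gE = gE, beta_E = beta_E, mu = cfg$mu_true,
                sigma_T = cfg$sigma_T_true, sigma_T_ge = cfg$sigma_T_ge_true,
                R = as.matrix(R), rho_true = cfg$rho_true, K = K,
                grid_env = envs[ei], grid_line = lines[li], kept = keep,
                realized_signal_fraction = realized_sf, seed = cfg$seed)
  list(pheno = pheno, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes the phenotype CSV, the marker CSV and a JSON truth record
#' (parameters only; the large effect draws are omitted from the JSON).
#'
#' @param sim output of [simulate_phenotypes()].
#' @param markers the marker matrix used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, markers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phenotypes(sim$pheno, file.path(dir, "phenotypes.csv"))
  write_markers(markers, file.path(dir, "markers.csv"))
  tr <- sim$truth
  jsonlite::write_json(
    list(rho_true = tr$rho_true, mu = tr$mu, beta_E = tr$beta_E,
         sigma_T = tr$sigma_T, sigma_T_ge = tr$sigma_T_ge, R = tr$R,
         realized_signal_fraction = tr$realized_signal_fraction,
         seed = tr$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
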