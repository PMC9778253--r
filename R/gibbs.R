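# Gibbs sampler for the multi-trait kernel mixed model
#
#   Y = 1 mu' + X_E beta_E + Z_L g + Z_EL gE + eps
#
# with g ~ MN(0, K, Sigma_T), gE ~ MN(0, (Z_E Z_E') * (Z_L K Z_L'), Sigma_ge)
# and eps rows iid N(0, R).  The sampler completes the full environment x
# line grid and samples every unobserved cell (absent combinations, missing
# trait values, cross-validation masks) from its conditional normal each
# sweep.  On the completed grid the line design is balanced, so a single
# eigendecomposition K = U D U' diagonalizes both the line-effect and the
# (block-diagonal) interaction-effect full conditionals; trait coupling is
# removed per sweep by simultaneous diagonalization of the effect covariance
# against R, leaving scalar shrinkage updates.

#' Prior and sampler settings for the multi-trait kernel model
#'
#' Inverse-Wishart priors are placed on the trait genetic covariance, the
#' interaction trait covariance and the residual covariance; fixed effects
#' get a flat prior.  The defaults (df = nT + 2, identity scale) are weakly
#' informative with a finite prior mean.
#'
#' @param nT number of traits.
#' @param iw_df_traits,iw_scale_traits inverse-Wishart degrees of freedom
#'   (must be at least nT + 2) and nT x nT scale for the genetic and
#'   interaction trait covariances.
#' @param iw_df_resid,iw_scale_resid same for the residual covariance.
#' @param n_iter,burn_in,thin Gibbs chain length, burn-in and thinning.
#' @param seed integer seed; identical seed and inputs give identical fits.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(nT,
                       iw_df_traits = nT + 2, iw_scale_traits = diag(nT),
                       iw_df_resid = nT + 2, iw_scale_resid = diag(nT),
                       n_iter = 3000L, burn_in = 1000L, thin = 2L,
                       seed = 1L) {
  stopifnot(nT >= 1, n_iter > burn_in, burn_in >= 0, thin >= 1)
  if (iw_df_traits < nT + 2 || iw_df_resid < nT + 2)
    stop("inverse-Wishart df must be at least nT + 2", call. = FALSE)
  structure(list(nT = as.integer(nT),
                 iw_df_traits = iw_df_traits,
                 iw_scale_traits = as.matrix(iw_scale_traits),
                 iw_df_resid = iw_df_resid,
                 iw_scale_resid = as.matrix(iw_scale_resid),
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "prior_spec")
}

# Inverse-Wishart draw: if W ~ Wishart(df, S^-1) then W^-1 ~ IW(df, S).
.riwish <- function(df, S) {
  W <- stats::rWishart(1L, df, solve(S))[, , 1L]
  V <- solve(W)
  (V + t(V)) / 2
}

# Sample rows a_l ~ posterior of: prior a_l ~ N(0, d[l] * Sigma),
# data ytil_l = a_l + e_l with e_l ~ N(0, Rnoise).  Returns the sampled
# effect matrix plus the quadratic form sum_l a_l' Sigma^-1 a_l / d[l]
# pieces needed by the covariance update are computed by the caller.
.sample_shrunk_rows <- function(ytil, d, Sigma, Rnoise) {
  L <- t(chol(Rnoise))
  S <- forwardsolve(L, t(forwardsolve(L, Sigma)))
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(es$values, 1e-12)
  C <- L %*% es$vectors                      # Sigma = C diag(lam) C', R = C C'
  z <- t(forwardsolve(L, t(ytil)))
  z <- z %*% es$vectors                      # z = C^-1 ytil (rowwise)
  w <- outer(d, lam)
  shrink <- w / (1 + w)
  b <- shrink * z +
    matrix(stats::rnorm(length(z)), nrow(z), ncol(z)) * sqrt(shrink)
  b %*% t(C)
}

#' Fit the multi-trait Gaussian-kernel model by Gibbs sampling
#'
#' Missing phenotype cells — absent (line, environment) combinations,
#' individual missing trait values, and any cells listed in `mask` — are
#' sampled from their conditional normal each sweep (data augmentation);
#' their posterior-mean conditional expectations are the model's
#' predictions, which is how cross-validation test cells are scored.
#'
#' The intercept is identified by a sum-to-zero constraint on the
#' environment effects: the sampler draws one mean per environment and
#' reports their average as `mu_T` and the deviations as `beta_E`.
#'
#' @param pheno a [pheno_table()].
#' @param k a J x J `kernel_matrix` covering every line of `pheno`.
#' @param design output of [build_design()] on `pheno`; built internally
#'   when `NULL`.
#' @param prior a [prior_spec()].
#' @param include_ge include the genotype-by-environment interaction term.
#' @param mask optional data.frame with columns `line`, `env`, `trait`:
#'   observed cells to hide from the sampler and predict (used by the
#'   cross-validation engine).
#' @param fixed optional list with any of `sigma_T`, `sigma_ge`, `R`:
#'   covariance matrices to hold fixed instead of sampling (used for
#'   validation against closed-form BLUP).
#' @return a `gk_fit` with posterior means `mu_T`, `beta_E` (I x nT),
#'   `g_hat` (J x nT), `ge_hat` (n_grid x nT), covariance matrices
#'   `sigma_T`, `sigma_T_ge`, `R`, predictions `y_pred` (full grid, no
#'   missing entries), the grid layout, retained covariance draws and the
#'   number of retained draws.
#' @export
fit_gibbs <- function(pheno, k, design = NULL, prior, include_ge = TRUE,
                      mask = NULL, fixed = NULL) {
  stopifnot(inherits(pheno, "pheno_table"), inherits(prior, "prior_spec"))
  traits <- trait_names(pheno)
  nT <- length(traits)
  if (nT != prior$nT) stop("prior was specified for ", prior$nT,
                           " trait(s), data has ", nT, call. = FALSE)
  if (is.null(design)) design <- build_design(pheno)
  envs <- design$envs; lines <- design$lines
  I <- length(envs); J <- length(lines); n <- I * J
  if (!all(lines %in% rownames(k)))
    stop("kernel does not cover every phenotyped line", call. = FALSE)
  K <- unclass(k)[lines, lines]

  # full environment-major grid; map phenotype records onto it
  grid <- data.frame(env = rep(envs, each = J), line = rep(lines, I),
                     stringsAsFactors = FALSE)
  ei <- rep(seq_len(I), each = J); li <- rep(seq_len(J), I)
  rec <- match(paste(grid$env, grid$line), paste(pheno$env, pheno$line))
  Yobs <- matrix(NA_real_, n, nT, dimnames = list(NULL, traits))
  got <- !is.na(rec)
  Yobs[got, ] <- as.matrix(pheno[rec[got], traits, drop = FALSE])
  if (!is.null(mask) && nrow(mask)) {
    mi <- match(paste(mask$env, mask$line), paste(grid$env, grid$line))
    if (anyNA(mi))
      stop("mask references (line, env) combinations absent from the fit",
           call. = FALSE)
    ti <- match(mask$trait, traits)
    if (anyNA(ti)) stop("mask references unknown trait(s)", call. = FALSE)
    Yobs[cbind(mi, ti)] <- NA_real_
  }
  miss <- is.na(Yobs)
  if (any(colSums(!miss) == 0L))
    stop("trait(s) with no observed value: ",
         paste(traits[colSums(!miss) == 0L], collapse = ", "), call. = FALSE)

  # eigendecomposition of K, shared by the g and gE updates
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- eK$values
  if (min(d) < -1e-6)
    stop("kernel is not positive semidefinite (min eigenvalue ",
         format(min(d)), ")", call. = FALSE)
  d <- pmax(d, max(d) * 1e-10)
  U <- eK$vectors
  d_ge <- rep(d, I)

  # group rows by missingness pattern once; patterns never change
  pat <- apply(miss, 1L, function(m) paste(as.integer(m), collapse = ""))
  groups <- lapply(split(seq_len(n), pat), function(rows) {
    m <- miss[rows[1L], ]
    list(rows = rows, m = which(m), o = which(!m))
  })
  groups <- Filter(function(g) length(g$m) > 0L, groups)

  # initial values
  set.seed(prior$seed)
  Y <- Yobs
  tr_mean <- colMeans(Yobs, na.rm = TRUE)
  for (t in seq_len(nT)) Y[miss[, t], t] <- tr_mean[t]
  tr_var <- apply(Yobs, 2L, stats::var, na.rm = TRUE)
  tr_var[!is.finite(tr_var) | tr_var <= 0] <- 1
  sigma_T <- diag(tr_var / 3, nT); sigma_ge <- diag(tr_var / 3, nT)
  R <- diag(tr_var / 3, nT)
  if (!is.null(fixed$sigma_T)) sigma_T <- as.matrix(fixed$sigma_T)
  if (!is.null(fixed$sigma_ge)) sigma_ge <- as.matrix(fixed$sigma_ge)
  if (!is.null(fixed$R)) R <- as.matrix(fixed$R)
  B <- matrix(0, I, nT)
  g <- matrix(0, J, nT); u <- matrix(0, n, nT)
  a_ge <- matrix(0, n, nT)

  env_rows <- split(seq_len(n), ei)           # rows of each env block, in order
  nu_t <- prior$iw_df_traits; S_t <- prior$iw_scale_traits
  nu_r <- prior$iw_df_resid;  S_r <- prior$iw_scale_resid

  keep <- prior$n_iter > prior$burn_in
  n_kept <- 0L
  acc <- list(mu = numeric(nT), B = matrix(0, I, nT), g = matrix(0, J, nT),
              u = matrix(0, n, nT), sigma_T = matrix(0, nT, nT),
              sigma_ge = matrix(0, nT, nT), R = matrix(0, nT, nT),
              pred = matrix(0, n, nT))
  draws_sT <- list(); draws_sge <- list(); draws_R <- list()

  for (it in seq_len(prior$n_iter)) {
    M <- B[ei, , drop = FALSE] + g[li, , drop = FALSE] + u

    # (a) impute unobserved cells from their conditional normal given the
    # observed traits of the same row; keep the conditional mean for y_pred
    condM <- M
    for (gr in groups) {
      rows <- gr$rows; m <- gr$m; o <- gr$o
      if (length(o) == 0L) {
        cm <- M[rows, m, drop = FALSE]
        cc <- R
      } else {
        A <- R[m, o, drop = FALSE] %*% solve(R[o, o, drop = FALSE])
        cm <- M[rows, m, drop = FALSE] +
          (Y[rows, o, drop = FALSE] - M[rows, o, drop = FALSE]) %*% t(A)
        cc <- R[m, m, drop = FALSE] - A %*% R[o, m, drop = FALSE]
        cc <- (cc + t(cc)) / 2
      }
      condM[rows, m] <- cm
      Y[rows, m] <- cm + matrix(stats::rnorm(length(rows) * length(m)),
                                length(rows)) %*% chol(cc + diag(1e-12, length(m)))
    }

    # (b) environment means (flat prior); balanced grid: J rows per env
    Y1 <- Y - g[li, , drop = FALSE] - u
    Ebar <- do.call(rbind, lapply(env_rows, function(r)
      colMeans(Y1[r, , drop = FALSE])))
    B <- Ebar + matrix(stats::rnorm(I * nT), I) %*% chol(R / J)

    # (c) line effects in the eigenbasis of K; the balanced grid averages
    # the I environment replicates, leaving noise covariance R / I
    Y2 <- Y - B[ei, , drop = FALSE] - u
    Ybar <- matrix(0, J, nT)
    for (r in env_rows) Ybar <- Ybar + Y2[r, , drop = FALSE]
    Ybar <- Ybar / I
    a <- .sample_shrunk_rows(crossprod(U, Ybar), d, sigma_T, R / I)
    g <- U %*% a

    # (d) interaction effects: block-diagonal kernel, one K block per env
    if (include_ge) {
      Y3 <- Y - B[ei, , drop = FALSE] - g[li, , drop = FALSE]
      ytil <- do.call(rbind, lapply(env_rows, function(r)
        crossprod(U, Y3[r, , drop = FALSE])))
      a_ge <- .sample_shrunk_rows(ytil, d_ge, sigma_ge, R)
      u <- do.call(rbind, lapply(seq_len(I), function(e)
        U %*% a_ge[(e - 1L) * J + seq_len(J), , drop = FALSE]))
    }

    # (e) covariance updates (inverse-Wishart full conditionals)
    if (is.null(fixed$sigma_T))
      sigma_T <- .riwish(nu_t + J, S_t + crossprod(a / sqrt(d)))
    if (include_ge && is.null(fixed$sigma_ge))
      sigma_ge <- .riwish(nu_t + n, S_t + crossprod(a_ge / sqrt(d_ge)))
    if (is.null(fixed$R)) {
      E <- Y - (B[ei, , drop = FALSE] + g[li, , drop = FALSE] + u)
      R <- .riwish(nu_r + n, S_r + crossprod(E))
    }

    if (keep && it > prior$burn_in &&
        (it - prior$burn_in) %% prior$thin == 0L) {
      n_kept <- n_kept + 1L
      mu <- colMeans(B)
      acc$mu <- acc$mu + mu
      acc$B <- acc$B + sweep(B, 2L, mu)
      acc$g <- acc$g + g
      acc$u <- acc$u + u
      acc$sigma_T <- acc$sigma_T + sigma_T
      acc$sigma_ge <- acc$sigma_ge + sigma_ge
      acc$R <- acc$R + R
      acc$pred <- acc$pred + condM
      draws_sT[[n_kept]] <- sigma_T
      draws_sge[[n_kept]] <- sigma_ge
      draws_R[[n_kept]] <- R
    }
  }

  lapply_names <- function(m, rn, cn) { dimnames(m) <- list(rn, cn); m }
  y_pred <- acc$pred / n_kept
  dimnames(y_pred) <- list(paste(grid$env, grid$line, sep = ":"), traits)
  structure(list(
    mu_T = stats::setNames(acc$mu / n_kept, traits),
    beta_E = lapply_names(acc$B / n_kept, envs, traits),
    g_hat = lapply_names(acc$g / n_kept, lines, traits),
    ge_hat = lapply_names(acc$u / n_kept,
                          paste(grid$env, grid$line, sep = ":"), traits),
    sigma_T = lapply_names(acc$sigma_T / n_kept, traits, traits),
    sigma_T_ge = lapply_names(acc$sigma_ge / n_kept, traits, traits),
    R = lapply_names(acc$R / n_kept, traits, traits),
    y_pred = y_pred,
    grid = grid, envs = envs, lines = lines, traits = traits,
    include_ge = include_ge, rho = attr(k, "rho"),
    n_draws = n_kept,
    draws = list(sigma_T = draws_sT, sigma_T_ge = draws_sge, R = draws_R),
    prior = prior), class = "gk_fit")
}

#' @export
print.gk_fit <- function(x, ...) {
  cat(sprintf(paste0("gk_fit: %d lines x %d environments, %d trait(s), ",
                     "%d retained draws%s\n"),
              length(x$lines), length(x$envs), length(x$traits), x$n_draws,
              if (!is.null(x$rho)) sprintf(", rho = %.4f", x$rho) else ""))
  invisible(x)
}

#' Extract predictions for a set of masked cells
#'
#' Returns the data-augmentation posterior-mean predictions for the
#' requested (line, environment, trait) cells.  These are the values used to
#' score cross-validation test sets: test cells are masked during fitting,
#' never dropped, so their line and environment structure still informs the
#' conditional.
#'
#' @param fit a `gk_fit`.
#' @param mask data.frame with columns `line`, `env`, `trait`.
#' @return `mask` with a `predicted` column appended.
#' @export
predict_masked <- function(fit, mask) {
  stopifnot(inherits(fit, "gk_fit"))
  if (is.null(mask) || nrow(mask) == 0L)
    return(data.frame(line = character(), env = character(),
                      trait = character(), predicted = numeric()))
  gi <- match(paste(mask$env, mask$line),
              paste(fit$grid$env, fit$grid$line))
  if (anyNA(gi))
    stop("mask references (line, env) combinations absent from the fit",
         call. = FALSE)
  ti <- match(mask$trait, fit$traits)
  if (anyNA(ti)) stop("mask references unknown trait(s)", call. = FALSE)
  out <- mask
  out$predicted <- fit$y_pred[cbind(gi, ti)]
  out
}

#' Serialize a fit to a directory of CSVs plus a JSON manifest
#'
#' @param fit a `gk_fit`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) utils::write.csv(
    data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE),
    file.path(dir, f), row.names = FALSE, quote = FALSE)
  wr(fit$beta_E, "beta_E.csv"); wr(fit$g_hat, "g_hat.csv")
  wr(fit$ge_hat, "ge_hat.csv"); wr(fit$sigma_T, "sigma_T.csv")
  wr(fit$sigma_T_ge, "sigma_T_ge.csv"); wr(fit$R, "R.csv")
  wr(fit$y_pred, "y_pred.csv")
  utils::write.csv(data.frame(trait = names(fit$mu_T), mu = fit$mu_T),
                   file.path(dir, "mu_T.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = fit$prior$seed, n_iter = fit$prior$n_iter,
         burn_in = fit$prior$burn_in, thin = fit$prior$thin,
         n_draws = fit$n_draws, rho = fit$rho, include_ge = fit$include_ge),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
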