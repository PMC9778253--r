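# Bandwidth-selection strategies for the Gaussian kernel.  All three
# strategies optimize (or skip optimizing) the same objective: the inner
# cross-validation mean NRMSE as a function of rho in (0, 1).

#' Bandwidth grid for grid search
#'
#' An arithmetic progression from `start` in steps of `step`, never
#' exceeding `stop`; `stop` itself is appended as the final value when the
#' progression does not reach it.  The defaults give the 26-value grid
#' 0.01, 0.05, ..., 0.97, 0.999.
#'
#' @param start,stop,step grid bounds and increment, with
#'   `0 < start < stop < 1` and `step > 0`.
#' @return increasing numeric vector of bandwidths.
#' @export
make_grid <- function(start = 0.01, stop = 0.999, step = 0.04) {
  if (!(start > 0 && start < stop && stop < 1 && step > 0))
    stop("need 0 < start < stop < 1 and step > 0", call. = FALSE)
  g <- seq(start, stop, by = step)
  if (max(g) < stop) g <- c(g, stop)
  g
}

.tune_result <- function(strategy, evaluations, seed = NA_integer_) {
  evaluations <- as.data.frame(evaluations)
  finite <- which(is.finite(evaluations$value))
  rho_opt <- if (length(finite)) {
    cand <- evaluations[finite, ]
    best <- cand$rho[cand$value <= min(cand$value) + 1e-15]
    min(best)                                   # ties: smallest rho
  } else evaluations$rho[1L]
  structure(list(strategy = strategy, evaluations = evaluations,
                 rho_opt = rho_opt, seed = seed),
            class = "tune_result")
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("tune_result [%s]: %d evaluation(s), rho_opt = %.4f\n",
              x$strategy, nrow(x$evaluations), x$rho_opt))
  invisible(x)
}

#' No-tuning strategy: the fixed bandwidth rho = exp(-1)
#'
#' @return a `tune_result` with a single (unevaluated) point at [nt_rho()].
#' @export
tune_nt <- function() {
  structure(list(strategy = "NT",
                 evaluations = data.frame(rho = nt_rho(), value = NA_real_),
                 rho_opt = nt_rho(), seed = NA_integer_),
            class = "tune_result")
}

#' Grid-search bandwidth tuning
#'
#' Evaluates the objective at every grid point and returns the minimizer
#' (ties broken toward the smallest rho).
#'
#' @param objective function of rho returning the inner-CV mean NRMSE.
#' @param grid increasing vector of bandwidths, see [make_grid()].
#' @return a `tune_result` with one evaluation per grid point.
#' @export
tune_grid <- function(objective, grid = make_grid()) {
  if (!length(grid)) stop("empty grid", call. = FALSE)
  grid <- sort(grid)
  vals <- vapply(grid, objective, numeric(1))
  .tune_result("GrS", data.frame(rho = grid, value = vals))
}

# ---- Bayesian optimization --------------------------------------------------

.matern52 <- function(r, len) {
  s <- sqrt(5) * r / len
  (1 + s + s^2 / 3) * exp(-s)
}

# Zero-mean GP posterior on standardized observations.
.gp_posterior <- function(x, y, xstar, len, noise = 1e-6) {
  Kxx <- .matern52(abs(outer(x, x, "-")), len) + diag(noise, length(x))
  Ks <- .matern52(abs(outer(xstar, x, "-")), len)
  L <- t(chol(Kxx))
  alpha <- backsolve(t(L), forwardsolve(L, y))
  mu <- as.vector(Ks %*% alpha)
  V <- forwardsolve(L, t(Ks))
  s2 <- pmax(1 + noise - colSums(V^2), 1e-12)
  ll <- -0.5 * sum(y * alpha) - sum(log(diag(L)))  # marginal log-likelihood
  list(mu = mu, sd = sqrt(s2), loglik = ll)
}

#' Bayesian-optimization bandwidth tuning
#'
#' A Gaussian-process surrogate (Matern-5/2 covariance, constant mean via
#' standardization, small fixed noise) is fit to the evaluated (rho,
#' objective) pairs; the next evaluation maximizes expected improvement on a
#' fine candidate lattice inside (0.001, 0.999).  The surrogate lengthscale
#' is re-selected each step by marginal likelihood over a small candidate
#' set.  Starts from `n_init` stratified random points, then runs `n_iter`
#' acquisitions; the returned optimum is the best evaluated point.
#'
#' @param objective function of rho returning the objective to minimize.
#' @param bounds search interval, a subinterval of (0, 1).
#' @param n_init number of space-filling initial evaluations (>= 2).
#' @param n_iter number of acquisition steps.
#' @param seed integer seed; same seed gives an identical evaluation list.
#' @return a `tune_result` with `n_init + n_iter` evaluations in order.
#' @export
tune_bo <- function(objective, bounds = c(0.001, 0.999), n_init = 6L,
                    n_iter = 14L, seed = 1L) {
  stopifnot(n_init >= 2L, n_iter >= 0L,
            bounds[1L] > 0, bounds[2L] < 1, bounds[1L] < bounds[2L])
  set.seed(seed)
  width <- diff(bounds)
  x <- bounds[1L] + width *
    (sample(seq_len(n_init)) - stats::runif(n_init)) / n_init
  y <- vapply(x, .check_finite_objective, numeric(1), objective = objective)
  lattice <- seq(max(0.001, bounds[1L]), min(0.999, bounds[2L]),
                 length.out = 512L)
  len_set <- width * c(0.05, 0.1, 0.2, 0.4, 0.8)
  for (step in seq_len(n_iter)) {
    mu_y <- mean(y); sd_y <- stats::sd(y)
    if (!is.finite(sd_y) || sd_y < 1e-12) sd_y <- 1
    ys <- (y - mu_y) / sd_y
    cand <- lattice[vapply(lattice, function(v) min(abs(v - x)) > 1e-6,
                           logical(1))]
    if (!length(cand)) break
    fits <- lapply(len_set, function(l) .gp_posterior(x, ys, cand, l))
    gp <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
    best <- min(ys)
    z <- (best - gp$mu) / gp$sd
    ei <- (best - gp$mu) * stats::pnorm(z) + gp$sd * stats::dnorm(z)
    xn <- cand[which.max(ei)]
    x <- c(x, xn)
    y <- c(y, .check_finite_objective(xn, objective))
  }
  .tune_result("BO", data.frame(rho = x, value = y), seed = as.integer(seed))
}

.check_finite_objective <- function(rho, objective) {
  v <- objective(rho)
  if (!is.finite(v))
    stop("objective returned a non-finite value at rho = ", format(rho),
         call. = FALSE)
  v
}
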