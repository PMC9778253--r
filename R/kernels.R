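# Gaussian and linear kernels over marker data, plus the genotype-by-
# environment kernel.  The Gaussian kernel is parameterized by the bandwidth
# rho in (0, 1): K[i, j] = rho ^ d2[i, j], equivalent to exp(-gamma * d2)
# with gamma = -log(rho).

#' Scaled squared Euclidean distances between marker rows
#'
#' Computes the pairwise squared Euclidean distances between the marker
#' vectors of all lines and divides by their maximum, so entries lie in
#' [0, 1].  With distances on this scale the bandwidth grid (0.01, 0.999)
#' and the fixed choice gamma = 1 are all informative: the Gaussian kernel
#' `rho ^ d2` then spans (rho, 1].  The normalizer is returned as
#' `scale_factor` so runs are reproducible on new data.
#'
#' @param markers a `marker_matrix` (J x p).
#' @return list with `d2` (J x J, symmetric, zero diagonal, max entry 1) and
#'   `scale_factor` (the raw maximum squared distance).
#' @export
squared_distance_matrix <- function(markers) {
  x <- unclass(markers)
  if (nrow(x) < 2L) stop("need at least 2 lines", call. = FALSE)
  d2 <- as.matrix(stats::dist(x))^2
  raw_max <- max(d2)
  if (raw_max <= 0)
    stop("all lines have identical marker vectors; the kernel would be ",
         "constant for every bandwidth", call. = FALSE)
  d2 <- d2 / raw_max
  d2 <- (d2 + t(d2)) / 2
  diag(d2) <- 0
  dimnames(d2) <- list(rownames(x), rownames(x))
  list(d2 = d2, scale_factor = raw_max)
}

#' Gaussian kernel from a scaled distance matrix
#'
#' `K[i, j] = rho ^ d2[i, j] = exp(log(rho) * d2[i, j])`.  The diagonal is
#' exactly 1.  If the smallest eigenvalue falls below `1e-10` a jitter of
#' `1e-8` is added to the diagonal (with a message); the Gaussian kernel is
#' positive semidefinite in exact arithmetic, so this is numerical rescue
#' only.
#'
#' @param d output of [squared_distance_matrix()].
#' @param rho bandwidth in (0, 1).
#' @return a `kernel_matrix`: the J x J matrix with attributes `kind`
#'   ("gaussian") and `rho`.
#' @export
gaussian_kernel <- function(d, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop("rho must be a single value in (0, 1)", call. = FALSE)
  K <- exp(log(rho) * d$d2)
  diag(K) <- 1
  K <- .psd_rescue(K)
  structure(K, kind = "gaussian", rho = rho,
            class = c("kernel_matrix", class(matrix())))
}

#' Fixed bandwidth used by the no-tuning strategy
#'
#' The no-tuning (NT) strategy fixes gamma = 1, i.e. rho = exp(-1).
#'
#' @return `exp(-1)`.
#' @export
nt_rho <- function() exp(-1)

#' VanRaden genomic relationship matrix (linear kernel)
#'
#' Columns of the 0/1/2 dosage matrix are centered at twice the observed
#' allele frequency and the cross-product is scaled by `2 * sum(f * (1 - f))`.
#'
#' @param markers a `marker_matrix`.
#' @return a `kernel_matrix` with attribute `kind = "linear"`.
#' @export
linear_grm <- function(markers) {
  x <- unclass(markers)
  f <- colMeans(x) / 2
  denom <- 2 * sum(f * (1 - f))
  if (denom <= 0)
    stop("all markers are monomorphic; the relationship matrix is undefined",
         call. = FALSE)
  W <- sweep(x, 2L, 2 * f, "-")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(x), rownames(x))
  structure(G, kind = "linear", rho = NULL,
            class = c("kernel_matrix", class(matrix())))
}

#' Genotype-by-environment interaction kernel
#'
#' The n x n covariance of the interaction effects:
#' `(Z_E Z_E') * (Z_L K Z_L')` (elementwise product), i.e. entry (a, b) is
#' `K[line_a, line_b]` when rows a and b share an environment and 0
#' otherwise.  In the canonical environment-major row order of a balanced
#' table this is block-diagonal with one copy of K per environment.
#'
#' @param k a J x J `kernel_matrix` covering all lines of the design.
#' @param design output of [build_design()].
#' @return an n x n `kernel_matrix` with attribute `kind = "ge"`.
#' @export
ge_kernel <- function(k, design) {
  if (!all(design$lines %in% rownames(k)))
    stop("kernel does not cover every line of the design", call. = FALSE)
  Zk <- design$Z_L %*% unclass(k)[design$lines, design$lines] %*% t(design$Z_L)
  mask <- tcrossprod(design$X_E)
  K <- Zk * mask
  K <- .psd_rescue(K)
  structure(K, kind = "ge", rho = attr(k, "rho"),
            class = c("kernel_matrix", class(matrix())))
}

# Adds 1e-8 to the diagonal when the minimum eigenvalue is below 1e-10.
.psd_rescue <- function(K, tol = 1e-10, jitter = 1e-8) {
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < tol) {
    message(sprintf("kernel min eigenvalue %.3g < %.0e; adding %.0e jitter",
                    ev_min, tol, jitter))
    diag(K) <- diag(K) + jitter
  }
  K
}

#' Write a kernel matrix as a square CSV with line-id headers
#' @param k a `kernel_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(k, path) {
  df <- data.frame(line = rownames(k), as.data.frame(unclass(k)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
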