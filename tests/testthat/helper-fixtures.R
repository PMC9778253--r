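# Shared fixture builders.  Everything is generated in code; expensive
# simulations are cached per test session.

tiny_pheno <- function(nT = 1L, I = 2L, J = 2L, value = NULL) {
  lines <- sprintf("L%02d", seq_len(J))
  envs <- sprintf("E%d", seq_len(I))
  df <- expand.grid(line = lines, env = envs, stringsAsFactors = FALSE)
  traits <- sprintf("T%d", seq_len(nT))
  set.seed(99)
  for (tr in traits)
    df[[tr]] <- if (is.null(value)) stats::rnorm(nrow(df), 10) else value
  pheno_table(df, traits)
}

random_markers <- function(J, p, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(stats::rbinom(J * p, 2, 0.3), J, p)
    if (all(apply(m, 2, function(x) length(unique(x)) > 1))) break
  }
  dimnames(m) <- list(sprintf("L%02d", seq_len(J)),
                      sprintf("M%d", seq_len(p)))
  marker_matrix(m)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small simulated dataset reused by several files
small_sim <- function() cached("small_sim", {
  cfg <- synthetic_config(J = 40L, I = 2L, nT = 2L, p = 80L, seed = 7L)
  m <- simulate_markers(cfg)
  c(simulate_phenotypes(m, cfg), list(markers = m, cfg = cfg))
})
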