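# ---- phenotype tables -------------------------------------------------------

#' Construct a multi-trait phenotype table
#'
#' A phenotype table holds one record per (line, environment) combination with
#' one numeric column per trait.  Records are kept in the canonical order used
#' throughout the package: sorted first by environment and then by line, the
#' same ordering assumed by the design matrices and the sampler.
#'
#' @param df data frame with columns `line`, `env` and the trait columns.
#' @param traits character vector naming the trait columns of `df`.
#' @return A `pheno_table`: a data.frame with columns `line`, `env` and the
#'   traits, sorted by (env, line), with attribute `traits`.
#' @export
pheno_table <- function(df, traits) {
  stopifnot(is.data.frame(df))
  if (!all(c("line", "env") %in% names(df)))
    stop("phenotype table must have 'line' and 'env' columns", call. = FALSE)
  missing_tr <- setdiff(traits, names(df))
  if (length(missing_tr))
    stop("missing trait column(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  if (length(traits) < 1L) stop("at least one trait is required", call. = FALSE)
  df <- df[, c("line", "env", traits), drop = FALSE]
  df$line <- as.character(df$line)
  df$env <- as.character(df$env)
  for (tr in traits) df[[tr]] <- as.numeric(df[[tr]])
  if (nrow(df) == 0L) stop("phenotype table has no records", call. = FALSE)
  key <- paste(df$env, df$line, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (line, env) record(s): ",
         paste(unique(paste(df$line, df$env, sep = "/")[duplicated(key)]),
               collapse = ", "), call. = FALSE)
  all_na <- rowSums(!is.na(as.matrix(df[, traits, drop = FALSE]))) == 0L
  if (any(all_na))
    stop(sum(all_na), " record(s) have no observed trait value", call. = FALSE)
  df <- df[order(df$env, df$line), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, traits = traits, class = c("pheno_table", "data.frame"))
}

#' @export
print.pheno_table <- function(x, ...) {
  cat(sprintf("pheno_table: %d records, %d lines, %d environments, %d trait(s) [%s]\n",
              nrow(x), length(unique(x$line)), length(unique(x$env)),
              length(attr(x, "traits")), paste(attr(x, "traits"), collapse = ", ")))
  NextMethod()
}

#' Trait names of a phenotype table
#' @param pheno a `pheno_table`.
#' @return character vector of trait column names.
#' @export
trait_names <- function(pheno) attr(pheno, "traits")

#' Read a long-format phenotype CSV
#'
#' The file must be comma-delimited with a header containing `line`, `env`
#' and the named trait columns.  Missing trait values (empty cells or `NA`)
#' are allowed and carried through; records with every trait missing are
#' rejected, as are duplicated (line, env) pairs.
#'
#' @param path CSV file path.
#' @param trait_columns names of the trait columns to read.
#' @return a [pheno_table()].
#' @export
read_phenotypes <- function(path, trait_columns) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse phenotype CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("phenotype CSV '", path, "' is empty", call. = FALSE)
  pheno_table(df, trait_columns)
}

#' Write a phenotype table as CSV
#' @param pheno a `pheno_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- marker matrices --------------------------------------------------------

#' Validate a line-by-marker genotype matrix
#'
#' Markers are coded as allele-dosage integers: 0/1/2 for biallelic SNP
#' panels, or 0/1 for presence/absence panels.  No missing entries are
#' allowed (inputs are assumed post-QC and imputed).
#'
#' @param codes numeric matrix, lines in rows (rownames are line ids).
#' @return the validated matrix (storage mode numeric, class `marker_matrix`).
#' @export
marker_matrix <- function(codes) {
  codes <- as.matrix(codes)
  if (nrow(codes) < 2L) stop("need at least 2 lines", call. = FALSE)
  if (ncol(codes) < 1L) stop("need at least 1 marker", call. = FALSE)
  if (is.null(rownames(codes)) || anyDuplicated(rownames(codes)))
    stop("marker matrix needs unique line ids as rownames", call. = FALSE)
  if (anyNA(codes)) stop("marker matrix contains missing entries", call. = FALSE)
  if (!all(codes %in% c(0, 1, 2)))
    stop("marker codes must be 0, 1 or 2", call. = FALSE)
  storage.mode(codes) <- "double"
  class(codes) <- c("marker_matrix", class(matrix()))
  codes
}

#' Read a marker CSV
#'
#' First column: line ids; remaining columns: integer codes in {0, 1, 2}.
#'
#' @param path CSV file path.
#' @return a [marker_matrix()].
#' @export
read_markers <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse marker CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("marker CSV '", path, "' is empty or has no marker columns",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated line id(s) in marker CSV: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m) || !all(m %in% c(0, 1, 2)))
    stop("marker codes must be integers in {0, 1, 2}", call. = FALSE)
  rownames(m) <- ids
  marker_matrix(m)
}

#' Write a marker matrix as CSV
#' @param markers a `marker_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  df <- data.frame(line = rownames(markers),
                   as.data.frame(unclass(markers)[, , drop = FALSE]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that every phenotyped line has marker data
#'
#' Line ids are matched by exact string equality.  Marker-only lines are
#' allowed (they can still be predicted); phenotype lines without markers are
#' an error.
#'
#' @param pheno a `pheno_table`.
#' @param markers a `marker_matrix`.
#' @return invisibly, the vector of phenotyped line ids.
#' @export
check_line_match <- function(pheno, markers) {
  lines <- unique(pheno$line)
  absent <- setdiff(lines, rownames(markers))
  if (length(absent))
    stop("phenotyped line(s) without marker data: ",
         paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) ", ...", call. = FALSE)
  invisible(lines)
}

# ---- design matrices --------------------------------------------------------

#' Build incidence (design) matrices from a phenotype table
#'
#' Returns the environment incidence `X_E` (n x I), the line incidence `Z_L`
#' (n x J) and the interaction incidence `Z_EL` (n x J*I).  `Z_EL` columns
#' are ordered environment-major over line: column (e - 1) * J + j is the
#' (environment e, line j) combination.  Every row of each matrix has exactly
#' one 1.
#'
#' @param pheno a `pheno_table` (canonical (env, line) row order).
#' @return list with elements `X_E`, `Z_L`, `Z_EL`, `envs`, `lines`.
#' @export
build_design <- function(pheno) {
  envs <- sort(unique(pheno$env))
  lines <- sort(unique(pheno$line))
  n <- nrow(pheno); I <- length(envs); J <- length(lines)
  ei <- match(pheno$env, envs)
  li <- match(pheno$line, lines)
  X_E <- matrix(0, n, I, dimnames = list(NULL, envs))
  X_E[cbind(seq_len(n), ei)] <- 1
  Z_L <- matrix(0, n, J, dimnames = list(NULL, lines))
  Z_L[cbind(seq_len(n), li)] <- 1
  Z_EL <- matrix(0, n, J * I)
  colnames(Z_EL) <- as.vector(outer(lines, envs, function(l, e)
    paste(e, l, sep = ":")))
  Z_EL[cbind(seq_len(n), (ei - 1L) * J + li)] <- 1
  structure(list(X_E = X_E, Z_L = Z_L, Z_EL = Z_EL,
                 envs = envs, lines = lines),
            class = "design_matrices")
}
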