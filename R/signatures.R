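## Signature matrices and exposure assignment.

#' Read a signature definition matrix
#'
#' TSV with a class-label column (96 rows, labels as in
#' [context_classes_96()]) and one column per signature.  Rows are
#' reordered to the package's class ordering; each signature column is
#' checked to sum to 1 (within 1e-8) after optional renormalization.
#'
#' @param path Path to the TSV.
#' @param class_column Name of the class-label column; defaults to the
#'   first column.
#' @param renormalize Renormalize columns to sum exactly to 1
#'   (default TRUE, tolerant to rounded published matrices).
#' @return Matrix K signatures x 96 (signatures in rows).
#' @export
read_signature_matrix <- function(path, class_column = NULL, renormalize = TRUE) {
  d <- data.table::fread(path, sep = "\t", header = TRUE)
  if (is.null(class_column)) class_column <- names(d)[1]
  labels <- as.character(d[[class_column]])
  ord <- match(context_classes_96(), labels)
  if (anyNA(ord))
    stop("signature matrix misses ", sum(is.na(ord)), " of the 96 class labels")
  signames <- setdiff(names(d), class_column)
  S <- t(as.matrix(d[, signames, with = FALSE])[ord, , drop = FALSE])
  rownames(S) <- signames
  colnames(S) <- context_classes_96()
  validate_signature_matrix(S, renormalize = renormalize)
}

#' Validate (and optionally renormalize) a signature matrix
#'
#' @param S Matrix K x 96, rows = signatures, non-negative.
#' @param renormalize Rescale rows to sum to 1.
#' @return The validated matrix.
#' @export
validate_signature_matrix <- function(S, renormalize = FALSE) {
  if (ncol(S) != 96L) stop("signature matrix must have 96 columns")
  if (any(S < 0)) stop("signature matrix has negative entries")
  rs <- rowSums(S)
  if (any(rs <= 0)) stop("signature matrix has an all-zero row")
  if (renormalize) S <- S / rs
  else if (any(abs(rs - 1) > 1e-8))
    stop("signature rows must sum to 1 within 1e-8 (use renormalize = TRUE)")
  S
}

#' Write a signature matrix as TSV
#'
#' @param S Matrix K x 96.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_signature_matrix <- function(S, path) {
  d <- data.table::data.table(class = context_classes_96())
  for (k in rownames(S)) d[[k]] <- as.numeric(S[k, ])
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Generate a synthetic signature set
#'
#' Random peaked probability distributions over the 96 classes, built
#' from a sparse Dirichlet so that signatures concentrate on a small
#' number of context classes (as real single-base-substitution signatures
#' do).  Used by the cohort simulator and the test fixtures.
#'
#' @param k Number of signatures.
#' @param n_peaks Approximate number of dominant classes per signature.
#' @param concentration Dirichlet concentration of the off-peak mass.
#' @param seed Integer seed (mandatory, for reproducibility).
#' @return Matrix `k` x 96 with rows summing to 1, named `SigS1`..`SigSk`.
#' @export
make_synthetic_signatures <- function(k = 5, n_peaks = 4, concentration = 0.05,
                                      seed) {
  stopifnot(!missing(seed))
  with_seed(seed, {
    S <- matrix(0, k, 96L, dimnames = list(paste0("SigS", seq_len(k)),
                                           context_classes_96()))
    for (i in seq_len(k)) {
      alpha <- rep(concentration, 96L)
      alpha[sample.int(96L, n_peaks)] <- 5
      S[i, ] <- rdirichlet(1, alpha)
    }
    S
  })
}

#' Estimate signature exposures by non-negative least squares
#'
#' For each tumor's 96-class count vector c, solves
#' `min || c - e' S ||_2  subject to  e >= 0` (a quadratic program solved
#' by active-set NNLS) and row-normalizes the solution to proportions.
#' Tumors with zero classifiable mutations get all-zero rows.
#'
#' @param catalog Matrix tumors x 96 (see [build_catalog()]).
#' @param signatures Matrix K x 96 with rows summing to 1.
#' @return Matrix tumors x K of normalized exposures (rows sum to 1, or
#'   to 0 for zero-mutation tumors); attribute `normalized` is TRUE.
#' @export
fit_exposures <- function(catalog, signatures) {
  signatures <- validate_signature_matrix(signatures)
  if (ncol(catalog) != 96L)
    stop("catalog must have 96 columns in the package class ordering")
  cm <- attr(catalog, "context_mode")
  A <- t(signatures)                      # 96 x K
  if (qr(A)$rank < ncol(A))
    warning("signature matrix is rank deficient; exposures resolved by the ",
            "solver's minimum-norm convention")
  E <- matrix(0, nrow(catalog), nrow(signatures),
              dimnames = list(rownames(catalog), rownames(signatures)))
  for (i in seq_len(nrow(catalog))) {
    ci <- as.numeric(catalog[i, ])
    if (sum(ci) == 0) next
    e <- pracma::lsqnonneg(A, ci)$x
    s <- sum(e)
    if (s > 0) E[i, ] <- e / s
  }
  attr(E, "normalized") <- TRUE
  attr(E, "context_mode") <- cm
  E
}

#' Signature positivity calls
#'
#' A tumor is called positive for a signature when its normalized
#' exposure strictly exceeds `threshold` (default 0.05, i.e. "more than
#' 5\%" of mutations attributed).
#'
#' @param exposures Normalized exposure matrix (tumors x K).
#' @param threshold Positivity cutoff, default 0.05.
#' @return Logical matrix of the same shape.
#' @export
positivity <- function(exposures, threshold = 0.05) {
  exposures > threshold
}

#' Write / read exposure matrices as TSV
#'
#' @param E Exposure matrix (tumors x K).
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_exposures <- function(E, path) {
  d <- data.table::data.table(tumor_id = rownames(E))
  for (k in colnames(E)) d[[k]] <- as.numeric(E[, k])
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_exposures
#' @export
read_exposures <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE)
  E <- as.matrix(d[, -1])
  rownames(E) <- as.character(d[[1]])
  attr(E, "normalized") <- all(abs(rowSums(E) - 1) < 1e-6 | rowSums(E) == 0)
  E
}

## Dirichlet sampler (gamma construction).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

## Evaluate an expression under a temporary RNG seed, restoring the
## caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
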