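#' Orthogonality of one left basis vector to the rest of its factorization
#'
#' For each dataset i, returns max over l != k of |t(u_{i,k}) u_{i,l}|.
#' When lambda_k = 1 exactly this residual vanishes: the left basis vector of
#' a common genelet is orthogonal to every other left basis vector of its
#' dataset.  For lambda_k > 1 the value is reported as a diagnostic only.
#'
#' @param factors a `hogsvd_factors` object.
#' @param k column index.
#' @return named numeric vector, one residual per dataset.
#' @export
orthogonality_check <- function(factors, k) {
  stopifnot(inherits(factors, "hogsvd_factors"))
  n <- ncol(factors$V)
  if (!(k %in% seq_len(n))) stop("k must be in 1..", n)
  res <- vapply(factors$U, function(u) {
    inner <- abs(crossprod(u[, k], u)[1L, ])
    max(inner[-k])
  }, numeric(1L))
  names(res) <- vapply(factors$datasets, function(d) d$name, character(1L))
  res
}

#' Identify the common subspace of a decomposition
#'
#' The common subspace is spanned by the right basis vectors whose
#' eigenvalues satisfy lambda_k <= 1 + epsilon.  For exact arithmetic the
#' theory gives lambda_k = 1; on real data the eigenvalues are only
#' approximately 1 and the threshold is a modelling choice.  The default
#' `epsilon = 1` (i.e. lambda <= 2) reproduces the five-genelet subspace of
#' the three-organism cell-cycle comparison; `epsilon = 1e-6` is appropriate
#' for exact-theory checks on synthetic data.
#'
#' Alongside the epsilon rule, the largest-gap partition of the inverse
#' eigenvalues 1/lambda is always reported: the indices on the near-1 side of
#' the biggest jump in sorted 1/lambda, a threshold-free diagnostic.
#'
#' @param factors a `hogsvd_factors` object.
#' @param epsilon nonnegative slack on the eigenvalue criterion.
#' @return object of class `hogsvd_common_subspace`: list with `indices`
#'   (the set K), `lambda_threshold` (= 1 + epsilon), `lambdas` (of K),
#'   `ratio_matrix` (list over K of pairwise sigma-ratio matrices),
#'   `orthogonality_residuals` (|K| x N matrix), `gap_indices`
#'   (largest-gap alternative), `epsilon`, `n`.
#' @export
common_subspace <- function(factors, epsilon = 1) {
  stopifnot(inherits(factors, "hogsvd_factors"))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    stop("'epsilon' must be a single nonnegative number")
  }
  lam <- factors$lambdas
  n <- length(lam)
  k_set <- which(lam <= 1 + epsilon)

  ratio <- lapply(k_set, function(k) significance_ratios(factors, k))
  names(ratio) <- as.character(k_set)
  orth <- t(vapply(k_set, function(k) orthogonality_check(factors, k),
                   numeric(length(factors$U))))
  if (length(k_set)) {
    rownames(orth) <- as.character(k_set)
  }

  # largest-gap partition of 1/lambda: lambda is descending so 1/lambda is
  # ascending towards 1; the common side sits above the biggest jump
  inv <- 1 / lam
  gap_indices <- integer(0L)
  if (n >= 2L) {
    jumps <- diff(inv)
    cut <- which.max(jumps)
    gap_indices <- seq.int(cut + 1L, n)
  }

  structure(
    list(indices = k_set,
         lambda_threshold = 1 + epsilon,
         lambdas = lam[k_set],
         ratio_matrix = ratio,
         orthogonality_residuals = orth,
         gap_indices = gap_indices,
         epsilon = epsilon,
         n = n),
    class = "hogsvd_common_subspace"
  )
}

#' @export
print.hogsvd_common_subspace <- function(x, ...) {
  cat("<hogsvd_common_subspace> ", length(x$indices), " of ", x$n,
      " right basis vectors at lambda <= ", format(x$lambda_threshold),
      "\n", sep = "")
  if (length(x$indices)) {
    cat("  indices:", paste(x$indices, collapse = ", "), "\n")
    cat("  lambdas:", paste(format(x$lambdas, digits = 6), collapse = ", "),
        "\n")
  } else {
    cat("  no common indices at this epsilon\n")
  }
  cat("  largest-gap alternative:", paste(x$gap_indices, collapse = ", "),
      "\n")
  invisible(x)
}
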