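#' Gram matrices of a dataset list
#'
#' Computes A_i = t(D_i) %*% D_i for every dataset.  With full column rank
#' each A_i is symmetric positive definite; the product is symmetrized as
#' (M + t(M))/2 to remove floating-point asymmetry.
#'
#' @param datasets list of [expression_dataset()] objects sharing n columns.
#' @param rank_rtol relative tolerance of the per-dataset rank check.
#' @return list of n x n symmetric positive-definite matrices.
#' @export
gram_matrices <- function(datasets, rank_rtol = 1e-12) {
  datasets <- check_dataset_list(datasets)
  lapply(datasets, function(d) {
    sv <- svd(d$values, nu = 0L, nv = 0L)$d
    if (sv[length(sv)] <= rank_rtol * sv[1L]) {
      stop("rank deficiency in dataset '", d$name,
           "': cannot form a positive-definite Gram matrix")
    }
    a <- crossprod(d$values)
    (a + t(a)) / 2
  })
}

#' Arithmetic mean of pairwise Gram-matrix quotients
#'
#' Given Gram matrices A_1..A_N, forms
#' S = (1/(N(N-1))) * sum_{i<j} (A_i A_j^-1 + A_j A_i^-1),
#' the balanced mean of all pairwise quotients whose eigensystem defines the
#' shared right basis of the decomposition.  Each quotient is computed by a
#' linear solve, never by explicit inversion, and the result is invariant
#' under permutation of the input list.
#'
#' This direct form is retained as a cross-check; the numerically preferred
#' route to the same eigensystem is [stable_eigensystem()].
#'
#' @param grams list of N >= 2 symmetric positive-definite matrices of equal
#'   size (as from [gram_matrices()]).
#' @return the n x n real (generally nonsymmetric) matrix S.
#' @export
quotient_mean_direct <- function(grams) {
  if (!is.list(grams) || length(grams) < 2L) {
    stop("need at least 2 Gram matrices")
  }
  n <- nrow(grams[[1L]])
  if (!all(vapply(grams, function(a) all(dim(a) == n), logical(1L)))) {
    stop("all Gram matrices must be square and of equal size")
  }
  N <- length(grams)
  s <- matrix(0, n, n)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      # A_i A_j^-1 = t(solve(A_j, A_i)) since the A's are symmetric
      q <- tryCatch(t(solve(grams[[j]], grams[[i]])),
                    error = function(e) {
                      stop("singular Gram matrix at position ", j,
                           ": ", conditionMessage(e), call. = FALSE)
                    })
      s <- s + q
    }
  }
  s / (N * (N - 1))
}
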