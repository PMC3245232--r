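#' Generalized SVD of two matrices via the quotient-mean construction
#'
#' Runs the joint decomposition at N = 2, where it coincides algebraically
#' with the classical generalized singular value decomposition: the
#' eigenvalues of A_1 A_2^-1 are the squared generalized singular value
#' ratios rho = (sigma_1/sigma_2)^2, and the quotient-mean eigenvalues are
#' lambda = (rho + 1/rho)/2 componentwise.
#'
#' @param d1,d2 [expression_dataset()] objects of full column rank sharing n
#'   columns.
#' @param ... passed to [hogsvd()].
#' @return a `hogsvd_factors` object with two datasets.
#' @export
gsvd_pair <- function(d1, d2, ...) {
  hogsvd(list(d1, d2), ...)
}

#' Common-subspace identification through all pairwise factorizations
#'
#' Every right basis vector of the common subspace is a generalized singular
#' vector of each pairwise factorization with equal generalized singular
#' values in the pair.  This routine computes all N(N-1)/2 pairwise
#' factorizations and flags the right basis vectors of the joint
#' decomposition that, in every pair, lie (up to `span_tol`) in the span of
#' the pair's columns whose sigma ratio is within `tol` of 1.
#'
#' This pairwise route is the numerically stable one: each pair can be
#' factored stably even when the joint eigenproblem is badly conditioned.
#'
#' @param datasets list of [expression_dataset()] objects, N >= 2.
#' @param tol tolerance on |sigma_{i,k}/sigma_{j,k} - 1| within a pair.
#' @param span_tol tolerance on the residual of projecting a candidate right
#'   basis vector onto a pair's equal-ratio span.
#' @return list with `flagged` (indices into the joint decomposition's
#'   columns), `factors` (the joint `hogsvd_factors`), and `pair_table`
#'   (data.frame: pair, column, sigma ratio, lambda).
#' @export
pairwise_common_subspace <- function(datasets, tol = 1e-6, span_tol = NULL) {
  datasets <- check_dataset_list(datasets)
  if (is.null(span_tol)) span_tol <- sqrt(tol)
  factors <- hogsvd(datasets)
  n <- ncol(factors$V)
  N <- length(datasets)
  flagged <- rep(TRUE, n)
  rows <- list()

  for (i in seq_len(N - 1L)) {
    for (j in seq.int(i + 1L, N)) {
      pf <- tryCatch(gsvd_pair(datasets[[i]], datasets[[j]]),
                     error = function(e) {
                       stop("pairwise factorization of datasets ", i, " ('",
                            datasets[[i]]$name, "') and ", j, " ('",
                            datasets[[j]]$name, "') failed: ",
                            conditionMessage(e), call. = FALSE)
                     })
      ratio <- pf$sigma[[1L]] / pf$sigma[[2L]]
      rows[[length(rows) + 1L]] <- data.frame(
        pair = sprintf("%d:%d", i, j),
        column = seq_len(n),
        sigma_ratio = ratio,
        lambda = pf$lambdas
      )
      eq <- which(abs(ratio - 1) <= tol)
      if (!length(eq)) {
        flagged[] <- FALSE
        next
      }
      # orthonormal basis of the pair's equal-ratio span
      basis <- qr.Q(qr(pf$V[, eq, drop = FALSE]))
      proj <- crossprod(basis, factors$V)          # |eq| x n
      resid <- sqrt(pmax(0, 1 - colSums(proj^2)))  # V columns are unit norm
      flagged <- flagged & (resid <= span_tol)
    }
  }

  list(flagged = which(flagged),
       factors = factors,
       pair_table = do.call(rbind, rows))
}
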