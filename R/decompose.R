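#' Eigensystem of the quotient mean via the real-symmetric route
#'
#' Computes the eigenvectors and eigenvalues of the pairwise-quotient mean S
#' without ever forming S itself, guaranteeing a real eigensystem in floating
#' point.  Writing A = sum_i A_i, the thin SVD of the row-wise stacked data
#' matrix gives A = Q Shat^2 t(Q).  The product-form matrix
#' T = (sum_i A_i)(sum_j A_j^-1) is then similar to the symmetric
#' positive-definite
#'   Shat_sym = sum_j (Shat t(Q)) A_j^-1 (Q Shat),
#' whose eigensystem is real with orthogonal eigenvectors Vhat.  Mapping back,
#' V_raw = Q Shat Vhat are eigenvectors of T, and since
#' S = (T - N I)/(N(N-1)), the eigenvalues of S are
#' lambda = (lambdahat - N)/(N(N-1)).
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param rank_rtol relative tolerance below which the stacked matrix is
#'   declared rank deficient.
#' @return list with `V_raw` (n x n eigenvector matrix, columns ordered by
#'   descending `lambdas`), `lambdas` (eigenvalues of S, descending), and
#'   `gram_system` (list with `grams`, `stacked_right` = list(Q, d),
#'   `symmetric_mean`).
#' @export
stable_eigensystem <- function(datasets, rank_rtol = 1e-12) {
  datasets <- check_dataset_list(datasets)
  N <- length(datasets)
  grams <- gram_matrices(datasets, rank_rtol = rank_rtol)
  n <- ncol(datasets[[1L]]$values)

  stacked <- do.call(rbind, lapply(datasets, function(d) d$values))
  sv <- svd(stacked, nu = 0L, nv = n)
  d_hat <- sv$d[seq_len(n)]
  if (d_hat[n] <= rank_rtol * d_hat[1L]) {
    stop("stacked matrix rank deficient: singular value ", format(d_hat[n]),
         " below ", format(rank_rtol), " * ", format(d_hat[1L]))
  }
  q <- sv$v                               # n x n orthogonal
  w <- q %*% (d_hat * diag(n))            # Q Shat

  s_hat <- matrix(0, n, n)
  for (a in grams) {
    s_hat <- s_hat + crossprod(w, solve(a, w))
  }
  s_hat <- (s_hat + t(s_hat)) / 2

  es <- eigen(s_hat, symmetric = TRUE)    # descending eigenvalues
  v_raw <- w %*% es$vectors
  lambdas <- (es$values - N) / (N * (N - 1))

  list(
    V_raw = v_raw,
    lambdas = lambdas,
    gram_system = list(
      grams = grams,
      stacked_right = list(Q = q, d = d_hat),
      symmetric_mean = s_hat
    )
  )
}

#' Normalize eigenvector columns into right basis vectors
#'
#' Scales each column to unit Euclidean norm and fixes its sign so that the
#' entry of largest magnitude is positive (ties broken by the earliest index),
#' making the output deterministic.
#'
#' @param V_raw square matrix of (unnormalized) eigenvectors.
#' @return matrix of unit-norm, sign-fixed columns.
#' @export
right_basis <- function(V_raw) {
  V_raw <- as.matrix(V_raw)
  apply(V_raw, 2L, function(col) {
    nrm <- sqrt(sum(col^2))
    if (nrm == 0) stop("degenerate eigenvector: zero column")
    col <- col / nrm
    piv <- which.max(abs(col))
    if (col[piv] < 0) col <- -col
    col
  })
}

#' Solve the left linear systems
#'
#' Given the shared right basis V, recovers B_i such that
#' D_i = B_i t(V), by a backward-stable solve of V X = t(D_i) for X = t(B_i)
#' (no explicit inverse of V is formed).
#'
#' @param dataset an [expression_dataset()].
#' @param V n x n nonsingular right basis matrix.
#' @param cond_warn condition-number threshold above which a warning is
#'   emitted (the solve still proceeds).
#' @return the m_i x n matrix B_i.
#' @export
left_systems_solve <- function(dataset, V, cond_warn = 1e12) {
  stopifnot(inherits(dataset, "expression_dataset"))
  V <- as.matrix(V)
  n <- ncol(dataset$values)
  if (!all(dim(V) == n)) stop("V must be ", n, " x ", n)
  sv <- svd(V, nu = 0L, nv = 0L)$d
  if (sv[n] <= 0 || !is.finite(sv[1L] / sv[n])) {
    stop("V not invertible")
  }
  kappa <- sv[1L] / sv[n]
  if (kappa > cond_warn) {
    warning("right basis V is ill-conditioned (condition number ",
            format(kappa, digits = 3), "); left systems may be inaccurate")
  }
  b <- tryCatch(t(solve(V, t(dataset$values))),
                error = function(e) stop("V not invertible: ",
                                         conditionMessage(e), call. = FALSE))
  dimnames(b) <- list(dataset$feature_ids, NULL)
  b
}

#' Split a solved left system into unit basis vectors and singular values
#'
#' Factors B_i = U_i diag(sigma_i) with each column of U_i of unit Euclidean
#' norm and sigma_i the column norms (the higher-order generalized singular
#' values of the dataset, all strictly positive for full-rank input).
#'
#' @param B_i matrix from [left_systems_solve()].
#' @return list with `U` (unit-column matrix) and `sigma` (positive vector).
#' @export
normalize_columns <- function(B_i) {
  B_i <- as.matrix(B_i)
  sigma <- sqrt(colSums(B_i^2))
  if (any(sigma == 0)) {
    stop("zero higher-order generalized singular value: column ",
         which(sigma == 0)[1L], " of the left system is zero")
  }
  u <- sweep(B_i, 2L, sigma, "/")
  list(U = u, sigma = sigma)
}

#' Higher-order generalized singular value decomposition
#'
#' Factors each of N >= 2 full-column-rank matrices D_i (m_i x n, shared
#' column dimension) exactly as D_i = U_i diag(sigma_i) t(V), with the right
#' basis V identical in all factorizations.  V is obtained from the
#' eigensystem of the arithmetic mean S of all pairwise Gram-matrix quotients
#' A_i A_j^-1; its eigenvalues satisfy lambda_k >= 1, and lambda_k = 1 exactly
#' when genelet k carries equal significance (sigma_{i,k}/sigma_{j,k} = 1) in
#' every pair of datasets, with the matching left vectors orthogonal to all
#' others in their factorization.
#'
#' Columns are ordered by descending lambda, so the common subspace (lambda
#' near 1) occupies the trailing positions.  Column signs follow the
#' deterministic convention of [right_basis()], with U column signs then
#' forced by the exactness of the factorization.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param route `"stable"` (default; real-symmetric eigensolve via the
#'   stacked SVD) or `"direct"` (dense nonsymmetric eigensolve of S itself,
#'   retained for cross-checks).
#' @param rank_rtol relative rank-check tolerance.
#' @param cond_warn condition-number warning threshold for V.
#' @return object of class `hogsvd_factors`: list with `V` (n x n, unit
#'   columns), `lambdas` (descending), `U` (list of m_i x n unit-column
#'   matrices), `sigma` (list of length-n positive vectors), `B` (list of
#'   unnormalized left systems), `datasets` (the inputs), `options`.
#' @examples
#' sim <- planted_instance(N = 3, n = 4, sizes = c(10, 12, 9),
#'                         common_count = 1, seed = 1)
#' f <- hogsvd(sim$datasets)
#' round(f$lambdas, 4)
#' @export
hogsvd <- function(datasets, route = c("stable", "direct"),
                   rank_rtol = 1e-12, cond_warn = 1e12) {
  route <- match.arg(route)
  datasets <- check_dataset_list(datasets)

  if (route == "stable") {
    es <- stable_eigensystem(datasets, rank_rtol = rank_rtol)
    v_raw <- es$V_raw
    lambdas <- es$lambdas
  } else {
    grams <- gram_matrices(datasets, rank_rtol = rank_rtol)
    s <- quotient_mean_direct(grams)
    ev <- eigen(s)
    if (max(abs(Im(ev$values))) > 1e-8 * max(abs(Re(ev$values)))) {
      warning("direct eigensolve returned complex parts; taking real part")
    }
    ord <- order(Re(ev$values), decreasing = TRUE)
    lambdas <- Re(ev$values)[ord]
    v_raw <- Re(ev$vectors)[, ord, drop = FALSE]
  }

  v <- right_basis(v_raw)
  bs <- lapply(datasets, left_systems_solve, V = v, cond_warn = cond_warn)
  norms <- lapply(bs, normalize_columns)

  structure(
    list(
      V = v,
      lambdas = lambdas,
      U = lapply(norms, `[[`, "U"),
      sigma = lapply(norms, `[[`, "sigma"),
      B = bs,
      datasets = datasets,
      options = list(route = route, rank_rtol = rank_rtol,
                     cond_warn = cond_warn)
    ),
    class = "hogsvd_factors"
  )
}

#' @export
print.hogsvd_factors <- function(x, ...) {
  n <- ncol(x$V)
  nms <- vapply(x$datasets, function(d) d$name, character(1L))
  cat("<hogsvd_factors> N =", length(x$U), "datasets (",
      paste(nms, collapse = ", "), "), n =", n, "\n")
  cat("  lambda range: [", format(min(x$lambdas), digits = 6), ", ",
      format(max(x$lambdas), digits = 6), "]\n", sep = "")
  cat("  lambda <= 2 for", sum(x$lambdas <= 2), "of", n, "right basis vectors\n")
  invisible(x)
}

#' Pairwise significance ratios of one right basis vector
#'
#' Entry (i, j) is sigma_{i,k} / sigma_{j,k}: the significance of genelet k in
#' dataset i relative to dataset j.  The diagonal is 1 and the matrix is
#' reciprocal-symmetric.
#'
#' @param factors a `hogsvd_factors` object.
#' @param k column index (1-based, in descending-lambda order).
#' @return N x N positive matrix with dataset names on both dimensions.
#' @export
significance_ratios <- function(factors, k) {
  stopifnot(inherits(factors, "hogsvd_factors"))
  n <- ncol(factors$V)
  if (!(k %in% seq_len(n))) stop("k must be in 1..", n)
  sig <- vapply(factors$sigma, `[`, numeric(1L), k)
  r <- outer(sig, sig, "/")
  nms <- vapply(factors$datasets, function(d) d$name, character(1L))
  dimnames(r) <- list(nms, nms)
  r
}
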