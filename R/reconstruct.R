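#' Reconstruct one dataset inside a subspace of right basis vectors
#'
#' Returns sum over k in K of u_{i,k} sigma_{i,k} t(v_k): the rank-|K|
#' reconstruction of dataset i from the selected genelets.  Reconstruction in
#' the common subspace keeps the expression variation shared by all datasets
#' and removes dataset-exclusive patterns such as experimental artifacts and
#' batch effects; with K = all columns the full matrix D_i is recovered.
#'
#' @param i dataset index into `factors$datasets`.
#' @param factors a `hogsvd_factors` object.
#' @param K nonempty integer vector of column indices (e.g.
#'   `common_subspace(factors)$indices`).
#' @return reconstructed m_i x n matrix with feature ids as row names.
#' @export
reconstruct_in_subspace <- function(i, factors, K) {
  stopifnot(inherits(factors, "hogsvd_factors"))
  if (!(i %in% seq_along(factors$U))) stop("no dataset with index ", i)
  K <- as.integer(K)
  n <- ncol(factors$V)
  if (length(K) == 0L) stop("K must be a nonempty set of column indices")
  if (anyDuplicated(K) || any(K < 1L | K > n)) {
    stop("K must be distinct indices in 1..", n)
  }
  u <- factors$U[[i]][, K, drop = FALSE]
  sig <- factors$sigma[[i]][K]
  v <- factors$V[, K, drop = FALSE]
  rec <- u %*% (sig * t(v))
  rownames(rec) <- factors$datasets[[i]]$feature_ids
  rec
}
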