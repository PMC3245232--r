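# Shared fixtures and independent oracles for the test suite.

# generic full-column-rank Gaussian datasets (no planted structure)
rand_datasets <- function(N, n, sizes, seed) {
  set.seed(seed)
  sizes <- rep_len(sizes, N)
  lapply(seq_len(N), function(i) {
    expression_dataset(matrix(rnorm(sizes[i] * n), sizes[i], n),
                       name = sprintf("rand_%d", i))
  })
}

# independent eigensolve of the explicitly formed quotient mean
direct_lambda_oracle <- function(datasets) {
  grams <- lapply(datasets, function(d) crossprod(d$values))
  s <- quotient_mean_direct(grams)
  sort(Re(eigen(s, only.values = TRUE)$values), decreasing = TRUE)
}

# brute-force upper-tail hypergeometric probability by enumeration over
# binomial coefficients (independent of dhyper)
hyper_tail_bruteforce <- function(population, annotated, top, overlap) {
  xs <- seq.int(overlap, min(annotated, top))
  sum(choose(annotated, xs) * choose(population - annotated, top - xs)) /
    choose(population, top)
}

# Fisher-Lee circular correlation, optionally on circular ranks
circ_cor <- function(a, b, rank_based = TRUE) {
  stopifnot(length(a) == length(b))
  if (rank_based) {
    a <- 2 * pi * rank(a) / length(a)
    b <- 2 * pi * rank(b) / length(b)
  }
  sa <- outer(a, a, function(p, q) sin(p - q))
  sb <- outer(b, b, function(p, q) sin(p - q))
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

rel_frob <- function(x, y) norm(x - y, "F") / norm(y, "F")

# a unit vector spanning the null space of a (rows < cols) matrix
nullspace_vec <- function(m) {
  sv <- svd(m, nv = ncol(m))
  sv$v[, ncol(m)]
}

# reconstruction residuals of a factorization against its inputs
factorization_residuals <- function(factors) {
  vapply(seq_along(factors$U), function(i) {
    rec <- factors$U[[i]] %*% (factors$sigma[[i]] * t(factors$V))
    rel_frob(rec, factors$datasets[[i]]$values)
  }, numeric(1L))
}

# closed-form eigenvalues for instances with orthonormal-column U_i:
# lambda_k = (1/(N(N-1))) sum_{i<j} (rho_ijk + 1/rho_ijk),
# rho_ijk = sigma_ik^2 / sigma_jk^2
closed_form_lambdas <- function(sigma_list) {
  N <- length(sigma_list)
  n <- length(sigma_list[[1L]])
  lam <- numeric(n)
  for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N)) {
    rho <- (sigma_list[[i]] / sigma_list[[j]])^2
    lam <- lam + rho + 1 / rho
  }
  lam / (N * (N - 1))
}
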