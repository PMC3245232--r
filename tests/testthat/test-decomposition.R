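test_that("stable eigensystem matches diagonal closed form and dense oracle", {
  # D1'D1 = diag(4,1), D2'D2 = I: lambda = (17/8, 1), axes as eigenvectors
  d1 <- expression_dataset(diag(c(2, 1)), name = "a")
  d2 <- expression_dataset(diag(2), name = "b")
  es <- stable_eigensystem(list(d1, d2))
  expect_equal(es$lambdas, c(17 / 8, 1))
  v <- right_basis(es$V_raw)
  expect_equal(abs(v), diag(2), tolerance = 1e-12)

  # random full-rank triple vs dense nonsymmetric eigensolve of S
  datasets <- rand_datasets(3, 5, c(12, 18, 25), seed = 101)
  es <- stable_eigensystem(datasets)
  oracle <- direct_lambda_oracle(datasets)
  expect_lt(max(abs(es$lambdas - oracle)), 1e-8)

  # eigenvectors actually diagonalize the explicitly formed S
  s <- quotient_mean_direct(gram_matrices(datasets))
  resid <- s %*% es$V_raw - es$V_raw %*% diag(es$lambdas)
  expect_lt(max(abs(resid)), 1e-8 * max(abs(es$lambdas)))

  expect_true(all(diff(es$lambdas) <= 0))
  expect_true(isSymmetric(es$gram_system$symmetric_mean, tol = 1e-10))

  # rank-deficient stack
  flat <- expression_dataset(matrix(rnorm(20), 10, 2), name = "f")
  flat$values[, 2] <- flat$values[, 1] # degrade after construction checks
  expect_error(stable_eigensystem(list(flat, flat)), "rank deficien")
})

test_that("right_basis normalizes, fixes signs deterministically", {
  expect_equal(right_basis(matrix(c(3, 4), 2, 1)), matrix(c(0.6, 0.8), 2, 1))
  expect_equal(right_basis(matrix(c(0, -2), 2, 1)), matrix(c(0, 1), 2, 1))
  set.seed(1)
  v <- right_basis(matrix(rnorm(36), 6, 6))
  expect_equal(colSums(v^2), rep(1, 6), tolerance = 1e-12)
  picks <- apply(v, 2, function(col) col[which.max(abs(col))])
  expect_true(all(picks > 0))
  expect_error(right_basis(matrix(c(1, 0, 0, 0), 2, 2)),
               "degenerate eigenvector")
})

test_that("left systems solve reproduces D = B t(V) cases", {
  d <- rand_datasets(1, 4, 9, seed = 5)[[1]]
  expect_equal(left_systems_solve(d, diag(4)), d$values,
               ignore_attr = TRUE)
  perm <- diag(4)[, c(2, 4, 1, 3)]
  b <- left_systems_solve(d, perm)
  expect_equal(b %*% t(perm), d$values, ignore_attr = TRUE)

  set.seed(9)
  v <- right_basis(matrix(rnorm(16), 4, 4))
  b <- left_systems_solve(d, v)
  expect_lt(rel_frob(b %*% t(v), d$values), 1e-8)

  expect_error(left_systems_solve(d, matrix(0, 4, 4)), "not invertible")
  ill <- diag(c(1, 1, 1, 1e-14))
  expect_warning(left_systems_solve(d, ill), "ill-conditioned")
})

test_that("normalize_columns splits B into unit columns and norms", {
  b <- cbind(c(3, 4, 0), c(0, 0, 5))
  nc <- normalize_columns(b)
  expect_equal(nc$sigma, c(5, 5))
  expect_equal(colSums(nc$U^2), c(1, 1))
  expect_equal(nc$U %*% diag(nc$sigma), b)

  u0 <- qr.Q(qr(matrix(rnorm(12), 4, 3)))
  nc0 <- normalize_columns(u0)
  expect_equal(nc0$sigma, rep(1, 3))
  expect_equal(nc0$U, u0)

  set.seed(2)
  b <- matrix(rnorm(20), 5, 4)
  nc <- normalize_columns(b)
  expect_lt(max(abs(sweep(nc$U, 2, nc$sigma, "*") - b)), 1e-12)
  expect_error(normalize_columns(cbind(b, 0)), "zero higher-order")
})

test_that("full decomposition is exact, ordered, deterministic", {
  for (seed in 1:3) {
    datasets <- rand_datasets(3, 4, c(8, 15, 30), seed = seed)
    f <- hogsvd(datasets)
    expect_lt(max(factorization_residuals(f)), 1e-8)
    expect_true(all(diff(f$lambdas) <= 1e-12))
    expect_equal(colSums(f$V^2), rep(1, 4), tolerance = 1e-10)
    for (u in f$U) expect_equal(colSums(u^2), rep(1, 4), tolerance = 1e-10)
    for (s in f$sigma) expect_true(all(s > 0))
    # identical rerun is bit-identical (deterministic sign conventions)
    f2 <- hogsvd(datasets)
    expect_identical(f$V, f2$V)
  }
})

test_that("both eigen-routes agree and permuting datasets changes nothing", {
  datasets <- rand_datasets(3, 5, c(11, 14, 17), seed = 77)
  f_stable <- hogsvd(datasets)
  f_direct <- hogsvd(datasets, route = "direct")
  expect_lt(max(abs(f_stable$lambdas - f_direct$lambdas)), 1e-8)
  expect_lt(max(abs(abs(f_stable$V) - abs(f_direct$V))), 1e-6)

  f_perm <- hogsvd(datasets[c(2, 3, 1)])
  expect_lt(max(abs(f_stable$lambdas - f_perm$lambdas)), 1e-10)
  expect_lt(max(abs(f_stable$V - f_perm$V)), 1e-8)
})

test_that("scaling one dataset scales its sigmas and only its sigmas", {
  datasets <- rand_datasets(2, 4, c(10, 12), seed = 31)
  f <- hogsvd(datasets)
  scaled <- datasets
  scaled[[1]]$values <- 3 * scaled[[1]]$values
  fs <- hogsvd(scaled)
  # columns may reorder if lambda order changes; match by V columns
  match_cols <- apply(abs(crossprod(f$V, fs$V)), 1, which.max)
  expect_equal(fs$sigma[[1]][match_cols], 3 * f$sigma[[1]], tolerance = 1e-8)
  expect_equal(fs$sigma[[2]][match_cols], f$sigma[[2]], tolerance = 1e-8)
  expect_lt(max(abs(abs(fs$V[, match_cols]) - abs(f$V))), 1e-8)
  # lambdas follow the closed form on the sigma ratios for N = 2
  rho <- (fs$sigma[[1]] / fs$sigma[[2]])^2
  expect_equal(fs$lambdas, (rho + 1 / rho) / 2, tolerance = 1e-8)
})

test_that("significance ratios are reciprocal with unit diagonal", {
  sim <- planted_instance(N = 3, n = 4, sizes = c(9, 10, 11),
                          common_count = 2, seed = 13)
  f <- hogsvd(sim$datasets)
  for (k in 1:4) {
    r <- significance_ratios(f, k)
    expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
    expect_equal(r * t(r), matrix(1, 3, 3), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  # equal planted sigma -> all-ones ratio matrix at the common columns
  r_common <- significance_ratios(f, 4)
  expect_equal(r_common, matrix(1, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_error(significance_ratios(f, 9), "must be in")
})
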