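test_that("reconstruction with all columns is the identity map", {
  sim <- planted_instance(N = 3, n = 4, sizes = c(9, 11, 13),
                          common_count = 1, seed = 6)
  f <- hogsvd(sim$datasets)
  for (i in 1:3) {
    rec <- reconstruct_in_subspace(i, f, 1:4)
    expect_lt(rel_frob(rec, sim$datasets[[i]]$values), 1e-8)
  }
  expect_error(reconstruct_in_subspace(1, f, integer(0)), "nonempty")
  expect_error(reconstruct_in_subspace(1, f, c(1, 9)), "distinct indices")
  expect_error(reconstruct_in_subspace(7, f, 1:2), "no dataset")
  # partial reconstruction has rank |K|
  rec2 <- reconstruct_in_subspace(1, f, c(2, 4))
  expect_identical(qr(rec2)$rank, 2L)
})

test_that("approximating plane: orthonormal, correct span in the 2-D case", {
  sim <- planted_instance(N = 2, n = 5, sizes = c(10, 12), common_count = 2,
                          orthonormal_V = TRUE, seed = 14)
  f <- hogsvd(sim$datasets)
  k <- 4:5
  plane <- approximating_plane(f, k)
  b <- unclass(plane)
  expect_equal(crossprod(b), diag(2), tolerance = 1e-10)
  # |K| = 2 with orthonormal v_k: plane spans exactly {v_k} (projector match)
  vk <- f$V[, k]
  p_plane <- b %*% t(b)
  p_vk <- vk %*% solve(crossprod(vk), t(vk))
  expect_lt(norm(p_plane - p_vk, "F"), 1e-8)
  expect_error(approximating_plane(f, 3), ">= 2")
})

test_that("entity projections: containment, orthogonality, radii", {
  sim <- planted_instance(N = 2, n = 6, sizes = c(12, 15), common_count = 3,
                          orthonormal_V = TRUE, seed = 25)
  f <- hogsvd(sim$datasets)
  k <- 4:6
  plane <- approximating_plane(f, k)
  pg <- project_entities(f, k, plane, which = "genes", i = 1)
  pa <- project_entities(f, k, plane, which = "arrays", i = 1)
  expect_true(all(pg$r <= 1 + 1e-10))
  expect_true(all(pa$r <= 1 + 1e-10))
  expect_equal(pg$r, sqrt(pg$x^2 + pg$y^2), tolerance = 1e-12)
  expect_identical(nrow(pa), 6L)
  expect_error(project_entities(f, 4:5, plane, i = 1), "does not match")

  # hand-built factors make in-plane and orthogonal entities exact:
  # coefficient space is 3-dim; plane from two orthonormal genelets
  g <- f
  k2 <- attr(plane, "K")
  basis_g <- apply(crossprod(f$V[, k2], unclass(plane)), 2,
                   function(z) z / sqrt(sum(z^2)))
  # gene with coefficient vector inside the plane -> r = 1
  coef_in <- basis_g[, 1] + 0.5 * basis_g[, 2]
  # gene with coefficient vector orthogonal to the plane -> r = 0
  coef_out <- nullspace_vec(t(basis_g))
  u_rows <- rbind(coef_in / f$sigma[[1]][k2], coef_out / f$sigma[[1]][k2])
  g$U[[1]][1, k2] <- u_rows[1, ]
  g$U[[1]][2, k2] <- u_rows[2, ]
  pg2 <- project_entities(g, k2, plane, which = "genes", i = 1)
  expect_equal(pg2$r[1], 1, tolerance = 1e-10)
  expect_equal(pg2$r[2], 0, tolerance = 1e-10)
  expect_true(is.na(pg2$theta[2]))

  # radius invariant under positive rescaling of the coefficient vector
  g$U[[1]][1, k2] <- 7.3 * u_rows[1, ]
  pg3 <- project_entities(g, k2, plane, which = "genes", i = 1)
  expect_equal(pg3$r[1], pg2$r[1], tolerance = 1e-12)
})

test_that("added-up counting respects subsets and cutoffs", {
  sim <- planted_instance(N = 2, n = 5, sizes = c(20, 20), common_count = 2,
                          seed = 33)
  f <- hogsvd(sim$datasets)
  k <- 4:5
  plane <- approximating_plane(f, k)
  pg <- project_entities(f, k, plane, which = "genes", i = 1)
  # |K| = 2: the coefficient space IS the plane, so every entity is in-plane
  expect_equal(count_added_up(pg, cutoff = 0.5), nrow(pg))
  expect_equal(count_added_up(pg, cutoff = 0), sum(pg$r > 0))
  sub <- pg$id[1:5]
  expect_equal(count_added_up(pg, subset = sub, cutoff = 0), 5L)
  expect_error(count_added_up(pg, cutoff = 2), "0, 1")
})

test_that("angular classification: boundaries, ties, rotation equivariance", {
  sim <- planted_instance(N = 2, n = 5, sizes = c(30, 30), common_count = 2,
                          seed = 44)
  f <- hogsvd(sim$datasets)
  k <- 4:5
  plane <- approximating_plane(f, k)
  pg <- project_entities(f, k, plane, which = "genes", i = 1)

  halves <- c(first = pi / 2, second = 3 * pi / 2)
  lab <- classify_by_angle(pg, halves)
  # entity at theta = pi/2 goes to the interval starting there
  on_boundary <- pg
  on_boundary$theta[1] <- pi / 2
  lab_b <- classify_by_angle(on_boundary, halves)
  expect_identical(unname(lab_b[1]), "first")
  # angles below pi/2 wrap to the interval starting at 3pi/2
  expect_identical(unname(lab[pg$theta < pi / 2 & !is.na(pg$theta)][1]),
                   "second")

  # rotating boundaries and angles together leaves labels unchanged
  off <- 0.9
  rot <- pg
  rot$theta <- (rot$theta + off) %% (2 * pi)
  lab_rot <- classify_by_angle(rot, (halves + off) %% (2 * pi))
  expect_identical(lab_rot, lab)

  expect_error(classify_by_angle(pg, c(a = 0, b = 0)), "overlapping")
  expect_error(classify_by_angle(pg, c(0, pi)), "named")
})

test_that("planted gene phases are recovered from the projection angles", {
  cc <- cell_cycle_triple(seed = 2)
  f <- hogsvd(cc$datasets)
  cs <- common_subspace(f, epsilon = 0.1)
  expect_identical(length(cs$indices), 2L)
  plane <- approximating_plane(f, cs$indices)
  for (i in 1:3) {
    pg <- project_entities(f, cs$indices, plane, which = "genes", i = i)
    rho <- circ_cor(cc$truth$phases[[i]][pg$id], pg$theta)
    expect_gte(abs(rho), 0.9)
  }
  # labels from angular classification agree with planted labels up to the
  # rotation/reflection of the recovered plane: check via best alignment of
  # the two label sets (confusion-matrix maximum)
  pg <- project_entities(f, cs$indices, plane, which = "genes", i = 1)
  lab <- classify_by_angle(pg, synthetic_phase_boundaries())
  truth_lab <- cc$truth$phase_labels[[1]][pg$id]
  tab <- table(lab, truth_lab)
  # each recovered class maps predominantly onto one planted class
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.7)
})

test_that("array angular order tracks time, twice around the circle", {
  cc <- cell_cycle_triple(seed = 2)
  f <- hogsvd(cc$datasets)
  cs <- common_subspace(f, epsilon = 0.1)
  plane <- approximating_plane(f, cs$indices)
  for (i in 1:3) {
    pa <- project_entities(f, cs$indices, plane, which = "arrays", i = i)
    # unwrap recovered angles along time; increments should have constant
    # sign and total winding ~ 2 turns
    th <- pa$theta
    d <- diff(th)
    d <- (d + pi) %% (2 * pi) - pi   # wrap to (-pi, pi]
    expect_true(all(d > 0) || all(d < 0))
    expect_equal(abs(sum(d)) + 2 * pi / 17, 4 * pi, tolerance = 0.2)
    # arrays sit essentially on the unit circle
    expect_gte(min(pa$r), 0.95)
  }
})
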