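# Synthetic instances with known factorization structure.  All randomness
# flows from the single integer `seed` argument; the caller's RNG state is
# left untouched.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# QR-based orthonormal columns of a Gaussian draw
random_orthonormal <- function(m, n) {
  q <- qr.Q(qr(matrix(stats::rnorm(m * n), m, n)))
  # deterministic column signs
  for (k in seq_len(n)) {
    piv <- which.max(abs(q[, k]))
    if (q[piv, k] < 0) q[, k] <- -q[, k]
  }
  q
}

#' Planted-structure instance of the joint decomposition
#'
#' Draws datasets D_i = U_i diag(sigma_i) t(V) with known factors: each U_i
#' has orthonormal columns (QR of a Gaussian matrix), V has unit-norm columns
#' (orthonormal if requested), and `common_count` designated columns receive
#' identical sigma values in every dataset.  With orthonormal U_i, those
#' columns are right basis vectors of equal significance in all datasets, so
#' the decomposition recovers them with eigenvalue exactly 1; the remaining
#' columns draw independent sigma per dataset and give eigenvalues above 1.
#'
#' @param N number of datasets.
#' @param n shared column dimension.
#' @param sizes integer vector of row counts m_i (each >= n); recycled to
#'   length N.
#' @param common_count number of planted equal-significance columns
#'   (0 <= c <= n); they occupy the trailing planted positions.
#' @param orthonormal_U if `FALSE`, U_i columns are unit-norm but not
#'   orthogonal, producing generic instances without exact eigenvalue-1
#'   structure.
#' @param orthonormal_V orthonormalize V as well (default `FALSE`: generic
#'   unit columns).
#' @param seed integer seed; same seed, same instance.
#' @return list with `datasets` (list of [expression_dataset()]) and `truth`
#'   (class `synthetic_truth`): planted `V`, `sigma` (list), `common`
#'   (planted column indices), `seed`.
#' @export
planted_instance <- function(N, n, sizes, common_count = 1L,
                             orthonormal_U = TRUE, orthonormal_V = FALSE,
                             seed = 1L) {
  N <- as.integer(N); n <- as.integer(n)
  sizes <- rep_len(as.integer(sizes), N)
  common_count <- as.integer(common_count)
  if (N < 2L || n < 2L) stop("need N >= 2 and n >= 2")
  if (any(sizes < n)) stop("every m_i must be >= n")
  if (common_count < 0L || common_count > n) stop("need 0 <= common_count <= n")

  with_seed(seed, {
    v <- matrix(stats::rnorm(n * n), n, n)
    if (orthonormal_V) {
      v <- random_orthonormal(n, n)
    } else {
      v <- right_basis(v)
      # guard against an accidentally ill-conditioned draw
      while (kappa_of(v) > 1e6) {
        v <- right_basis(matrix(stats::rnorm(n * n), n, n))
      }
    }

    common <- if (common_count > 0L) seq.int(n - common_count + 1L, n) else integer(0L)
    shared_sigma <- exp(stats::runif(n, log(0.8), log(1.25)))
    sigma <- lapply(seq_len(N), function(i) {
      s <- exp(stats::runif(n, log(0.5), log(2)))
      s[common] <- shared_sigma[common]
      s
    })

    datasets <- lapply(seq_len(N), function(i) {
      u <- if (orthonormal_U) {
        random_orthonormal(sizes[i], n)
      } else {
        right_basis(matrix(stats::rnorm(sizes[i] * n), sizes[i], n))
      }
      d <- u %*% (sigma[[i]] * t(v))
      expression_dataset(d, name = sprintf("planted_%d", i))
    })

    truth <- structure(
      list(V = v, sigma = sigma, common = common,
           artifact_pattern = NULL, artifact_host = NA_integer_,
           phases = NULL, seed = as.integer(seed)),
      class = "synthetic_truth"
    )
    list(datasets = datasets, truth = truth)
  })
}

kappa_of <- function(m) {
  sv <- svd(m, nu = 0L, nv = 0L)$d
  sv[1L] / sv[length(sv)]
}

#' Synthetic three-dataset cell-cycle time courses
#'
#' Emulates the structure of a multi-organism cell-cycle expression
#' comparison: three datasets over the same `n_arrays` time points spanning
#' approximately two cell-cycle periods.  A shared cosine/sine pair of
#' two-period oscillatory right basis vectors carries equal significance in
#' all three datasets; each gene's loadings on the pair encode its cell-cycle
#' phase (binned into G1/S/G2/M annotation labels).  One dataset additionally
#' hosts an exponentially decaying pattern, emulating a synchronization-agent
#' response artifact that is nearly exclusive to that dataset; the remaining
#' basis vectors are random dataset-specific structure with deliberately
#' unequal significance.  Gaussian measurement noise is added entrywise.
#'
#' The planted basis is orthonormalized (the decay pattern is orthogonalized
#' against the oscillatory pair), so that with zero noise the oscillatory
#' eigenvalues equal 1 exactly and reconstruction in the common subspace is
#' exactly artifact-free.
#'
#' @param n_arrays number of time points (>= 8; default 17).
#' @param gene_counts integer vector of genes per dataset (recycled to 3).
#' @param noise_sd entrywise Gaussian noise standard deviation.
#' @param artifact_amplitude sigma of the decaying pattern in its host
#'   dataset (its sigma elsewhere is 0.05 to preserve full rank); 0 plants
#'   the pattern with equal tiny significance everywhere.
#' @param artifact_host index (1..3) of the dataset hosting the artifact.
#' @param osc_sigma shared sigma of each oscillatory basis vector; the
#'   default 10 makes a gene with amplitude parameter `a` oscillate with
#'   amplitude close to `a` in expression units at 200 genes per dataset.
#' @param seed integer seed.
#' @return list with `datasets` (three annotated [expression_dataset()]s) and
#'   `truth` (`synthetic_truth`): planted `V`, `sigma`, `common` (the two
#'   oscillatory column indices), `artifact_pattern`, `artifact_host`,
#'   `artifact_index`, `phases` (list of per-gene planted phase angles),
#'   `phase_labels`, `seed`.
#' @export
cell_cycle_triple <- function(n_arrays = 17L, gene_counts = c(200L, 200L, 200L),
                              noise_sd = 0.1, artifact_amplitude = 4,
                              artifact_host = 2L, osc_sigma = 10,
                              seed = 1L) {
  n <- as.integer(n_arrays)
  if (n < 8L) stop("need at least 8 time points")
  gene_counts <- rep_len(as.integer(gene_counts), 3L)
  if (any(gene_counts < n)) stop("each dataset needs at least n_arrays genes")
  if (noise_sd < 0 || artifact_amplitude < 0) stop("degenerate parameters")
  artifact_host <- as.integer(artifact_host)
  if (!(artifact_host %in% 1:3)) stop("'artifact_host' must be 1, 2 or 3")

  with_seed(seed, {
    tt <- seq_len(n) - 1L
    theta_t <- 4 * pi * tt / n             # two full periods over n points
    cosg <- cos(theta_t)
    sing <- sin(theta_t)
    decay <- exp(-3 * tt / (n - 1L))

    raw <- cbind(cosg, sing, decay,
                 matrix(stats::rnorm(n * (n - 3L)), n, n - 3L))
    v <- qr.Q(qr(raw))
    for (k in seq_len(n)) {                # align signs with the raw patterns
      if (sum(v[, k] * raw[, k]) < 0) v[, k] <- -v[, k]
    }

    art_floor <- 0.05
    filler_base <- if (n > 3L) stats::runif(n - 3L, 1.5, 3.5) else numeric(0L)
    # fixed per-dataset multipliers give the fillers clearly unequal
    # significance (ratios 2 and 4), keeping them out of the common subspace
    filler_mult <- c(0.5, 1, 2)
    sigma <- lapply(1:3, function(i) {
      s <- numeric(n)
      s[1:2] <- osc_sigma
      s[3L] <- if (artifact_amplitude == 0) art_floor else
        if (i == artifact_host) artifact_amplitude else art_floor
      if (n > 3L) s[4:n] <- filler_base * filler_mult[i]
      s
    })

    phases <- vector("list", 3L)
    labels <- vector("list", 3L)
    datasets <- vector("list", 3L)
    nms <- c("synthetic_pombe", "synthetic_cerevisiae", "synthetic_human")
    for (i in 1:3) {
      m <- gene_counts[i]
      # each gene gets a planted phase and an amplitude bounded away from
      # zero; the loading matrix is then orthonormalized (QR), which leaves
      # the phase encoding intact up to O(1/sqrt(m)) mixing
      phi0 <- stats::runif(m, 0, 2 * pi)
      amp <- stats::runif(m, 0.5, 1.5)
      x <- cbind(amp * cos(phi0), amp * sin(phi0),
                 matrix(stats::rnorm(m * (n - 2L)), m, n - 2L))
      u <- qr.Q(qr(x))
      for (k in seq_len(n)) {
        if (sum(u[, k] * x[, k]) < 0) u[, k] <- -u[, k]
      }
      d <- u %*% (sigma[[i]] * t(v))
      if (noise_sd > 0) d <- d + matrix(stats::rnorm(m * n, sd = noise_sd), m, n)
      phi <- atan2(u[, 2L], u[, 1L]) %% (2 * pi)
      lab <- phase_bin(phi)
      ids <- sprintf("%s_g%04d", c("sp", "sc", "hs")[i], seq_len(m))
      names(lab) <- ids
      colnames(d) <- sprintf("t%02d", tt)
      datasets[[i]] <- expression_dataset(d, feature_ids = ids, name = nms[i],
                                          annotations = lab)
      phases[[i]] <- stats::setNames(phi, ids)
      labels[[i]] <- lab
    }

    truth <- structure(
      list(V = v, sigma = sigma, common = 1:2,
           artifact_pattern = v[, 3L], artifact_host = artifact_host,
           artifact_index = 3L, phases = phases, phase_labels = labels,
           theta_time = theta_t, seed = as.integer(seed)),
      class = "synthetic_truth"
    )
    list(datasets = datasets, truth = truth)
  })
}

# quadrant binning of a phase angle into cell-cycle-like labels
phase_bin <- function(phi) {
  cut_points <- c(0, pi / 2, pi, 3 * pi / 2)
  labels <- c("G1", "S", "G2", "M")
  idx <- findInterval(phi %% (2 * pi), cut_points)
  labels[idx]
}

#' Default phase boundaries matching the synthetic generator's labels
#'
#' @return named numeric vector of interval start angles for
#'   [classify_by_angle()].
#' @export
synthetic_phase_boundaries <- function() {
  c(G1 = 0, S = pi / 2, G2 = pi, M = 3 * pi / 2)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> seed", x$seed, "\n")
  cat("  planted common columns:", paste(x$common, collapse = ", "), "\n")
  if (!is.null(x$artifact_pattern)) {
    cat("  artifact pattern in dataset", x$artifact_host,
        "(planted column", x$artifact_index, ")\n")
  }
  invisible(x)
}
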