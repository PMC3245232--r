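#' Two-dimensional plane approximating the common subspace
#'
#' Returns the top two left singular vectors of the n x |K| matrix whose
#' columns are the common right basis vectors {v_k : k in K}: the plane that
#' best approximates the |K|-dimensional common subspace in the array space.
#' Orientation is deterministic: the first axis has its largest-magnitude
#' entry positive, and the second axis is flipped if needed so that the first
#' array's plane coordinate lies in the closed upper half-plane.
#'
#' @param factors a `hogsvd_factors` object.
#' @param K integer vector of at least 2 column indices.
#' @return n x 2 matrix with orthonormal columns, class attribute
#'   `hogsvd_plane`; attribute `K` records the indices used.
#' @export
approximating_plane <- function(factors, K) {
  stopifnot(inherits(factors, "hogsvd_factors"))
  K <- as.integer(K)
  n <- ncol(factors$V)
  if (length(K) < 2L) stop("need |K| >= 2 to define a plane")
  if (anyDuplicated(K) || any(K < 1L | K > n)) {
    stop("K must be distinct indices in 1..", n)
  }
  vk <- factors$V[, K, drop = FALSE]
  sv <- svd(vk, nu = 2L, nv = 0L)
  basis <- sv$u

  piv <- which.max(abs(basis[, 1L]))
  if (basis[piv, 1L] < 0) basis[, 1L] <- -basis[, 1L]
  if (basis[1L, 2L] < 0) {
    basis[, 2L] <- -basis[, 2L]
  } else if (basis[1L, 2L] == 0) {
    piv2 <- which.max(abs(basis[, 2L]))
    if (basis[piv2, 2L] < 0) basis[, 2L] <- -basis[, 2L]
  }
  structure(basis, K = K, class = c("hogsvd_plane", class(basis)))
}

#' Project arrays or genes onto the approximating plane
#'
#' Each entity is represented by its coefficient vector over the |K| selected
#' basis vectors: an array a of dataset i by sigma_{i,k} * V[a, k] (its row of
#' the diagonalized representation), a gene g by sigma_{i,k} * U[g, k] (its
#' sigma-weighted left-basis loadings).  The coefficient vector is normalized
#' to unit length and projected onto the plane, expressed in coefficient
#' space through the right singular vectors pairing with the plane's axes.
#' The projection radius r in [0, 1] is the "added-up fraction": the share of
#' the entity's common-subspace signal that the two plane axes reinforce
#' rather than cancel; the angle theta in [0, 2pi) orders entities around the
#' cycle (axis 1 = angle 0, counterclockwise).
#'
#' Entities with a zero coefficient vector are flagged and excluded from the
#' angular ordering (theta = NA).
#'
#' @param factors a `hogsvd_factors` object.
#' @param K the column indices defining the subspace (must match the plane).
#' @param plane result of [approximating_plane()].
#' @param which `"arrays"` or `"genes"`.
#' @param i dataset index.
#' @return object of class `plane_projection`: data.frame with columns `id`,
#'   `x`, `y`, `theta`, `r`, `zero` plus attributes `basis`, `K`, `which`,
#'   `dataset`.
#' @export
project_entities <- function(factors, K, plane, which = c("arrays", "genes"),
                             i = 1L) {
  stopifnot(inherits(factors, "hogsvd_factors"))
  which <- match.arg(which)
  if (!(i %in% seq_along(factors$U))) stop("no dataset with index ", i)
  K <- as.integer(K)
  if (!identical(K, as.integer(attr(plane, "K")))) {
    stop("K does not match the index set the plane was built from")
  }
  vk <- factors$V[, K, drop = FALSE]
  # coefficient-space images of the plane axes: V_K g_j = s_j b_j, so
  # g_j = normalize(t(V_K) b_j); orthonormal rows of the SVD's right factor
  g <- apply(crossprod(vk, unclass(plane)), 2L, function(z) {
    z / sqrt(sum(z^2))
  })

  sig <- factors$sigma[[i]][K]
  if (which == "arrays") {
    coeff <- sweep(factors$V[, K, drop = FALSE], 2L, sig, "*")
    ids <- colnames(factors$datasets[[i]]$values)
    if (is.null(ids)) ids <- sprintf("array_%02d", seq_len(nrow(coeff)))
  } else {
    coeff <- sweep(factors$U[[i]][, K, drop = FALSE], 2L, sig, "*")
    ids <- factors$datasets[[i]]$feature_ids
  }

  nrm <- sqrt(rowSums(coeff^2))
  zero <- nrm == 0
  unit <- coeff
  unit[!zero, ] <- coeff[!zero, , drop = FALSE] / nrm[!zero]
  unit[zero, ] <- 0

  xy <- unit %*% g
  r <- sqrt(rowSums(xy^2))
  theta <- atan2(xy[, 2L], xy[, 1L]) %% (2 * pi)
  theta[zero | r < 1e-10] <- NA_real_   # angle undefined at the origin

  out <- data.frame(id = ids, x = xy[, 1L], y = xy[, 2L],
                    theta = theta, r = r, zero = zero,
                    stringsAsFactors = FALSE)
  attr(out, "basis") <- unclass(plane)
  attr(out, "K") <- K
  attr(out, "which") <- which
  attr(out, "dataset") <- factors$datasets[[i]]$name
  class(out) <- c("plane_projection", class(out))
  out
}

#' Count entities whose contributions add up in the plane
#'
#' Number of entities in `subset` whose added-up fraction r is at least
#' `cutoff` (the half-unit circle of the projection display corresponds to
#' cutoff 0.5).
#'
#' @param projection a `plane_projection`.
#' @param subset entity ids to restrict to; `NULL` means all.
#' @param cutoff radius threshold in [0, 1], default 0.5.
#' @return integer count.
#' @export
count_added_up <- function(projection, subset = NULL, cutoff = 0.5) {
  stopifnot(inherits(projection, "plane_projection"))
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff > 1) {
    stop("'cutoff' must be in [0, 1]")
  }
  p <- projection
  if (!is.null(subset)) {
    p <- p[p$id %in% subset, , drop = FALSE]
  }
  if (cutoff == 0) {
    sum(!p$zero & p$r > 0)
  } else {
    sum(p$r >= cutoff)
  }
}

#' Classify projected entities by angular interval
#'
#' Assigns each entity whose radius exceeds `r_cutoff` the label of the
#' angular interval containing its angle.  `phase_boundaries` is a named
#' numeric vector of interval start angles in [0, 2pi); interval l spans
#' from its start (inclusive) to the next start (exclusive), the last one
#' wrapping around to the first.  An entity sitting exactly on a boundary is
#' assigned to the interval that starts there.
#'
#' @param projection a `plane_projection`.
#' @param phase_boundaries named numeric vector of distinct start angles.
#' @param r_cutoff minimum radius for classification (default 0: everything
#'   with a defined angle is classified).
#' @return character vector of labels, NA for unclassified entities, named
#'   by entity id.
#' @export
classify_by_angle <- function(projection, phase_boundaries, r_cutoff = 0) {
  stopifnot(inherits(projection, "plane_projection"))
  if (is.null(names(phase_boundaries)) || any(names(phase_boundaries) == "")) {
    stop("'phase_boundaries' must be a named vector of start angles")
  }
  starts <- as.numeric(phase_boundaries) %% (2 * pi)
  if (anyDuplicated(starts)) {
    stop("overlapping intervals: duplicate start angles in 'phase_boundaries'")
  }
  ord <- order(starts)
  starts <- starts[ord]
  labels <- names(phase_boundaries)[ord]

  out <- rep(NA_character_, nrow(projection))
  ok <- !is.na(projection$theta) & projection$r > r_cutoff
  th <- projection$theta[ok]
  # findInterval over sorted starts; angles below the first start wrap to the
  # last interval
  idx <- findInterval(th, starts)
  idx[idx == 0L] <- length(starts)
  out[ok] <- labels[idx]
  names(out) <- projection$id
  out
}
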