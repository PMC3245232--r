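#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of drawing at least `overlap` annotated genes when `top` genes
#' are sampled without replacement from a population of `population` genes of
#' which `annotated` carry the annotation: P(X >= overlap) for
#' X ~ Hypergeometric(population, annotated, top).  The tail is accumulated
#' as an exact sum of log-probability terms, so tiny p-values are computed
#' without underflow.
#'
#' @param population total number of genes.
#' @param annotated number of genes carrying the annotation.
#' @param top size of the top-gene list.
#' @param overlap observed number of annotated genes in the list.
#' @return p-value in (0, 1].
#' @examples
#' enrichment_pvalue(10, 5, 3, 3)  # 1/12
#' @export
enrichment_pvalue <- function(population, annotated, top, overlap) {
  for (v in c(population, annotated, top, overlap)) {
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop("all counts must be single nonnegative integers")
    }
  }
  if (annotated > population) stop("'annotated' exceeds 'population'")
  if (top > population) stop("'top' exceeds 'population'")
  if (overlap > min(annotated, top)) {
    stop("'overlap' exceeds min(annotated, top)")
  }
  if (overlap == 0L) return(1)
  xs <- seq.int(overlap, min(annotated, top))
  lp <- stats::dhyper(xs, m = annotated, n = population - annotated,
                      k = top, log = TRUE)
  lmax <- max(lp)
  exp(lmax) * sum(exp(lp - lmax))
}

#' Annotation enrichment of the leading genes of each left basis vector
#'
#' For each dataset carrying annotations and each selected column k, ranks
#' the genes by their left-basis entry u_{i,k}: the `top` most positive
#' entries form the overexpressed list and the `top` most negative the
#' underexpressed list (ties at the cutoff broken by feature-id order, so the
#' lists are deterministic).  Every annotation label present in the dataset
#' is then scored with [enrichment_pvalue()] against each list.
#'
#' @param factors a `hogsvd_factors` object whose datasets carry annotations.
#' @param K column indices to score (e.g. the common subspace).
#' @param top size of each gene list (default 100).
#' @return data.frame with columns `dataset`, `arraylet`, `direction`,
#'   `annotation`, `overlap`, `annotated`, `population`, `top`, `p_value`,
#'   sorted by dataset, arraylet, direction, p_value.
#' @export
enrichment_table <- function(factors, K, top = 100L) {
  stopifnot(inherits(factors, "hogsvd_factors"))
  K <- as.integer(K)
  n <- ncol(factors$V)
  if (!length(K) || any(K < 1L | K > n)) stop("K must be indices in 1..", n)
  top <- as.integer(top)
  if (top < 1L) stop("'top' must be at least 1")

  rows <- list()
  for (i in seq_along(factors$datasets)) {
    d <- factors$datasets[[i]]
    if (is.null(d$annotations) || !length(d$annotations)) {
      warning("dataset '", d$name, "' has no annotations; skipped")
      next
    }
    ids <- d$feature_ids
    m <- length(ids)
    ntop <- min(top, m)
    labels <- sort(unique(d$annotations))
    ann_count <- table(factor(d$annotations, levels = labels))
    for (k in K) {
      u <- factors$U[[i]][, k]
      for (direction in c("over", "under")) {
        score <- if (direction == "over") -u else u
        sel <- ids[order(score, ids)][seq_len(ntop)]
        sel_ann <- d$annotations[intersect(sel, names(d$annotations))]
        for (lab in labels) {
          x <- sum(sel_ann == lab)
          p <- enrichment_pvalue(m, as.integer(ann_count[[lab]]), ntop, x)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = d$name, arraylet = k, direction = direction,
            annotation = lab, overlap = x,
            annotated = as.integer(ann_count[[lab]]),
            population = m, top = ntop, p_value = p,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(dataset = character(), arraylet = integer(),
                      direction = character(), annotation = character(),
                      overlap = integer(), annotated = integer(),
                      population = integer(), top = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$dataset, out$arraylet, out$direction, out$p_value), ,
      drop = FALSE]
}
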