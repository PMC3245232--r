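#' Construct an expression dataset
#'
#' Bundles one expression matrix (rows = features/genes, columns = arrays or
#' time points) with its feature identifiers and optional per-feature
#' annotations (e.g. cell-cycle phase labels).  All datasets entering one
#' joint decomposition must share the same number of columns, with a
#' one-to-one mapping among them (same arrays, same order); the rows are
#' organism- or dataset-specific and need not map onto each other.
#'
#' The full decomposition requires each matrix to have full column rank, so
#' construction checks the numerical rank of `values`: the smallest singular
#' value must exceed `rank_rtol` times the largest.
#'
#' @param values numeric matrix, m_i x n with m_i >= n >= 2.
#' @param feature_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param name short label used in messages and output file names.
#' @param annotations optional named character vector mapping feature ids to
#'   annotation labels (features may be missing = unannotated).
#' @param na_action how to treat non-finite entries: `"error"` (default),
#'   `"drop"` rows containing any, or `"impute_row_mean"`.
#' @param rank_rtol relative tolerance of the full-column-rank check.
#' @return an object of class `expression_dataset` with elements `name`,
#'   `feature_ids`, `annotations`, `values`.
#' @examples
#' d <- expression_dataset(matrix(rnorm(40), 10, 4), name = "toy")
#' dim(d$values)
#' @export
expression_dataset <- function(values, feature_ids = rownames(values),
                               name = "dataset", annotations = NULL,
                               na_action = c("error", "drop", "impute_row_mean"),
                               rank_rtol = 1e-12) {
  na_action <- match.arg(na_action)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values)
  n <- ncol(values)
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("feature_%0*d", nchar(m), seq_len(m))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != m) {
    stop("'feature_ids' must have one entry per row of 'values' (",
         length(feature_ids), " vs ", m, ")")
  }
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    stop("duplicate feature ids in dataset '", name, "': ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }

  bad <- !is.finite(values)
  if (any(bad)) {
    if (na_action == "error") {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop("non-finite value in dataset '", name, "' at row ", idx[1L],
           " (", feature_ids[idx[1L]], "), column ", idx[2L],
           "; use na_action = 'drop' or 'impute_row_mean' to handle it")
    } else if (na_action == "drop") {
      keep <- rowSums(bad) == 0L
      values <- values[keep, , drop = FALSE]
      feature_ids <- feature_ids[keep]
      m <- nrow(values)
    } else {
      for (r in which(rowSums(bad) > 0L)) {
        row <- values[r, ]
        fin <- is.finite(row)
        if (!any(fin)) stop("row ", r, " of dataset '", name,
                            "' has no finite values to impute from")
        row[!fin] <- mean(row[fin])
        values[r, ] <- row
      }
    }
  }

  if (n < 2L) stop("dataset '", name, "' must have at least 2 columns")
  if (m < n) stop("dataset '", name, "' has fewer rows (", m,
                  ") than columns (", n, "); full column rank is impossible")

  sv <- svd(values, nu = 0L, nv = 0L)$d
  if (sv[n] <= rank_rtol * sv[1L]) {
    stop("rank deficiency in dataset '", name, "': smallest singular value ",
         format(sv[n]), " is below ", format(rank_rtol), " * largest (",
         format(sv[1L]), ")")
  }

  if (!is.null(annotations)) {
    annotations <- annotations[!is.na(annotations)]
    if (is.null(names(annotations)) || any(names(annotations) == "")) {
      stop("'annotations' must be a named character vector keyed by feature id")
    }
    unknown <- setdiff(names(annotations), feature_ids)
    if (length(unknown)) {
      stop("annotations refer to unknown feature ids in dataset '", name,
           "': ", paste(utils::head(unknown, 5L), collapse = ", "))
    }
    annotations <- vapply(annotations, as.character, character(1L))
  }

  rownames(values) <- feature_ids
  structure(
    list(name = name, feature_ids = feature_ids,
         annotations = annotations, values = values),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> '", x$name, "': ", nrow(x$values), " features x ",
      ncol(x$values), " arrays", sep = "")
  if (!is.null(x$annotations)) {
    cat("; ", length(x$annotations), " annotated features (",
        length(unique(x$annotations)), " labels)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# shared validation for a list of datasets entering one decomposition
check_dataset_list <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2L) {
    stop("need a list of at least 2 datasets")
  }
  if (!all(vapply(datasets, inherits, logical(1L), "expression_dataset"))) {
    stop("all elements must be 'expression_dataset' objects ",
         "(see expression_dataset())")
  }
  ns <- vapply(datasets, function(d) ncol(d$values), integer(1L))
  if (length(unique(ns)) != 1L) {
    stop("all datasets must share the same number of columns; got ",
         paste(ns, collapse = ", "))
  }
  nms <- vapply(datasets, function(d) d$name, character(1L))
  if (anyDuplicated(nms)) {
    nms <- make.unique(nms)
    for (i in seq_along(datasets)) datasets[[i]]$name <- nms[i]
  }
  datasets
}
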