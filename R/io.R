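# Tab-delimited readers/writers.  Dialect: UTF-8, tab separated, header row,
# feature id in the first (or a named) column, optional annotation columns,
# remaining columns numeric arrays.  All floating output is serialized with
# 12 significant digits, enough to round-trip within 1e-10 relative.

format_num <- function(x) {
  out <- formatC(x, digits = 12L, format = "g", flag = "")
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  trimws(out)
}

write_tsv_matrix <- function(m, path, row_label = "id") {
  df <- as.data.frame(apply(m, 2L, format_num), stringsAsFactors = FALSE)
  if (is.null(colnames(m))) {
    colnames(df) <- sprintf("c%d", seq_len(ncol(m)))
  } else {
    colnames(df) <- colnames(m)
  }
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("r%d", seq_len(nrow(m)))
  df <- cbind(stats::setNames(data.frame(ids, stringsAsFactors = FALSE),
                              row_label), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-delimited expression table
#'
#' Parses a header-rowed, tab-separated table into an
#' [expression_dataset()]: one identifier column, optional annotation
#' columns, and the remaining (or an explicitly named set of) numeric array
#' columns.  Row order is preserved; duplicate ids and non-numeric array
#' entries are errors that name the offending row and column.
#'
#' @param path file path.
#' @param name dataset label; defaults to the file name without extension.
#' @param id_col name of the identifier column (default: first column).
#' @param annotation_cols character vector of annotation column names
#'   (optional); empty-string and NA annotation entries mean "unannotated".
#' @param array_cols character vector of array column names; default: every
#'   column that is neither the id nor an annotation column.
#' @param na_action passed to [expression_dataset()] for rows with missing
#'   or non-finite values: `"error"`, `"drop"`, or `"impute_row_mean"`.
#' @return an [expression_dataset()].
#' @export
read_expression_table <- function(path, name = NULL, id_col = NULL,
                                  annotation_cols = NULL, array_cols = NULL,
                                  na_action = "error") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8",
                          quote = "")
  if (!nrow(df) || !ncol(df)) stop("empty table: ", path)
  if (is.null(id_col)) id_col <- colnames(df)[1L]
  for (col in c(id_col, annotation_cols, array_cols)) {
    if (!(col %in% colnames(df))) {
      stop("configured column '", col, "' not found in ", path)
    }
  }
  if (is.null(array_cols)) {
    array_cols <- setdiff(colnames(df), c(id_col, annotation_cols))
  }
  if (length(array_cols) < 2L) stop("need at least 2 array columns in ", path)

  ids <- df[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature id '", ids[duplicated(ids)][1L], "' in ", path)
  }

  values <- matrix(NA_real_, nrow(df), length(array_cols),
                   dimnames = list(ids, array_cols))
  for (j in seq_along(array_cols)) {
    raw <- df[[array_cols[j]]]
    blank <- is.na(raw) | trimws(raw) == "" | toupper(trimws(raw)) %in%
      c("NA", "NAN", "NULL")
    num <- suppressWarnings(as.numeric(raw))
    bad <- !blank & is.na(num)
    if (any(bad)) {
      r <- which(bad)[1L]
      stop("non-numeric value '", raw[r], "' at row ", r, " (", ids[r],
           "), column '", array_cols[j], "' of ", path)
    }
    values[, j] <- num
  }

  annotations <- NULL
  if (!is.null(annotation_cols)) {
    # first non-empty annotation column entry per feature wins
    ann <- rep(NA_character_, nrow(df))
    for (col in annotation_cols) {
      raw <- trimws(df[[col]])
      use <- is.na(ann) & !is.na(raw) & raw != ""
      ann[use] <- raw[use]
    }
    keep <- !is.na(ann)
    if (any(keep)) annotations <- stats::setNames(ann[keep], ids[keep])
  }

  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  ds <- expression_dataset(values, feature_ids = ids, name = name,
                           annotations = annotations, na_action = na_action)
  message("read ", length(ds$feature_ids), " features x ",
          ncol(ds$values), " arrays from ", path)
  ds
}

#' Write an expression dataset as a tab-delimited table
#'
#' Inverse of [read_expression_table()]: id column first, one `annotation`
#' column when annotations are present, then the array columns at 12
#' significant digits.
#'
#' @param dataset an [expression_dataset()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_expression_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  m <- dataset$values
  df <- data.frame(id = dataset$feature_ids, stringsAsFactors = FALSE)
  if (!is.null(dataset$annotations)) {
    ann <- dataset$annotations[dataset$feature_ids]
    ann[is.na(ann)] <- ""
    df$annotation <- unname(ann)
  }
  vals <- as.data.frame(apply(m, 2L, format_num), stringsAsFactors = FALSE)
  if (is.null(colnames(m))) colnames(vals) <- sprintf("array_%02d",
                                                      seq_len(ncol(m)))
  utils::write.table(cbind(df, vals), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write decomposition factors and the common-subspace report
#'
#' Serializes V, the eigenvalues, the per-dataset U and sigma, and a
#' human-readable common-subspace report into `outdir` as tab-separated
#' files with 12 significant digits (round-tripping within 1e-10).  Output
#' is byte-identical for identical input.  Column indices in the report are
#' 1-based, in descending-eigenvalue order.
#'
#' @param factors a `hogsvd_factors` object.
#' @param common optional `hogsvd_common_subspace` (from
#'   [common_subspace()]).
#' @param outdir output directory, created if needed.
#' @return character vector of written file paths, invisibly.
#' @export
write_factors <- function(factors, common = NULL, outdir = ".") {
  stopifnot(inherits(factors, "hogsvd_factors"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0L)
  n <- ncol(factors$V)
  kn <- sprintf("k%02d", seq_len(n))

  v <- factors$V
  dimnames(v) <- list(sprintf("array_%02d", seq_len(n)), kn)
  p <- file.path(outdir, "V.tsv")
  write_tsv_matrix(v, p, row_label = "array")
  written <- c(written, p)

  lam <- cbind(lambda = factors$lambdas, inv_lambda = 1 / factors$lambdas)
  rownames(lam) <- kn
  p <- file.path(outdir, "lambda.tsv")
  write_tsv_matrix(lam, p, row_label = "k")
  written <- c(written, p)

  nms <- vapply(factors$datasets, function(d) d$name, character(1L))
  sig <- do.call(rbind, factors$sigma)
  dimnames(sig) <- list(nms, kn)
  p <- file.path(outdir, "sigma.tsv")
  write_tsv_matrix(sig, p, row_label = "dataset")
  written <- c(written, p)

  for (i in seq_along(factors$U)) {
    u <- factors$U[[i]]
    colnames(u) <- kn
    p <- file.path(outdir, paste0("U_", nms[i], ".tsv"))
    write_tsv_matrix(u, p, row_label = "id")
    written <- c(written, p)
  }

  p <- file.path(outdir, "common_subspace.txt")
  con <- file(p, "w", encoding = "UTF-8")
  if (is.null(common)) {
    writeLines("common subspace: not computed", con)
  } else if (!length(common$indices)) {
    writeLines(sprintf(
      "no common indices at lambda <= %s (epsilon = %s)",
      format_num(common$lambda_threshold), format_num(common$epsilon)), con)
    writeLines(sprintf("largest-gap alternative: %s",
                       paste(common$gap_indices, collapse = ", ")), con)
  } else {
    writeLines(sprintf("common indices at lambda <= %s: %s",
                       format_num(common$lambda_threshold),
                       paste(common$indices, collapse = ", ")), con)
    writeLines(sprintf("lambdas: %s",
                       paste(format_num(common$lambdas), collapse = ", ")), con)
    writeLines(sprintf("largest-gap alternative: %s",
                       paste(common$gap_indices, collapse = ", ")), con)
    writeLines("", con)
    writeLines("orthogonality residuals (rows k, columns datasets):", con)
    orth <- common$orthogonality_residuals
    writeLines(paste(c("k", nms), collapse = "\t"), con)
    for (r in seq_len(nrow(orth))) {
      writeLines(paste(c(rownames(orth)[r], format_num(orth[r, ])),
                       collapse = "\t"), con)
    }
    writeLines("", con)
    writeLines("pairwise sigma ratios per common index:", con)
    for (kchr in names(common$ratio_matrix)) {
      writeLines(paste0("k = ", kchr), con)
      rm_ <- common$ratio_matrix[[kchr]]
      writeLines(paste(c("", colnames(rm_)), collapse = "\t"), con)
      for (r in seq_len(nrow(rm_))) {
        writeLines(paste(c(rownames(rm_)[r], format_num(rm_[r, ])),
                         collapse = "\t"), con)
      }
    }
  }
  close(con)
  written <- c(written, p)
  invisible(written)
}

#' Write a plane projection as a tab-delimited table
#'
#' @param projection a `plane_projection`.
#' @param path output file path.
#' @param labels optional named character vector of entity labels (as from
#'   [classify_by_angle()]) merged in as a `label` column.
#' @return the path, invisibly.
#' @export
write_projection <- function(projection, path, labels = NULL) {
  stopifnot(inherits(projection, "plane_projection"))
  df <- data.frame(id = projection$id,
                   x = format_num(projection$x),
                   y = format_num(projection$y),
                   theta = format_num(projection$theta),
                   r = format_num(projection$r),
                   stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    lab <- labels[projection$id]
    lab[is.na(lab)] <- ""
    df$label <- unname(lab)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
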