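# Connectivity feature construction: Pearson correlation between ROI time
# series, Fisher z variance stabilization, and strictly-upper-triangle
# vectorization into per-view feature matrices.

#' Pearson correlation matrix of ROI time series
#'
#' Computes the sample Pearson correlation between every pair of regions
#' (columns) of a time-series matrix. Any region with zero variance makes the
#' correlation undefined, so such input is rejected rather than silently
#' imputed.
#'
#' @param ts Numeric matrix, `T` timepoints (rows) by `n` regions (columns),
#'   `T >= 2`, `n >= 2`, all entries finite.
#' @return An `n x n` symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stop("need at least 2 timepoints, got ", nrow(ts))
  if (ncol(ts) < 2L) stop("need at least 2 regions, got ", ncol(ts))
  if (!all(is.finite(ts))) stop("time series contains non-finite values")
  sds <- apply(ts, 2L, stats::sd)
  bad <- which(sds == 0)
  if (length(bad) > 0L) {
    stop("degenerate (zero-variance) series for region(s): ",
         paste(bad, collapse = ", "))
  }
  r <- stats::cor(ts)
  # guard against floating noise pushing |r| microscopically above 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Fisher z transform of a correlation coefficient
#'
#' `atanh(r)` with the argument clipped to `±(1 - 1e-7)` so that perfectly
#' correlated (degenerate) pairs map to a large finite value instead of
#' `±Inf`.
#'
#' @param r Numeric vector or matrix of correlations in `[-1, 1]`.
#' @return Object of the same shape with `atanh` applied elementwise.
#' @export
fisher_z <- function(r) {
  eps <- 1e-7
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlation outside [-1, 1]: max |r| = ", max(abs(r), na.rm = TRUE))
  }
  r <- pmin(pmax(r, -1 + eps), 1 - eps)
  out <- atanh(r)
  if (is.matrix(r)) dim(out) <- dim(r)
  out
}

#' Number of distinct functional connections for n regions
#'
#' The strictly upper triangle of an `n x n` symmetric connectivity matrix
#' holds `n (n - 1) / 2` entries; this is the per-view feature dimension.
#'
#' @param n Integer region count, `n >= 1`.
#' @return Integer `n (n - 1) / 2`.
#' @export
feature_count <- function(n) {
  if (any(n < 1) || any(n != floor(n))) stop("n must be a positive integer")
  as.integer(n * (n - 1) / 2)
}

#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Entries `(i, j)` with `i < j` are emitted in row-major order:
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). The diagonal is excluded;
#' self-connections carry no information.
#'
#' @param cm Symmetric numeric matrix (`n >= 2`).
#' @param tol Asymmetry tolerance (default `1e-10`).
#' @return Numeric vector of length `feature_count(n)`.
#' @export
vectorize_upper <- function(cm, tol = 1e-10) {
  cm <- as.matrix(cm)
  n <- nrow(cm)
  if (n < 2L || ncol(cm) != n) stop("need a square matrix with n >= 2")
  if (max(abs(cm - t(cm))) > tol) {
    stop("matrix is not symmetric within tolerance ", tol)
  }
  # t() because R stores column-major but row-major upper-triangle order
  # equals column-major lower-triangle order of the transpose
  tcm <- t(cm)
  tcm[lower.tri(tcm)]
}

#' Connectivity feature vector from one ROI time-series matrix
#'
#' The full chain: Pearson correlation, Fisher z, upper-triangle
#' vectorization.
#'
#' @inheritParams pearson_matrix
#' @return Numeric vector of length `feature_count(ncol(ts))`.
#' @export
connectivity_vector <- function(ts) {
  vectorize_upper(fisher_z(pearson_matrix(ts)))
}

#' Load an ROI time-series file
#'
#' Reads whitespace-delimited `.1D`-style exports (the dialect used by the
#' Preprocessed Connectomes Project) or CSV. Rows are timepoints, columns are
#' regions. Leading lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension, default), `"1D"` (whitespace) or
#'   `"csv"`.
#' @return Numeric matrix with attributes `subject_id` (file stem) and
#'   `atlas_name` (`NA` unless set by the caller).
#' @export
load_timeseries <- function(path, dialect = c("auto", "1D", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "1D"
  }
  lines <- readLines(path)
  body_start <- 1L
  while (body_start <= length(lines) &&
         (grepl("^\\s*#", lines[body_start]) ||
          !nzchar(trimws(lines[body_start])))) {
    body_start <- body_start + 1L
  }
  if (body_start > length(lines)) stop("no data rows in ", path)
  body <- lines[body_start:length(lines)]
  body <- body[nzchar(trimws(body))]
  split_row <- function(line) {
    if (dialect == "csv") strsplit(trimws(line), ",")[[1L]]
    else strsplit(trimws(line), "\\s+")[[1L]]
  }
  rows <- lapply(body, split_row)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    stop("ragged row at line ", body_start + bad - 1L, " of ", path)
  }
  vals <- suppressWarnings(vapply(rows, as.numeric, numeric(ncols[1L])))
  if (anyNA(vals)) {
    bad <- which(apply(matrix(is.na(vals), nrow = ncols[1L]), 2L, any))[1L]
    stop("non-numeric cell at line ", body_start + bad - 1L, " of ", path)
  }
  ts <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  if (nrow(ts) < 2L) stop("fewer than 2 timepoints in ", path)
  attr(ts, "subject_id") <- sub("\\.[^.]*$", "", basename(path))
  ts
}

#' Write an ROI time-series matrix
#'
#' Inverse of [load_timeseries()]; emits the whitespace dialect.
#'
#' @param ts Numeric matrix, timepoints by regions.
#' @param path Output path.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(ts, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble a multiview dataset aligned by subject identifier
#'
#' Takes one feature matrix per view (rows named by subject id, or a
#' `subject_id` attribute vector) plus a label table, and aligns all views and
#' labels to the label table's subject order. Alignment is by identifier, never
#' by file/row order.
#'
#' @param views Named list of numeric matrices, one per view; each must have
#'   rownames giving subject identifiers.
#' @param labels Data frame with columns `subject_id` and `label`, or a named
#'   vector/factor of labels.
#' @return An object of class `mv_dataset`: list with `views` (aligned
#'   matrices), `labels` (factor), `subject_ids`, and `D` (total feature
#'   dimension).
#' @export
assemble_views <- function(views, labels) {
  if (!is.list(views) || length(views) < 1L) stop("views must be a non-empty list")
  if (is.null(names(views)) || any(!nzchar(names(views)))) {
    names(views) <- paste0("view", seq_along(views))
  }
  if (is.data.frame(labels)) {
    if (!all(c("subject_id", "label") %in% names(labels))) {
      stop("label table needs columns subject_id and label")
    }
    ids <- as.character(labels$subject_id)
    y <- labels$label
  } else {
    ids <- names(labels)
    y <- unname(labels)
    if (is.null(ids)) stop("labels must be named by subject_id")
  }
  if (anyDuplicated(ids)) stop("duplicate subject identifiers in label table")
  for (v in names(views)) {
    m <- as.matrix(views[[v]])
    rn <- rownames(m)
    if (is.null(rn)) stop("view '", v, "' has no subject identifiers (rownames)")
    missing <- setdiff(ids, rn)
    if (length(missing) > 0L) {
      stop("view '", v, "' is missing subject(s): ",
           paste(missing, collapse = ", "))
    }
    views[[v]] <- m[ids, , drop = FALSE]
  }
  y <- factor(y)
  if (nlevels(y) < 2L) stop("labels must contain at least two classes")
  structure(
    list(views = views, labels = y, subject_ids = ids,
         D = sum(vapply(views, ncol, integer(1L)))),
    class = "mv_dataset")
}

#' @export
print.mv_dataset <- function(x, ...) {
  cat("Multiview dataset: ", length(x$subject_ids), " subjects, ",
      length(x$views), " views (D = ", x$D, ")\n", sep = "")
  for (v in names(x$views)) {
    cat("  ", v, ": ", ncol(x$views[[v]]), " features\n", sep = "")
  }
  cat("  classes: ", paste(levels(x$labels), table(x$labels),
                           sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build a multiview dataset from per-subject time-series files
#'
#' For each view, loads every subject's time-series file, runs the
#' connectivity chain ([connectivity_vector()]) and stacks the vectors into a
#' subjects-by-features matrix, then aligns everything with
#' [assemble_views()].
#'
#' @param file_sets Named list (one entry per view) of named character vectors
#'   mapping subject_id to file path.
#' @param labels Label table as in [assemble_views()].
#' @param dialect Passed to [load_timeseries()].
#' @return An `mv_dataset`.
#' @export
assemble_from_timeseries <- function(file_sets, labels, dialect = "auto") {
  views <- lapply(file_sets, function(files) {
    if (is.null(names(files))) stop("file sets must be named by subject_id")
    feats <- lapply(files, function(p) connectivity_vector(load_timeseries(p, dialect)))
    widths <- lengths(feats)
    if (length(unique(widths)) != 1L) {
      stop("inconsistent region counts within a view: ",
           paste(unique(widths), collapse = ", "))
    }
    m <- do.call(rbind, feats)
    rownames(m) <- names(files)
    m
  })
  assemble_views(views, labels)
}

#' Write a per-view feature matrix as delimited text
#'
#' One comment header line records the view name and feature count; the body
#' is CSV with the subject identifier in the first column.
#'
#' @param X Numeric matrix with subject rownames.
#' @param view_id View name recorded in the header.
#' @param path Output path.
#' @export
write_view_matrix <- function(X, view_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# view=%s n_v=%d", view_id, ncol(X)), con)
  df <- data.frame(subject_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_view_matrix()]
#'
#' Also accepts plain CSV/TSV with a `subject_id` first column.
#'
#' @param path Input path.
#' @return Numeric matrix with subject rownames and a `view_id` attribute when
#'   the header is present.
#' @export
read_view_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  view_id <- NA_character_
  skip <- 0L
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("view=(\\S+)", first))[[1L]]
    if (length(m) == 2L) view_id <- m[2L]
    skip <- 1L
  }
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, skip = skip,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "subject_id") stop("first column must be subject_id")
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- as.character(df$subject_id)
  storage.mode(X) <- "double"
  attr(X, "view_id") <- view_id
  X
}
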