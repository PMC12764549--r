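#' Construct a mother-media composition matrix
#'
#' A composition matrix `A` holds the relative concentrations of `d` medium
#' components (columns) across `m` mother media (rows). Concentrations are
#' nonnegative and in arbitrary relative units (e.g. peak areas from media
#' analysis); all downstream design steps standardize per component, so the
#' units only need to be consistent within a column.
#'
#' @param values numeric matrix, `m` media by `d` components, all entries >= 0.
#' @param media_ids character vector of unique row labels (defaults to
#'   rownames of `values`).
#' @param component_ids character vector of unique column labels (defaults to
#'   colnames of `values`).
#' @return An object of class `composition_matrix` with elements `values`,
#'   `media_ids`, `component_ids`, `m`, `d`.
#' @export
composition_matrix <- function(values, media_ids = rownames(values),
                               component_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("composition values must be numeric")
  m <- nrow(values); d <- ncol(values)
  if (m < 2L) stop("a composition matrix needs at least 2 mother media")
  if (d < 1L) stop("a composition matrix needs at least 1 component")
  if (is.null(media_ids)) media_ids <- paste0("medium_", seq_len(m))
  if (is.null(component_ids)) component_ids <- paste0("component_", seq_len(d))
  media_ids <- as.character(media_ids)
  component_ids <- as.character(component_ids)
  if (anyDuplicated(media_ids))
    stop("duplicate media labels: ",
         paste(unique(media_ids[duplicated(media_ids)]), collapse = ", "))
  if (anyDuplicated(component_ids))
    stop("duplicate component labels: ",
         paste(unique(component_ids[duplicated(component_ids)]), collapse = ", "))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing/non-numeric value at medium '%s', component '%s'",
                 media_ids[bad[1L]], component_ids[bad[2L]]))
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative concentration at medium '%s', component '%s'",
                 media_ids[bad[1L]], component_ids[bad[2L]]))
  }
  dimnames(values) <- list(media_ids, component_ids)
  structure(list(values = values, media_ids = media_ids,
                 component_ids = component_ids, m = m, d = d),
            class = "composition_matrix")
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("Composition matrix: %d mother media x %d components\n", x$m, x$d))
  cat("Media:", paste(head(x$media_ids, 6), collapse = ", "),
      if (x$m > 6) "..." else "", "\n")
  invisible(x)
}

#' Load a composition matrix from CSV
#'
#' The expected layout has a first column `medium_id` and one numeric column
#' per component (rows are media). Set `rows_are_media = FALSE` if the file
#' is transposed (first column holds component ids, remaining columns are
#' media).
#'
#' @param path path to a CSV file.
#' @param rows_are_media logical flag; `TRUE` (default) means rows are media.
#' @return A [composition_matrix()].
#' @export
load_composition <- function(path, rows_are_media = TRUE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("composition CSV needs a label column plus data")
  labels <- as.character(df[[1L]])
  num <- df[, -1L, drop = FALSE]
  not_num <- !vapply(num, is.numeric, logical(1L))
  if (any(not_num))
    stop("non-numeric composition columns: ",
         paste(names(num)[not_num], collapse = ", "))
  mat <- as.matrix(num)
  rownames(mat) <- labels
  if (!rows_are_media) mat <- t(mat)
  composition_matrix(mat)
}

#' Write a composition matrix to CSV
#'
#' Writes the rows-are-media layout read back by [load_composition()].
#'
#' @param A a [composition_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(A, path) {
  stopifnot(inherits(A, "composition_matrix"))
  df <- data.frame(medium_id = A$media_ids, A$values,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardize a composition matrix per component
#'
#' Each component column is z-scored using its population standard
#' deviation. Columns with zero variance carry no design information and
#' cannot be z-scored; they are dropped with a warning and recorded in
#' `dropped_components`.
#'
#' @param A a [composition_matrix()], or a plain numeric matrix.
#' @return An object of class `standardized_matrix` with elements `values`
#'   (retained columns, mean 0 / sd 1), `column_means`, `column_sds`,
#'   `dropped_components`, `media_ids`, `component_ids`.
#' @export
standardize <- function(A) {
  mat <- if (inherits(A, "composition_matrix")) A$values else as.matrix(A)
  if (nrow(mat) < 2L) stop("standardization needs at least 2 rows")
  if (is.null(colnames(mat))) colnames(mat) <- paste0("component_", seq_len(ncol(mat)))
  mu <- colMeans(mat)
  sds <- apply(mat, 2L, pop_sd)
  keep <- sds > 0
  if (!any(keep)) stop("all components have zero variance; nothing to standardize")
  dropped <- colnames(mat)[!keep]
  if (length(dropped))
    warning("dropping zero-variance components: ", paste(dropped, collapse = ", "))
  vals <- sweep(sweep(mat[, keep, drop = FALSE], 2L, mu[keep]), 2L, sds[keep], "/")
  structure(list(values = vals, column_means = mu[keep], column_sds = sds[keep],
                 dropped_components = dropped,
                 media_ids = rownames(mat),
                 component_ids = colnames(mat)[keep]),
            class = "standardized_matrix")
}

#' Pairwise absolute-correlation summary of a matrix's columns
#'
#' Computes Pearson product-moment correlations between all column pairs and
#' summarizes their absolute values: the maximum, the mean, and the fraction
#' of off-diagonal pairs exceeding each requested threshold. This is the
#' multicollinearity profile used to compare composition matrices and
#' selected designs.
#'
#' @param X numeric matrix with at least 3 rows. Constant columns have an
#'   undefined correlation and are excluded with a warning.
#' @param thresholds numeric vector of |r| thresholds (default `c(0.7, 0.9)`).
#' @return An object of class `correlation_summary` with elements
#'   `pairwise_abs_r` (symmetric, unit diagonal), `max_abs_r`, `mean_abs_r`,
#'   `frac_above` (named by threshold), `n_pairs`, `excluded` (constant
#'   column labels).
#' @export
correlation_summary <- function(X, thresholds = c(0.7, 0.9)) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("correlation summary needs at least 3 rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2L, stats::sd)
  excluded <- colnames(X)[sds == 0]
  if (length(excluded)) {
    warning("excluding constant columns from correlation summary: ",
            paste(excluded, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  d <- ncol(X)
  if (d < 2L) stop("need at least 2 non-constant columns for correlations")
  absr <- abs(cor(X))
  diag(absr) <- 1
  off <- absr[upper.tri(absr)]
  fr <- vapply(thresholds, function(t) mean(off > t), numeric(1L))
  structure(list(pairwise_abs_r = absr,
                 max_abs_r = max(off),
                 mean_abs_r = mean(off),
                 frac_above = setNames(fr, format(thresholds)),
                 n_pairs = d * (d - 1L) / 2L,
                 excluded = excluded),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("Correlation summary over %d pairs: max |r| = %.3f, mean |r| = %.3f\n",
              x$n_pairs, x$max_abs_r, x$mean_abs_r))
  for (nm in names(x$frac_above))
    cat(sprintf("  fraction |r| > %s: %.4f\n", nm, x$frac_above[[nm]]))
  invisible(x)
}

#' Hierarchically cluster mother media
#'
#' Agglomerative clustering of the media rows with Ward's method on
#' Euclidean distances (`stats::hclust`, method `"ward.D2"`), a standard
#' diagnostic for spotting near-duplicate media before blending. By default
#' distances are computed on the per-component standardized values so that
#' high-magnitude components do not dominate.
#'
#' @param A a [composition_matrix()].
#' @param use_standardized cluster on standardized values (default) or raw
#'   concentrations.
#' @return An `hclust` tree with media labels.
#' @export
cluster_media <- function(A, use_standardized = TRUE) {
  stopifnot(inherits(A, "composition_matrix"))
  vals <- if (use_standardized) {
    suppressWarnings(standardize(A)$values)
  } else {
    A$values
  }
  hclust(dist(vals), method = "ward.D2")
}
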