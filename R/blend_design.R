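#' Enumerate all blend combinations of mother media
#'
#' Lists every way of dispensing `total_units` equal volume units across `m`
#' mother media (weak integer compositions), the candidate set for design
#' selection. With 11 media and 6 units of 200 uL this yields the
#' choose(11 + 6 - 1, 6) = 8008 combinations of a 1200 uL blend. Rows are
#' generated in colexicographic order (the last medium's unit count varies
#' slowest), which is deterministic.
#'
#' @param m number of mother media (>= 1).
#' @param total_units number of dispense units per blend (>= 1).
#' @param unit_volume volume per unit in uL (metadata only; default 200).
#' @param max_rows guard against combinatorial blow-up (default 1e7).
#' @return An object of class `blend_enumeration` with elements `units`
#'   (k x m integer matrix, each row summing to `total_units`),
#'   `total_units`, `unit_volume`, `k`.
#' @export
enumerate_blends <- function(m, total_units, unit_volume = 200, max_rows = 1e7) {
  stopifnot(m >= 1L, total_units >= 1L)
  k <- choose(m + total_units - 1, total_units)
  if (k > max_rows)
    stop(sprintf("enumeration would have %.3g rows (> %.3g); use coarser units",
                 k, max_rows))
  rec <- function(total, slots) {
    if (slots == 1L) return(matrix(total, 1L, 1L))
    do.call(rbind, lapply(0:total, function(u)
      cbind(rec(total - u, slots - 1L), u)))
  }
  units <- rec(as.integer(total_units), as.integer(m))
  storage.mode(units) <- "integer"
  colnames(units) <- paste0("medium_", seq_len(m))
  structure(list(units = units, total_units = as.integer(total_units),
                 unit_volume = unit_volume, k = nrow(units)),
            class = "blend_enumeration")
}

#' @export
print.blend_enumeration <- function(x, ...) {
  cat(sprintf("Blend enumeration: %d combinations of %d units over %d media (%g uL/unit)\n",
              x$k, x$total_units, ncol(x$units), x$unit_volume))
  invisible(x)
}

#' Project a standardized composition matrix onto its principal components
#'
#' Reduces the standardized composition matrix to the smallest orthogonal
#' principal-component subspace retaining at least `var_threshold` of its
#' variance. Because a standardized m x d matrix with m < d is rank
#' deficient (rank <= m - 1), this projection is what makes the D-optimal
#' determinant criterion non-degenerate: the PC scores are uncorrelated, so
#' the Gram matrix of a selected design is full rank in the retained
#' subspace. Loadings follow a deterministic sign convention: in each
#' component the largest-magnitude loading is positive.
#'
#' @param A_std a `standardized_matrix` from [standardize()].
#' @param var_threshold fraction of variance to retain, in (0, 1]
#'   (default 0.99).
#' @return An object of class `pca_projection` with elements `loadings`
#'   (d x p, orthonormal columns), `scores` (m x p), `explained_variance_ratio`
#'   (length p), `cumulative_evr`, `p`, `singular_values`.
#' @export
pca_project <- function(A_std, var_threshold = 0.99) {
  stopifnot(inherits(A_std, "standardized_matrix"))
  if (!is.numeric(var_threshold) || var_threshold <= 0 || var_threshold > 1)
    stop("var_threshold must be in (0, 1]")
  X <- A_std$values
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1L]
  r <- sum(sv$d > tol)
  evr_all <- sv$d^2 / sum(sv$d^2)
  p <- which(cumsum(evr_all) >= var_threshold - 1e-12)[1L]
  p <- min(p, r)
  V <- sv$v[, seq_len(p), drop = FALSE]
  for (j in seq_len(p)) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  scores <- X %*% V
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(p))
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(V)
  structure(list(loadings = V, scores = scores,
                 explained_variance_ratio = evr_all[seq_len(p)],
                 cumulative_evr = sum(evr_all[seq_len(p)]),
                 p = p, singular_values = sv$d),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("PCA projection: p = %d components, cumulative EVR = %.4f\n",
              x$p, x$cumulative_evr))
  invisible(x)
}

#' Map blend combinations into principal-component space
#'
#' Plain matrix product `E = D B`: row i of `E` is the PC-space location of
#' blend combination i (units of each medium times that medium's PC score).
#'
#' @param D a `blend_enumeration` (or a plain units matrix).
#' @param B a `pca_projection` (or a plain media-by-p score matrix).
#' @return Numeric k x p matrix, rows aligned 1:1 with the enumeration.
#' @export
blend_space <- function(D, B) {
  units <- if (inherits(D, "blend_enumeration")) D$units else as.matrix(D)
  scores <- if (inherits(B, "pca_projection")) B$scores else as.matrix(B)
  if (ncol(units) != nrow(scores))
    stop(sprintf("shape mismatch: %d media in blends vs %d media in scores",
                 ncol(units), nrow(scores)))
  units %*% scores
}

#' Determinant of the Gram matrix of a selected design
#'
#' `det(E'^T E')` for an n x p selected-score matrix: the squared volume of
#' the parallelepiped spanned by the design's column vectors, the quantity
#' maximized by D-optimal selection. The Gram matrix is positive
#' semidefinite, so tiny negative determinants from floating-point noise are
#' clamped to zero.
#'
#' @param E_sel numeric n x p matrix with n >= p.
#' @param standardize_cols z-score the columns first (population sd) before
#'   forming the Gram matrix. Off by default: the selection criterion is
#'   computed on raw PC-score columns.
#' @return Nonnegative determinant value.
#' @export
gram_determinant <- function(E_sel, standardize_cols = FALSE) {
  E_sel <- as.matrix(E_sel)
  if (nrow(E_sel) < ncol(E_sel))
    stop(sprintf("need at least as many rows (%d) as columns (%d)",
                 nrow(E_sel), ncol(E_sel)))
  if (standardize_cols) {
    sds <- apply(E_sel, 2L, pop_sd)
    if (any(sds == 0)) return(0)
    E_sel <- sweep(sweep(E_sel, 2L, colMeans(E_sel)), 2L, sds, "/")
  }
  d <- det(crossprod(E_sel))
  if (d < 0) d <- 0
  d
}

#' Random-search D-optimal selection of design rows
#'
#' Repeats `iters` times: draw `n` distinct rows of `E` uniformly without
#' replacement and score the draw by the Gram determinant; the
#' first-encountered maximum wins. The full determinant trace is kept (its
#' histogram shows where the selected design sits in the search
#' distribution). The worst (minimum-determinant) subset is also recorded
#' for diagnostic comparisons.
#'
#' @param E numeric k x p candidate matrix (rows = blend combinations in PC
#'   space).
#' @param n number of experimental conditions to select (n <= k).
#' @param iters number of random subsets to score (default 10000).
#' @param seed optional integer seed (`set.seed`) for reproducibility.
#' @param standardize_cols z-score the selected columns before each
#'   determinant (see [gram_determinant()]); default FALSE.
#' @return An object of class `dopt_search` with elements `indices` (length
#'   n, into the rows of `E`), `gram_det`, `worst_indices`, `worst_det`,
#'   `search_trace` (length `iters`).
#' @export
doptimal_search <- function(E, n, iters = 10000L, seed = NULL,
                            standardize_cols = FALSE) {
  E <- as.matrix(E)
  k <- nrow(E)
  if (n > k) stop(sprintf("cannot select n = %d rows from k = %d candidates", n, k))
  if (iters < 1L) stop("iters must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  res <- dopt_search_cpp(E, as.integer(n), as.integer(iters),
                         isTRUE(standardize_cols))
  structure(list(indices = as.integer(res$indices),
                 gram_det = max(res$det, 0),
                 worst_indices = as.integer(res$worst_indices),
                 worst_det = max(res$worst_det, 0),
                 search_trace = as.numeric(res$trace)),
            class = "dopt_search")
}

#' Collinearity diagnostics of a selected design
#'
#' Pairwise absolute correlations among the design's columns plus the
#' variance inflation factor of each column, VIF_j = 1 / (1 - R^2_j) from
#' regressing column j on the others (computed via the inverse correlation
#' matrix). Perfectly collinear columns give an infinite VIF sentinel with a
#' warning.
#'
#' @param E_sel numeric n x p matrix with n >= p + 1.
#' @param thresholds |r| thresholds for the correlation summary.
#' @return A list with `cor_summary` (a [correlation_summary()]), `vif`
#'   (named vector), `max_vif`.
#' @export
design_diagnostics <- function(E_sel, thresholds = c(0.7, 0.9)) {
  E_sel <- as.matrix(E_sel)
  if (nrow(E_sel) < ncol(E_sel) + 1L)
    stop("diagnostics need n >= p + 1 rows")
  cs <- correlation_summary(E_sel, thresholds)
  R <- cor(E_sel[, apply(E_sel, 2L, stats::sd) > 0, drop = FALSE])
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv)) {
    warning("perfectly collinear design columns; VIF reported as Inf")
    vif <- rep(Inf, ncol(R))
    names(vif) <- colnames(R)
  } else {
    vif <- diag(Rinv)
    names(vif) <- colnames(R)
    if (any(vif < 0 | vif > 1e12)) {
      warning("near-singular correlation matrix; VIF reported as Inf")
      vif[vif < 0 | vif > 1e12] <- Inf
    }
  }
  list(cor_summary = cs, vif = vif, max_vif = max(vif))
}

#' Run the full blending design workflow
#'
#' End-to-end experimental design for media blending: standardize the
#' composition matrix, project it onto the principal components retaining
#' `var_threshold` of the variance, enumerate all blend combinations, map
#' them into PC space, and pick `n_conditions` rows by random-search
#' D-optimal selection. The returned object carries the dispense plan (the
#' selected rows of the enumeration, in units and in uL), the selected PC
#' scores, the determinant and its search trace, and collinearity
#' diagnostics.
#'
#' @param composition a [composition_matrix()].
#' @param n_conditions number of experimental conditions to select.
#' @param total_units dispense units per blend (default 6).
#' @param iters random-search iterations (default 10000).
#' @param var_threshold PCA variance-retention threshold (default 0.99).
#' @param unit_volume uL per dispense unit (default 200).
#' @param seed optional integer seed.
#' @param standardize_det_cols standardize E' columns before the determinant
#'   (default FALSE; see [gram_determinant()]).
#' @param common_medium_volume constant uL of common medium added to every
#'   condition. It does not enter the design mathematics (constant across
#'   conditions); it is only reported in the dispense plan.
#' @param enumeration optional precomputed [enumerate_blends()] result (must
#'   match `total_units` and the media count).
#' @return An object of class `design_selection`; see Details.
#' @export
design_blending <- function(composition, n_conditions, total_units = 6L,
                            iters = 10000L, var_threshold = 0.99,
                            unit_volume = 200, seed = NULL,
                            standardize_det_cols = FALSE,
                            common_medium_volume = 0,
                            enumeration = NULL) {
  stopifnot(inherits(composition, "composition_matrix"))
  A_std <- suppressWarnings(standardize(composition))
  B <- pca_project(A_std, var_threshold)
  if (is.null(enumeration)) {
    enumeration <- enumerate_blends(composition$m, total_units,
                                    unit_volume = unit_volume)
  } else {
    stopifnot(inherits(enumeration, "blend_enumeration"),
              ncol(enumeration$units) == composition$m,
              enumeration$total_units == total_units)
  }
  E <- blend_space(enumeration, B)
  if (!is.null(seed)) set.seed(seed)
  search <- doptimal_search(E, n_conditions, iters,
                            standardize_cols = standardize_det_cols)
  sel <- search$indices
  dispense <- enumeration$units[sel, , drop = FALSE]
  colnames(dispense) <- composition$media_ids
  rownames(dispense) <- sprintf("C%03d", seq_along(sel))
  scores <- E[sel, , drop = FALSE]
  rownames(scores) <- rownames(dispense)
  gd <- gram_determinant(scores, standardize_cols = standardize_det_cols)
  diag_ <- if (nrow(scores) >= ncol(scores) + 1L) {
    suppressWarnings(design_diagnostics(scores))
  } else NULL
  structure(list(indices = sel, dispense = dispense,
                 dispense_volume = dispense * enumeration$unit_volume,
                 scores = scores, gram_det = gd,
                 worst_indices = search$worst_indices,
                 worst_det = search$worst_det,
                 search_trace = search$search_trace,
                 diagnostics = diag_,
                 pca = B, standardized = A_std,
                 enumeration_k = enumeration$k,
                 total_units = enumeration$total_units,
                 unit_volume = enumeration$unit_volume,
                 common_medium_volume = common_medium_volume,
                 media_ids = composition$media_ids,
                 component_ids = composition$component_ids),
            class = "design_selection")
}

#' @export
print.design_selection <- function(x, ...) {
  cat(sprintf("D-optimal blending design: %d conditions from %d candidates (p = %d)\n",
              nrow(x$dispense), x$enumeration_k, ncol(x$scores)))
  cat(sprintf("  det(E'^T E') = %.4g\n", x$gram_det))
  if (!is.null(x$diagnostics))
    cat(sprintf("  max |r| = %.3f, mean |r| = %.3f, max VIF = %.2f\n",
                x$diagnostics$cor_summary$max_abs_r,
                x$diagnostics$cor_summary$mean_abs_r,
                x$diagnostics$max_vif))
  invisible(x)
}

#' Component concentrations of the designed conditions
#'
#' Theoretical relative concentration of every medium component in every
#' selected condition: the selected dispense rows times the composition
#' matrix, divided by the total units (i.e. the volume-weighted mean of the
#' blended mother media). These are the explanatory variables used for
#' regression modeling. A constant common-medium contribution, if any, is
#' identical across conditions and therefore omitted.
#'
#' @param design a `design_selection` from [design_blending()].
#' @param composition the [composition_matrix()] used for the design.
#' @return Numeric n x d matrix (conditions by components).
#' @export
condition_compositions <- function(design, composition) {
  stopifnot(inherits(design, "design_selection"),
            inherits(composition, "composition_matrix"))
  X <- (design$dispense %*% composition$values) / design$total_units
  rownames(X) <- rownames(design$dispense)
  X
}
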