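#' Configuration for mother-media simulation
#'
#' Parameters of the simulated design of a dedicated mother-media set:
#' candidate media matrices are drawn with discrete concentration levels,
#' screened by a correlation penalty (inner loop), and the surviving
#' candidates compete on the determinant of their designed blending
#' conditions (outer loop).
#'
#' @param n_media number of mother media m (default 11).
#' @param n_components number of components d (default 67).
#' @param levels number of discrete concentration levels; values are
#'   0..levels-1 (default 5).
#' @param inner_iters random candidates per outer iteration (default 1000).
#' @param outer_iters design-workflow iterations (default 100).
#' @param hard_r_threshold |r| above this incurs a high penalty
#'   (default 0.9).
#' @param soft_r_threshold |r| above this (and below the hard threshold)
#'   incurs a unit penalty (default 0.7).
#' @param n_conditions designed experimental conditions (default 120).
#' @param total_units,design_iters,var_threshold blending-design parameters
#'   passed through to [design_blending()] (defaults 6, 10000, 0.99).
#' @param inner_strategy how the inner loop uses its `inner_iters` random
#'   draws: `"swap"` (default) maintains a working media set and swaps in
#'   each freshly drawn medium wherever it reduces the penalty, selecting a
#'   low-penalty combination from the stream of generated media;
#'   `"regenerate"` draws a full fresh candidate set per iteration and
#'   keeps the single best.
#' @param seed optional integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_media = 11L, n_components = 67L, levels = 5L,
                              inner_iters = 1000L, outer_iters = 100L,
                              hard_r_threshold = 0.9, soft_r_threshold = 0.7,
                              n_conditions = 120L, total_units = 6L,
                              design_iters = 10000L, var_threshold = 0.99,
                              inner_strategy = c("swap", "regenerate"),
                              seed = NULL) {
  inner_strategy <- match.arg(inner_strategy)
  stopifnot(n_media >= 2L, n_components >= 2L, levels >= 1L,
            inner_iters >= 1L, outer_iters >= 1L,
            0 < soft_r_threshold, soft_r_threshold < hard_r_threshold,
            hard_r_threshold <= 1)
  structure(list(n_media = as.integer(n_media),
                 n_components = as.integer(n_components),
                 levels = as.integer(levels),
                 inner_iters = as.integer(inner_iters),
                 outer_iters = as.integer(outer_iters),
                 hard_r_threshold = hard_r_threshold,
                 soft_r_threshold = soft_r_threshold,
                 n_conditions = as.integer(n_conditions),
                 total_units = as.integer(total_units),
                 design_iters = as.integer(design_iters),
                 var_threshold = var_threshold,
                 inner_strategy = inner_strategy, seed = seed),
            class = "simulation_config")
}

#' Propose a random candidate mother-media set
#'
#' Draws every entry of the m x d composition matrix uniformly from the
#' discrete level set 0..levels-1 (via `floor(runif() * levels)`, the same
#' primitive the compiled screening loop consumes, so both paths share one
#' RNG stream).
#'
#' @param cfg a [simulation_config()].
#' @return A [composition_matrix()] candidate.
#' @export
propose_media <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  draws <- pmin(floor(runif(cfg$n_media * cfg$n_components) * cfg$levels),
                cfg$levels - 1L)
  vals <- matrix(draws, cfg$n_media, cfg$n_components)
  rownames(vals) <- sprintf("sim_medium_%02d", seq_len(cfg$n_media))
  colnames(vals) <- sprintf("component_%03d", seq_len(cfg$n_components))
  composition_matrix(vals)
}

#' Correlation penalty of a candidate mother-media set
#'
#' Three penalty rules, in lexicographic severity: zero-variance components
#' or media rows (high), component pairs with |r| above the hard threshold
#' (high), and pairs with |r| above the soft threshold (unit penalty each).
#' High-penalty violations are weighted by H = d^2 + 1, which exceeds any
#' possible count of soft violations, so any candidate with a high
#' violation scores strictly worse than any candidate with only soft ones.
#'
#' @param candidate a [composition_matrix()] (or plain matrix).
#' @param cfg a [simulation_config()].
#' @return A list with `zero_variance` (constant columns + constant rows),
#'   `hard_pairs`, `soft_pairs`, `high_weight`, `total`.
#' @export
media_penalty <- function(candidate, cfg) {
  vals <- if (inherits(candidate, "composition_matrix")) candidate$values
          else as.matrix(candidate)
  d <- ncol(vals)
  m <- nrow(vals)
  H <- d^2 + 1
  col_var <- colMeans(vals^2) - colMeans(vals)^2
  row_var <- rowMeans(vals^2) - rowMeans(vals)^2
  ok <- col_var > 1e-12
  zero_var <- sum(!ok) + sum(row_var <= 1e-12)
  hard <- 0L; soft <- 0L
  if (sum(ok) >= 2L) {
    r <- abs(cor(vals[, ok, drop = FALSE]))
    off <- r[upper.tri(r)]
    hard <- sum(off > cfg$hard_r_threshold)
    soft <- sum(off > cfg$soft_r_threshold & off <= cfg$hard_r_threshold)
  }
  list(zero_variance = zero_var, hard_pairs = hard, soft_pairs = soft,
       high_weight = H,
       total = H * (zero_var + hard) + soft)
}

#' Select a low-penalty candidate mother-media set
#'
#' Uses `inner_iters` random draws per the configuration's
#' `inner_strategy`. With `"swap"` (default) a working media set is
#' maintained and each freshly drawn medium replaces the row where it most
#' reduces the penalty (if any), selecting a low-penalty combination from
#' the stream of randomly generated media. With `"regenerate"`, a full
#' fresh candidate set is drawn each iteration and the minimum-penalty one
#' is kept (first encountered on ties). The screening loops run in
#' compiled code drawing the same R RNG stream as [propose_media()], so
#' with `"regenerate"` and `inner_iters = 1` this reproduces a single
#' [propose_media()] draw exactly; `use_reference = TRUE` forces the plain
#' R loop over [propose_media()]/[media_penalty()] (regenerate only).
#'
#' @param cfg a [simulation_config()].
#' @param use_reference run the uncompiled reference loop (default FALSE).
#' @return A list with `composition` (the winning candidate) and `penalty`
#'   (its [media_penalty()] breakdown).
#' @export
best_candidate <- function(cfg, use_reference = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (identical(cfg$inner_strategy, "swap")) {
    res <- swap_candidate_cpp(cfg$n_media, cfg$n_components, cfg$levels,
                              cfg$inner_iters, cfg$soft_r_threshold,
                              cfg$hard_r_threshold)
    vals <- res$values
    rownames(vals) <- sprintf("sim_medium_%02d", seq_len(cfg$n_media))
    colnames(vals) <- sprintf("component_%03d", seq_len(cfg$n_components))
    return(list(composition = composition_matrix(vals),
                penalty = list(zero_variance = res$zero_variance,
                               hard_pairs = res$hard_pairs,
                               soft_pairs = res$soft_pairs,
                               high_weight = cfg$n_components^2 + 1,
                               total = res$total)))
  }
  if (use_reference) {
    best <- NULL; best_pen <- NULL
    for (i in seq_len(cfg$inner_iters)) {
      cand <- propose_media(cfg)
      pen <- media_penalty(cand, cfg)
      if (is.null(best) || pen$total < best_pen$total) {
        best <- cand; best_pen <- pen
      }
    }
    return(list(composition = best, penalty = best_pen))
  }
  res <- best_candidate_cpp(cfg$n_media, cfg$n_components, cfg$levels,
                            cfg$inner_iters, cfg$soft_r_threshold,
                            cfg$hard_r_threshold)
  vals <- res$values
  rownames(vals) <- sprintf("sim_medium_%02d", seq_len(cfg$n_media))
  colnames(vals) <- sprintf("component_%03d", seq_len(cfg$n_components))
  list(composition = composition_matrix(vals),
       penalty = list(zero_variance = res$zero_variance,
                      hard_pairs = res$hard_pairs,
                      soft_pairs = res$soft_pairs,
                      high_weight = cfg$n_components^2 + 1,
                      total = res$total))
}

## Condition-level correlation metrics over the blended compositions.
## Fractions use the full pair count d(d-1)/2 as denominator (constant
## columns count as uncorrelated pairs).
pair_metrics <- function(X, threshold = 0.7) {
  d <- ncol(X)
  n_pairs <- d * (d - 1) / 2
  ok <- apply(X, 2L, stats::sd) > 0
  if (sum(ok) < 2L)
    return(list(mean_abs_r = 0, n_high = 0L, frac_high = 0, n_pairs = n_pairs))
  r <- abs(cor(X[, ok, drop = FALSE]))
  off <- r[upper.tri(r)]
  n_high <- sum(off > threshold)
  list(mean_abs_r = sum(off) / n_pairs, n_high = n_high,
       frac_high = n_high / n_pairs, n_pairs = n_pairs)
}

#' Simulate a dedicated mother-media set
#'
#' Runs `outer_iters` rounds of: pick the minimum-penalty candidate of
#' `inner_iters` random level assignments, then run the full blending
#' design workflow on it (standardize, PCA, enumerate, D-optimal random
#' search for `n_conditions`). The mother-media set whose designed
#' conditions achieve the maximal Gram determinant is returned, together
#' with correlation metrics at the media level (across the m media rows)
#' and at the condition level (across the designed blended compositions).
#'
#' @param cfg a [simulation_config()].
#' @return An object of class `simulated_media_set` with elements
#'   `composition`, `penalty`, `design`, `media_metrics`,
#'   `condition_metrics`, `outer_dets`.
#' @export
simulate_mother_media <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  k <- choose(cfg$n_media + cfg$total_units - 1, cfg$total_units)
  if (cfg$n_conditions > k)
    stop(sprintf("design infeasible: n_conditions = %d > k = %d",
                 cfg$n_conditions, k))
  enum <- enumerate_blends(cfg$n_media, cfg$total_units)
  best <- NULL
  outer_dets <- numeric(cfg$outer_iters)
  for (it in seq_len(cfg$outer_iters)) {
    cand <- best_candidate(cfg)
    des <- design_blending(cand$composition, cfg$n_conditions,
                           total_units = cfg$total_units,
                           iters = cfg$design_iters,
                           var_threshold = cfg$var_threshold,
                           enumeration = enum)
    outer_dets[it] <- des$gram_det
    if (is.null(best) || des$gram_det > best$design$gram_det)
      best <- list(composition = cand$composition, penalty = cand$penalty,
                   design = des)
  }
  media_m <- pair_metrics(best$composition$values, cfg$soft_r_threshold)
  Xc <- condition_compositions(best$design, best$composition)
  cond_m <- pair_metrics(Xc, cfg$soft_r_threshold)
  structure(c(best, list(media_metrics = media_m, condition_metrics = cond_m,
                         outer_dets = outer_dets, config = cfg)),
            class = "simulated_media_set")
}

#' @export
print.simulated_media_set <- function(x, ...) {
  cat(sprintf("Simulated mother-media set: %d media x %d components\n",
              x$composition$m, x$composition$d))
  cat(sprintf("  penalty: %d zero-variance, %d hard, %d soft pairs\n",
              x$penalty$zero_variance, x$penalty$hard_pairs, x$penalty$soft_pairs))
  cat(sprintf("  media-level |r|>%.1f fraction: %.4f%%\n",
              x$config$soft_r_threshold, 100 * x$media_metrics$frac_high))
  cat(sprintf("  condition-level mean |r| = %.3f, |r|>%.1f fraction = %.4f%% (%d pairs)\n",
              x$condition_metrics$mean_abs_r, x$config$soft_r_threshold,
              100 * x$condition_metrics$frac_high, x$condition_metrics$n_high))
  invisible(x)
}

#' Sweep condition-level correlation over components x media grids
#'
#' Runs a full [simulate_mother_media()] for every combination of component
#' count and media count, recording the fraction and absolute count of
#' highly correlated component pairs among the designed conditions. This
#' maps how many mother media are needed for a given screening breadth.
#'
#' @param components integer vector of component counts (e.g.
#'   `c(25, 50, 75, 100)`).
#' @param media_counts integer vector of media counts (e.g.
#'   `c(4, 6, 8, 10, 12)`).
#' @param cfg a [simulation_config()] providing all remaining parameters;
#'   its `n_media`/`n_components` are overridden cell by cell.
#' @param seed optional integer seed (re-seeded per cell for
#'   reproducibility of individual cells).
#' @return A data.frame with columns `n_components`, `n_media`,
#'   `mean_abs_r`, `n_high_pairs`, `frac_high`, `gram_det`.
#' @export
correlation_sweep <- function(components, media_counts, cfg, seed = NULL) {
  stopifnot(length(components) >= 1L, length(media_counts) >= 1L)
  grid <- expand.grid(n_components = components, n_media = media_counts)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell_cfg <- cfg
    cell_cfg$n_components <- as.integer(grid$n_components[i])
    cell_cfg$n_media <- as.integer(grid$n_media[i])
    cell_cfg$seed <- if (!is.null(seed)) seed + i else cfg$seed
    sim <- simulate_mother_media(cell_cfg)
    data.frame(n_components = cell_cfg$n_components,
               n_media = cell_cfg$n_media,
               mean_abs_r = sim$condition_metrics$mean_abs_r,
               n_high_pairs = sim$condition_metrics$n_high,
               frac_high = sim$condition_metrics$frac_high,
               gram_det = sim$design$gram_det)
  })
  do.call(rbind, rows)
}
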