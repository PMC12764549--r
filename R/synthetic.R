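#' Specification for synthetic composition and culture data
#'
#' Defines the statistical structure of generated data: a composition
#' matrix whose component pairs show a mixed correlation profile like that
#' of commercial chemically defined media (a tunable fraction of highly
#' correlated pairs, induced by a small number of latent factors), and a
#' culture response driven by a handful of truly active components with
#' condition- and replicate-level noise calibrated so that the
#' between-condition share of the total variance lands in a realistic band.
#'
#' @param m number of mother media (default 11).
#' @param d number of components (default 67).
#' @param target_high_corr_fraction target fraction of component pairs with
#'   |r| > 0.7 (default 0.12).
#' @param k_true number of truly active components (default 12).
#' @param effect_sizes numeric vector of length `k_true`; standardized
#'   effect magnitudes with alternating signs by default
#'   (`seq(1, 0.4, length.out = k_true)`).
#' @param condition_noise_sd condition-level noise, as a fraction of the
#'   signal standard deviation (default 0.5: the linear signal can explain
#'   at most ~80% of the between-condition variance).
#' @param ssb_target target between-condition share of the total sum of
#'   squares (default 0.8); replicate noise is solved to hit it.
#' @param replicates biological replicates per condition (default 3).
#' @param response_mean,response_sd location/scale of the final response,
#'   defaulting to a viable-cell-concentration-like range around
#'   1.26e7 +/- 2.9e6 cells/mL.
#' @param n_factors latent factors inducing the correlation structure
#'   (default 4).
#' @param seed optional integer seed stored for the generator.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(m = 11L, d = 67L, target_high_corr_fraction = 0.12,
                       k_true = 12L, effect_sizes = NULL,
                       condition_noise_sd = 0.5, ssb_target = 0.8,
                       replicates = 3L, response_mean = 1.26e7,
                       response_sd = 2.9e6, n_factors = 4L, seed = NULL) {
  stopifnot(m >= 2L, d >= 2L, k_true <= d, replicates >= 1L,
            target_high_corr_fraction >= 0, target_high_corr_fraction < 1,
            ssb_target > 0, ssb_target <= 1)
  if (is.null(effect_sizes))
    effect_sizes <- seq(1, 0.4, length.out = k_true) *
      rep_len(c(1, -1), k_true)
  stopifnot(length(effect_sizes) == k_true)
  structure(list(m = as.integer(m), d = as.integer(d),
                 target_high_corr_fraction = target_high_corr_fraction,
                 k_true = as.integer(k_true), effect_sizes = effect_sizes,
                 condition_noise_sd = condition_noise_sd,
                 ssb_target = ssb_target, replicates = as.integer(replicates),
                 response_mean = response_mean, response_sd = response_sd,
                 n_factors = as.integer(n_factors), seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic mother-media composition matrix
#'
#' Emulates the correlation profile of commercial chemically defined media
#' with a latent-factor model: every component loads on one of `n_factors`
#' latent factors, and the within-factor correlation is solved so that the
#' expected fraction of *sample* |r| > 0.7 pairs -- measured, like the
#' real profile, across only m media rows, where sample correlations are
#' noisy -- matches the target. Generation is retried (fresh draws) until
#' the achieved fraction is within +/- 0.05 of the target. Columns are
#' shifted to be nonnegative and given heterogeneous positive scales
#' (affine maps that leave Pearson correlations unchanged).
#'
#' @param spec a [synth_spec()].
#' @param seed optional integer seed (overrides `spec$seed`).
#' @param max_retries bounded retries before erroring (default 20).
#' @return A [composition_matrix()] with attribute `achieved_high_corr`
#'   (the measured fraction of |r| > 0.7 pairs).
#' @export
synth_composition <- function(spec, seed = spec$seed, max_retries = 20L) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(seed)) set.seed(seed)
  m <- spec$m; d <- spec$d
  target <- spec$target_high_corr_fraction
  group <- rep_len(seq_len(spec$n_factors), d)
  # With only m rows, sample correlations are noisy: a pair with moderate
  # true correlation rho often shows sample |r| > 0.7. Solve (via the
  # Fisher-z normal approximation) the within-factor rho for which the
  # expected fraction of sample |r| > 0.7 pairs matches the target, given
  # that only same-factor pairs are truly correlated.
  sg <- sum(choose(as.numeric(table(group)), 2)) / choose(d, 2)
  zc <- atanh(0.7)
  sz <- 1 / sqrt(max(m - 3, 1))
  q0 <- 2 * (1 - stats::pnorm(zc / sz))      # null pairs crossing 0.7
  q_need <- (target - (1 - sg) * q0) / sg
  rho <- if (target <= 0 || q_need <= 0) 0 else
    max(0, tanh(zc - qnorm(1 - min(q_need, 0.95)) * sz))
  bload <- sqrt(rho / (1 - rho))
  best_fail <- NULL
  for (try in seq_len(max_retries)) {
    f <- matrix(rnorm(m * spec$n_factors), m)
    z <- matrix(rnorm(m * d), m, d)
    vals <- bload * f[, group, drop = FALSE] + z
    # nonnegative shift and heterogeneous positive scale per component
    vals <- apply(vals, 2L, function(x) (x - min(x)))
    vals <- sweep(vals, 2L, exp(rnorm(d, 0, 1)), "*")
    rownames(vals) <- sprintf("synth_medium_%02d", seq_len(m))
    colnames(vals) <- sprintf("component_%03d", seq_len(d))
    r <- abs(cor(vals))
    achieved <- mean(r[upper.tri(r)] > 0.7)
    if (abs(achieved - target) <= 0.05) {
      out <- composition_matrix(vals)
      attr(out, "achieved_high_corr") <- achieved
      return(out)
    }
    if (is.null(best_fail) || abs(achieved - target) < abs(best_fail - target))
      best_fail <- achieved
  }
  stop(sprintf(
    "could not reach target high-correlation fraction %.3f within %d retries (best achieved %.3f)",
    target, max_retries, best_fail))
}

#' Generate a synthetic culture response for designed conditions
#'
#' The response is a linear function of `k_true` planted components
#' (standardized condition-level concentrations times the spec's effect
#' sizes), plus condition-level noise and replicate-level noise. The
#' replicate noise variance is solved analytically so that the
#' between-condition sum of squares is the spec's `ssb_target` share of the
#' total, then the response is affinely mapped to the spec's
#' viable-cell-concentration-like location and scale. Ground truth (which
#' components are active, with which effects) is returned separately from
#' the dataset so the analysis path never sees it.
#'
#' @param X condition x component concentration matrix (e.g. from
#'   [condition_compositions()]).
#' @param spec a [synth_spec()].
#' @param seed optional integer seed.
#' @return A list with `dataset` (a [culture_dataset()]) and `truth` (list
#'   with `planted`, `effects`, `ssb_tss`, `sigma_condition`,
#'   `sigma_replicate`).
#' @export
synth_response <- function(X, spec, seed = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  X <- as.matrix(X)
  if (!is.null(seed)) set.seed(seed)
  n_c <- nrow(X)
  usable <- which(apply(X, 2L, stats::sd) > 0)
  if (length(usable) < spec$k_true)
    stop("not enough non-constant components to plant effects in")
  planted <- sort(sample(usable, spec$k_true))
  Xs <- scale(X[, planted, drop = FALSE])
  if (anyNA(Xs)) stop("degenerate X: a planted component is constant")
  signal <- as.numeric(Xs %*% spec$effect_sizes)
  sd_sig <- stats::sd(signal)
  if (sd_sig < 1e-12)
    stop("planted effects produce a constant signal; nothing to recover")
  sigma_c <- spec$condition_noise_sd * sd_sig
  g <- signal + rnorm(n_c, 0, sigma_c)
  # replicate noise solved so E[SSB]/E[TSS] = ssb_target:
  # SSB ~ r*(n_c-1)*var(g) + (n_c-1)*s2, SSW ~ n_c*(r-1)*s2
  r <- spec$replicates
  rho <- spec$ssb_target
  u <- n_c - 1; w <- n_c * (r - 1)
  a <- r * u * var(g)
  denom <- rho * (u + w) - u
  sigma_r <- if (w == 0) 0 else {
    if (denom <= 0)
      stop("ssb_target unreachable with this replicate count")
    sqrt(a * (1 - rho) / denom)
  }
  y <- rep(g, each = r) + rnorm(n_c * r, 0, sigma_r)
  y <- spec$response_mean + (y - mean(y)) / stats::sd(y) * spec$response_sd
  cond <- rep(rownames(X) %||% sprintf("C%03d", seq_len(n_c)), each = r)
  ds <- culture_dataset(condition_id = cond,
                        replicate_id = rep(seq_len(r), times = n_c),
                        X = X[rep(seq_len(n_c), each = r), , drop = FALSE],
                        y = y)
  vb <- variance_breakdown(ds)
  list(dataset = ds,
       truth = list(planted = colnames(X)[planted],
                    effects = setNames(spec$effect_sizes, colnames(X)[planted]),
                    ssb_tss = vb$ssb / vb$tss,
                    sigma_condition = sigma_c, sigma_replicate = sigma_r))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Between/within-condition variance breakdown of a culture dataset
#'
#' Partitions the response's total sum of squares into the between-condition
#' part (SSB, sum of squares of condition means around the grand mean) and
#' the within-condition replicate part (SSW).
#'
#' @param ds a [culture_dataset()].
#' @return A list with `ssb`, `ssw`, `tss`.
#' @export
variance_breakdown <- function(ds) {
  stopifnot(inherits(ds, "culture_dataset"))
  gm <- mean(ds$y)
  means <- tapply(ds$y, ds$condition_id, mean)
  counts <- tapply(ds$y, ds$condition_id, length)
  ssb <- sum(counts * (means[names(counts)] - gm)^2)
  ssw <- sum((ds$y - means[ds$condition_id])^2)
  list(ssb = ssb, ssw = ssw, tss = ssb + ssw)
}
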