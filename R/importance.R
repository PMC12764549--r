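#' Permutation feature importance
#'
#' Measures how much the model's test-set R^2 drops when one explanatory
#' variable's values are randomly permuted, averaged over `J` independent
#' permutations: importance_i = bs - mean_j(s_ij), where bs is the
#' unpermuted (baseline) score. Variables the model does not rely on score
#' near zero. Note that with highly correlated variables plain permutation
#' importance is systematically underestimated -- a correlated partner
#' carries the same information and compensates for the shuffle; see
#' [adjusted_pfi()].
#'
#' @param model a `tuned_model` (or anything with a numeric `predict`).
#' @param X test sample x component matrix (>= 2 rows).
#' @param y test responses.
#' @param J number of shuffle repeats per variable (default 10).
#' @param seed optional integer seed.
#' @return An object of class `importance_table`: a data.frame with columns
#'   `component`, `baseline_score`, `mean_shuffled_score`, `importance`,
#'   `rank`; attributes `method` ("plain") and `J`.
#' @export
pfi <- function(model, X, y, J = 10L, seed = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("permutation importance needs at least 2 samples")
  if (J < 1L) stop("J must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  bs <- r_squared(y, predict(model, X))
  d <- ncol(X)
  mean_shuffled <- numeric(d)
  for (i in seq_len(d)) {
    s <- numeric(J)
    for (j in seq_len(J)) {
      Xp <- X
      Xp[, i] <- X[sample.int(nrow(X)), i]
      s[j] <- r_squared(y, predict(model, Xp))
    }
    mean_shuffled[i] <- mean(s)
  }
  importance_table(colnames(X), bs, mean_shuffled, method = "plain", J = J)
}

importance_table <- function(components, baseline, mean_shuffled, method, J) {
  imp <- baseline - mean_shuffled
  out <- data.frame(component = components,
                    baseline_score = baseline,
                    mean_shuffled_score = mean_shuffled,
                    importance = imp,
                    rank = rank(-imp, ties.method = "first"),
                    row.names = NULL)
  attr(out, "method") <- method
  attr(out, "J") <- J
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Shrunk pairwise correlations via Fisher's z confidence interval
#'
#' For each pair of explanatory variables the absolute Pearson correlation
#' r is transformed to z = atanh(r); z is treated as normal with variance
#' 1/(m - 3) (m = number of rows used), giving a confidence interval at
#' level `ci_alpha` that is back-transformed to correlation scale (L, U).
#' If the interval spans zero the correlation is considered incidental and
#' the shrunk value r' is 0; otherwise r' is the conservative lower bound
#' L. The r' matrix drives the co-shuffling probabilities of
#' [adjusted_pfi()].
#'
#' @param X numeric matrix with at least 4 rows.
#' @param ci_alpha significance level of the interval (default 0.05).
#' @return An object of class `correlation_shrinkage` with elements
#'   `r_matrix` (|r|, unit diagonal), `z_matrix`, `ci_alpha`, `sample_size`,
#'   `lower`, `upper`, `r_prime` (zero diagonal).
#' @export
shrunk_correlations <- function(X, ci_alpha = 0.05) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m <= 3L) stop("Fisher-z shrinkage needs sample size >= 4 (variance 1/(m-3))")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2L, stats::sd)
  r <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  ok <- sds > 0
  if (sum(ok) >= 2L) r[ok, ok] <- abs(cor(X[, ok, drop = FALSE]))
  diag(r) <- 1
  r_cl <- pmin(r, 1 - 1e-12)
  z <- atanh(r_cl)
  half <- qnorm(1 - ci_alpha / 2) / sqrt(m - 3)
  L <- tanh(z - half)
  U <- tanh(z + half)
  r_prime <- ifelse(L < 0 & U > 0, 0, L)
  r_prime <- pmax(r_prime, 0)
  diag(r_prime) <- 0
  structure(list(r_matrix = r, z_matrix = z, ci_alpha = ci_alpha,
                 sample_size = m, lower = L, upper = U, r_prime = r_prime),
            class = "correlation_shrinkage")
}

#' @export
print.correlation_shrinkage <- function(x, ...) {
  nz <- sum(x$r_prime[upper.tri(x$r_prime)] > 0)
  cat(sprintf("Shrunk correlations (m = %d, alpha = %g): %d pair(s) retained\n",
              x$sample_size, x$ci_alpha, nz))
  invisible(x)
}

#' Correlation-adjusted permutation feature importance
#'
#' Like [pfi()], but when variable p is permuted, every other variable q is
#' co-shuffled sample-by-sample with probability r'_{p,q} (the shrunk
#' correlation from [shrunk_correlations()]): for each test sample a fresh
#' uniform draw decides whether that sample's q value also takes the
#' permuted value, reusing p's permutation. With r' = 1 this reduces to
#' jointly permuting the pair, so a variable's correlated partners can no
#' longer compensate for its shuffle and the importance of correlated
#' predictive variables is not underestimated.
#'
#' @inheritParams pfi
#' @param shrink a `correlation_shrinkage` computed on the same variable
#'   set (column names must match).
#' @return An `importance_table` with method `"adjusted"`.
#' @export
adjusted_pfi <- function(model, X, y, shrink, J = 10L, seed = NULL) {
  X <- as.matrix(X)
  stopifnot(inherits(shrink, "correlation_shrinkage"))
  if (nrow(X) < 2L) stop("permutation importance needs at least 2 samples")
  if (!identical(colnames(X), rownames(shrink$r_prime)))
    stop("variable sets of X and the shrinkage object do not match")
  if (J < 1L) stop("J must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  bs <- r_squared(y, predict(model, X))
  n <- nrow(X); d <- ncol(X)
  mean_shuffled <- numeric(d)
  for (p in seq_len(d)) {
    partners <- which(shrink$r_prime[p, ] > 0)
    s <- numeric(J)
    for (j in seq_len(J)) {
      perm <- sample.int(n)
      Xp <- X
      Xp[, p] <- X[perm, p]
      for (q in partners) {
        sel <- runif(n) < shrink$r_prime[p, q]
        if (any(sel)) Xp[sel, q] <- X[perm[sel], q]
      }
      s[j] <- r_squared(y, predict(model, Xp))
    }
    mean_shuffled[p] <- mean(s)
  }
  importance_table(colnames(X), bs, mean_shuffled, method = "adjusted", J = J)
}

#' Consensus components across importance tables
#'
#' Takes the top fraction of components (by importance rank) in each
#' model's table and intersects them across models. Also reports tiered
#' membership: which components are common to all models within the top
#' 5%, 10%, ..., up to `top_fraction`.
#'
#' @param tables named list of `importance_table`s over the same component
#'   set (one per model, typically the superior models).
#' @param top_fraction fraction of components defining each model's top set
#'   (default 0.25).
#' @return A list with `consensus` (character vector), `top_n` (per-model
#'   set size), `per_model_top` (named list), `tiers` (named list of
#'   consensus sets at each tier fraction).
#' @export
consensus_components <- function(tables, top_fraction = 0.25) {
  stopifnot(length(tables) >= 1L)
  comp_sets <- lapply(tables, function(tb) tb$component[order(tb$rank)])
  d <- length(comp_sets[[1L]])
  top_at <- function(frac) {
    nn <- ceiling(frac * d)
    sets <- lapply(comp_sets, head, nn)
    Reduce(intersect, sets)
  }
  top_n <- ceiling(top_fraction * d)
  tier_fracs <- seq(0.05, top_fraction, by = 0.05)
  tiers <- lapply(tier_fracs, top_at)
  names(tiers) <- sprintf("top_%d%%", round(100 * tier_fracs))
  list(consensus = top_at(top_fraction),
       top_n = top_n,
       per_model_top = lapply(comp_sets, head, top_n),
       tiers = tiers)
}

#' Variable importance in projection (VIP) scores of a PLS model
#'
#' Standard VIP: the weighted share of the response variance explained by
#' each component's weight vector, scaled so that the mean squared VIP over
#' components equals 1. Available whenever partial least squares is among
#' the superior models, as an established cross-check of the adjusted
#' permutation importances.
#'
#' @param model a `tuned_model` with `model_name == "pls"`.
#' @return Named numeric vector of VIP scores (one per component of X).
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "tuned_model"))
  if (!identical(model$model_name, "pls"))
    stop("VIP scores are defined for PLS models only")
  fit <- model$fit
  H <- fit$.ncomp_used
  W <- fit$loadings$X[, seq_len(H), drop = FALSE]   # X weight vectors
  Tm <- fit$variates$X[, seq_len(H), drop = FALSE]  # X scores
  Yc <- scale(fit$Y)                                # centered/scaled response
  ss <- vapply(seq_len(H), function(h) {
    th <- Tm[, h]
    b <- sum(th * Yc) / sum(th * th)
    b^2 * sum(th * th)
  }, numeric(1L))
  d <- nrow(W)
  wnorm2 <- colSums(W^2)
  vip <- sqrt(d * as.numeric((W^2 %*% (ss / wnorm2))) / sum(ss))
  names(vip) <- rownames(W)
  vip
}
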