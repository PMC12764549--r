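## a minimal tuned_model wrapper around a fixed prediction function
fn_model <- function(f) {
  structure(list(model_name = "fn", params = list(), fit = f,
                 .predict = function(fit, X) fit(X)),
            class = "tuned_model")
}

test_that("permutation importance is near zero for unused features and exact for a tiny oracle", {
  set.seed(1)
  n <- 120
  X <- cbind(a = runif(n), b = runif(n))
  y <- 3 * X[, "a"] + rnorm(n, 0, 0.1)
  model <- fn_model(function(X) 3 * X[, "a"])  # ignores b entirely
  tab <- pfi(model, X, y, J = 20, seed = 2)
  expect_lt(abs(tab$importance[tab$component == "b"]), 0.01)
  expect_gt(tab$importance[tab$component == "a"], 0.5)

  # exhaustive-permutation oracle at n = 5: the mean shuffled R^2 over all
  # 5! permutations fixes the expected importance of the single feature
  x5 <- c(0.3, 1.1, 2.0, 2.8, 4.0)
  y5 <- 2 * x5
  m5 <- fn_model(function(X) 2 * X[, 1])
  perms <- all_perms(5)
  shuffled_r2 <- vapply(perms, function(p) r_squared(y5, 2 * x5[p]), numeric(1))
  oracle <- r_squared(y5, y5) - mean(shuffled_r2)
  X5 <- matrix(x5, dimnames = list(NULL, "x"))
  tab5 <- pfi(m5, X5, y5, J = 4000, seed = 3)
  se <- sd(shuffled_r2) / sqrt(4000)
  expect_equal(tab5$importance, oracle, tolerance = 6 * se + 1e-8)

  expect_error(pfi(m5, X5[1, , drop = FALSE], y5[1]), "at least 2 samples")
})

test_that("Fisher-z shrinkage matches closed forms and behaves as a confidence bound", {
  expect_equal(atanh(0.5), 0.5 * log(3))
  X <- cbind(a = rnorm(20), b = rnorm(20))
  sh <- shrunk_correlations(X, 0.05)
  expect_identical(sh$sample_size, 20L)
  expect_equal(unname(diag(sh$r_prime)), c(0, 0))
  # z matrix is the Fisher transform of |r|
  expect_equal(sh$z_matrix[1, 2], atanh(abs(cor(X))[1, 2]), tolerance = 1e-12)

  # an (almost) zero correlation always has a CI spanning zero
  set.seed(4)
  Z <- cbind(x = rnorm(200), y = rnorm(200))
  shz <- shrunk_correlations(Z)
  expect_equal(shz$r_prime[1, 2], 0)

  # monotone in sample size for fixed r > 0
  r_fixed <- 0.6
  lower_at <- function(m) {
    z <- atanh(r_fixed)
    tanh(z - qnorm(0.975) / sqrt(m - 3))
  }
  ms <- c(10, 30, 100, 300)
  expect_true(all(diff(vapply(ms, lower_at, numeric(1))) > 0))
  shr_small <- shrunk_correlations(matrix(rnorm(8), 4), 0.05)
  expect_s3_class(shr_small, "correlation_shrinkage")
  expect_error(shrunk_correlations(matrix(rnorm(6), 3)), "sample size")
})

test_that("the shrunk interval is a valid confidence interval for rho = 0.9, m = 144", {
  # Monte-Carlo oracle: coverage of [L, U] for the true correlation
  set.seed(5)
  rho <- 0.9; m <- 144
  hits <- 0L; n_sims <- 300L
  for (i in seq_len(n_sims)) {
    z1 <- rnorm(m); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
    sh <- shrunk_correlations(cbind(z1, z2), 0.05)
    if (sh$lower[1, 2] <= rho && rho <= sh$upper[1, 2]) hits <- hits + 1L
    # the shrunk value is the conservative lower bound when retained
    expect_lte(sh$r_prime[1, 2], sh$r_matrix[1, 2])
  }
  expect_gt(hits / n_sims, 0.90)
  expect_lt(hits / n_sims, 0.99)
})

test_that("adjusted PFI reduces to plain PFI when no correlations are retained", {
  set.seed(6)
  n <- 80
  X <- cbind(a = runif(n), b = runif(n), c = runif(n))
  y <- 2 * X[, "a"] - X[, "b"] + rnorm(n, 0, 0.2)
  model <- fn_model(function(X) 2 * X[, "a"] - X[, "b"])
  sh <- shrunk_correlations(X)
  sh$r_prime[] <- 0
  p1 <- pfi(model, X, y, J = 15, seed = 7)
  p2 <- adjusted_pfi(model, X, y, sh, J = 15, seed = 7)
  expect_equal(p2$importance, p1$importance, tolerance = 0.05)
})

test_that("a unit shrunk correlation equals jointly permuting the pair", {
  set.seed(8)
  n <- 60
  X <- cbind(a = runif(n), b = runif(n))
  y <- X[, "a"] + X[, "b"] + rnorm(n, 0, 0.1)
  model <- fn_model(function(X) X[, "a"] + X[, "b"])
  sh <- shrunk_correlations(X)
  sh$r_prime[] <- 0
  sh$r_prime["a", "b"] <- 1  # b always co-shuffled with a
  J <- 5
  adj <- adjusted_pfi(model, X, y, sh, J = J, seed = 9)
  # oracle: explicit joint permutation drawing the identical RNG stream
  set.seed(9)
  bs <- r_squared(y, predict(model, X))
  s <- numeric(J)
  for (j in seq_len(J)) {
    perm <- sample.int(n)
    runif(n)  # the per-sample gating draws (all below r' = 1)
    s[j] <- r_squared(y, predict(model, X[perm, , drop = FALSE]))
  }
  expect_equal(adj$importance[adj$component == "a"], bs - mean(s),
               tolerance = 1e-12)
})

test_that("adjusted PFI rescues duplicated predictive features", {
  fx <- make_duplicate_fixture()
  sh <- shrunk_correlations(fx$train$X)
  expect_gt(sh$r_prime["dup1", "dup2"], 0.99)
  plain <- pfi(fx$model, fx$test$X, fx$test$y, J = 10, seed = 11)
  adj <- adjusted_pfi(fx$model, fx$test$X, fx$test$y, sh, J = 10, seed = 11)
  dups <- paste0("dup", 1:5)
  for (dd in dups) {
    p <- plain$importance[plain$component == dd]
    a <- adj$importance[adj$component == dd]
    expect_gte(a, p)
    expect_gt(a, 0.3)
  }
})

test_that("plain PFI of an independent noise feature is unbiased around zero", {
  set.seed(12)
  n <- 300
  X <- cbind(sig = runif(n), noise = runif(n))
  y <- 2 * X[, "sig"] + rnorm(n, 0, 0.2)
  ds <- culture_dataset(paste0("c", 1:n), rep(1, n), X, y)
  sp <- grouped_split(ds, 0.6, seed = 1)
  tm <- tune_and_fit("ridge", sp$train, folds = 3, seed = 2,
                     grid = list(list(lambda = 0.02)))
  imps <- vapply(1:50, function(i) {
    tab <- pfi(tm, sp$test$X, sp$test$y, J = 1, seed = 100 + i)
    tab$importance[tab$component == "noise"]
  }, numeric(1))
  expect_lt(abs(mean(imps)), 2 * sd(imps) / sqrt(50))
})

test_that("consensus intersects per-model top sets with tier labels", {
  mk <- function(scores) {
    tab <- data.frame(component = paste0("c", seq_along(scores)),
                      baseline_score = 1, mean_shuffled_score = 1 - scores,
                      importance = scores,
                      rank = rank(-scores, ties.method = "first"))
    class(tab) <- c("importance_table", "data.frame")
    tab
  }
  d <- 67
  s1 <- seq(d, 1); s2 <- s1
  cons <- consensus_components(list(a = mk(s1), b = mk(s2)), 0.25)
  expect_identical(cons$top_n, 17)
  expect_length(cons$consensus, 17)

  # single model: consensus is its own top set
  c1 <- consensus_components(list(a = mk(s1)), 0.25)
  expect_identical(c1$consensus, paste0("c", 1:17))

  # disjoint top sets give an empty consensus
  s3 <- seq_len(d)
  c2 <- consensus_components(list(a = mk(s1), b = mk(s3)), 0.1)
  expect_length(c2$consensus, 0)
  expect_named(c2$tiers, c("top_5%", "top_10%"))
})

test_that("VIP scores match the established implementation and normalize to 1", {
  ds <- local({
    set.seed(13)
    n <- 90
    X <- matrix(runif(n * 6, 0, 3), n, 6,
                dimnames = list(NULL, paste0("c", 1:6)))
    y <- 2 * X[, 1] - X[, 2] + rnorm(n, 0, 0.3)
    culture_dataset(paste0("s", 1:n), rep(1, n), X, y)
  })
  tm <- tune_and_fit("pls", ds, folds = 3, seed = 14,
                     grid = list(list(ncomp = 3)))
  v <- vip_scores(tm)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  ref <- mixOmics::vip(tm$fit)[, tm$fit$.ncomp_used]
  expect_equal(v, ref, tolerance = 1e-6)
  expect_true(which.max(v) %in% 1:2)

  ridge <- tune_and_fit("ridge", ds, folds = 3, seed = 15,
                        grid = list(list(lambda = 0.05)))
  expect_error(vip_scores(ridge), "PLS")
})
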