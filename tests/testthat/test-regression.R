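make_linear_dataset <- function(n_cond = 40, d = 8, reps = 2, noise = 0.3,
                                seed = 1) {
  set.seed(seed)
  Xc <- matrix(runif(n_cond * d, 0, 4), n_cond, d,
               dimnames = list(NULL, paste0("c", seq_len(d))))
  beta <- c(2, -1, 0.5, rep(0, d - 3))
  g <- as.numeric(Xc %*% beta)
  y <- rep(g, each = reps) + rnorm(n_cond * reps, 0, noise * sd(g))
  culture_dataset(rep(paste0("cond", seq_len(n_cond)), each = reps),
                  rep(seq_len(reps), n_cond),
                  Xc[rep(seq_len(n_cond), each = reps), ], y)
}

test_that("grouped splits separate conditions exactly and hit the target fraction", {
  ds <- make_linear_dataset(n_cond = 120, reps = 3)
  sp <- grouped_split(ds, 0.6, seed = 2)
  expect_identical(sp$train$n_conditions, 72L)
  expect_identical(sp$test$n_conditions, 48L)
  expect_length(intersect(sp$train$condition_id, sp$test$condition_id), 0)

  two <- make_linear_dataset(n_cond = 2, reps = 2)
  sp2 <- grouped_split(two, 0.5, seed = 1)
  expect_identical(sp2$train$n_conditions, 1L)
  expect_identical(sp2$test$n_conditions, 1L)

  one <- culture_dataset(rep("c1", 3), 1:3, matrix(runif(24), 3, 8), runif(3))
  expect_error(grouped_split(one, 0.6), "at least 2 conditions")
})

test_that("metrics match hand computations", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(mse(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("hyperparameter tuning follows the mean-minus-sd criterion", {
  ds <- make_linear_dataset(seed = 3)
  # single grid point: chosen trivially
  tm1 <- tune_and_fit("ridge", ds, folds = 3, seed = 1,
                      grid = list(list(lambda = 0.02)))
  expect_equal(tm1$params$lambda, 0.02)

  # a dominant setting (sane penalty vs absurd penalty) wins on every fold
  tm2 <- tune_and_fit("ridge", ds, folds = 3, seed = 1,
                      grid = list(list(lambda = 1e6), list(lambda = 0.02)))
  expect_equal(tm2$params$lambda, 0.02)
  expect_identical(which.max(tm2$cv_results$criterion), 2L)

  expect_error(tune_and_fit("not_a_model", ds), "unknown model")
})

test_that("chosen ridge penalty is near-optimal under independent grid re-scoring", {
  ds <- make_linear_dataset(n_cond = 60, seed = 4)
  grid <- lapply(10^seq(-3, 2, length.out = 6), function(l) list(lambda = l))
  seed <- 11
  tm <- tune_and_fit("ridge", ds, folds = 5, seed = seed, grid = grid)
  # independent re-evaluation of every grid point over the same folds
  set.seed(seed)
  fold_id <- mediablend:::grouped_folds(ds$condition_id, 5)
  mean_r2 <- vapply(grid, function(g) {
    r2 <- vapply(1:5, function(f) {
      tr <- fold_id != f
      fit <- glmnet::glmnet(ds$X[tr, ], ds$y[tr], alpha = 0, lambda = g$lambda)
      r_squared(ds$y[!tr], as.numeric(predict(fit, ds$X[!tr, ])))
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  chosen <- which(vapply(grid, function(g) g$lambda, numeric(1)) ==
                    tm$params$lambda)
  expect_gte(mean_r2[chosen], max(mean_r2) - 0.05)
})

test_that("every algorithm in the suite fits and predicts under the protocol", {
  ds <- make_linear_dataset(n_cond = 30, d = 6, reps = 2, seed = 5)
  small_grids <- list(
    rf = list(list(mtry = 2, min_node = 5)),
    gbdt = list(list(nrounds = 40, max_depth = 2, eta = 0.1)),
    xgb = list(list(nrounds = 40, max_depth = 2, eta = 0.3)),
    gpr_rbf = list(list(var = 0.01, sigma = 0.2)),
    gpr_linear = list(list(var = 0.01)),
    svr_rbf = list(list(cost = 10, gamma = 0.2)),
    svr_linear = list(list(cost = 10)),
    pls = list(list(ncomp = 2)),
    ridge = list(list(lambda = 0.05)),
    lasso = list(list(lambda = 0.05)),
    enet = list(list(lambda = 0.05))
  )
  for (mn in model_names()) {
    tm <- tune_and_fit(mn, ds, folds = 3, seed = 7, grid = small_grids[[mn]])
    ev <- evaluate_model(tm, ds$X, ds$y)
    expect_gt(ev$r2, 0.3)
  }
})

test_that("baseline comparison yields p near 1 for a baseline-equivalent model", {
  ds <- make_linear_dataset(n_cond = 40, seed = 6)
  sp <- grouped_split(ds, 0.6, seed = 3)
  const_model <- structure(
    list(model_name = "const", params = list(), fit = mean(sp$train$y),
         .predict = function(fit, X) rep(fit, nrow(X))),
    class = "tuned_model")
  ridge <- tune_and_fit("ridge", sp$train, folds = 3, seed = 1,
                        grid = list(list(lambda = 0.02)))
  cmp <- compare_to_baseline(list(const = const_model, ridge = ridge),
                             sp$train, sp$test, n_subsets = 5, seed = 8)
  expect_gte(cmp$p_raw[cmp$model == "const"], 0.99)
  expect_lt(cmp$p_raw[cmp$model == "ridge"], 0.05)
  # Holm step-down applied across the candidate models
  expect_equal(cmp$p_holm, p.adjust(cmp$p_raw, "holm"))
  expect_error(compare_to_baseline(list(ridge = ridge), sp$train, sp$test,
                                   n_subsets = 1), "at least 2")
})

test_that("superior-model selection enforces significance and the generalizability band", {
  base <- data.frame(model = c("a", "b", "c"),
                     r2_train = c(0.6, 0.8, 0.6),
                     r2_test = c(0.6, 0.5, 0.6),
                     mse_train = c(1, 1, 1),
                     mse_test = c(1, 1.6, 1),
                     p_holm = c(0.001, 0.001, 0.2))
  out <- select_superior(base, alpha = 0.05, band = 0.15)
  expect_identical(out$superior, c(TRUE, FALSE, FALSE))
  expect_equal(out$r2_ratio[2], 1.6)
})

test_that("the grouped protocol keeps the baseline near zero test R^2 and finds linear structure", {
  ds <- make_linear_dataset(n_cond = 60, reps = 3, noise = 0.2, seed = 9)
  suite <- run_model_suite(ds, models = c("ridge", "lasso"), seed = 10)
  sp <- suite$split
  base_r2 <- r_squared(sp$test$y, rep(mean(sp$train$y), sp$test$n_samples))
  expect_lt(abs(base_r2), 0.25)
  # every linear model clearly beats the baseline on linear-truth data,
  # and its train/test metric ratios center near 1 (the ratios themselves
  # carry ~20% sampling noise at this test-set size)
  expect_true(all(suite$reports$p_holm < 0.05))
  expect_lt(abs(mean(suite$reports$r2_ratio) - 1), 0.25)
  expect_lt(abs(mean(suite$reports$mse_ratio) - 1), 0.35)
  # no leakage anywhere
  expect_length(intersect(sp$train$condition_id, sp$test$condition_id), 0)
})
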