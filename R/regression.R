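#' Construct a culture dataset
#'
#' Holds one row per cultured sample: the condition it belongs to, the
#' replicate index, the theoretical relative concentrations of each medium
#' component (explanatory variables X), and the measured response y (e.g.
#' viable cell concentration at harvest). Replicates of the same condition
#' share identical X rows; every grouped operation in the modeling protocol
#' splits at the condition level so replicates never leak across partitions.
#'
#' @param condition_id vector of condition labels, one per sample.
#' @param replicate_id vector of replicate labels, one per sample.
#' @param X numeric sample x component matrix, nonnegative.
#' @param y numeric response vector, no missing values.
#' @return An object of class `culture_dataset`.
#' @export
culture_dataset <- function(condition_id, replicate_id, X, y) {
  X <- as.matrix(X)
  condition_id <- as.character(condition_id)
  replicate_id <- as.character(replicate_id)
  n <- length(condition_id)
  if (nrow(X) != n || length(y) != n || length(replicate_id) != n)
    stop("condition_id, replicate_id, X rows and y must have equal length")
  if (anyNA(y)) stop("missing response values are not allowed")
  if (anyNA(X) || any(X < 0)) stop("X must be complete and nonnegative")
  if (is.null(colnames(X))) colnames(X) <- paste0("component_", seq_len(ncol(X)))
  structure(list(condition_id = condition_id, replicate_id = replicate_id,
                 X = X, y = as.numeric(y), n_samples = n,
                 n_conditions = length(unique(condition_id))),
            class = "culture_dataset")
}

#' @export
print.culture_dataset <- function(x, ...) {
  cat(sprintf("Culture dataset: %d samples, %d conditions, %d components\n",
              x$n_samples, x$n_conditions, ncol(x$X)))
  invisible(x)
}

#' Read/write a culture dataset CSV
#'
#' Layout: columns `condition_id`, `replicate_id`, `response`, then one
#' column per component.
#'
#' @param path CSV path.
#' @return [culture_dataset()] for `read_culture`; `path` invisibly for
#'   `write_culture`.
#' @export
read_culture <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("condition_id", "replicate_id", "response")
  if (!all(need %in% names(df)))
    stop("culture CSV must have columns: ", paste(need, collapse = ", "))
  comp <- setdiff(names(df), need)
  culture_dataset(df$condition_id, df$replicate_id,
                  as.matrix(df[, comp, drop = FALSE]), df$response)
}

#' @param ds a [culture_dataset()].
#' @rdname read_culture
#' @export
write_culture <- function(ds, path) {
  stopifnot(inherits(ds, "culture_dataset"))
  df <- data.frame(condition_id = ds$condition_id, replicate_id = ds$replicate_id,
                   response = ds$y, ds$X, check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

subset_culture <- function(ds, idx) {
  culture_dataset(ds$condition_id[idx], ds$replicate_id[idx],
                  ds$X[idx, , drop = FALSE], ds$y[idx])
}

#' Grouped train/test split of a culture dataset
#'
#' Splits at the condition level: a condition's replicates all go to the
#' same partition, so no information leaks between training and test data
#' through shared conditions.
#'
#' @param ds a [culture_dataset()].
#' @param train_fraction target fraction of conditions in the training set
#'   (default 0.6, the 6:4 protocol).
#' @param seed optional integer seed.
#' @return List with `train` and `test` culture datasets.
#' @export
grouped_split <- function(ds, train_fraction = 0.6, seed = NULL) {
  stopifnot(inherits(ds, "culture_dataset"))
  conds <- unique(ds$condition_id)
  if (length(conds) < 2L) stop("need at least 2 conditions to split")
  if (!is.null(seed)) set.seed(seed)
  n_train <- round(train_fraction * length(conds))
  n_train <- max(1L, min(length(conds) - 1L, n_train))
  train_conds <- sample(conds, n_train)
  in_train <- ds$condition_id %in% train_conds
  list(train = subset_culture(ds, which(in_train)),
       test = subset_culture(ds, which(!in_train)))
}

#' Coefficient of determination and mean squared error
#'
#' `r_squared` is 1 minus the ratio of residual to total sum of squares;
#' `mse` is the mean squared prediction error.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return A single numeric value.
#' @export
r_squared <- function(y, yhat) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("R^2 undefined: response has zero variance")
  1 - sum((y - yhat)^2) / tss
}

#' @rdname r_squared
#' @export
mse <- function(y, yhat) mean((y - yhat)^2)

## ---- model registry ---------------------------------------------------

## Each entry: grid(X, y) -> list of named parameter lists;
##             fit(X, y, params) -> fitted object;
##             predict(fit, X) -> numeric vector.
## Grids are deliberately small defaults; pass `grids` to override.
model_registry <- function() {
  list(
    ridge = glmnet_entry(alpha = 0),
    lasso = glmnet_entry(alpha = 1),
    enet  = glmnet_entry(alpha = 0.5),
    pls = list(
      grid = function(X, y) {
        # blending X is rank deficient (conditions are mixtures of few
        # media); components beyond the rank are degenerate
        r <- qr(scale(X))$rank
        lapply(seq_len(max(1L, min(8L, ncol(X), nrow(X) - 2L, r - 1L))),
               function(nc) list(ncomp = nc))
      },
      fit = function(X, y, params) {
        X <- as.matrix(X)
        rownames(X) <- paste0("s", seq_len(nrow(X)))  # mixOmics requires ids
        fit <- mixOmics::pls(X, y, ncomp = params$ncomp, mode = "regression",
                             scale = TRUE)
        fit$.ncomp_used <- params$ncomp
        fit
      },
      predict = function(fit, X) {
        X <- as.matrix(X)
        rownames(X) <- paste0("s", seq_len(nrow(X)))
        as.numeric(predict(fit, X)$predict[, 1L, fit$.ncomp_used])
      }
    ),
    svr_linear = list(
      grid = function(X, y) lapply(c(0.1, 1, 10, 100), function(cc) list(cost = cc)),
      fit = function(X, y, params)
        e1071::svm(x = X, y = y, kernel = "linear", cost = params$cost),
      predict = function(fit, X) as.numeric(predict(fit, X))
    ),
    svr_rbf = list(
      grid = function(X, y) {
        gam <- c(0.5, 2) / ncol(X)
        do.call(c, lapply(c(0.1, 1, 10, 100), function(cc)
          lapply(gam, function(g) list(cost = cc, gamma = g))))
      },
      fit = function(X, y, params)
        e1071::svm(x = X, y = y, kernel = "radial", cost = params$cost,
                   gamma = params$gamma),
      predict = function(fit, X) as.numeric(predict(fit, X))
    ),
    gpr_linear = list(
      grid = function(X, y) lapply(c(0.001, 0.01, 0.1, 1), function(v) list(var = v)),
      fit = function(X, y, params)
        kernlab::gausspr(x = X, y = y, kernel = kernlab::vanilladot(),
                         var = params$var, scaled = TRUE),
      predict = function(fit, X) as.numeric(kernlab::predict(fit, X))
    ),
    gpr_rbf = list(
      grid = function(X, y) {
        sig <- c(0.5, 2) / ncol(X)
        do.call(c, lapply(c(0.001, 0.01, 0.1), function(v)
          lapply(sig, function(s) list(var = v, sigma = s))))
      },
      fit = function(X, y, params)
        kernlab::gausspr(x = X, y = y,
                         kernel = kernlab::rbfdot(sigma = params$sigma),
                         var = params$var, scaled = TRUE),
      predict = function(fit, X) as.numeric(kernlab::predict(fit, X))
    ),
    rf = list(
      grid = function(X, y) {
        mtry <- unique(pmax(1L, floor(ncol(X) * c(1 / 3, 2 / 3))))
        do.call(c, lapply(mtry, function(mt)
          lapply(c(1L, 5L), function(ns) list(mtry = mt, min_node = ns))))
      },
      fit = function(X, y, params)
        ranger::ranger(y = y, x = as.data.frame(X), num.trees = 500L,
                       mtry = params$mtry, min.node.size = params$min_node,
                       num.threads = 1L,
                       seed = sample.int(.Machine$integer.max, 1L)),
      predict = function(fit, X)
        predict(fit, data = as.data.frame(X), num.threads = 1L)$predictions
    ),
    gbdt = xgb_entry(classic = TRUE),
    xgb = xgb_entry(classic = FALSE)
  )
}

glmnet_entry <- function(alpha) {
  force(alpha)
  list(
    grid = function(X, y) {
      lam <- stats::sd(y) * 10^seq(-4, 0, length.out = 8L)
      lapply(lam, function(l) list(lambda = l))
    },
    fit = function(X, y, params)
      glmnet::glmnet(X, y, alpha = alpha, lambda = params$lambda),
    predict = function(fit, X) as.numeric(predict(fit, X))
  )
}

xgb_entry <- function(classic) {
  force(classic)
  list(
    grid = function(X, y) {
      if (classic) {
        do.call(c, lapply(c(100L, 300L), function(nr)
          lapply(c(2L, 3L), function(md) list(nrounds = nr, max_depth = md,
                                              eta = 0.05))))
      } else {
        do.call(c, lapply(c(50L, 150L), function(nr)
          do.call(c, lapply(c(2L, 4L), function(md)
            lapply(c(0.1, 0.3), function(e)
              list(nrounds = nr, max_depth = md, eta = e))))))
      }
    },
    fit = function(X, y, params) {
      pars <- list(max_depth = params$max_depth, eta = params$eta,
                   nthread = 1L, seed = sample.int(.Machine$integer.max, 1L))
      if (classic) {
        # classical gradient-boosted trees: no L1/L2 shrinkage, full sampling
        pars$lambda <- 0; pars$alpha <- 0
        pars$subsample <- 1; pars$colsample_bytree <- 1
      }
      xgboost::xgb.train(params = pars,
                         data = xgboost::xgb.DMatrix(as.matrix(X), label = y,
                                                     nthread = 1L),
                         nrounds = params$nrounds, verbose = 0L)
    },
    predict = function(fit, X)
      as.numeric(predict(fit, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1L)))
  )
}

#' Names of the supported regression algorithms
#'
#' The suite covers three modeling assumptions: tree ensembles for drastic
#' changes (`rf`, `gbdt`, `xgb`), kernel methods for smooth nonlinearity
#' (`gpr_rbf`, `svr_rbf`), and linear structure (`pls`, `ridge`, `lasso`,
#' `enet`, `svr_linear`, `gpr_linear`).
#'
#' @return Character vector of model names.
#' @export
model_names <- function() names(model_registry())

#' @export
#' @rdname model_names
linear_model_names <- function() c("pls", "ridge", "lasso", "enet")

## Assign conditions to k folds, shuffled; returns per-sample fold index.
grouped_folds <- function(condition_id, folds) {
  conds <- unique(condition_id)
  if (length(conds) < folds) stop("fewer conditions than folds")
  fold_of <- setNames(rep_len(seq_len(folds), length(conds)), sample(conds))
  unname(fold_of[condition_id])
}

#' Tune and fit one model under the grouped cross-validation protocol
#'
#' Hyperparameters are selected by grouped k-fold cross-validation on the
#' training set (conditions are never split across folds). Each grid point
#' is scored by the mean minus the standard deviation of the validation R^2
#' across folds -- a pessimistic criterion that favors settings that are
#' both accurate and stable -- and the best point (first on ties) is refit
#' on the full training set.
#'
#' @param model_name one of [model_names()].
#' @param train a [culture_dataset()].
#' @param folds number of CV folds (default 5).
#' @param seed optional integer seed (controls fold assignment and any
#'   stochastic fitting).
#' @param grid optional list of named parameter lists overriding the
#'   default grid.
#' @return An object of class `tuned_model` with elements `model_name`,
#'   `params`, `fit`, `cv_results` (data.frame of grid scores),
#'   `cv_score`.
#' @export
tune_and_fit <- function(model_name, train, folds = 5L, seed = NULL,
                         grid = NULL) {
  reg <- model_registry()
  if (!model_name %in% names(reg))
    stop("unknown model '", model_name, "'; valid: ",
         paste(names(reg), collapse = ", "))
  stopifnot(inherits(train, "culture_dataset"), folds >= 2L)
  entry <- reg[[model_name]]
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) grid <- entry$grid(train$X, train$y)
  fold_id <- grouped_folds(train$condition_id, folds)
  scores <- matrix(NA_real_, length(grid), folds)
  for (gi in seq_along(grid)) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- entry$fit(train$X[tr, , drop = FALSE], train$y[tr], grid[[gi]])
      yhat <- entry$predict(fit, train$X[!tr, , drop = FALSE])
      scores[gi, f] <- r_squared(train$y[!tr], yhat)
    }
  }
  crit <- rowMeans(scores) - apply(scores, 1L, sd)
  best <- which.max(crit)
  fit <- entry$fit(train$X, train$y, grid[[best]])
  cv <- data.frame(grid_point = seq_along(grid),
                   mean_r2 = rowMeans(scores),
                   sd_r2 = apply(scores, 1L, sd),
                   criterion = crit)
  structure(list(model_name = model_name, params = grid[[best]], fit = fit,
                 cv_results = cv, cv_score = crit[best],
                 .predict = entry$predict),
            class = "tuned_model")
}

#' @export
predict.tuned_model <- function(object, newdata, ...) {
  object$.predict(object$fit, as.matrix(newdata))
}

#' @export
print.tuned_model <- function(x, ...) {
  cat(sprintf("Tuned %s model; CV criterion (mean - SD of validation R^2) = %.3f\n",
              x$model_name, x$cv_score))
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a fitted model on a dataset
#'
#' @param model a `tuned_model` (or any object with a `predict` method
#'   returning a numeric vector).
#' @param X sample x component matrix.
#' @param y observed responses (non-constant).
#' @return List with `r2` and `mse`.
#' @export
evaluate_model <- function(model, X, y) {
  yhat <- predict(model, X)
  list(r2 = r_squared(y, yhat), mse = mse(y, yhat))
}

#' Compare models to the predict-the-mean baseline on test subsets
#'
#' The test set is partitioned (grouped by condition) into `n_subsets`
#' random subsets; each model's MSE and the baseline's MSE (predicting the
#' training-set mean response) are computed per subset, and each model is
#' compared to the baseline by a one-sided paired t-test (model MSE lower).
#' The p-values are Holm-adjusted across models.
#'
#' @param models named list of `tuned_model` objects.
#' @param train,test culture datasets from [grouped_split()].
#' @param n_subsets number of test subsets (default 5).
#' @param seed optional integer seed for the subset partition.
#' @param alpha significance level recorded in the result (default 0.05).
#' @return A data.frame with one row per model: mean subset MSE, raw and
#'   Holm-adjusted p-values, and a `significant` flag. The per-subset MSE
#'   matrix (models + baseline) is attached as attribute `subset_mse`.
#' @export
compare_to_baseline <- function(models, train, test, n_subsets = 5L,
                                seed = NULL, alpha = 0.05) {
  stopifnot(inherits(train, "culture_dataset"), inherits(test, "culture_dataset"))
  if (n_subsets < 2L) stop("need at least 2 test subsets")
  if (!is.null(seed)) set.seed(seed)
  sub_id <- grouped_folds(test$condition_id, n_subsets)
  base_pred <- mean(train$y)
  mse_mat <- matrix(NA_real_, length(models) + 1L, n_subsets,
                    dimnames = list(c(names(models), ".baseline"), NULL))
  preds <- lapply(models, function(mdl) predict(mdl, test$X))
  for (s in seq_len(n_subsets)) {
    idx <- sub_id == s
    for (i in seq_along(models))
      mse_mat[i, s] <- mse(test$y[idx], preds[[i]][idx])
    mse_mat[length(models) + 1L, s] <- mse(test$y[idx], rep(base_pred, sum(idx)))
  }
  base_mse <- mse_mat[length(models) + 1L, ]
  p_raw <- vapply(seq_along(models), function(i) {
    diffs <- mse_mat[i, ] - base_mse
    if (all(abs(diffs) < 1e-12 * max(1, mean(base_mse)))) return(1)
    t.test(mse_mat[i, ], base_mse, paired = TRUE,
           alternative = "less")$p.value
  }, numeric(1L))
  out <- data.frame(model = names(models),
                    mse_test_mean = rowMeans(mse_mat)[seq_along(models)],
                    p_raw = p_raw,
                    p_holm = p.adjust(p_raw, method = "holm"),
                    row.names = NULL)
  out$significant <- out$p_holm < alpha
  attr(out, "subset_mse") <- mse_mat
  attr(out, "alpha") <- alpha
  out
}

#' Flag superior models
#'
#' A model is superior when (a) its test MSE is significantly lower than
#' the baseline's (Holm-adjusted p below `alpha`) and (b) it generalizes:
#' the train/test ratios of both R^2 and MSE are within `band` of 1.
#'
#' @param reports data.frame with columns `model`, `r2_train`, `r2_test`,
#'   `mse_train`, `mse_test`, `p_holm`.
#' @param alpha significance level (default 0.05).
#' @param band allowed relative deviation of the train/test metric ratios
#'   from 1 (default 0.15).
#' @return `reports` with added columns `r2_ratio`, `mse_ratio`, `superior`.
#' @export
select_superior <- function(reports, alpha = 0.05, band = 0.15) {
  need <- c("model", "r2_train", "r2_test", "mse_train", "mse_test", "p_holm")
  stopifnot(all(need %in% names(reports)))
  safe_ratio <- function(a, b) ifelse(abs(b) < 1e-12, Inf, a / b)
  reports$r2_ratio <- safe_ratio(reports$r2_train, reports$r2_test)
  reports$mse_ratio <- safe_ratio(reports$mse_train, reports$mse_test)
  reports$superior <- reports$p_holm < alpha &
    abs(reports$r2_ratio - 1) <= band &
    abs(reports$mse_ratio - 1) <= band
  reports
}

#' Run the full modeling protocol over a model suite
#'
#' Grouped 6:4 train/test split, grouped 5-fold cross-validated tuning of
#' every requested algorithm, evaluation on both partitions, comparison to
#' the predict-the-mean baseline on grouped test subsets with Holm
#' correction, and superior-model selection.
#'
#' @param ds a [culture_dataset()].
#' @param models character vector of model names (default the full suite).
#' @param train_fraction,folds,n_subsets,alpha,band protocol parameters.
#' @param seed optional integer seed governing the split, fold assignments,
#'   subset partition and stochastic fits.
#' @param grids optional named list of per-model hyperparameter grids.
#' @return An object of class `model_suite`: list with `reports`
#'   (data.frame incl. `superior`), `models` (named list of tuned models),
#'   `split` (train/test datasets).
#' @export
run_model_suite <- function(ds, models = model_names(), train_fraction = 0.6,
                            folds = 5L, n_subsets = 5L, alpha = 0.05,
                            band = 0.15, seed = NULL, grids = NULL) {
  stopifnot(inherits(ds, "culture_dataset"))
  if (!is.null(seed)) set.seed(seed)
  split <- grouped_split(ds, train_fraction)
  fits <- lapply(models, function(mn)
    tune_and_fit(mn, split$train, folds = folds,
                 grid = grids[[mn]]))
  names(fits) <- models
  ev_tr <- lapply(fits, function(m) evaluate_model(m, split$train$X, split$train$y))
  ev_te <- lapply(fits, function(m) evaluate_model(m, split$test$X, split$test$y))
  cmp <- compare_to_baseline(fits, split$train, split$test,
                             n_subsets = n_subsets, alpha = alpha)
  reports <- data.frame(model = models,
                        r2_train = vapply(ev_tr, `[[`, numeric(1L), "r2"),
                        r2_test = vapply(ev_te, `[[`, numeric(1L), "r2"),
                        mse_train = vapply(ev_tr, `[[`, numeric(1L), "mse"),
                        mse_test = vapply(ev_te, `[[`, numeric(1L), "mse"),
                        row.names = NULL)
  reports <- merge(reports, cmp[, c("model", "p_raw", "p_holm")],
                   by = "model", sort = FALSE)
  reports <- select_superior(reports, alpha = alpha, band = band)
  structure(list(reports = reports, models = fits, split = split,
                 comparison = cmp),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("Model suite results:\n")
  print(x$reports[, c("model", "r2_train", "r2_test", "p_holm", "superior")],
        digits = 3)
  invisible(x)
}
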