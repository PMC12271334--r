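#' Hyperparameter grids for the per-person boosted-tree fits
#'
#' `default_hyper_grid()` is the full tuning grid; `sanitize_grid()` maps the
#' values that fall outside the booster's legal domain onto their nearest
#' legal counterparts (gamma -0.5 -> 0; colsample_bytree 2 -> 1) and drops
#' the resulting duplicates. A learning rate of 0 is retained: it yields a
#' constant model and simply never wins on informative data.
#' `fast_hyper_grid()` is a 12-point subset (informative learning rates,
#' all depths) for large simulation runs and tests.
#'
#' @return Data frame with one row per grid point: `nrounds`, `eta`,
#'   `max_depth`, `gamma`, `colsample_bytree`, `min_child_weight`,
#'   `subsample`.
#' @export
default_hyper_grid <- function() {
  expand.grid(nrounds = c(50, 100, 150),
              eta = c(0, 0.0001, 0.001, 0.01, 0.015),
              max_depth = c(1, 2, 3),
              gamma = c(-0.5, 0, 0.5),
              colsample_bytree = c(0.5, 1, 2),
              min_child_weight = c(1, 2),
              subsample = 1)
}

#' @rdname default_hyper_grid
#' @param grid A grid data frame.
#' @export
sanitize_grid <- function(grid) {
  grid$gamma[grid$gamma < 0] <- 0
  grid$colsample_bytree[grid$colsample_bytree > 1] <- 1
  unique(grid)
}

#' @rdname default_hyper_grid
#' @export
fast_hyper_grid <- function() {
  expand.grid(nrounds = c(50, 100),
              eta = c(0.01, 0.015),
              max_depth = c(1, 2, 3),
              gamma = 0, colsample_bytree = 1, min_child_weight = 1,
              subsample = 1)
}

#' Chronological within-person train/test split
#'
#' First `floor(train_frac * n)` rows train, remainder test; no shuffling, so
#' the test set lies strictly after the training set in time. Requires at
#' least 20 rows (14 train / 6 test at the default fraction).
#'
#' @param n Number of chronologically ordered rows.
#' @param train_frac Training fraction (default 0.70).
#' @return List with integer index vectors `train` and `test`.
#' @export
chrono_split <- function(n, train_frac = 0.70) {
  if (n < 20) stop("eligibility error: need >= 20 observations, got ", n)
  n_train <- floor(train_frac * n)
  list(train = seq_len(n_train), test = seq.int(n_train + 1L, n))
}

#' Rolling-origin cross-validation folds
#'
#' Partitions `n_train` chronologically ordered rows into `k + 1` contiguous
#' blocks of near-equal size (earlier blocks take the remainder). Fold j fits
#' on blocks 1..j and validates on block j+1, so the fitting window expands
#' forward and every validation index is later than every fit index.
#'
#' @param n_train Number of training rows.
#' @param k Number of folds (default 4).
#' @return List of `k` lists with integer vectors `fit` and `val`.
#' @export
rolling_origin_folds <- function(n_train, k = 4) {
  if (n_train < k + 1) stop("need at least k + 1 = ", k + 1, " training rows")
  base <- n_train %/% (k + 1)
  rem <- n_train %% (k + 1)
  sizes <- rep(base, k + 1) + c(rep(1L, rem), rep(0L, k + 1 - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(k), function(j) {
    list(fit = seq_len(ends[j]), val = seq.int(starts[j + 1], ends[j + 1]))
  })
}

# F1 of the positive class at a fixed threshold; NA when precision or recall
# is undefined (no positive predictions / no positive labels)
.fold_f1 <- function(labels, preds) {
  s <- score(labels, preds)
  s$f1
}

.fit_booster <- function(x, y, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = params$eta, max_depth = params$max_depth,
                  gamma = params$gamma,
                  colsample_bytree = params$colsample_bytree,
                  min_child_weight = params$min_child_weight,
                  subsample = params$subsample,
                  base_score = 0.5,  # fixed: single-class fit sets are legal
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Grid-searched gradient-boosted-tree fit for one participant
#'
#' For every sanitized grid point, fits a binary-logistic booster on each
#' rolling-origin fold's fit set, predicts the validation set at threshold
#' 0.5, and scores F1 of the positive class. Folds with undefined F1 (e.g.
#' an all-negative validation block, or no positive predictions) are dropped
#' from that grid point's mean. The point maximizing mean defined-fold F1
#' wins; ties break toward the simplest model (fewer rounds, then shallower
#' trees, then larger learning rate). The winner is refit on the full
#' training set with a fixed seed. If every fold of every grid point is
#' undefined, a majority-class constant predictor is returned, flagged.
#'
#' @param x Numeric feature matrix (training rows, chronological).
#' @param y Binary 0/1 target vector.
#' @param grid Hyperparameter grid (sanitized internally).
#' @param k Number of rolling-origin folds.
#' @param seed Integer seed for the booster.
#' @param threshold Classification threshold.
#' @return List: `chosen_params` (1-row data frame), `cv_f1` (per-fold F1 of
#'   the winner), `mean_cv_f1`, `booster` (or NULL for the fallback),
#'   `fallback` flag, `majority_class`.
#' @export
grid_search_fit <- function(x, y, grid = default_hyper_grid(), k = 4,
                            seed = 1L, threshold = 0.5) {
  grid <- sanitize_grid(grid)
  # simplest-model-first order so ties resolve by position
  grid <- grid[order(grid$nrounds, grid$max_depth, -grid$eta,
                     grid$gamma, -grid$colsample_bytree,
                     grid$min_child_weight), , drop = FALSE]
  folds <- rolling_origin_folds(nrow(x), k)

  fold_data <- lapply(folds, function(f) {
    list(dfit_x = x[f$fit, , drop = FALSE], dfit_y = y[f$fit],
         dval_x = x[f$val, , drop = FALSE], dval_y = y[f$val])
  })

  best_i <- NA_integer_; best_mean <- -Inf; best_cv <- rep(NA_real_, k)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cv <- vapply(fold_data, function(fd) {
      m <- .fit_booster(fd$dfit_x, fd$dfit_y, g, g$nrounds, seed)
      p <- as.numeric(predict(m, xgboost::xgb.DMatrix(fd$dval_x)) > threshold)
      .fold_f1(fd$dval_y, p)
    }, numeric(1))
    mn <- if (all(is.na(cv))) NA_real_ else mean(cv, na.rm = TRUE)
    if (!is.na(mn) && mn > best_mean) {
      best_mean <- mn; best_i <- i; best_cv <- cv
    }
  }

  maj <- as.integer(mean(y) >= 0.5)
  if (is.na(best_i)) {
    return(list(chosen_params = NULL, cv_f1 = best_cv, mean_cv_f1 = NA_real_,
                booster = NULL, fallback = TRUE, majority_class = maj))
  }
  g <- grid[best_i, ]
  booster <- .fit_booster(x, y, g, g$nrounds, seed)
  list(chosen_params = g, cv_f1 = best_cv, mean_cv_f1 = best_mean,
       booster = booster, fallback = FALSE, majority_class = maj)
}

#' Fit one participant under one feature schema
#'
#' Chronological 70/30 split of the assembled matrix, grid-searched fit on
#' the training rows, prediction of the held-out test rows at the fixed
#' threshold. The test rows influence nothing upstream: imputation medians
#' come from the training portion and the grid is selected within the
#' training rows only.
#'
#' @param matrix_df Output of [assemble_matrix()].
#' @param grid,k,seed,threshold Passed to [grid_search_fit()].
#' @param train_frac Training fraction for [chrono_split()].
#' @return List of class `ppg_fit`: `participant_id`, `schema`,
#'   `train_idx`, `test_idx`, `fit` (from [grid_search_fit()]),
#'   `test_labels`, `test_pred`, `feature_cols`, `x` (full matrix).
#' @export
fit_participant <- function(matrix_df, grid = default_hyper_grid(), k = 4,
                            seed = 1L, threshold = 0.5, train_frac = 0.70) {
  feature_cols <- c(attr(matrix_df, "feature_cols"),
                    attr(matrix_df, "flag_cols"))
  x <- as.matrix(matrix_df[, feature_cols, drop = FALSE])
  storage.mode(x) <- "double"
  y <- matrix_df$target
  sp <- chrono_split(nrow(x), train_frac)
  fit <- grid_search_fit(x[sp$train, , drop = FALSE], y[sp$train],
                         grid = grid, k = k, seed = seed,
                         threshold = threshold)
  test_pred <- if (fit$fallback) {
    rep(fit$majority_class, length(sp$test))
  } else {
    as.numeric(predict(fit$booster,
                       xgboost::xgb.DMatrix(x[sp$test, , drop = FALSE]))
               > threshold)
  }
  structure(
    list(participant_id = matrix_df$participant_id[1],
         schema = attr(matrix_df, "schema"),
         train_idx = sp$train, test_idx = sp$test,
         fit = fit, test_labels = y[sp$test], test_pred = test_pred,
         feature_cols = feature_cols, x = x),
    class = "ppg_fit")
}
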