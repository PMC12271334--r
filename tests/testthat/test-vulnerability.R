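# build a ppg_fit by hand around a small booster
mk_fit <- function(x, y, seed = 1L, nrounds = 30) {
  d <- xgboost::xgb.DMatrix(x, label = y)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.3, max_depth = 2,
                  base_score = 0.5, nthread = 1, seed = seed),
    data = d, nrounds = nrounds, verbose = 0)
  structure(list(participant_id = "V1", schema = "high_burden",
                 fit = list(booster = bst, fallback = FALSE),
                 feature_cols = colnames(x), x = x),
            class = "ppg_fit")
}

test_that("a model splitting on one feature concentrates 100% there", {
  set.seed(2)
  n <- 60
  x <- cbind(staples_g_now = rep(c(10, 200), length.out = n),
             vegetables_g_now = rep(50, n))  # constant: unusable for splits
  y <- as.integer(x[, 1] > 100)
  ft <- mk_fit(x, y)
  gp <- gain_profile(ft)
  expect_equal(gp$per_feature_pct[["staples_g_now"]], 100)
  expect_equal(gp$per_feature_pct[["vegetables_g_now"]], 0)
  expect_equal(gp$ranking[1], "staples")

  sp <- shap_profile(ft)
  expect_equal(sp$per_feature_pct[["staples_g_now"]], 100)
})

test_that("profiles normalize to 100 and categories partition the features", {
  set.seed(3)
  n <- 80
  x <- cbind(staples_g_now = runif(n, 0, 300),
             hour_of_day = sample(0:23, n, TRUE),
             prev_excursion = rbinom(n, 1, 0.5))
  y <- as.integer(x[, 1] + 10 * x[, 3] + rnorm(n, 0, 20) > 150)
  ft <- mk_fit(x, y)
  for (p in list(gain_profile(ft), shap_profile(ft))) {
    expect_equal(sum(p$per_feature_pct), 100, tolerance = 1e-6)
    expect_equal(sum(p$per_category_pct), 100, tolerance = 1e-6)
    # regrouped sums are exact
    cm <- feature_category_map(colnames(x))
    for (ct in unique(cm)) {
      expect_equal(p$per_category_pct[[ct]],
                   sum(p$per_feature_pct[names(cm)[cm == ct]]),
                   tolerance = 1e-9)
    }
    expect_false(p$all_zero)
  }
})

test_that("SHAP contributions reconstruct the margin prediction", {
  set.seed(4)
  n <- 50
  x <- cbind(a = rnorm(n), b = rnorm(n))
  colnames(x) <- c("staples_g_now", "hour_of_day")
  y <- as.integer(x[, 1] > 0)
  ft <- mk_fit(x, y)
  contrib <- predict(ft$fit$booster, xgboost::xgb.DMatrix(x),
                     predcontrib = TRUE)
  margin <- predict(ft$fit$booster, xgboost::xgb.DMatrix(x),
                    outputmargin = TRUE)
  expect_equal(unname(rowSums(contrib)), unname(margin), tolerance = 1e-4)
})

test_that("fallback (constant) models yield flagged all-zero profiles", {
  ft <- structure(list(participant_id = "V2", schema = "low_burden",
                       fit = list(booster = NULL, fallback = TRUE),
                       feature_cols = c("hour_of_day", "prev_excursion"),
                       x = NULL),
                  class = "ppg_fit")
  gp <- gain_profile(ft)
  expect_true(gp$all_zero)
  expect_true(all(gp$per_feature_pct == 0))
  expect_true(shap_profile(ft)$all_zero)
})

test_that("every feature of both schemas gets exactly one category", {
  rec <- make_clean_participant(seed = 17L, days = 8)
  obs <- label_participant(rec)
  for (schema in c("low_burden", "high_burden")) {
    mat <- assemble_matrix(rec, obs, schema)
    cols <- c(attr(mat, "feature_cols"), attr(mat, "flag_cols"))
    cm <- feature_category_map(cols)
    expect_equal(length(cm), length(cols))
    expect_false(any(cm == "other"))
    # indicator columns inherit the parent feature's category
    expect_equal(unname(cm["miss_prev_excursion"]),
                 unname(cm["prev_excursion"]))
  }
})

test_that("cohort heterogeneity summarizes shares and detects duplicate rankings", {
  mk_profile <- function(id, pct) {
    structure(list(participant_id = id, best_schema = "high_burden",
                   per_feature_pct = pct, per_category_pct = pct,
                   ranking = names(sort(pct, decreasing = TRUE)),
                   all_zero = FALSE),
              class = "ppg_profile")
  }
  a <- mk_profile("A", c(staples = 70, `hour of the day` = 30, mealtime = 0))
  b <- mk_profile("B", c(staples = 60, `hour of the day` = 40, mealtime = 0))
  c3 <- mk_profile("C", c(staples = 10, `hour of the day` = 90, mealtime = 0))
  het <- cohort_heterogeneity(list(a, b, c3))
  tab <- het$table
  expect_equal(tab$shared_by[tab$category == "staples"], 3)
  expect_equal(tab$shared_by[tab$category == "mealtime"], 0)
  expect_equal(tab$mean_pct[tab$category == "mealtime"], 0)
  # A and B share a ranking; C does not
  expect_equal(nrow(het$duplicate_rankings), 1)
  expect_equal(het$duplicate_rankings$id_a, "A")
  expect_equal(het$duplicate_rankings$id_b, "B")
  het2 <- cohort_heterogeneity(list(a, c3))
  expect_equal(nrow(het2$duplicate_rankings), 0)
})
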