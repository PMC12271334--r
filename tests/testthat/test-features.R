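t0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

test_that("temporal features cover clock, calendar and fasting indicators", {
  f <- temporal_features(t0 + 7.5 * 3600, t0, as.POSIXct(character(), tz = "UTC"))
  expect_equal(f[["hour_of_day"]], 7)
  expect_equal(f[["time_in_study"]], 0)
  expect_equal(f[["ate_last_8h"]], 0)
  expect_equal(f[["ate_last_24h"]], 0)
  expect_equal(f[["slot_breakfast"]], 1)

  f2 <- temporal_features(t0 + 12.25 * 3600, t0, t0 + 7.5 * 3600)
  expect_equal(f2[["ate_last_8h"]], 1)
  expect_equal(f2[["slot_lunch"]], 1)
  expect_equal(sum(f2[c("slot_breakfast", "slot_lunch", "slot_dinner",
                        "slot_other")]), 1)

  nye <- as.POSIXct("2020-12-31 23:59:00", tz = "UTC")
  f3 <- temporal_features(nye, nye - 86400 * 10, nye - 3600)
  expect_equal(f3[["month"]], 12)
  expect_equal(f3[["day_of_month"]], 31)
  expect_equal(f3[["slot_other"]], 1)
  expect_equal(f3[["time_in_study"]], 10)
})

test_that("meal lag features sum strictly-prior windows and flag presence", {
  m <- empty_meals()
  m <- rbind(m[0, ], data.frame(timestamp = t0 + c(3, 10, 12) * 3600,
                                staples = c(0, 0, 150), vegetables = c(100, 50, 0),
                                fruits = 0, animal_foods = 0, dairy = 0,
                                legumes_nuts_seeds = 0, sweets = 0,
                                total_grams = c(100, 50, 150),
                                raw_text = NA_character_))
  at <- t0 + 12 * 3600
  f <- meal_lag_features(m, at)
  expect_equal(f[["staples_g_now"]], 150)
  expect_equal(f[["staples_g_8h"]], 0)
  expect_equal(f[["vegetables_g_8h"]], 50)   # t-9h meal is outside 8h
  expect_equal(f[["vegetables_g_24h"]], 150)
  expect_equal(f[["total_g_now"]], 150)
  expect_equal(f[["total_g_24h"]], 150)
  expect_equal(f[["vegetables_any_8h"]], 1)
  expect_equal(f[["staples_any_8h"]], 0)

  # all-zero current meal: zero features, zero presence
  m0 <- m; m0[3, food_groups()] <- 0; m0$total_grams[3] <- 0
  f0 <- meal_lag_features(m0, at)
  expect_equal(f0[["staples_g_now"]], 0)
  expect_equal(f0[["staples_any_now"]], 0)
})

test_that("lag sums match a brute-force double loop on random schedules", {
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(3:15, 1)
    m <- data.frame(timestamp = t0 + sort(runif(n, 0, 96)) * 3600)
    for (g in food_groups()) m[[g]] <- round(runif(n, 0, 200), 1)
    m$total_grams <- rowSums(m[, food_groups()])
    at <- m$timestamp[sample(n, 1)]
    f <- meal_lag_features(m, at)
    g <- sample(food_groups(), 1)
    expect_equal(f[[paste0(g, "_g_8h")]], brute_force_lag(m, at, 8, g))
    expect_equal(f[[paste0(g, "_g_24h")]], brute_force_lag(m, at, 24, g))
    expect_equal(f[["total_g_24h"]], brute_force_lag(m, at, 24, "total_grams"))
  }
})

test_that("medication features respect onset and offset of each action window", {
  at <- t0 + 20 * 3600
  mk <- function(lag_h, cls, dose = 6) {
    data.frame(timestamp = at - lag_h * 3600, agent_class = cls,
               dose = dose, dose_unit = "IU")
  }
  f <- medication_features(mk(1, "bolus_insulin"), at)
  expect_equal(f[["bolus_insulin_active"]], 1)
  expect_equal(f[["bolus_insulin_active_dose"]], 6)

  # 10 min after the dose: before the 15-min onset, but inside the 8-h sum
  f2 <- medication_features(mk(1 / 6, "bolus_insulin"), at)
  expect_equal(f2[["bolus_insulin_active"]], 0)
  expect_equal(f2[["bolus_insulin_dose_8h"]], 6)

  f3 <- medication_features(mk(30, "basal_insulin", 20), at)
  expect_true(all(f3[grep("basal", names(f3))] == 0))

  # boundary: basal at exactly 2 h is not yet active (half-open window)
  f4 <- medication_features(mk(2, "basal_insulin", 20), at)
  expect_equal(f4[["basal_insulin_active"]], 0)
  f5 <- medication_features(mk(24, "basal_insulin", 20), at)
  expect_equal(f5[["basal_insulin_active"]], 1)
})

test_that("assembled matrix imputes from the training portion and flags exactly the blanks", {
  tr <- synthetic_truth("F1", c(staples = 30), noise_sd = 5, seed = 88L)
  rec <- generate_participant(tr, days = 12, missing_gram_rate = 0.3)
  obs <- label_participant(rec)
  mat <- assemble_matrix(rec, obs, "high_burden")
  expect_false(anyNA(mat[, attr(mat, "feature_cols")]))

  # flags match the planted blanks for the staples 'now' feature
  usable <- obs[obs$usable, ]
  blanked <- is.na(rec$meals$staples[usable$meal_index])
  if ("miss_staples_g_now" %in% names(mat)) {
    expect_equal(mat$miss_staples_g_now, as.numeric(blanked))
    n_train <- floor(0.7 * nrow(mat))
    train_vals <- rec$meals$staples[usable$meal_index[seq_len(n_train)]]
    med <- median(train_vals, na.rm = TRUE)
    expect_true(all(mat$staples_g_now[blanked] == med))
  }

  # fully observed input: no flags except the structural first-row lag
  rec2 <- generate_participant(tr, days = 12)
  mat2 <- assemble_matrix(rec2, label_participant(rec2), "high_burden")
  expect_equal(attr(mat2, "flag_cols"), "miss_prev_excursion")
})

test_that("low-burden schema holds temporal + previous-excursion features only", {
  rec <- make_clean_participant(seed = 91L, days = 8)
  obs <- label_participant(rec)
  mat <- assemble_matrix(rec, obs, "low_burden")
  fc <- attr(mat, "feature_cols")
  expect_true("prev_excursion" %in% fc)
  expect_false(any(grepl("_g_|insulin|agent", fc)))
  mat_h <- assemble_matrix(rec, obs, "high_burden")
  expect_true(all(fc %in% attr(mat_h, "feature_cols")))
})

test_that("no feature uses events at or after its meal time", {
  tr <- synthetic_truth(
    "L1", c(staples = 30), noise_sd = 5,
    regimen = data.frame(agent_class = "bolus_insulin", dose = 6,
                         dose_unit = "IU", hour = 12.0, prob = 1),
    seed = 93L)
  rec <- generate_participant(tr, days = 10)
  obs <- label_participant(rec)
  mat <- assemble_matrix(rec, obs, "high_burden")

  cut_time <- mat$meal_time[floor(nrow(mat) * 0.6)]
  # perturb every meal and medication event at or after the cut
  rec2 <- rec
  late_m <- rec2$meals$timestamp >= cut_time
  rec2$meals$staples[late_m] <- rec2$meals$staples[late_m] + 500
  rec2$meals$total_grams[late_m] <- rec2$meals$total_grams[late_m] + 500
  late_d <- rec2$meds$timestamp >= cut_time
  rec2$meds$dose[late_d] <- rec2$meds$dose[late_d] + 99
  mat2 <- assemble_matrix(rec2, obs, "high_burden")

  early <- mat$meal_time < cut_time
  fc <- attr(mat, "feature_cols")
  expect_identical(mat[early, fc], mat2[early, fc])
})

test_that("prev_excursion lags the previous usable label with no time cap", {
  rec <- make_clean_participant(seed = 95L, days = 8)
  obs <- label_participant(rec)
  mat <- assemble_matrix(rec, obs, "low_burden")
  usable <- obs[obs$usable, ]
  expect_equal(mat$prev_excursion[-1], as.numeric(head(usable$label, -1)))
  expect_equal(mat$miss_prev_excursion[1], 1)
})
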