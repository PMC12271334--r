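test_that("generation is deterministic under (seed, parameters)", {
  tr <- synthetic_truth("D1", c(staples = 25, hour = 10), noise_sd = 12,
                        seed = 77L)
  a <- generate_participant(tr, days = 7)
  b <- generate_participant(tr, days = 7)
  expect_identical(a$glucose, b$glucose)
  expect_identical(a$meals, b$meals)
  expect_identical(a$meds, b$meds)

  ca <- generate_cohort(4, "mixed", seed = 5L, days = 6)
  cb <- generate_cohort(4, "mixed", seed = 5L, days = 6)
  for (i in 1:4) expect_identical(ca[[i]]$glucose, cb[[i]]$glucose)
})

test_that("null model (no drivers, no noise, no circadian) gives a flat trace and zero iAUCs", {
  tr <- synthetic_truth("N1", c(staples = 0), circadian_amplitude = 0,
                        noise_sd = 0, seed = 11L)
  rec <- generate_participant(tr, days = 5)
  expect_lt(diff(range(rec$glucose$glucose_mgdl)), 1e-9)
  obs <- label_participant(rec)
  expect_true(all(obs$iauc[!is.na(obs$iauc)] == 0))
})

test_that("noise-free iAUC is strictly increasing in staples grams across isolated meals", {
  tr <- synthetic_truth("M1", c(staples = 30), circadian_amplitude = 0,
                        noise_sd = 0, seed = 21L)
  rec <- generate_participant(tr, days = 10)
  gt <- attr(rec, "ground_truth")
  obs <- label_participant(rec)
  mt <- as.numeric(gt$meal_times)
  iso <- which(c(Inf, diff(mt)) / 60 >= 180 & c(diff(mt), Inf) / 60 >= 120 &
                 !is.na(obs$iauc))
  g <- rec$meals$staples[iso]
  ord <- order(g)
  expect_gt(length(iso), 10)
  expect_true(all(diff(obs$iauc[iso][ord]) >= -1e-9))
  # and monotone strictly where grams strictly increase
  strict <- diff(g[ord]) > 1e-9
  expect_true(all(diff(obs$iauc[iso][ord])[strict] > 0))
})

test_that("closed-form pulse area matches a dense Riemann oracle", {
  for (h in c(5, 30, 80)) {
    t <- seq(0, 120, by = 0.01)
    shape <- ifelse(t <= 45, t / 45, (180 - t) / 135)
    riemann <- sum(diff(t) * (head(shape, -1) + tail(shape, -1)) / 2) * h
    expect_equal(pulse_area(h, 120), riemann, tolerance = 1e-6)
  }
  expect_equal(pulse_area(10, 180), 0.5 * 180 * 10)
})

test_that("trapezoidal iAUC matches the analytic pulse area on clean pulses", {
  rec <- make_clean_participant(seed = 31L, days = 12)
  gt <- attr(rec, "ground_truth")
  obs <- label_participant(rec)
  mt <- as.numeric(gt$meal_times)
  iso <- which(c(Inf, diff(mt)) / 60 >= 180 & c(diff(mt), Inf) / 60 >= 120 &
                 !is.na(obs$iauc) & gt$pulse_heights > 1)
  expect_gt(length(iso), 15)
  expected <- pulse_area(gt$pulse_heights[iso], 120)
  expect_true(all(abs(obs$iauc[iso] - expected) / expected < 0.02))
})

test_that("cohort statistics land near the scenario targets", {
  cohort <- generate_cohort(50, "mixed", seed = 400L, days = 10)
  mpd <- sapply(cohort, function(r) nrow(r$meals) / 10)
  expect_lt(abs(mean(mpd) - 3.23) / 3.23, 0.15)
  daily <- sapply(cohort, function(r) sum(r$meals$total_grams) / 10)
  target_total <- 222 + 155.93 + 144.88 + 82.32 + 31 + 8.81 + 1.54
  expect_lt(abs(mean(daily) - target_total) / target_total, 0.15)
  staples_daily <- sapply(cohort, function(r) sum(r$meals$staples) / 10)
  expect_lt(abs(mean(staples_daily) - 222) / 222, 0.15)
})

test_that("medication suppression shrinks pulses only when an agent is active", {
  reg <- data.frame(agent_class = "non_insulin_agent", dose = 50,
                    dose_unit = "mg", hour = 7.0, prob = 1)
  tr_on <- synthetic_truth("R1", c(staples = 30), med_suppression = 0.6,
                           regimen = reg, circadian_amplitude = 0,
                           noise_sd = 0, seed = 55L)
  tr_off <- tr_on; tr_off$med_suppression <- 0
  on <- attr(generate_participant(tr_on, days = 6), "ground_truth")
  off <- attr(generate_participant(tr_off, days = 6), "ground_truth")
  # agent taken 07:00 acts (0, 6] h: breakfast and lunch pulses shrink,
  # dinner (>6 h later) does not
  hrs <- (as.numeric(difftime(on$meal_times, on$day0, units = "hours"))) %% 24
  covered <- hrs > 7 & hrs <= 13
  expect_equal(on$pulse_heights[covered], 0.4 * off$pulse_heights[covered],
               tolerance = 1e-9)
  expect_equal(on$pulse_heights[!covered], off$pulse_heights[!covered],
               tolerance = 1e-9)
})

test_that("missingness injection blanks gram cells and flags totals", {
  tr <- synthetic_truth("Z1", c(staples = 25), seed = 66L)
  rec <- generate_participant(tr, days = 8, missing_gram_rate = 0.3)
  gm <- as.matrix(rec$meals[, food_groups()])
  expect_gt(sum(is.na(gm)), 0)
  miss_rows <- !complete.cases(rec$meals[, food_groups()])
  expect_true(all(is.na(rec$meals$total_grams[miss_rows])))
  expect_true(all(!is.na(rec$meals$total_grams[!miss_rows])))
})
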