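test_that("error metrics match their closed forms", {
  expect_equal(rmse(c(1, 2), c(0, 0)), sqrt(2.5))
  expect_equal(mae(c(1, 2), c(0, 0)), 1.5)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(mae(1:5, 1:5), 0)
  expect_error(rmse(1:3, 1:2), class = "afbnp_contract_error")
  expect_error(mae(numeric(), numeric()), class = "afbnp_contract_error")
})

test_that("RMSE dominates MAE on random vectors", {
  withr::with_seed(14, {
    for (i in 1:100) {
      p <- rnorm(20); o <- rnorm(20)
      expect_gte(rmse(p, o), mae(p, o))
    }
  })
})

test_that("directional accuracy follows the strict-positive rule", {
  expect_equal(directional_accuracy(c(1, -1, 2), c(5, -3, 1)), 1)
  # a zero prediction counts as decrease_or_stable, so it misses a true rise
  expect_equal(directional_accuracy(0, 10), 0)
  expect_equal(direction_label(0), "decrease_or_stable")
  # 41 of 50 correct
  pred <- c(rep(1, 41), rep(-1, 9))
  truth <- rep(1, 50)
  expect_equal(directional_accuracy(pred, truth), 0.82)
  # invariance to strictly positive rescaling of predictions
  withr::with_seed(3, {
    p <- rnorm(30); o <- rnorm(30)
    expect_equal(directional_accuracy(p, o),
                 directional_accuracy(1e4 * p, o))
  })
})

test_that("LOOCV holds every patient out exactly once with no leakage", {
  fx <- small_features()
  rep <- loocv(fx, tiny_model_config(seed = 55, max_epochs = 2))
  ids <- sort(fx$static$patient_id)
  expect_identical(sort(rep$folds$held_out_patient), ids)
  expect_false(rep$incomplete)
  expect_gte(rep$rmse, rep$mae)
  # leakage audit: every fold's scaler hash equals the hash of exactly
  # the other n-1 patients, and the training-input hash never includes
  # the held-out patient's outcome
  for (i in seq_len(nrow(rep$folds))) {
    held <- rep$folds$held_out_patient[i]
    train_ids <- setdiff(ids, held)
    expect_identical(rep$folds$scaler_hash[i],
                     afbnp:::content_hash(list(sort(train_ids), rep$groups)))
    oc_train <- dplyr::filter(fx$outcomes, patient_id %in% train_ids)
    expect_identical(rep$folds$train_hash[i],
                     afbnp:::content_hash(list(train_ids,
                                               oc_train$followup_ntprobnp,
                                               oc_train$baseline_ntprobnp)))
  }
})

test_that("fold artifacts reproduce independently of execution order", {
  fx <- small_features()
  cfg <- tiny_model_config(seed = 56, max_epochs = 2)
  r1 <- loocv(fx, cfg)
  r2 <- loocv(fx, cfg)
  expect_identical(r1$folds, r2$folds)
  expect_identical(glance(r1), glance(r2))
})

test_that("cv reports round-trip losslessly through JSON", {
  fx <- small_features()
  rep <- loocv(fx, tiny_model_config(seed = 57, max_epochs = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep, path)
  back <- read_cv_report(path)
  expect_equal(back$folds, rep$folds)
  expect_equal(back$rmse, rep$rmse, tolerance = 1e-12)
  expect_equal(back$mae, rep$mae, tolerance = 1e-12)
  expect_identical(back$directional_accuracy, rep$directional_accuracy)
  expect_equal(back$abs_error_quartiles, rep$abs_error_quartiles,
               tolerance = 1e-12)
})

test_that("tidy and glance expose the fold table and headline metrics", {
  fx <- small_features()
  rep <- loocv(fx, tiny_model_config(seed = 58, max_epochs = 2))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("held_out_patient", "predicted_delta", "true_delta",
                    "predicted_direction", "true_direction") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$n_folds, nrow(td))
  expect_equal(gl$directional_accuracy, rep$directional_accuracy)
})

test_that("trajectory plots coincide for perfect predictions", {
  fx <- small_features()
  oc <- fx$outcomes
  folds <- tibble::tibble(
    held_out_patient = oc$patient_id,
    predicted_delta = oc$delta,
    true_delta = oc$delta,
    predicted_direction = direction_label(oc$delta),
    true_direction = direction_label(oc$delta),
    train_epochs = 1L, scaler_hash = "x", train_hash = "y",
    failed = FALSE, message = ""
  )
  rep <- structure(list(folds = folds, rmse = 0, mae = 0,
                        directional_accuracy = 1,
                        abs_error_quartiles = c(0, 0, 0),
                        groups = "CM", config = tiny_model_config(),
                        seed = 1, incomplete = FALSE),
                   class = "cv_report")
  df <- afbnp:::trajectory_data(rep, oc)
  obs <- df[df$series == "observed", ]
  prd <- df[df$series == "predicted", ]
  expect_equal(prd$value, obs$value)
  p <- autoplot(rep, oc)
  expect_s3_class(p, "ggplot")
})

test_that("trajectory confidence intervals shrink like 1/sqrt(n)", {
  base <- seq(-1, 1, length.out = 10) * 300 + 1500
  hw <- vapply(c(1, 4, 16), function(k) {
    vals <- rep(base, k)
    df <- tibble::tibble(patient_id = as.character(seq_along(vals)),
                         series = "observed", time = 8, value = vals)
    ci <- afbnp:::trajectory_summary(df)
    (ci$hi - ci$lo) / 2
  }, numeric(1))
  # identical dispersion, n growing 4x each step: halfwidth halves
  expect_equal(hw[1] / hw[2], 2, tolerance = 0.05)
  expect_equal(hw[2] / hw[3], 2, tolerance = 0.05)
})

test_that("directional accuracy responds to the planted effect strength", {
  # matched design: identical recordings and latent states, outcomes
  # regenerated under different effect strengths (same outcome seed)
  base <- cohort_config(n_patients = 30, recording_days_range = c(3, 3),
                        seed = 77, effect_strength = 0)
  co <- simulate_cohort(base)
  fx <- extract_features(co)
  prep <- prepare_loocv(fx)
  mcfg <- model_config(max_epochs = 8, seed = 77)
  accs <- vapply(c(0, 0.9), function(es) {
    cfg_es <- cohort_config(n_patients = 30,
                            recording_days_range = c(3, 3),
                            seed = 77, effect_strength = es)
    fx_es <- fx
    fx_es$outcomes <- simulate_outcomes(co$clinical, co$latent, cfg_es)
    loocv(fx_es, mcfg, prep = prep)$directional_accuracy
  }, numeric(1))
  expect_gte(accs[1], 0.3)   # null cohort: chance level
  expect_lte(accs[1], 0.7)
  expect_gte(accs[2], accs[1] + 0.05)  # strong signal is recovered
})

test_that("label permutation preserves the outcome set but breaks pairing", {
  fx <- small_features()
  perm <- permute_outcomes(fx, seed = 9)
  expect_setequal(perm$outcomes$followup_ntprobnp,
                  fx$outcomes$followup_ntprobnp)
  expect_identical(perm$outcomes$patient_id, fx$outcomes$patient_id)
  expect_false(identical(perm$outcomes$followup_ntprobnp,
                         fx$outcomes$followup_ntprobnp))
})
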