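#' Root mean squared error and mean absolute error
#'
#' @param predicted,observed Equal-length non-empty numeric vectors.
#' @return A scalar (pg/mL when applied to NT-proBNP changes).
#' @export
rmse <- function(predicted, observed) {
  check_paired(predicted, observed)
  sqrt(mean((predicted - observed)^2))
}

#' @rdname rmse
#' @export
mae <- function(predicted, observed) {
  check_paired(predicted, observed)
  mean(abs(predicted - observed))
}

check_paired <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(predicted)) {
    abort("`predicted` and `observed` must be equal-length, non-empty",
          class = "afbnp_contract_error")
  }
  invisible(NULL)
}

#' Direction label of an NT-proBNP change
#'
#' "increase" iff the change is strictly positive; an exact zero counts
#' as "decrease_or_stable".
#'
#' @param delta Numeric vector of changes (pg/mL).
#' @return Character vector of labels.
#' @export
direction_label <- function(delta) {
  ifelse(delta > 0, "increase", "decrease_or_stable")
}

#' Directional accuracy
#'
#' Fraction of patients whose predicted change has the same direction
#' label as the observed change. Numeric inputs are converted with
#' [direction_label()]; character inputs are compared as labels.
#'
#' @param predicted,observed Changes (numeric, pg/mL) or direction labels
#'   (character).
#' @return Fraction in `[0, 1]`.
#' @export
directional_accuracy <- function(predicted, observed) {
  check_paired(predicted, observed)
  p <- if (is.numeric(predicted)) direction_label(predicted) else predicted
  o <- if (is.numeric(observed)) direction_label(observed) else observed
  mean(p == o)
}

#' Patient-level leave-one-out cross-validation
#'
#' For each patient, fits the Yeo-Johnson/z-score scalers and the
#' context-aware model on the remaining patients only, then predicts the
#' held-out NT-proBNP change. Fold seeds derive deterministically from
#' the configuration seed and the held-out patient's rank, so folds are
#' reproducible regardless of execution order. Each fold records the
#' scaler fit-population and a content hash of its training inputs for
#' leakage auditing.
#'
#' @param features An `af_features` store from [extract_features()].
#' @param config A [model_config()].
#' @param groups Feature groups to use (see [select_groups()]).
#' @param prep Optional fold cache from [prepare_loocv()]; scalers and
#'   standardized tensors depend only on the features (never on outcome
#'   labels), so repeated evaluations of the same cohort — e.g. label
#'   permutations — can share one cache.
#' @return A `cv_report`: `folds` tibble (one row per patient), `rmse`,
#'   `mae`, `directional_accuracy`, absolute-error quartiles, `groups`,
#'   `config`, and `incomplete` flag if any fold failed.
#' @export
loocv <- function(features, config = model_config(),
                  groups = c("CM", "RR", "HRV72h", "HRV30min"),
                  prep = NULL) {
  stopifnot(inherits(features, "af_features"))
  ids <- sort(features$static$patient_id)
  if (length(ids) < 3) abort("LOOCV needs at least 3 patients",
                             class = "afbnp_config_error")
  if (is.null(prep)) prep <- prepare_loocv(features, groups)
  stopifnot(identical(prep$ids, ids), identical(prep$groups, groups))
  folds <- purrr::map(seq_along(ids), function(i) {
    run_fold(features, ids, i, config, groups, prep$folds[[i]])
  })
  folds <- dplyr::bind_rows(folds)
  ok <- !folds$failed
  abs_err <- abs(folds$predicted_delta[ok] - folds$true_delta[ok])
  structure(
    list(
      folds = folds,
      rmse = rmse(folds$predicted_delta[ok], folds$true_delta[ok]),
      mae = mae(folds$predicted_delta[ok], folds$true_delta[ok]),
      directional_accuracy = directional_accuracy(
        folds$predicted_direction[ok], folds$true_direction[ok]),
      abs_error_quartiles = unname(quantile(abs_err, c(0.25, 0.5, 0.75))),
      groups = groups,
      config = config,
      seed = config$seed,
      incomplete = any(folds$failed)
    ),
    class = "cv_report"
  )
}

#' Precompute per-fold scalers and standardized tensors for LOOCV
#'
#' For every leave-one-out fold, fits the scaler state on the n-1
#' training patients and standardizes all patient tensors with it. The
#' result feeds [loocv()] via its `prep` argument; because nothing here
#' touches the outcome labels, one cache serves both the real evaluation
#' and label-permutation nulls of the same cohort.
#'
#' @inheritParams loocv
#' @return A `loocv_prep` list (one entry per fold).
#' @export
prepare_loocv <- function(features, groups = c("CM", "RR", "HRV72h",
                                               "HRV30min")) {
  stopifnot(inherits(features, "af_features"))
  ids <- sort(features$static$patient_id)
  folds <- purrr::map(seq_along(ids), function(i) {
    held <- ids[i]
    train_ids <- setdiff(ids, held)
    scalers <- fit_scalers(features, train_ids, groups)
    list(
      scalers = scalers,
      tensors = purrr::map(train_ids,
                           ~ build_patient_tensor(features, .x, scalers)),
      held_tensor = build_patient_tensor(features, held, scalers)
    )
  })
  structure(list(ids = ids, groups = groups, folds = folds),
            class = "loocv_prep")
}

run_fold <- function(features, ids, i, config, groups, prep_fold) {
  held <- ids[i]
  train_ids <- setdiff(ids, held)
  fold_seed <- substream_seed(config$seed, i, purpose = 9L)
  fail_row <- function(msg) tibble::tibble(
    held_out_patient = held, predicted_delta = NA_real_,
    true_delta = NA_real_, predicted_direction = NA_character_,
    true_direction = NA_character_, train_epochs = NA_integer_,
    scaler_hash = NA_character_, train_hash = NA_character_,
    failed = TRUE, message = msg)
  tryCatch({
    scalers <- prep_fold$scalers
    stopifnot(identical(scalers$train_ids, sort(train_ids)),
              !held %in% scalers$train_ids)
    tensors <- prep_fold$tensors
    train_oc <- dplyr::filter(features$outcomes,
                              .data$patient_id %in% train_ids)
    cfg <- config
    cfg$seed <- fold_seed
    f_seq <- ncol(tensors[[1]]$X)
    model <- build_model(cfg, f_seq = f_seq, ctx_dim = 2)
    model <- train_model(model, tensors, train_oc)
    held_tensor <- prep_fold$held_tensor
    held_oc <- dplyr::filter(features$outcomes, .data$patient_id == held)
    pred <- predict_delta(model, held_tensor, held_oc$baseline_ntprobnp)
    tibble::tibble(
      held_out_patient = held,
      predicted_delta = pred,
      true_delta = held_oc$delta,
      predicted_direction = direction_label(pred),
      true_direction = direction_label(held_oc$delta),
      train_epochs = nrow(model$history),
      scaler_hash = scalers$fit_hash,
      train_hash = content_hash(list(train_ids, train_oc$followup_ntprobnp,
                                     train_oc$baseline_ntprobnp)),
      failed = FALSE, message = ""
    )
  }, afbnp_training_divergence = function(e) fail_row(conditionMessage(e)),
     afbnp_insufficient_data = function(e) fail_row(conditionMessage(e)))
}

#' Permute outcome labels across patients
#'
#' Returns a feature store whose outcome rows (baseline/follow-up pair,
#' change, direction) are shuffled across patients while all ECG-derived
#' and clinical features stay in place — the null pipeline for
#' permutation checks of directional accuracy.
#'
#' @param features An `af_features` store.
#' @param seed Integer seed for the permutation.
#' @return The modified `af_features`.
#' @export
permute_outcomes <- function(features, seed) {
  oc <- features$outcomes
  perm <- with_seed(seed, sample.int(nrow(oc)))
  shuffled <- oc[perm, setdiff(names(oc), "patient_id")]
  features$outcomes <- dplyr::bind_cols(
    tibble::tibble(patient_id = oc$patient_id), shuffled)
  features
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d folds%s | RMSE %.2f pg/mL | MAE %.2f pg/mL | directional accuracy %.3f\n",
    nrow(x$folds), if (x$incomplete) " (incomplete)" else "",
    x$rmse, x$mae, x$directional_accuracy))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$folds),
    n_failed = sum(x$folds$failed),
    rmse = x$rmse,
    mae = x$mae,
    directional_accuracy = x$directional_accuracy,
    abs_err_q1 = x$abs_error_quartiles[1],
    abs_err_median = x$abs_error_quartiles[2],
    abs_err_q3 = x$abs_error_quartiles[3]
  )
}

#' Observed vs predicted NT-proBNP trajectories
#'
#' Spaghetti plot of per-patient baseline-to-follow-up trajectories with
#' group means and 95% confidence intervals, observed (solid) vs
#' predicted (dashed).
#'
#' @param object A `cv_report`.
#' @param outcomes Outcome tibble with `followup_months` per patient.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, outcomes, ...) {
  df <- trajectory_data(object, outcomes)
  ci <- trajectory_summary(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$patient_id,
                                                        .data$series)),
                       color = "grey70", linewidth = 0.3, alpha = 0.6) +
    ggplot2::geom_ribbon(data = ci,
                         ggplot2::aes(y = .data$mean, ymin = .data$lo,
                                      ymax = .data$hi, fill = .data$series),
                         alpha = 0.2) +
    ggplot2::geom_line(data = ci,
                       ggplot2::aes(y = .data$mean, color = .data$series,
                                    linetype = .data$series),
                       linewidth = 1) +
    ggplot2::scale_y_continuous(trans = "log10") +
    ggplot2::labs(x = "Months from baseline", y = "NT-proBNP (pg/mL)",
                  color = NULL, fill = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

# Normal-approximation 95% CI of the mean trajectory per series/time.
trajectory_summary <- function(df) {
  df |>
    dplyr::summarise(
      mean = mean(.data$value),
      lo = mean(.data$value) - 1.96 * sd(.data$value) / sqrt(dplyr::n()),
      hi = mean(.data$value) + 1.96 * sd(.data$value) / sqrt(dplyr::n()),
      .by = c("time", "series")
    )
}

trajectory_data <- function(report, outcomes) {
  folds <- dplyr::filter(report$folds, !.data$failed)
  oc <- outcomes[match(folds$held_out_patient, outcomes$patient_id), ]
  tibble::tibble(
    patient_id = rep(folds$held_out_patient, 4),
    series = rep(c("observed", "observed", "predicted", "predicted"),
                 each = nrow(folds)),
    time = c(rep(0, nrow(folds)), oc$followup_months,
             rep(0, nrow(folds)), oc$followup_months),
    value = pmax(c(oc$baseline_ntprobnp, oc$followup_ntprobnp,
                   oc$baseline_ntprobnp,
                   oc$baseline_ntprobnp + folds$predicted_delta), 1)
  )
}

#' Serialize / restore a cross-validation report
#'
#' `write_cv_report()` writes the folds and metrics as JSON (full double
#' precision); `read_cv_report()` restores an equivalent `cv_report`.
#'
#' @param report A `cv_report`.
#' @param path JSON file path.
#' @return `write_cv_report()`: the path, invisibly. `read_cv_report()`:
#'   a `cv_report`.
#' @export
write_cv_report <- function(report, path) {
  payload <- list(
    folds = report$folds,
    rmse = report$rmse,
    mae = report$mae,
    directional_accuracy = report$directional_accuracy,
    abs_error_quartiles = report$abs_error_quartiles,
    groups = report$groups,
    config = unclass(report$config),
    seed = report$seed,
    incomplete = report$incomplete
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_cv_report
#' @export
read_cv_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- p$config
  structure(
    list(folds = tibble::as_tibble(p$folds),
         rmse = p$rmse, mae = p$mae,
         directional_accuracy = p$directional_accuracy,
         abs_error_quartiles = p$abs_error_quartiles,
         groups = p$groups,
         config = do.call(model_config, cfg[names(formals(model_config))[
           names(formals(model_config)) %in% names(cfg)]]),
         seed = p$seed,
         incomplete = p$incomplete),
    class = "cv_report"
  )
}
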