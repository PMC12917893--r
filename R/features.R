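# Table-driven registry of the four feature groups. CM holds the 19
# clinical metrics; RR and HRV72h are whole-recording static summaries;
# HRV30min is the per-window sequence family.
feature_group_registry <- list(
  CM = c("age", "bmi", "hbp", "dm", "cva", "hfpef", "aad", "noac",
         "antiplatelet", "bb", "ccb", "hb", "platelet", "creatinine",
         "uric_acid", "e_over_eprime", "ef_tte", "tr_tte", "baseline_bnp"),
  RR = c("minRR", "maxRR", "avgRR"),
  HRV72h = c("minHR", "maxHR", "avgHR"),
  HRV30min = hrv_metric_names
)

interaction_names <- c("int_rmssd_hr", "int_lfhf_sdnn")

#' Resolve feature groups into static and sequence feature names
#'
#' `CM`, `RR` and `HRV72h` contribute static (per-patient) features;
#' `HRV30min` contributes the per-window sequence features.
#'
#' @param groups Character subset of
#'   `c("CM", "RR", "HRV72h", "HRV30min")`.
#' @return List with `static` and `sequence` character vectors.
#' @export
select_groups <- function(groups) {
  if (!length(groups)) abort("at least one feature group is required",
                             class = "afbnp_config_error")
  unknown <- setdiff(groups, names(feature_group_registry))
  if (length(unknown)) {
    abort(sprintf("unknown feature group(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "afbnp_config_error")
  }
  static <- unlist(feature_group_registry[intersect(c("CM", "RR", "HRV72h"),
                                                    groups)],
                   use.names = FALSE)
  sequence <- if ("HRV30min" %in% groups) feature_group_registry$HRV30min else character()
  list(static = static, sequence = sequence)
}

#' Yeo-Johnson power transformation
#'
#' The four-branch power transform defined for all real inputs:
#' for `x >= 0`, `((x+1)^lambda - 1)/lambda` (or `log(x+1)` at
#' `lambda = 0`); for `x < 0`, `-((1-x)^(2-lambda) - 1)/(2-lambda)`
#' (or `-log(1-x)` at `lambda = 2`).
#'
#' @param x Numeric vector.
#' @param lambda Transformation parameter.
#' @return Transformed vector.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  neg <- !is.na(x) & x < 0
  if (abs(lambda - 2) > 1e-12) {
    out[neg] <- -((1 - x[neg])^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out[is.na(x)] <- NA_real_
  out
}

#' Maximum-likelihood Yeo-Johnson parameter
#'
#' Profiles the Gaussian log-likelihood of the transformed sample over
#' `lambda` in `[-3, 5]`.
#'
#' @param x Numeric vector (finite values).
#' @return The fitted `lambda`.
#' @export
fit_yeo_johnson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2 || sd(x) == 0) return(1)
  jac <- sum(sign(x) * log1p(abs(x)))
  nll <- function(l) {
    y <- yeo_johnson(x, l)
    v <- var(y) * (n - 1) / n
    if (!is.finite(v) || v <= 0) return(Inf)
    n / 2 * log(v) - (l - 1) * jac
  }
  optimize(nll, c(-3, 5))$minimum
}

fit_feature_scaler <- function(x, name) {
  x <- x[is.finite(x)]
  if (length(x) == 0) {
    return(tibble::tibble(feature = name, lambda = 1, center = 0, scale = 1,
                          zero_var = TRUE))
  }
  if (length(unique(x)) < 2) {
    return(tibble::tibble(feature = name, lambda = 1, center = mean(x),
                          scale = 1, zero_var = TRUE))
  }
  l <- fit_yeo_johnson(x)
  y <- yeo_johnson(x, l)
  tibble::tibble(feature = name, lambda = l, center = mean(y),
                 scale = sd(y), zero_var = FALSE)
}

apply_feature_scaler <- function(x, scaler_row) {
  (yeo_johnson(x, scaler_row$lambda) - scaler_row$center) / scaler_row$scale
}

#' Fit Yeo-Johnson + z-score scalers on a training fold
#'
#' Static scalers are fit across the training patients' static rows;
#' sequence scalers are fit on the pooled valid windows of the training
#' patients (sentinel windows never enter the statistics); context
#' scalers cover baseline NT-proBNP and meanRMSSD. The state records the
#' training patient ids and a content hash so leave-one-out hygiene is
#' auditable.
#'
#' @param features An `af_features` object from [extract_features()].
#' @param train_ids Patient ids of the training fold.
#' @param groups Feature groups (see [select_groups()]).
#' @return A `scaler_state` list with tibbles `static`, `sequence`,
#'   `context`, plus `train_ids` and `fit_hash`.
#' @export
fit_scalers <- function(features, train_ids,
                        groups = c("CM", "RR", "HRV72h", "HRV30min")) {
  sel <- select_groups(groups)
  st <- dplyr::filter(features$static, .data$patient_id %in% train_ids)
  if (!nrow(st)) abort("empty training fold", class = "afbnp_config_error")
  wf <- dplyr::filter(features$windows, .data$patient_id %in% train_ids,
                      .data$valid)
  seq_feats <- c(sel$sequence,
                 if (length(sel$sequence)) interaction_names else character())
  static_tbl <- dplyr::bind_rows(
    purrr::map(sel$static, ~ fit_feature_scaler(st[[.x]], .x)))
  sequence_tbl <- dplyr::bind_rows(
    purrr::map(seq_feats, ~ fit_feature_scaler(wf[[.x]], .x)))
  context_tbl <- dplyr::bind_rows(
    fit_feature_scaler(st[["baseline_bnp"]], "baseline_bnp"),
    fit_feature_scaler(st[["meanRMSSD"]], "meanRMSSD"))
  structure(
    list(static = static_tbl, sequence = sequence_tbl, context = context_tbl,
         groups = groups,
         train_ids = sort(train_ids),
         fit_hash = content_hash(list(sort(train_ids), groups))),
    class = "scaler_state"
  )
}

standardize_columns <- function(df, scaler_tbl) {
  out <- purrr::map(seq_len(nrow(scaler_tbl)), function(i) {
    row <- scaler_tbl[i, ]
    apply_feature_scaler(df[[row$feature]], row)
  })
  m <- do.call(cbind, out)
  colnames(m) <- scaler_tbl$feature
  m
}

#' Extract the raw (unstandardized) feature store for a cohort
#'
#' Runs [extract_recording_features()] on every usable recording and
#' assembles: `static` (one row per patient: clinical metrics, RR and
#' HRV72h summaries, meanRMSSD), `windows` (per-window HRV metrics plus
#' interaction terms, sentinel -1 on invalid windows), `quality`, and the
#' cohort outcomes. Recordings failing the quality gate, or with no valid
#' window, are excluded and listed in `rejected`.
#'
#' @param cohort An `af_cohort` from [simulate_cohort()].
#' @param window_min Window length (minutes).
#' @param ... Passed to [extract_recording_features()].
#' @return An `af_features` list.
#' @export
extract_features <- function(cohort, window_min = 30, ...) {
  stopifnot(inherits(cohort, "af_cohort"))
  per <- purrr::imap(cohort$recordings, function(ann, pid) {
    rec <- extract_recording_features(ann, window_min = window_min, ...)
    rec$quality$patient_id <- pid
    rec
  })
  quality <- dplyr::bind_rows(purrr::map(per, "quality"))
  rejected <- quality$patient_id[!quality$usable]
  windows <- dplyr::bind_rows(purrr::imap(per, function(rec, pid) {
    wf <- rec$windows
    wf$patient_id <- pid
    # interaction terms: products of within-window metrics, sentinel
    # propagated on invalid windows
    wf$int_rmssd_hr <- ifelse(wf$valid, wf$RMSSD * (60000 / wf$meanNN),
                              HRV_SENTINEL)
    wf$int_lfhf_sdnn <- ifelse(wf$valid, wf$LF_HF * wf$SDNN, HRV_SENTINEL)
    wf
  }))
  no_valid <- windows |>
    dplyr::summarise(any_valid = any(.data$valid), .by = "patient_id") |>
    dplyr::filter(!.data$any_valid) |>
    dplyr::pull("patient_id")
  rejected <- union(rejected, no_valid)
  summaries <- dplyr::bind_rows(purrr::imap(per, function(rec, pid) {
    if (is.null(rec$summary)) return(NULL)
    dplyr::mutate(rec$summary, patient_id = pid)
  }))
  static <- cohort$clinical |>
    dplyr::inner_join(summaries, by = "patient_id") |>
    dplyr::filter(!.data$patient_id %in% rejected)
  windows <- dplyr::filter(windows, !.data$patient_id %in% rejected)
  structure(
    list(static = static,
         windows = dplyr::relocate(windows, "patient_id"),
         quality = quality,
         outcomes = dplyr::filter(cohort$outcomes,
                                  !.data$patient_id %in% rejected),
         rejected = rejected,
         window_min = window_min),
    class = "af_features"
  )
}

#' Build the standardized model input for one patient
#'
#' The sequence block holds, per 30-min window, the standardized HRV30min
#' metrics and interaction terms (zero fill on masked windows) with the
#' standardized static block replicated across rows; the context vector
#' is the standardized pair (baseline NT-proBNP, meanRMSSD); the validity
#' mask marks sentinel windows, which never contribute to training
#' statistics or attention.
#'
#' @param features An `af_features` store.
#' @param patient_id Patient to assemble.
#' @param scalers A `scaler_state` from [fit_scalers()].
#' @return An `af_tensor` list: `X` (T x F matrix), `mask` (length-T
#'   logical), `context` (length-2), `patient_id`, `feature_names`.
#' @export
build_patient_tensor <- function(features, patient_id, scalers) {
  wf <- features$windows |>
    dplyr::filter(.data$patient_id == !!patient_id) |>
    dplyr::arrange(.data$window_index)
  if (!nrow(wf)) abort(sprintf("no windows for patient %s", patient_id),
                       class = "afbnp_insufficient_data")
  if (!any(wf$valid)) {
    abort(sprintf("patient %s has no valid window", patient_id),
          class = "afbnp_insufficient_data")
  }
  st <- dplyr::filter(features$static, .data$patient_id == !!patient_id)
  if (nrow(st) != 1) abort(sprintf("no static row for patient %s", patient_id),
                           class = "afbnp_insufficient_data")
  t_len <- nrow(wf)
  mask <- wf$valid
  blocks <- list()
  if (nrow(scalers$sequence)) {
    seq_block <- standardize_columns(wf, scalers$sequence)
    seq_block[!mask, ] <- 0 # fixed post-standardization fill, masked out
    blocks$seq <- seq_block
  }
  if (nrow(scalers$static)) {
    static_row <- standardize_columns(st, scalers$static)
    blocks$static <- matrix(rep(static_row, each = t_len), nrow = t_len,
                            dimnames = list(NULL, colnames(static_row)))
  }
  x <- do.call(cbind, blocks)
  ctx <- as.numeric(standardize_columns(st, scalers$context))
  structure(
    list(patient_id = patient_id, X = x, mask = mask, context = ctx,
         feature_names = colnames(x)),
    class = "af_tensor"
  )
}
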