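#' Configuration of the context-aware sequence regressor
#'
#' Defaults follow the published training recipe: three LSTM layers with
#' 64/32/16 hidden units, Adam at learning rate 0.001, batch size 8,
#' mean-squared-error loss, early stopping on training loss with
#' patience 10, L2 weight decay 0.001 and dropout 0.5. Attention
#' projection and head sizes are package defaults.
#'
#' @param lstm_units Hidden units of the three stacked LSTM layers.
#' @param attention_dim Size of the additive-attention projection.
#' @param head_hidden Width of the first regression-head layer.
#' @param dropout Dropout rate in `[0, 1)`, applied to the pooled
#'   attention output and the head hidden layer.
#' @param l2 L2 penalty on all weight matrices (not biases).
#' @param lr Adam learning rate.
#' @param batch_size Patients per gradient step.
#' @param patience Early-stopping patience (epochs without improvement of
#'   the training loss).
#' @param max_epochs Epoch cap.
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(lstm_units = c(64, 32, 16), attention_dim = 16,
                         head_hidden = 16, dropout = 0.5, l2 = 0.001,
                         lr = 0.001, batch_size = 8, patience = 10,
                         max_epochs = 200, seed = 1) {
  stopifnot(length(lstm_units) == 3, all(lstm_units > 0))
  assert_scalar_number(dropout, "dropout", 0, 0.999)
  assert_scalar_number(l2, "l2", 0)
  assert_scalar_number(lr, "lr", 1e-12)
  assert_scalar_number(batch_size, "batch_size", 1)
  assert_scalar_number(patience, "patience", 1)
  assert_scalar_number(max_epochs, "max_epochs", 1)
  structure(
    list(lstm_units = as.integer(lstm_units),
         attention_dim = as.integer(attention_dim),
         head_hidden = as.integer(head_hidden),
         dropout = dropout, l2 = l2, lr = lr,
         batch_size = as.integer(batch_size),
         patience = as.integer(patience),
         max_epochs = as.integer(max_epochs),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_model_params <- function(config, f_seq, ctx_dim) {
  u <- config$lstm_units
  a <- config$attention_dim
  hh <- config$head_hidden
  dims <- c(f_seq, u)
  params <- list()
  for (l in 1:3) {
    n <- u[l]; d <- dims[l]
    b <- rep(0, 4 * n)
    b[(n + 1):(2 * n)] <- 1 # forget-gate bias init
    params[[paste0("W", l)]] <- glorot(4 * n, d)
    params[[paste0("U", l)]] <- glorot(4 * n, n)
    params[[paste0("b", l)]] <- b
  }
  params$Wh <- glorot(a, u[3])
  params$Wc <- glorot(a, ctx_dim)
  params$ba <- rep(0, a)
  params$va <- as.numeric(glorot(a, 1))
  params$W1h <- glorot(hh, u[3] + ctx_dim)
  params$b1h <- rep(0, hh)
  params$w2h <- glorot(1, hh)
  params$b2h <- 0
  params
}

weight_param_names <- c("W1", "U1", "W2", "U2", "W3", "U3",
                        "Wh", "Wc", "va", "W1h", "w2h")

#' Build an untrained context-aware LSTM-attention model
#'
#' Composition: sequence block -> LSTM(64) -> LSTM(32) -> LSTM(16) ->
#' context-conditioned additive attention -> concatenate(pooled state,
#' context) -> dense(tanh, dropout) -> dense(1, linear). Initialization
#' is fully determined by `config$seed`.
#'
#' @param config A [model_config()].
#' @param f_seq Number of sequence-block features per window.
#' @param ctx_dim Context-vector dimension (2 for baseline NT-proBNP and
#'   meanRMSSD).
#' @return An `af_model` list; `n_params` reports the parameter count.
#' @export
build_model <- function(config, f_seq, ctx_dim = 2) {
  assert_scalar_number(f_seq, "f_seq", 1)
  assert_scalar_number(ctx_dim, "ctx_dim", 1)
  params <- with_seed(substream_seed(config$seed, 0L, purpose = 7L),
                      init_model_params(config, f_seq, ctx_dim))
  structure(
    list(config = config, params = params, f_seq = as.integer(f_seq),
         ctx_dim = as.integer(ctx_dim),
         n_params = sum(vapply(params, length, integer(1))),
         trained = FALSE, history = NULL, target_transform = NULL),
    class = "af_model"
  )
}

#' @export
print.af_model <- function(x, ...) {
  cat(sprintf("<af_model> LSTM(%s) + context attention, %d parameters, %s\n",
              paste(x$config$lstm_units, collapse = "/"), x$n_params,
              if (x$trained) sprintf("trained (%d epochs)",
                                     nrow(x$history)) else "untrained"))
  invisible(x)
}

#' Context-conditioned additive attention
#'
#' Scores each time step as `e_t = va' tanh(Wh h_t + Wc c + ba)`, assigns
#' masked steps a score of -Inf before softmax normalization (so their
#' weights are exactly zero), and pools the hidden states with the
#' resulting simplex weights.
#'
#' @param hidden_states T x H matrix of final-layer hidden states.
#' @param context Context vector.
#' @param params List with `Wh` (A x H), `Wc` (A x C), `ba` (A), `va` (A).
#' @param mask Optional length-T logical; `FALSE` steps are excluded.
#' @return List with `weights` (length T, sums to 1) and `pooled_state`
#'   (length H).
#' @export
context_attention <- function(hidden_states, context, params, mask = NULL) {
  h <- as.matrix(hidden_states)
  t_len <- nrow(h)
  if (is.null(mask)) mask <- rep(TRUE, t_len)
  if (!any(mask)) abort("all time steps are masked",
                        class = "afbnp_insufficient_data")
  r <- h %*% t(params$Wh)
  r <- sweep(r, 2, as.numeric(params$Wc %*% context) + params$ba, "+")
  e <- as.numeric(tanh(r) %*% params$va)
  e[!mask] <- -Inf
  w <- exp(e - max(e[mask]))
  w[!mask] <- 0
  w <- w / sum(w)
  list(weights = w, pooled_state = as.numeric(crossprod(w, h)))
}

tensor_to_batch <- function(tensors) {
  xs <- purrr::map(tensors, function(tn) t(tn$X[tn$mask, , drop = FALSE]))
  ctx <- do.call(cbind, purrr::map(tensors, "context"))
  list(xs = xs, ctx = ctx)
}

#' Train the model with Adam, MSE loss and early stopping
#'
#' The regression target is the standardized log ratio
#' `log(followup / baseline)` of NT-proBNP (centre/scale estimated on the
#' training patients and stored in the model for inverse transformation).
#' Training monitors the epoch-mean training loss and stops after
#' `patience` epochs without improvement, restoring the best parameters.
#'
#' @param model An `af_model` from [build_model()].
#' @param tensors List of `af_tensor` objects (training patients).
#' @param outcomes Outcome tibble with `patient_id`, `baseline_ntprobnp`,
#'   `followup_ntprobnp` covering the training patients.
#' @return The trained `af_model`, with `history` (tibble of per-epoch
#'   loss) and `target_transform`.
#' @export
train_model <- function(model, tensors, outcomes) {
  stopifnot(inherits(model, "af_model"))
  n <- length(tensors)
  if (n < 2) abort("need at least 2 training patients",
                   class = "afbnp_config_error")
  ids <- vapply(tensors, function(x) x$patient_id, character(1))
  oc <- outcomes[match(ids, outcomes$patient_id), ]
  if (anyNA(oc$patient_id)) abort("outcomes missing for some training patients",
                                  class = "afbnp_config_error")
  lr_raw <- log(oc$followup_ntprobnp / oc$baseline_ntprobnp)
  tt <- list(center = mean(lr_raw),
             scale = if (sd(lr_raw) > 0) sd(lr_raw) else 1)
  targets <- (lr_raw - tt$center) / tt$scale

  cfg <- model$config
  params <- model$params
  adam_m <- purrr::map(params, ~ .x * 0)
  adam_v <- purrr::map(params, ~ .x * 0)
  step <- 0L
  n3 <- cfg$lstm_units[3]
  use_drop <- cfg$dropout > 0
  keep <- 1 - cfg$dropout
  best <- Inf; best_params <- params; wait <- 0L
  history <- numeric(0)

  batch_data <- tensor_to_batch(tensors)
  # batches group patients of similar sequence length (less tail padding);
  # batch order and in-batch order reshuffle every epoch
  len_order <- order(vapply(batch_data$xs, ncol, integer(1)))
  batches <- split(len_order, ceiling(seq_along(len_order) / cfg$batch_size))
  with_seed(substream_seed(cfg$seed, 1L, purpose = 8L), {
    for (epoch in seq_len(cfg$max_epochs)) {
      epoch_loss <- 0
      for (bi in sample.int(length(batches))) {
        bvec <- batches[[bi]]
        idx <- bvec[sample.int(length(bvec))]
        bsz <- length(idx)
        dp <- if (use_drop) {
          matrix(rbinom(n3 * bsz, 1, keep) / keep, n3, bsz)
        } else matrix(1, 1, 1)
        dh <- if (use_drop) {
          matrix(rbinom(cfg$head_hidden * bsz, 1, keep) / keep,
                 cfg$head_hidden, bsz)
        } else matrix(1, 1, 1)
        res <- cpp_model_grad(params, batch_data$xs[idx],
                              batch_data$ctx[, idx, drop = FALSE],
                              targets[idx], dp, dh, use_drop)
        if (!is.finite(res$loss)) {
          abort(sprintf("training diverged (non-finite loss at epoch %d)",
                        epoch),
                class = "afbnp_training_divergence")
        }
        g <- res$grads
        step <- step + 1L
        for (nm in names(params)) {
          gi <- g[[nm]]
          if (cfg$l2 > 0 && nm %in% weight_param_names) {
            gi <- gi + 2 * cfg$l2 * params[[nm]]
          }
          adam_m[[nm]] <- 0.9 * adam_m[[nm]] + 0.1 * gi
          adam_v[[nm]] <- 0.999 * adam_v[[nm]] + 0.001 * gi^2
          mhat <- adam_m[[nm]] / (1 - 0.9^step)
          vhat <- adam_v[[nm]] / (1 - 0.999^step)
          params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + 1e-8)
        }
        epoch_loss <- epoch_loss + res$loss * bsz
      }
      epoch_loss <- epoch_loss / n
      history <- c(history, epoch_loss)
      if (epoch_loss < best - 1e-9) {
        best <- epoch_loss
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$params <- best_params
  model$trained <- TRUE
  model$history <- tibble::tibble(epoch = seq_along(history), loss = history)
  model$best_loss <- best
  model$target_transform <- tt
  model$train_ids <- sort(ids)
  model
}

#' Predict on the standardized target scale
#'
#' Deterministic at inference (dropout off).
#'
#' @param model A trained `af_model`.
#' @param tensors One `af_tensor` or a list of them.
#' @return Numeric vector of standardized log-ratio predictions.
#' @export
predict_score <- function(model, tensors) {
  if (inherits(tensors, "af_tensor")) tensors <- list(tensors)
  bd <- tensor_to_batch(tensors)
  as.numeric(cpp_model_forward(model$params, bd$xs, bd$ctx)$y)
}

#' Predict the NT-proBNP change in pg/mL
#'
#' Inverts the standardized log-ratio target: predicted change =
#' `baseline * (exp(score * scale + center) - 1)`.
#'
#' @param model A trained `af_model`.
#' @param tensors One `af_tensor` or a list of them.
#' @param baseline_ntprobnp Baseline NT-proBNP (pg/mL), recycled to the
#'   number of tensors.
#' @return Numeric vector of predicted changes (pg/mL).
#' @export
predict_delta <- function(model, tensors, baseline_ntprobnp) {
  if (!isTRUE(model$trained)) abort("model is not trained",
                                    class = "afbnp_contract_error")
  score <- predict_score(model, tensors)
  tt <- model$target_transform
  lr_hat <- score * tt$scale + tt$center
  as.numeric(baseline_ntprobnp) * (exp(lr_hat) - 1)
}

#' Attention weights for one patient (diagnostics)
#'
#' @param model A trained `af_model`.
#' @param tensor An `af_tensor`.
#' @return Tibble with `window_index` (positions of unmasked windows in
#'   the tensor) and `weight`.
#' @export
attention_weights <- function(model, tensor) {
  bd <- tensor_to_batch(list(tensor))
  w <- cpp_model_forward(model$params, bd$xs, bd$ctx,
                         return_attention = TRUE)$attention[[1]]
  tibble::tibble(window_index = which(tensor$mask), weight = w)
}

#' @exportS3Method generics::tidy
tidy.af_model <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble(epoch = integer(),
                                                loss = numeric()))
  x$history
}

#' @exportS3Method generics::glance
glance.af_model <- function(x, ...) {
  tibble::tibble(
    n_params = x$n_params,
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_loss = x$best_loss %||% NA_real_
  )
}
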