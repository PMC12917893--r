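tiny_params <- function(seed = 11, f = 3, ctxd = 2) {
  cfg <- model_config(lstm_units = c(4, 3, 2), attention_dim = 3,
                      head_hidden = 3, dropout = 0, l2 = 0, seed = seed)
  build_model(cfg, f, ctxd)
}

test_that("analytic gradients match central finite differences", {
  m <- tiny_params()
  withr::with_seed(2, {
    xs <- lapply(c(5, 3, 4), function(tl) matrix(rnorm(3 * tl), 3, tl))
    ctx <- matrix(rnorm(6), 2, 3)
    targets <- rnorm(3)
  })
  dm <- matrix(1, 1, 1)
  res <- afbnp:::cpp_model_grad(m$params, xs, ctx, targets, dm, dm, FALSE)
  lossfun <- function(p) afbnp:::cpp_model_grad(p, xs, ctx, targets,
                                                dm, dm, FALSE)$loss
  eps <- 1e-5
  for (nm in names(m$params)) {
    g <- as.numeric(res$grads[[nm]])
    gn <- vapply(seq_along(m$params[[nm]]), function(i) {
      up <- m$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      (lossfun(up) - lossfun(dn)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(g - gn) / pmax(1e-4, abs(g) + abs(gn))), 1e-4)
  }
})

test_that("attention weights form a simplex and vanish on masked steps", {
  m <- tiny_params()
  p <- m$params[c("Wh", "Wc", "ba", "va")]
  withr::with_seed(9, {
    for (i in 1:25) {
      t_len <- sample(1:12, 1)
      h <- matrix(rnorm(t_len * 2), t_len, 2)
      mask <- runif(t_len) > 0.3
      if (!any(mask)) mask[1] <- TRUE
      a <- context_attention(h, rnorm(2), p, mask)
      expect_true(all(a$weights >= 0))
      expect_equal(sum(a$weights), 1, tolerance = 1e-6)
      expect_true(all(a$weights[!mask] == 0))
      expect_equal(a$pooled_state, as.numeric(crossprod(a$weights, h)))
    }
  })
})

test_that("attention worked examples hold", {
  m <- tiny_params()
  p <- m$params[c("Wh", "Wc", "ba", "va")]
  h1 <- matrix(rnorm(2), 1, 2)
  one <- context_attention(h1, rnorm(2), p)
  expect_equal(one$weights, 1)
  expect_equal(one$pooled_state, as.numeric(h1)) # softmax of a singleton

  # zero context projection + identical states => uniform weights
  p0 <- p
  p0$Wc <- p0$Wc * 0
  h <- matrix(rep(c(0.3, -0.2), each = 5), 5, 2)
  u <- context_attention(h, rnorm(2), p0)
  expect_equal(u$weights, rep(0.2, 5))

  # explicit mask: step 2 gets exactly zero
  h3 <- matrix(rnorm(6), 3, 2)
  a <- context_attention(h3, c(0.1, -0.4), p, mask = c(TRUE, FALSE, TRUE))
  expect_identical(a$weights[2], 0)
  expect_equal(a$weights[1] + a$weights[3], 1, tolerance = 1e-12)

  expect_error(context_attention(h3, c(0, 0), p, mask = rep(FALSE, 3)),
               class = "afbnp_insufficient_data")
})

test_that("the R attention surface agrees with the compiled model path", {
  m <- tiny_params(seed = 5)
  tn <- random_tensor(10, 3, seed = 31, n_masked = 3)
  bd <- afbnp:::tensor_to_batch(list(tn))
  # run the compiled forward to the attention stage: recompute hidden
  # states via the full forward and compare its weights with the R module
  out <- afbnp:::cpp_model_forward(m$params, bd$xs, bd$ctx,
                                   return_attention = TRUE)
  w_cpp <- out$attention[[1]]
  # reproduce hidden states in R with a direct LSTM recurrence
  lstm_r <- function(W, U, b, X) {
    n <- ncol(U); tl <- ncol(X)
    h <- matrix(0, n, tl); hp <- rep(0, n); cp <- rep(0, n)
    sig <- function(z) 1 / (1 + exp(-z))
    for (t in seq_len(tl)) {
      a <- W %*% X[, t] + U %*% hp + b
      i <- sig(a[1:n]); f <- sig(a[n + 1:n])
      g <- tanh(a[2 * n + 1:n]); o <- sig(a[3 * n + 1:n])
      cp <- f * cp + i * g
      hp <- o * tanh(cp)
      h[, t] <- hp
    }
    h
  }
  x <- bd$xs[[1]]
  h1 <- lstm_r(m$params$W1, m$params$U1, m$params$b1, x)
  h2 <- lstm_r(m$params$W2, m$params$U2, m$params$b2, h1)
  h3 <- lstm_r(m$params$W3, m$params$U3, m$params$b3, h2)
  a_r <- context_attention(t(h3), tn$context,
                           m$params[c("Wh", "Wc", "ba", "va")])
  expect_equal(w_cpp, a_r$weights, tolerance = 1e-10)
})

test_that("model building is deterministic and counts parameters exactly", {
  cfg <- model_config(seed = 77, head_hidden = 8)
  m1 <- build_model(cfg, f_seq = 9, ctx_dim = 2)
  m2 <- build_model(cfg, f_seq = 9, ctx_dim = 2)
  expect_identical(m1$params, m2$params)
  expect_identical(cfg$lstm_units, c(64L, 32L, 16L))
  # closed-form parameter arithmetic for the declared architecture
  lstm <- function(d, n) 4 * n * (d + n + 1)
  att <- 16 * 16 + 16 * 2 + 16 + 16    # Wh + Wc + ba + va
  head <- 8 * (16 + 2) + 8 + 8 + 1     # W1h + b1h + w2h + b2h
  expect_equal(m1$n_params,
               lstm(9, 64) + lstm(64, 32) + lstm(32, 16) + att + head)
})

test_that("predictions are deterministic and invariant to masked padding", {
  m <- tiny_params(seed = 19)
  m$trained <- TRUE
  m$target_transform <- list(center = 0.1, scale = 0.5)
  tn <- random_tensor(12, 3, seed = 4, n_masked = 2)
  p1 <- predict_delta(m, tn, 1000)
  p2 <- predict_delta(m, tn, 1000)
  expect_identical(p1, p2)

  # appending masked padding rows never changes the prediction
  pad <- matrix(7, 5, ncol(tn$X))
  tn_pad <- tn
  tn_pad$X <- rbind(tn$X, pad)
  tn_pad$mask <- c(tn$mask, rep(FALSE, 5))
  expect_identical(predict_delta(m, tn_pad, 1000), p1)

  # permuting masked rows (mask positions) leaves the prediction unchanged
  ord <- order(!tn$mask) # valid rows first, same relative order
  tn_perm <- tn
  tn_perm$X <- tn$X[ord, , drop = FALSE]
  tn_perm$mask <- tn$mask[ord]
  expect_identical(predict_delta(m, tn_perm, 1000), p1)

  expect_error(predict_delta(tiny_params(), tn, 1000),
               class = "afbnp_contract_error")
})

make_teacher_data <- function(n, t_len = 20, f = 4, seed = 1, noise = 0) {
  withr::with_seed(seed, {
    beta <- c(1.5, -2, 0.8, 0.5)
    tensors <- lapply(seq_len(n), function(i) {
      x <- matrix(rnorm(t_len * f), t_len, f)
      structure(list(patient_id = sprintf("S%02d", i), X = x,
                     mask = rep(TRUE, t_len), context = rnorm(2)),
                class = "af_tensor")
    })
    lr <- vapply(tensors, function(tn) sum(colMeans(tn$X) * beta),
                 numeric(1)) + rnorm(n, 0, noise)
    oc <- tibble::tibble(patient_id = sprintf("S%02d", seq_len(n)),
                         baseline_ntprobnp = 1000,
                         followup_ntprobnp = 1000 * exp(lr))
    list(tensors = tensors, outcomes = oc, logratio = lr)
  })
}

test_that("training learns a noiseless linear teacher", {
  td <- make_teacher_data(40, seed = 6)
  cfg <- model_config(lstm_units = c(8, 6, 4), attention_dim = 4,
                      head_hidden = 6, dropout = 0, l2 = 0,
                      max_epochs = 150, patience = 30, seed = 2)
  m <- train_model(build_model(cfg, f_seq = 4), td$tensors, td$outcomes)
  expect_lt(min(m$history$loss), 0.1 * m$history$loss[1])
  # held-in prediction recovers the teacher on the log-ratio scale
  sc <- predict_score(m, td$tensors)
  pred_lr <- sc * m$target_transform$scale + m$target_transform$center
  expect_lt(sqrt(mean((pred_lr - td$logratio)^2)), 0.5 * sd(td$logratio))
})

test_that("training is seeded and monitors a running-minimum loss", {
  td <- make_teacher_data(10, t_len = 8, seed = 3)
  cfg <- model_config(lstm_units = c(5, 4, 3), attention_dim = 3,
                      head_hidden = 4, max_epochs = 12, patience = 3,
                      seed = 21)
  m1 <- train_model(build_model(cfg, f_seq = 4), td$tensors, td$outcomes)
  m2 <- train_model(build_model(cfg, f_seq = 4), td$tensors, td$outcomes)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  # early stopping: the run ends at most `patience` epochs after the
  # last improvement of the running minimum
  best_epoch <- which.min(m1$history$loss)
  run_min <- cummin(m1$history$loss)
  last_improve <- max(which(m1$history$loss == run_min))
  expect_lte(nrow(m1$history) - last_improve, cfg$patience)
  expect_equal(m1$best_loss, min(m1$history$loss))
})

test_that("the model can overfit a single patient to near-zero loss", {
  td <- make_teacher_data(2, t_len = 10, seed = 8)
  cfg <- model_config(lstm_units = c(6, 5, 4), attention_dim = 4,
                      head_hidden = 6, dropout = 0, l2 = 0,
                      max_epochs = 300, patience = 300, lr = 0.01, seed = 5)
  m <- train_model(build_model(cfg, f_seq = 4), td$tensors, td$outcomes)
  expect_lt(min(m$history$loss), 1e-3)
})

test_that("one small step changes parameters on the order of the step size", {
  td <- make_teacher_data(4, t_len = 6, seed = 10)
  base <- model_config(lstm_units = c(4, 3, 2), attention_dim = 3,
                       head_hidden = 3, dropout = 0, l2 = 0,
                       max_epochs = 1, patience = 5, seed = 9)
  deltas <- vapply(c(1e-3, 1e-4), function(lr_val) {
    cfg <- base; cfg$lr <- lr_val
    m0 <- build_model(cfg, f_seq = 4)
    m1 <- train_model(m0, td$tensors, td$outcomes)
    max(abs(unlist(m1$params) - unlist(m0$params)))
  }, numeric(1))
  # Adam's first step is ~lr in magnitude
  expect_equal(deltas[1], 1e-3, tolerance = 0.2)
  expect_equal(deltas[2], 1e-4, tolerance = 0.2)
})
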