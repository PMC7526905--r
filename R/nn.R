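## One-hidden-layer feedforward regressor for radii prediction:
## 64 tanh hidden units, linear 3-unit output, mean-squared-error loss
## E = 1/(2N) sum_n sum_i (rhat_i - r_i)^2, minimized by mini-batch Adam
## with early stopping on a held-out fraction of the training data.

#' Regressor specification
#'
#' @param n_bits Input width (fingerprint length).
#' @param hidden Hidden-layer width (default 64 tanh units).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param val_fraction Fraction of the training data held out for early
#'   stopping (default 0.10).
#' @param patience Epochs without validation improvement before stopping
#'   (default 20).
#' @param max_epochs Hard epoch cap (default 2000).
#' @param seed Integer seed controlling initialization, the early-stopping
#'   split and mini-batch shuffling.
#' @return A list of class `"nn_spec"`.
#' @export
nn_spec <- function(n_bits = 2048, hidden = 64, lr = 0.001, batch_size = 32,
                    val_fraction = 0.10, patience = 20, max_epochs = 2000,
                    seed = 1) {
  stopifnot(n_bits >= 1, hidden >= 1, lr > 0, batch_size >= 1,
            val_fraction > 0, val_fraction < 1, patience >= 1,
            max_epochs >= 1)
  structure(list(n_bits = n_bits, hidden = hidden, lr = lr,
                 batch_size = batch_size, val_fraction = val_fraction,
                 patience = patience, max_epochs = max_epochs,
                 seed = as.integer(seed)),
            class = "nn_spec")
}

nn_forward <- function(par, X) {
  H <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
  list(H = H, Y = sweep(H %*% par$W2, 2, par$b2, "+"))
}

# mean per-record half squared error: E/N with E as in the model loss
nn_loss <- function(par, X, Y) {
  mean(rowSums((nn_forward(par, X)$Y - Y)^2)) / 2
}

#' Train the radii regressor
#'
#' Splits off `val_fraction` of the data for early stopping, then runs
#' mini-batch Adam on the remainder, minimizing the half mean squared
#' error over the three output radii.  Training stops when the validation
#' loss has not improved for `patience` epochs (or at `max_epochs`); the
#' parameters achieving the best validation loss are returned.  Fully
#' reproducible given `spec$seed`.
#'
#' @param dataset A `"fingerprint_dataset"` (see [generate_ml_dataset()]),
#'   or a list with elements `X` (n x n_bits matrix) and `Y` (n x 3).
#' @param spec An [nn_spec()]; its `n_bits` must match `ncol(dataset$X)`.
#' @return A list of class `"ellipack_nn"`: weights (`W1`, `b1`, `W2`,
#'   `b2`), `spec`, `history` (per-epoch train/validation loss),
#'   `best_epoch`, `best_val_loss`.
#' @export
nn_train <- function(dataset, spec = nn_spec(n_bits = ncol(dataset$X))) {
  X <- dataset$X; Y <- dataset$Y
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y), ncol(Y) == 3)
  N <- nrow(X)
  if (N < 10) stop("need at least 10 records to train (got ", N, ")")
  if (ncol(X) != spec$n_bits)
    stop("spec$n_bits (", spec$n_bits, ") does not match data width (",
         ncol(X), ")")
  set.seed(spec$seed)
  n_val <- max(1, round(spec$val_fraction * N))
  idx <- sample(N)
  val <- idx[seq_len(n_val)]
  tr <- idx[-seq_len(n_val)]
  Xt <- X[tr, , drop = FALSE]; Yt <- Y[tr, , drop = FALSE]
  Xv <- X[val, , drop = FALSE]; Yv <- Y[val, , drop = FALSE]

  d <- spec$n_bits; h <- spec$hidden
  glorot <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin)
  par <- list(W1 = glorot(d, h), b1 = rep(0, h),
              W2 = glorot(h, 3), b2 = rep(0, 3))
  adam <- lapply(par, function(p) list(m = p * 0, v = p * 0))
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8; t_step <- 0

  best <- list(loss = Inf, par = par, epoch = 0)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  stall <- 0
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample(length(tr))
    starts <- seq(1, length(tr), by = spec$batch_size)
    for (s in starts) {
      b <- ord[s:min(s + spec$batch_size - 1, length(tr))]
      Xb <- Xt[b, , drop = FALSE]; Yb <- Yt[b, , drop = FALSE]
      fw <- nn_forward(par, Xb)
      dY <- (fw$Y - Yb) / length(b)
      gW2 <- t(fw$H) %*% dY
      gb2 <- colSums(dY)
      dH <- (dY %*% t(par$W2)) * (1 - fw$H^2)
      gW1 <- t(Xb) %*% dH
      gb1 <- colSums(dH)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      t_step <- t_step + 1
      for (nm in names(par)) {
        adam[[nm]]$m <- b1m * adam[[nm]]$m + (1 - b1m) * grads[[nm]]
        adam[[nm]]$v <- b2m * adam[[nm]]$v + (1 - b2m) * grads[[nm]]^2
        mhat <- adam[[nm]]$m / (1 - b1m^t_step)
        vhat <- adam[[nm]]$v / (1 - b2m^t_step)
        par[[nm]] <- par[[nm]] - spec$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    tl <- nn_loss(par, Xt, Yt)
    vl <- nn_loss(par, Xv, Yv)
    if (!is.finite(tl) || !is.finite(vl))
      stop("non-finite loss at epoch ", epoch, " (train ", tl,
           ", validation ", vl, ")")
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                         val_loss = vl))
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, par = par, epoch = epoch)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= spec$patience) break
    }
  }
  structure(c(best$par,
              list(spec = spec, history = history,
                   best_epoch = best$epoch, best_val_loss = best$loss)),
            class = "ellipack_nn")
}

#' Predict radii from fingerprints
#'
#' @param model An `"ellipack_nn"` from [nn_train()].
#' @param fingerprints A fingerprint matrix (rows = molecules), a single
#'   fingerprint vector, or a `"fingerprint_dataset"`.
#' @param sort_radii If `TRUE`, sort each predicted triple descending.
#' @return An n x 3 matrix of predicted radii (nm), columns r1, r2, r3.
#' @export
nn_predict <- function(model, fingerprints, sort_radii = FALSE) {
  stopifnot(inherits(model, "ellipack_nn"))
  X <- if (inherits(fingerprints, "fingerprint_dataset")) fingerprints$X
       else if (is.null(dim(fingerprints))) matrix(fingerprints, nrow = 1)
       else as.matrix(fingerprints)
  if (ncol(X) != nrow(model$W1))
    stop("fingerprint width ", ncol(X), " does not match model input ",
         nrow(model$W1))
  Y <- nn_forward(model, X)$Y
  if (sort_radii) Y <- t(apply(Y, 1, sort, decreasing = TRUE))
  colnames(Y) <- c("r1", "r2", "r3")
  Y
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

#' K-fold cross validation of the radii regressor
#'
#' Deterministic fold assignment from `spec$seed`; each fold's model is
#' trained on the remaining folds (with the early-stopping split taken
#' inside that training portion) and evaluated on the held-out fold.
#' A constant predictor at the training-fold mean is evaluated alongside
#' as a baseline.
#'
#' @param dataset A `"fingerprint_dataset"` or list with `X`, `Y`.
#' @param spec An [nn_spec()].
#' @param folds Number of folds (default 4).
#' @return A list of class `"nn_cv"`: `per_fold` (data frame with train /
#'   test RMSE and MAE, per-radius test RMSE, and baseline test RMSE per
#'   fold), `mean_train_rmse`, `mean_test_rmse`, `mean_test_mae`,
#'   `fold_id`.
#' @export
nn_cross_validate <- function(dataset, spec = nn_spec(n_bits = ncol(dataset$X)),
                              folds = 4) {
  X <- dataset$X; Y <- dataset$Y
  N <- nrow(X)
  stopifnot(folds >= 2, N >= folds)
  set.seed(spec$seed)
  fold_id <- sample(rep(seq_len(folds), length.out = N))
  rows <- lapply(seq_len(folds), function(k) {
    tr <- fold_id != k
    fold_spec <- spec
    fold_spec$seed <- spec$seed + k
    model <- nn_train(list(X = X[tr, , drop = FALSE],
                           Y = Y[tr, , drop = FALSE]), fold_spec)
    pred_tr <- nn_predict(model, X[tr, , drop = FALSE])
    pred_te <- nn_predict(model, X[!tr, , drop = FALSE])
    Yte <- Y[!tr, , drop = FALSE]
    base_pred <- matrix(colMeans(Y[tr, , drop = FALSE]),
                        nrow = sum(!tr), ncol = 3, byrow = TRUE)
    data.frame(
      fold = k,
      train_rmse = rmse(pred_tr, Y[tr, , drop = FALSE]),
      test_rmse = rmse(pred_te, Yte),
      train_mae = mean(abs(pred_tr - Y[tr, , drop = FALSE])),
      test_mae = mean(abs(pred_te - Yte)),
      test_rmse_r1 = rmse(pred_te[, 1], Yte[, 1]),
      test_rmse_r2 = rmse(pred_te[, 2], Yte[, 2]),
      test_rmse_r3 = rmse(pred_te[, 3], Yte[, 3]),
      baseline_test_rmse = rmse(base_pred, Yte),
      best_epoch = model$best_epoch)
  })
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean_train_rmse = mean(per_fold$train_rmse),
                 mean_test_rmse = mean(per_fold$test_rmse),
                 mean_test_mae = mean(per_fold$test_mae),
                 fold_id = fold_id),
            class = "nn_cv")
}

#' @export
print.nn_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean train RMSE %.4f nm, mean test RMSE %.4f nm\n",
              nrow(x$per_fold), x$mean_train_rmse, x$mean_test_rmse))
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}
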