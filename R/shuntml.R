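#' Configuration of the shunt-recovery MLP
#'
#' A dense feed-forward regressor: 10 input features, `hidden_layers` fully
#' connected ReLU layers of `units` each, and a single linear output unit,
#' trained with RMSprop on mean squared error.  The default architecture
#' (6 x 128) has 84,097 trainable parameters.
#'
#' @param n_features number of input features.
#' @param hidden_layers number of hidden layers.
#' @param units units per hidden layer.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr RMSprop learning rate.
#' @param rho RMSprop decay.
#' @param eps RMSprop epsilon.
#' @param lr_decay per-epoch multiplicative learning-rate decay (1 keeps the
#'   rate constant).
#' @param val_fraction fraction of training rows held out for loss
#'   monitoring only (0 disables).
#' @param seed integer seed for initialization and shuffling.
#' @return An object of class `mlp_config`.
#' @export
#' @examples
#' count_params(mlp_config())   # 84097
mlp_config <- function(n_features = 10, hidden_layers = 6, units = 128,
                       epochs = 500, batch_size = 32, lr = 1e-3,
                       rho = 0.9, eps = 1e-7, lr_decay = 0.994,
                       val_fraction = 0.1, seed = 1L) {
  stopifnot(n_features >= 1, hidden_layers >= 0, units >= 1, epochs >= 1,
            batch_size >= 1, lr > 0, rho > 0, rho < 1, lr_decay > 0,
            lr_decay <= 1, val_fraction >= 0, val_fraction < 1)
  structure(list(n_features = as.integer(n_features),
                 hidden_layers = as.integer(hidden_layers),
                 units = as.integer(units), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, rho = rho,
                 eps = eps, lr_decay = lr_decay, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Trainable parameter count of a dense MLP
#'
#' `(f + 1) u + (L - 1)(u + 1) u + (u + 1)` for `L >= 1` hidden layers of `u`
#' units on `f` features with one output unit (every dense layer carries a
#' bias); `f + 1` when there are no hidden layers.
#'
#' @param cfg an [mlp_config()].
#' @return Integer parameter count.
#' @export
count_params <- function(cfg = mlp_config()) {
  f <- cfg$n_features; L <- cfg$hidden_layers; u <- cfg$units
  if (L == 0) return(f + 1L)
  (f + 1L) * u + (L - 1L) * (u + 1L) * u + (u + 1L)
}

#' Train the shunt-recovery MLP
#'
#' Fits the configured MLP to predict the shunt label (% of pulmonary blood
#' flow) from the ten z-scored bedside features of the training split.
#' Normalization statistics are computed from training rows only and stored
#' with the model.
#'
#' @param ds a `scenario_dataset` with a `split` column (see
#'   [randomize_split()]), or a data frame with the ten feature columns and a
#'   `shunt` column (all rows then used for training).
#' @param cfg an [mlp_config()].
#' @return An object of class `shunt_mlp`: weights, normalization statistics,
#'   and the training/validation loss history.
#' @export
train_shunt_mlp <- function(ds, cfg = mlp_config()) {
  rec <- if (inherits(ds, "scenario_dataset")) ds$records else ds
  stopifnot(is.data.frame(rec), "shunt" %in% names(rec))
  missing <- setdiff(ten_features, names(rec))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  train <- if (!is.null(rec$split)) rec[rec$split == "train", ] else rec
  if (nrow(train) == 0) stop("empty training split")
  X <- as.matrix(train[, ten_features[seq_len(cfg$n_features)]])
  if (any(!is.finite(X))) stop("non-finite feature values in training data")
  y <- train$shunt

  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Xz <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  nval <- floor(cfg$val_fraction * nrow(Xz))
  if (nval > 0) {
    set.seed(cfg$seed)
    vi <- sample.int(nrow(Xz), nval)
    Xv <- Xz[vi, , drop = FALSE]; yv <- y[vi]
    Xt <- Xz[-vi, , drop = FALSE]; yt <- y[-vi]
  } else {
    Xv <- matrix(numeric(0), 0, ncol(Xz)); yv <- numeric(0)
    Xt <- Xz; yt <- y
  }

  fit <- cpp_mlp_train(Xt, yt, cfg$hidden_layers, cfg$units, cfg$epochs,
                       cfg$batch_size, cfg$lr, cfg$rho, cfg$eps, cfg$lr_decay,
                       cfg$seed, Xv, yv)
  structure(list(weights = fit$weights, biases = fit$biases,
                 loss = as.numeric(fit$loss), val_loss = as.numeric(fit$val_loss),
                 center = mu, scale = sdv, config = cfg,
                 features = ten_features[seq_len(cfg$n_features)]),
            class = "shunt_mlp")
}

#' @export
print.shunt_mlp <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Shunt-recovery MLP: %d features, %d x %d ReLU, %d parameters\n",
              cfg$n_features, cfg$hidden_layers, cfg$units, count_params(cfg)))
  cat(sprintf("  %d epochs, final training MSE %.4g\n",
              cfg$epochs, x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict shunt from bedside records
#'
#' @param object a fitted `shunt_mlp`.
#' @param newdata data frame (or `scenario_dataset`) carrying the ten feature
#'   columns.
#' @param ... unused.
#' @return Numeric vector of shunt estimates (% of pulmonary blood flow).
#' @export
predict.shunt_mlp <- function(object, newdata, ...) {
  rec <- if (inherits(newdata, "scenario_dataset")) newdata$records else newdata
  missing <- setdiff(object$features, names(rec))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  X <- as.matrix(rec[, object$features, drop = FALSE])
  Xz <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  as.numeric(cpp_mlp_predict(object$weights, object$biases, Xz))
}
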