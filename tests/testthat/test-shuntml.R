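enumerate_params <- function(f, L, u) {
  # explicit weight enumeration: every dense layer is (fan_in + 1) x fan_out
  dims <- c(f, rep(u, L), 1)
  total <- 0L
  for (l in seq_len(length(dims) - 1))
    total <- total + (dims[l] + 1L) * dims[l + 1L]
  total
}

test_that("parameter count matches the closed form and enumeration", {
  expect_equal(count_params(mlp_config()), 84097)
  expect_equal(count_params(mlp_config(hidden_layers = 0)), 11)
  expect_equal(count_params(mlp_config(n_features = 3, hidden_layers = 2, units = 4)), 41)
  set.seed(99)
  for (i in 1:10) {
    f <- sample(2:12, 1); L <- sample(1:5, 1); u <- sample(2:40, 1)
    expect_equal(count_params(mlp_config(n_features = f, hidden_layers = L, units = u)),
                 enumerate_params(f, L, u))
  }
})

ml_toy_frame <- function(n, seed = 1, label = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * 10), n, 10)
  df <- as.data.frame(X)
  names(df) <- c("fio2", "hb", "sao2", "ph", "pao2", "paco2",
                 "mean_paco2", "co", "vco2", "r")
  df$shunt <- if (is.null(label)) 10 + 4 * X[, 1] - 3 * X[, 2] + 2 * X[, 3] else label
  df
}

test_that("a constant label is learned to the optimizer's jitter floor", {
  df <- ml_toy_frame(300, seed = 2, label = rep(17.5, 300))
  m <- train_shunt_mlp(df, mlp_config(hidden_layers = 2, units = 16,
                                      epochs = 800, batch_size = 16,
                                      lr_decay = 1, val_fraction = 0, seed = 4))
  pred <- predict(m, df)
  # RMSprop with a fixed learning rate settles within ~0.1 of the constant
  expect_lt(max(abs(pred - 17.5)), 0.1)
  expect_lt(sd(pred), 0.05)
})

test_that("training is deterministic given the seed", {
  df <- ml_toy_frame(200, seed = 3)
  m1 <- train_shunt_mlp(df, mlp_config(hidden_layers = 2, units = 8, epochs = 20, seed = 7))
  m2 <- train_shunt_mlp(df, mlp_config(hidden_layers = 2, units = 8, epochs = 20, seed = 7))
  expect_identical(predict(m1, df), predict(m2, df))
})

test_that("training-set MSE is consistent with the recorded loss history", {
  df <- ml_toy_frame(400, seed = 5)
  cfg <- mlp_config(hidden_layers = 2, units = 16, epochs = 80,
                    val_fraction = 0, seed = 6)
  m <- train_shunt_mlp(df, cfg)
  mse <- mean((predict(m, df) - df$shunt)^2)
  # post-hoc MSE cannot exceed the final running epoch loss by more than noise
  expect_lte(mse, m$loss[length(m$loss)] + 1e-6)
  # smoothed loss history decreases
  sm <- stats::filter(m$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
})

test_that("a learnable signal is fit and a permuted one is not", {
  df <- ml_toy_frame(600, seed = 8)
  cfg <- mlp_config(hidden_layers = 3, units = 32, epochs = 150,
                    val_fraction = 0, seed = 9)
  m <- train_shunt_mlp(df, cfg)
  holdout <- ml_toy_frame(300, seed = 88)
  r2 <- function(y, p) 1 - sum((y - p)^2) / sum((y - mean(y))^2)
  expect_gt(r2(holdout$shunt, predict(m, holdout)), 0.9)
  # destroyed-signal control
  set.seed(10)
  dfp <- df
  dfp$shunt <- sample(dfp$shunt)
  mp <- train_shunt_mlp(dfp, cfg)
  expect_lt(r2(holdout$shunt, predict(mp, holdout)), 0.2)
})

test_that("prediction demands the ten named features", {
  df <- ml_toy_frame(100, seed = 11)
  m <- train_shunt_mlp(df, mlp_config(hidden_layers = 1, units = 4, epochs = 5, seed = 1))
  expect_error(predict(m, df[, -which(names(df) == "paco2")]), "paco2")
  expect_error(train_shunt_mlp(df[, -which(names(df) == "co")],
                               mlp_config(hidden_layers = 1, units = 4)), "co")
})

test_that("normalization statistics come from training rows only", {
  df <- ml_toy_frame(300, seed = 12)
  df$split <- rep(c("train", "test"), length.out = 300)
  # make the test rows wildly offset; training stats must be unaffected
  df[df$split == "test", "hb"] <- df[df$split == "test", "hb"] + 1000
  m <- train_shunt_mlp(structure(list(records = df), class = "scenario_dataset"),
                       mlp_config(hidden_layers = 1, units = 4, epochs = 5, seed = 2))
  expect_equal(unname(m$center["hb"]),
               mean(df$hb[df$split == "train"]), tolerance = 1e-12)
})
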