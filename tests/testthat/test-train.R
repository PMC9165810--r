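test_that("cosine annealing follows its closed form and caps at t_max", {
  expect_equal(cosine_lr(0, 0.001, 29000), 0.001)
  expect_equal(cosine_lr(29000, 0.001, 29000), 0)
  expect_equal(cosine_lr(14500, 0.001, 29000), 0.0005)
  expect_equal(cosine_lr(40000, 0.001, 29000), 0)      # held at zero after t_max
  steps <- 0:100
  expect_equal(cosine_lr(steps, 0.002, 100),
               0.002 * (1 + cos(pi * steps / 100)) / 2)
  expect_error(cosine_lr(10, 0.001, 0), "t_max")
})

test_that("the NLL loss matches its closed forms and a direct recomputation", {
  onehot <- log(diag(3) + 1e-300)
  expect_equal(loss_nll(onehot, 0:2), 0, tolerance = 1e-10)
  uniform <- matrix(log(1 / 3), 4, 3)
  expect_equal(loss_nll(uniform, c(0, 1, 2, 0)), log(3))
  set.seed(30)
  raw <- matrix(rnorm(15), 5, 3)
  lp <- raw - log(rowSums(exp(raw)))
  lab <- sample(0:2, 5, replace = TRUE)
  brute <- -sum(sapply(1:5, function(i) lp[i, lab[i] + 1])) / 5
  expect_equal(loss_nll(lp, lab), brute)
  expect_error(loss_nll(lp, c(0, 1, 2, 0)), "labels length")
})

test_that("training is deterministic given the seed and records cosine rates", {
  ds <- tiny_dataset(seed = 2, effect_channel = 2, effect = 0.9)
  cfg <- train_config(epochs = 3, batch_size = 6, seed = 42)
  m <- tiny_model(seed = 1)
  f1 <- train_model(m, subset_subjects(ds, 1:3), subset_subjects(ds, 4),
                    config = cfg)
  f2 <- train_model(m, subset_subjects(ds, 1:3), subset_subjects(ds, 4),
                    config = cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$history$val_acc, f2$history$val_acc)
  # learning-rate trace equals the closed form at each global step
  expect_equal(f1$lr_trace,
               cosine_lr(seq_along(f1$lr_trace) - 1, cfg$lr0, cfg$t_max))
  # best-epoch bookkeeping
  expect_equal(f1$best_val_acc, max(f1$history$val_acc))
  expect_identical(f1$best_epoch,
                   which(f1$history$val_acc == f1$best_val_acc)[1])
})

test_that("augmentation touches exactly the training presentations", {
  ds <- tiny_dataset(seed = 3)
  n_train <- sum(ds$subject %in% 1:3)
  cfg <- train_config(epochs = 2, batch_size = 5, seed = 7)
  fit <- train_model(tiny_model(), subset_subjects(ds, 1:3),
                     subset_subjects(ds, 4), config = cfg)
  expect_identical(fit$n_augmented, 2L * n_train)
  fit0 <- train_model(tiny_model(), subset_subjects(ds, 1:3),
                      subset_subjects(ds, 4),
                      augment = augment_params(enabled = FALSE), config = cfg)
  expect_identical(fit0$n_augmented, 0L)
  # the no-preprocessing ablation disables augmentation too
  fitnp <- train_model(tiny_model(), subset_subjects(ds, 1:3),
                       subset_subjects(ds, 4), config = cfg,
                       normalize = FALSE)
  expect_identical(fitnp$n_augmented, 0L)
})

test_that("subject leakage between train and validation is refused", {
  ds <- tiny_dataset(seed = 4)
  expect_error(train_model(tiny_model(), subset_subjects(ds, 1:3),
                           subset_subjects(ds, 3:4)),
               "leakage")
})

test_that("loss decreases over the first steps on an easy problem", {
  ds <- tiny_dataset(seed = 5, n_subjects = 2, trials_per_class = 5,
                     effect_channel = 1, effect = 0.95)
  fit <- train_model(tiny_model(seed = 2, dropout_p = 0),
                     subset_subjects(ds, 1), subset_subjects(ds, 2),
                     augment = augment_params(enabled = FALSE),
                     config = train_config(epochs = 10, batch_size = 15,
                                           lr0 = 0.01, seed = 6))
  expect_lt(mean(tail(fit$history$loss, 3)), fit$history$loss[1])
})

test_that("max-norm holds on the spatial filters after every step", {
  ds <- tiny_dataset(seed = 6)
  fit <- train_model(tiny_model(seed = 3),
                     subset_subjects(ds, 1:3), subset_subjects(ds, 4),
                     config = train_config(epochs = 2, batch_size = 8,
                                           lr0 = 0.05, seed = 8))
  for (model in list(fit$model, fit$final_model))
    for (b in model$blocks)
      for (l in b$layers)
        if (l$kind == "conv_spatial")
          expect_true(all(sqrt(rowSums(l$W^2)) <= 1 + 1e-6))
})

test_that("train_config validates its fields", {
  expect_error(train_config(lr0 = 0), "lr0")
  expect_error(train_config(epochs = 0), "epochs")
})
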