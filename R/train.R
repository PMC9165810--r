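#' Optimization hyperparameters
#'
#' Reference settings: SGD with initial learning rate 0.001 and momentum
#' 0.9, cosine annealing over a maximum update period of 29,000 iterations,
#' batch size 100, 1000 epochs.
#'
#' @param lr0 Initial learning rate.
#' @param momentum SGD momentum.
#' @param t_max Cosine-annealing period in optimizer iterations.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param seed Integer seed controlling batching, dropout and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 0.001, momentum = 0.9, t_max = 29000L,
                         batch_size = 100L, epochs = 1000L, seed = 1L) {
  if (lr0 <= 0 || momentum < 0 || t_max < 1 || batch_size < 1 || epochs < 1)
    stop("invalid train_config: lr0 > 0, momentum >= 0, t_max/batch/epochs >= 1")
  structure(list(lr0 = lr0, momentum = momentum, t_max = as.integer(t_max),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr = lr0 * (1 + cos(pi * min(step, t_max) / t_max)) / 2`, with no
#' restarts: the rate is held at 0 once `step` reaches `t_max`.
#'
#' @param step Iteration counter (0-based, vectorized).
#' @param lr0 Initial learning rate.
#' @param t_max Annealing period in iterations.
#' @return The learning rate(s).
#' @export
cosine_lr <- function(step, lr0 = 0.001, t_max = 29000) {
  if (t_max <= 0) stop("t_max must be > 0")
  if (any(step < 0)) stop("step must be >= 0")
  lr0 * (1 + cos(pi * pmin(step, t_max) / t_max)) / 2
}

#' Mean negative log-likelihood of the true labels
#'
#' The categorical cross-entropy on log-softmax outputs: the mean over
#' trials of minus the log score at the true label.
#'
#' @param log_scores `N x n_class` matrix of per-trial log class scores.
#' @param labels Length-`N` task labels (codes 0..n_class-1 or names).
#' @return The scalar loss.
#' @export
loss_nll <- function(log_scores, labels) {
  labels <- as_label_code(labels)
  if (nrow(log_scores) != length(labels))
    stop("log_scores rows (", nrow(log_scores), ") != labels length (",
         length(labels), ")")
  -mean(log_scores[cbind(seq_along(labels), labels + 1L)])
}

# Parameter names carried by each layer kind
layer_param_names <- function(l) {
  switch(l$kind,
         conv_time = , conv_spatial = , conv_dw = , conv_pw = "W",
         bn = c("gamma", "beta"),
         classifier = c("W", "b"),
         character())
}

init_velocity <- function(model) {
  lapply(model$blocks, function(b)
    lapply(b$layers, function(l) {
      nm <- layer_param_names(l)
      if (!length(nm)) return(NULL)
      v <- lapply(nm, function(n) {
        p <- l[[n]]
        if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else rep(0, length(p))
      })
      names(v) <- nm
      v
    }))
}

# One SGD-with-momentum step (v <- mu v + g; p <- p - lr v), followed by
# max-norm projection of any constrained spatial filters.
sgd_step <- function(model, grads, vel, lr, momentum) {
  for (bi in seq_along(model$blocks)) {
    for (j in seq_along(model$blocks[[bi]]$layers)) {
      g <- grads[[bi]][[j]]
      if (is.null(g)) next
      for (nm in names(g)) {
        v <- momentum * vel[[bi]][[j]][[nm]] + g[[nm]]
        vel[[bi]][[j]][[nm]] <- v
        model$blocks[[bi]]$layers[[j]][[nm]] <-
          model$blocks[[bi]]$layers[[j]][[nm]] - lr * v
      }
      l <- model$blocks[[bi]]$layers[[j]]
      if (l$kind == "conv_spatial" && !is.null(l$maxnorm))
        model$blocks[[bi]]$layers[[j]]$W <- project_maxnorm(l$W, l$maxnorm)
    }
  }
  list(model = model, vel = vel)
}

# Evaluation-mode log scores over a dataset, chunked to bound memory.
predict_logp <- function(model, dataset, chunk = 64L) {
  N <- n_epochs(dataset)
  out <- matrix(NA_real_, N, model$config$n_class)
  for (s in seq(1L, N, by = chunk)) {
    e <- min(s + chunk - 1L, N)
    out[s:e, ] <- model_forward(model, dataset$x[, , s:e, drop = FALSE],
                                train = FALSE)
  }
  out
}

#' Train the network with SGD, cosine annealing and augmentation
#'
#' Per optimizer iteration: draw a shuffled mini-batch, add two-scale
#' noise to the training epochs only (see [augment_params()]), run the
#' forward pass in training mode, take an SGD-with-momentum step at the
#' cosine-annealed learning rate for the global step counter, and project
#' the spatial filters onto the max-norm ball. Validation accuracy is
#' recorded each epoch in evaluation mode and the best-validation
#' parameters are returned. The run is deterministic given
#' `config$seed`.
#'
#' Training and validation sets must come from disjoint subjects; epochs
#' are normalized internally with [zscore_epoch()] semantics unless
#' `normalize = FALSE` (the "no preprocessing" ablation, which also
#' disables augmentation).
#'
#' @param model An `eegnet_model` from [build_model()].
#' @param train_set,val_set `eeg_dataset`s with disjoint subjects.
#' @param augment [augment_params()]; applied to training batches only.
#' @param config [train_config()].
#' @param normalize Normalize epochs per channel per trial (default TRUE).
#' @param zscore_scope Normalization scope, see [zscore_epoch()].
#' @return An `eegnet_fit`: the best-validation model plus training
#'   history (loss, validation accuracy, learning-rate trace, best epoch,
#'   augmentation call count, final training accuracy).
#' @export
train_model <- function(model, train_set, val_set,
                        augment = augment_params(), config = train_config(),
                        normalize = TRUE, zscore_scope = "per_channel") {
  stopifnot(inherits(model, "eegnet_model"),
            inherits(train_set, "eeg_dataset"),
            inherits(val_set, "eeg_dataset"))
  overlap <- intersect(unique(train_set$subject), unique(val_set$subject))
  if (length(overlap))
    stop("subject leakage between train and validation: ",
         paste(overlap, collapse = ", "))
  if (!normalize) augment <- augment_params(enabled = FALSE)
  if (normalize) {
    train_set <- dataset_zscore(train_set, zscore_scope)
    val_set <- dataset_zscore(val_set, zscore_scope)
  }
  n_tr <- n_epochs(train_set)
  with_seed(derive_seed(config$seed, "train"), {
    vel <- init_velocity(model)
    step <- 0L
    lr_trace <- numeric(0)
    loss_trace <- numeric(config$epochs)
    val_trace <- numeric(config$epochs)
    n_aug <- 0L
    best <- list(acc = -Inf, epoch = NA_integer_, model = NULL)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      batch_losses <- numeric(0)
      for (s in seq(1L, n_tr, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1L, n_tr)]
        xb <- train_set$x[, , idx, drop = FALSE]
        if (augment$enabled) {
          xb <- augment_batch(xb, augment)
          n_aug <- n_aug + length(idx)
        }
        fp <- forward_pass(model, batch_to_mat(xb), length(idx), train = TRUE)
        model <- fp$model   # refreshed batch-norm running stats
        logp <- t(fp$out)
        loss <- loss_nll(logp, train_set$label[idx])
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep, ", step ", step,
               " (lr = ", cosine_lr(step, config$lr0, config$t_max), ")")
        batch_losses <- c(batch_losses, loss)
        dOut <- matrix(0, model$config$n_class, length(idx))
        dOut[cbind(train_set$label[idx] + 1L, seq_along(idx))] <-
          -1 / length(idx)
        bp <- backward_pass(model, fp$caches, dOut)
        lr <- cosine_lr(step, config$lr0, config$t_max)
        lr_trace <- c(lr_trace, lr)
        upd <- sgd_step(model, bp$grads, vel, lr, config$momentum)
        model <- upd$model; vel <- upd$vel
        step <- step + 1L
      }
      loss_trace[ep] <- mean(batch_losses)
      val_pred <- max.col(predict_logp(model, val_set), ties.method = "first") - 1L
      val_trace[ep] <- mean(val_pred == val_set$label)
      if (val_trace[ep] > best$acc)
        best <- list(acc = val_trace[ep], epoch = ep, model = model)
    }
    train_pred <- max.col(predict_logp(model, train_set),
                          ties.method = "first") - 1L
    structure(list(model = best$model, final_model = model,
                   config = model$config, train_config = config,
                   augment = augment, normalize = normalize,
                   zscore_scope = zscore_scope,
                   history = data.frame(epoch = seq_len(config$epochs),
                                        loss = loss_trace,
                                        val_acc = val_trace),
                   lr_trace = lr_trace, best_epoch = best$epoch,
                   best_val_acc = best$acc,
                   final_train_acc = mean(train_pred == train_set$label),
                   n_augmented = n_aug, n_steps = step),
              class = "eegnet_fit")
  })
}

#' Fit a residual EEG decoding network
#'
#' Convenience wrapper: builds the network with [build_model()] and trains
#' it with [train_model()].
#'
#' @param train_set,val_set `eeg_dataset`s with disjoint subjects.
#' @param config [model_config()].
#' @param train_cfg [train_config()].
#' @param augment [augment_params()].
#' @param ... Passed to [train_model()].
#' @return An `eegnet_fit`.
#' @export
residual_eegnet <- function(train_set, val_set, config = model_config(),
                            train_cfg = train_config(),
                            augment = augment_params(), ...) {
  model <- build_model(config, n_samples = dim(train_set$x)[2],
                       seed = train_cfg$seed)
  train_model(model, train_set, val_set, augment = augment,
              config = train_cfg, ...)
}

#' @export
print.eegnet_fit <- function(x, ...) {
  cat(sprintf(paste0("<eegnet_fit> %d epochs (%d steps); best val acc %.3f",
                     " at epoch %d; final train acc %.3f\n"),
              nrow(x$history), x$n_steps, x$best_val_acc, x$best_epoch,
              x$final_train_acc))
  invisible(x)
}

#' @export
summary.eegnet_fit <- function(object, ...) {
  cat("Residual EEG decoding network fit\n")
  print(object)
  cat("\nLast epochs:\n")
  print(utils::tail(object$history, 5))
  cat("\nArchitecture:\n")
  print(model_summary(object$model))
  invisible(object)
}

#' Predict task labels or log scores for new epochs
#'
#' Epochs are normalized the same way as during training, then passed
#' through the best-validation model in evaluation mode. Ties in the
#' arg-max are broken toward the lowest label index.
#'
#' @param object An `eegnet_fit`.
#' @param newdata An `eeg_dataset` (or array/epoch accepted by
#'   [model_forward()]).
#' @param type `"label"` (integer codes, default) or `"logp"`.
#' @param ... Unused.
#' @return Integer label codes, or an `N x n_class` log-score matrix.
#' @export
predict.eegnet_fit <- function(object, newdata, type = c("label", "logp"),
                               ...) {
  type <- match.arg(type)
  ds <- if (inherits(newdata, "eeg_dataset")) newdata
        else as_eeg_dataset(list(eeg_epoch(unclass(newdata), 0L, 1L, "rest",
                                           attr(newdata, "sfreq") %||% 160)))
  if (object$normalize) ds <- dataset_zscore(ds, object$zscore_scope)
  logp <- predict_logp(object$model, ds)
  if (type == "logp") return(logp)
  labs <- max.col(logp, ties.method = "first") - 1L
  n_ties <- sum(rowSums(logp == logp[cbind(seq_len(nrow(logp)),
                                           labs + 1L)]) > 1L)
  if (n_ties > 0) log_msg(n_ties, " tied prediction(s) broken toward the ",
                          "lowest label index")
  structure(labs, n_ties = n_ties)
}

#' @export
plot.eegnet_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "Loss", ...)
  plot(x$history$epoch, x$history$val_acc, type = "l", xlab = "epoch",
       ylab = "validation accuracy", main = "Validation", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
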