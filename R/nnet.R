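# Forward and backward passes over the block stack.
#
# Activation layout: F x (T*C*N) matrices; T consecutive time columns per
# (channel, trial) block, channel blocks consecutive within a trial.
# Convolutions are evaluated by the compiled kernels in src/convops.cpp.

# (C, T, N) array -> 1 x (T*C*N) input matrix
batch_to_mat <- function(xarr) {
  if (length(dim(xarr)) == 2L) dim(xarr) <- c(dim(xarr), 1L)
  matrix(as.vector(aperm(xarr, c(2, 1, 3))), nrow = 1L)
}

# index of the last convolution sub-layer of a block (the ".conv" capture point)
conv_point <- function(block) {
  kinds <- vapply(block$layers, function(l) l$kind, "")
  idx <- which(startsWith(kinds, "conv") | kinds == "classifier")
  if (length(idx)) max(idx) else NA_integer_
}

layer_fw <- function(l, A, Tn, C, N, train) {
  switch(l$kind,
    conv_time = list(out = conv_time_fw(A, l$W, Tn, l$K, l$pad),
                     cache = list(A = A, Tn = Tn)),
    conv_spatial = {
      out <- conv_spatial_fw(A, l$W, Tn, C)
      list(out = out, cache = list(A = A, Tn = Tn, C = C), C = 1L)
    },
    conv_dw = list(out = conv_dw_fw(A, l$W, Tn, l$K, l$pad),
                   cache = list(A = A, Tn = Tn)),
    conv_pw = list(out = l$W %*% A, cache = list(A = A)),
    bn = {
      if (train) {
        r <- bn_fw_train(A, l$gamma, l$beta, l$eps)
        st <- list(run_mean = (1 - l$momentum) * l$run_mean +
                     l$momentum * as.vector(r$mu),
                   run_var = (1 - l$momentum) * l$run_var +
                     l$momentum * as.vector(r$v))
        list(out = r$out,
             cache = list(xhat = r$xhat, inv = as.vector(r$inv),
                          train = TRUE),
             state = st)
      } else {
        inv <- 1 / sqrt(l$run_var + l$eps)
        out <- (A - l$run_mean) * inv * l$gamma + l$beta
        list(out = out, cache = list(inv = inv, train = FALSE))
      }
    },
    elu = {
      neg <- A < 0
      out <- A
      out[neg] <- exp(A[neg]) - 1
      list(out = out, cache = list(neg = neg, out = out))
    },
    pool = {
      p <- l$p; B <- ncol(A) %/% Tn; T2 <- Tn %/% p
      idx <- as.vector(outer(seq_len(T2 * p), (seq_len(B) - 1L) * Tn, `+`))
      A3 <- array(A[, idx], c(nrow(A), p, T2 * B))
      out <- A3[, 1, , drop = FALSE]
      if (p > 1) for (i in 2:p) out <- out + A3[, i, , drop = FALSE]
      list(out = matrix(out / p, nrow(A)),
           cache = list(Tn_in = Tn, idx = idx, p = p), Tn = T2)
    },
    dropout = {
      if (train && l$p > 0) {
        mask <- matrix((runif(length(A)) >= l$p) / (1 - l$p),
                       nrow(A), ncol(A))
        list(out = A * mask, cache = list(mask = mask))
      } else list(out = A, cache = list(mask = NULL))
    },
    classifier = {
      N_tr <- ncol(A) %/% l$Tfin
      X <- matrix(A, nrow(A) * l$Tfin, N_tr)
      list(out = l$W %*% X + l$b, cache = list(X = X, F_in = nrow(A)),
           Tn = 1L)
    },
    logsoftmax = {
      m <- apply(A, 2, max)
      Z <- sweep(A, 2, m)
      lse <- log(colSums(exp(Z)))
      out <- sweep(Z, 2, lse)
      list(out = out, cache = list(P = exp(out)))
    },
    stop("unknown layer kind: ", l$kind))
}

layer_bw <- function(l, dO, cache, need_param_grads = TRUE) {
  switch(l$kind,
    conv_time = {
      r <- conv_time_bw(cache$A, l$W, dO, cache$Tn, l$K, l$pad)
      list(dA = r$dA, grads = if (need_param_grads) list(W = r$dW))
    },
    conv_spatial = {
      r <- conv_spatial_bw(cache$A, l$W, dO, cache$Tn, cache$C)
      list(dA = r$dA, grads = if (need_param_grads) list(W = r$dW))
    },
    conv_dw = {
      r <- conv_dw_bw(cache$A, l$W, dO, cache$Tn, l$K, l$pad)
      list(dA = r$dA, grads = if (need_param_grads) list(W = r$dw))
    },
    conv_pw = list(dA = crossprod(l$W, dO),
                   grads = if (need_param_grads)
                     list(W = tcrossprod(dO, cache$A))),
    bn = {
      if (isTRUE(cache$train)) {
        r <- bn_bw_train(dO, cache$xhat, cache$inv, l$gamma)
        list(dA = r$dA, grads = if (need_param_grads)
          list(gamma = as.vector(r$dgamma), beta = as.vector(r$dbeta)))
      } else {
        list(dA = dO * (l$gamma * cache$inv), grads = NULL)
      }
    },
    elu = {
      dA <- dO
      dA[cache$neg] <- dO[cache$neg] * (cache$out[cache$neg] + 1)
      list(dA = dA, grads = NULL)
    },
    pool = {
      # B blocks of Tn_in columns; expanded gradient fills the kept columns
      B <- ncol(dO) %/% (cache$Tn_in %/% cache$p)
      dA <- matrix(0, nrow(dO), cache$Tn_in * B)
      dA[, cache$idx] <- (dO / cache$p)[, rep(seq_len(ncol(dO)),
                                              each = cache$p)]
      list(dA = dA, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dA = dO, grads = NULL)
      else list(dA = dO * cache$mask, grads = NULL)
    },
    classifier = {
      dX <- crossprod(l$W, dO)
      list(dA = matrix(dX, cache$F_in, l$Tfin * ncol(dO)),
           grads = if (need_param_grads)
             list(W = tcrossprod(dO, cache$X), b = rowSums(dO)))
    },
    logsoftmax = {
      s <- colSums(dO)
      list(dA = dO - sweep(cache$P, 2, s, `*`), grads = NULL)
    },
    stop("unknown layer kind: ", l$kind))
}

# Forward pass. `capture` is a character vector of activation ids
# ("<block>" for a block output, "<block>.conv" for its last convolution
# output); `replace` is list(id =, value =) substituting an activation and
# continuing. Returns out (n_class x N log scores), caches, captured
# activations, and the model (with refreshed batch-norm running stats when
# train = TRUE).
forward_pass <- function(model, X, N, train = FALSE, capture = character(),
                         replace = NULL) {
  Tn <- model$n_samples; C <- model$n_channels
  if (ncol(X) != Tn * C * N || nrow(X) != 1L)
    stop("input geometry mismatch: expected 1 x ", Tn * C * N,
         " (T=", Tn, ", C=", C, ", N=", N, ")")
  A <- X
  caches <- vector("list", length(model$blocks))
  captured <- list()
  for (bi in seq_along(model$blocks)) {
    b <- model$blocks[[bi]]
    cp <- conv_point(b)
    A_in <- A
    lc <- vector("list", length(b$layers))
    for (j in seq_along(b$layers)) {
      l <- b$layers[[j]]
      r <- layer_fw(l, A, Tn, C, N, train)
      A <- r$out
      lc[[j]] <- r$cache
      if (!is.null(r$Tn)) Tn <- r$Tn
      if (!is.null(r$C)) C <- r$C
      if (!is.null(r$state))
        model$blocks[[bi]]$layers[[j]][names(r$state)] <- r$state
      id_conv <- paste0(b$name, ".conv")
      if (!is.na(cp) && j == cp) {
        if (id_conv %in% capture)
          captured[[id_conv]] <- list(A = A, Tn = Tn, C = C)
        if (!is.null(replace) && identical(replace$id, id_conv))
          A <- replace$value
      }
      if (!is.na(b$residual_at) && j == b$residual_at) A <- A + A_in
    }
    caches[[bi]] <- list(layers = lc)
    if (b$name %in% capture)
      captured[[b$name]] <- list(A = A, Tn = Tn, C = C)
    if (!is.null(replace) && identical(replace$id, b$name)) A <- replace$value
  }
  list(out = A, caches = caches, captured = captured, model = model)
}

# Backward pass from dOut (same shape as the forward output). Computes
# parameter gradients (nested list parallel to blocks/layers) unless
# need_param_grads = FALSE, and optionally captures the gradient flowing
# through an activation id; with stop_at set, unwinding ends there.
# skip_logsoftmax treats dOut as a gradient w.r.t. the pre-softmax scores.
backward_pass <- function(model, caches, dOut, need_param_grads = TRUE,
                          capture_grad = character(), stop_at = NULL,
                          skip_logsoftmax = FALSE) {
  dA <- dOut
  grads <- vector("list", length(model$blocks))
  captured <- list()
  for (bi in rev(seq_along(model$blocks))) {
    b <- model$blocks[[bi]]
    cp <- conv_point(b)
    if (b$name %in% capture_grad) captured[[b$name]] <- dA
    if (identical(stop_at, b$name))
      return(list(grads = grads, dX = dA, captured = captured))
    d_short <- NULL
    gl <- vector("list", length(b$layers))
    for (j in rev(seq_along(b$layers))) {
      l <- b$layers[[j]]
      if (!is.na(b$residual_at) && j == b$residual_at) d_short <- dA
      if (skip_logsoftmax && l$kind == "logsoftmax") next
      id_conv <- paste0(b$name, ".conv")
      if (!is.na(cp) && j == cp) {
        if (id_conv %in% capture_grad) captured[[id_conv]] <- dA
        if (identical(stop_at, id_conv))
          return(list(grads = grads, dX = dA, captured = captured))
      }
      r <- layer_bw(l, dA, caches[[bi]]$layers[[j]], need_param_grads)
      dA <- r$dA
      if (!is.null(r$grads)) gl[[j]] <- r$grads
    }
    if (!is.null(d_short)) dA <- dA + d_short
    grads[[bi]] <- gl
  }
  list(grads = grads, dX = dA, captured = captured)
}

#' Run the network forward on a batch of epochs
#'
#' @param model An `eegnet_model`.
#' @param x An [eeg_epoch()], a channels-by-samples matrix, a
#'   `channels x samples x trials` array, or an `eeg_dataset`. Epochs are
#'   expected to be normalized already (see [zscore_epoch()]).
#' @param train Logical: training mode (dropout active, batch-norm batch
#'   statistics) or evaluation mode (deterministic).
#' @return An `N x n_class` matrix of per-trial log class scores; each
#'   row's exponentials sum to 1.
#' @export
model_forward <- function(model, x, train = FALSE) {
  xarr <- if (inherits(x, "eeg_dataset")) x$x else unclass(x)
  if (length(dim(xarr)) == 2L) dim(xarr) <- c(dim(xarr), 1L)
  if (dim(xarr)[1] != model$n_channels || dim(xarr)[2] != model$n_samples)
    stop("input geometry mismatch: model expects ", model$n_channels, " x ",
         model$n_samples, ", got ", dim(xarr)[1], " x ", dim(xarr)[2])
  N <- dim(xarr)[3]
  fp <- forward_pass(model, batch_to_mat(xarr), N, train = train)
  t(fp$out)
}
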