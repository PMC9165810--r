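#' Noise-augmentation parameters
#'
#' Training-time data expansion adds normalized random noise at two
#' scales: one Gaussian offset per trial (sd `sigma_trial`, default 10%)
#' and one per channel (sd `sigma_channel`, default 3%), on the normalized
#' (unit-sd) signal. An alternative reading - i.i.d. per-sample noise at
#' those sds - is available via `mode = "iid_samples"`.
#'
#' @param sigma_trial Sd of the per-trial offset (default 0.10).
#' @param sigma_channel Sd of the per-channel offsets (default 0.03).
#' @param mode `"scalar_offsets"` (default) or `"iid_samples"`.
#' @param enabled Logical master switch.
#' @return An `augment_params` list.
#' @export
augment_params <- function(sigma_trial = 0.10, sigma_channel = 0.03,
                           mode = c("scalar_offsets", "iid_samples"),
                           enabled = TRUE) {
  if (sigma_trial < 0 || sigma_channel < 0) stop("sigmas must be >= 0")
  structure(list(sigma_trial = sigma_trial, sigma_channel = sigma_channel,
                 mode = match.arg(mode), enabled = isTRUE(enabled)),
            class = "augment_params")
}

#' Normalize an epoch to zero mean and unit standard deviation
#'
#' Normalization is scoped per channel within each trial by default (the
#' motivation for preprocessing is impedance/noise differences between
#' electrodes and subjects); `scope = "per_trial_pooled"` normalizes the
#' trial as a whole instead.
#'
#' @param epoch An [eeg_epoch()] or a channels-by-samples matrix.
#' @param scope `"per_channel"` (default) or `"per_trial_pooled"`.
#' @return The normalized epoch (metadata preserved).
#' @export
zscore_epoch <- function(epoch, scope = c("per_channel", "per_trial_pooled")) {
  scope <- match.arg(scope)
  x <- unclass(epoch)
  if (scope == "per_channel") {
    m <- rowMeans(x)
    s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
    if (any(s == 0))
      stop("zero-variance channel(s): ", paste(which(s == 0), collapse = ", "))
    out <- (x - m) / s
  } else {
    s <- sd(x)
    if (s == 0) stop("zero-variance trial")
    out <- (x - mean(x)) / s
  }
  attributes(out) <- attributes(epoch)
  out
}

#' Add two-scale training noise to a normalized epoch
#'
#' In the default `scalar_offsets` mode the output is
#' `x + t + c_k` where `t ~ Normal(0, sigma_trial^2)` is a single scalar
#' added to every sample of the trial and `c_k ~ Normal(0,
#' sigma_channel^2)` is one scalar per channel `k`. Draws come from the
#' R random stream, so results are deterministic under [set.seed()].
#' Augmentation is for training folds only; validation and test epochs
#' must pass through [zscore_epoch()] untouched.
#'
#' @param epoch A normalized [eeg_epoch()] or matrix.
#' @param params An [augment_params()].
#' @return The augmented epoch (metadata preserved).
#' @export
augment_epoch <- function(epoch, params = augment_params()) {
  if (!isTRUE(params$enabled)) return(epoch)
  x <- unclass(epoch)
  if (params$mode == "scalar_offsets") {
    out <- x + rnorm(1, sd = params$sigma_trial) +
      rnorm(nrow(x), sd = params$sigma_channel)
  } else {
    out <- x + matrix(rnorm(length(x), sd = params$sigma_trial), nrow(x)) +
      matrix(rnorm(length(x), sd = params$sigma_channel), nrow(x))
  }
  attributes(out) <- attributes(epoch)
  out
}

# Vectorized helpers on the dataset array (same math as the epoch-level
# operations; used by the training pipeline).
dataset_zscore <- function(dataset, scope = "per_channel") {
  x <- dataset$x
  for (i in seq_len(dim(x)[3])) {
    xi <- x[, , i]
    if (scope == "per_channel") {
      m <- rowMeans(xi)
      s <- sqrt(rowSums((xi - m)^2) / (ncol(xi) - 1))
      if (any(s == 0))
        stop("zero-variance channel(s) in epoch ", i, ": ",
             paste(which(s == 0), collapse = ", "))
      x[, , i] <- (xi - m) / s
    } else {
      x[, , i] <- (xi - mean(xi)) / sd(xi)
    }
  }
  dataset$x <- x
  dataset
}

# Augment a C x T x n batch array in place; one trial offset + per-channel
# offsets per epoch (or iid noise), fresh draws every call.
augment_batch <- function(xb, params) {
  if (!isTRUE(params$enabled)) return(xb)
  d <- dim(xb)
  for (i in seq_len(d[3])) {
    if (params$mode == "scalar_offsets") {
      xb[, , i] <- xb[, , i] + rnorm(1, sd = params$sigma_trial) +
        rnorm(d[1], sd = params$sigma_channel)
    } else {
      xb[, , i] <- xb[, , i] +
        matrix(rnorm(d[1] * d[2], sd = params$sigma_trial), d[1]) +
        matrix(rnorm(d[1] * d[2], sd = params$sigma_channel), d[1])
    }
  }
  xb
}
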