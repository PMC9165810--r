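# Grad-CAM attribution: which channels and time points drive a class
# decision. The target layer defaults to the convolution output of the
# last residual temporal block, whose feature maps still span the full
# 64-channel x 720-sample input geometry.

default_gradcam_layer <- function(model) {
  paste0("type1.", model$config$n_type1_blocks, ".conv")
}

valid_capture_ids <- function(model) {
  nm <- vapply(model$blocks, function(b) b$name, "")
  c(nm, paste0(nm, ".conv"))
}

#' Capture feature maps and class-score gradients at a layer
#'
#' Runs one epoch forward in evaluation mode, records the K feature maps
#' `A` at the target layer, and back-propagates the class score `y_c` to
#' obtain the gradients of identical geometry. The differentiated score
#' is the log-softmax output for class `c` by default
#' (`score_from = "logp"`); `score_from = "logits"` uses the pre-softmax
#' class score instead.
#'
#' @param model An `eegnet_model` (trained) or an `eegnet_fit`.
#' @param epoch A normalized [eeg_epoch()] or channels-by-samples matrix.
#' @param class_index Target class (code 0..2 or name).
#' @param layer Activation id, e.g. `"type1.10.conv"` (default: the
#'   convolution output of the last Conv2Dtype1 block) or a block name.
#' @param score_from `"logp"` (default) or `"logits"`.
#' @return A `feature_map_stack`: list with `maps` and `grads` (arrays
#'   `channels x time x K`), `class_index`, `layer`, `Z` (pixels per map).
#' @export
capture_layer <- function(model, epoch, class_index,
                          layer = NULL, score_from = c("logp", "logits")) {
  if (inherits(model, "eegnet_fit")) model <- model$model
  score_from <- match.arg(score_from)
  layer <- layer %||% default_gradcam_layer(model)
  if (!layer %in% valid_capture_ids(model))
    stop("unknown layer id: ", layer)
  cls <- as_label_code(class_index)
  x <- unclass(epoch)
  fp <- forward_pass(model, batch_to_mat(x), 1L, train = FALSE,
                     capture = layer)
  cap <- fp$captured[[layer]]
  dOut <- matrix(0, model$config$n_class, 1L)
  dOut[cls + 1L, 1L] <- 1
  bp <- backward_pass(model, fp$caches, dOut, need_param_grads = FALSE,
                      capture_grad = layer, stop_at = layer,
                      skip_logsoftmax = (score_from == "logits"))
  grad <- bp$captured[[layer]]
  to_ct <- function(m, Tn, C) {
    # F x (T*C) -> channels x time x K
    a <- array(t(m), c(Tn, C, nrow(m)))
    aperm(a, c(2, 1, 3))
  }
  structure(list(maps = to_ct(cap$A, cap$Tn, cap$C),
                 grads = to_ct(grad, cap$Tn, cap$C),
                 class_index = cls, layer = layer,
                 score_from = score_from,
                 Z = cap$Tn * cap$C),
            class = "feature_map_stack")
}

#' Global-average-pooled gradient weights
#'
#' `alpha_k = (1/Z) * sum_ij dy_c / dA_ijk`: the mean gradient over all
#' pixels of each feature map.
#'
#' @param stack A `feature_map_stack` from [capture_layer()].
#' @return Numeric vector of K weights.
#' @export
alpha_weights <- function(stack) {
  apply(stack$grads, 3, mean)
}

#' Rectified weighted feature-map combination (the Grad-CAM heatmap)
#'
#' `L = max(0, sum_k alpha_k A_k)` elementwise. The target layer already
#' matches the input resolution, so no upsampling is applied.
#'
#' @param stack A `feature_map_stack`.
#' @param alphas K weights, typically from [alpha_weights()].
#' @return An `attribution_map`: non-negative channels-by-time matrix
#'   with `class_index` and `layer` attributes.
#' @export
cam_heatmap <- function(stack, alphas = alpha_weights(stack)) {
  K <- dim(stack$maps)[3]
  if (length(alphas) != K) stop("alpha length (", length(alphas),
                                ") != number of maps (", K, ")")
  L <- matrix(0, dim(stack$maps)[1], dim(stack$maps)[2])
  for (k in seq_len(K)) L <- L + alphas[k] * stack$maps[, , k]
  L[L < 0] <- 0
  structure(L, class_index = stack$class_index, layer = stack$layer,
            class = c("attribution_map", "matrix", "array"))
}

#' Grad-CAM maps for every correctly classified trial
#'
#' Predicts each epoch with the fitted model, keeps only trials whose
#' prediction matches the true label, and computes the Grad-CAM heatmap
#' with respect to the true class for each kept trial, grouped by
#' participant and task. Participants with no correct trial for a task
#' are excluded from that task's group (and logged).
#'
#' @param fit An `eegnet_fit` (or an `eegnet_model` plus pre-normalized
#'   data).
#' @param dataset A labelled `eeg_dataset`.
#' @param layer Target activation id (default: last Conv2Dtype1 conv).
#' @param score_from Passed to [capture_layer()].
#' @return A `gradcam_groups` object: nested list `maps[[task]][[subject]]`
#'   of `attribution_map`s, with `n_correct`, `n_total` counts.
#' @export
gradcam_for_correct_trials <- function(fit, dataset, layer = NULL,
                                       score_from = "logp") {
  model <- if (inherits(fit, "eegnet_fit")) fit$model else fit
  layer <- layer %||% default_gradcam_layer(model)
  norm <- if (inherits(fit, "eegnet_fit") && fit$normalize)
    dataset_zscore(dataset, fit$zscore_scope) else dataset
  preds <- max.col(predict_logp(model, norm), ties.method = "first") - 1L
  correct <- which(preds == dataset$label)
  if (!length(correct)) log_msg("no correctly classified trials")
  maps <- stats::setNames(vector("list", 3L), TASK_LABELS)
  for (i in correct) {
    task <- label_name(dataset$label[i])
    subj <- as.character(dataset$subject[i])
    stack <- capture_layer(model, norm$x[, , i], dataset$label[i],
                           layer = layer, score_from = score_from)
    maps[[task]][[subj]] <- c(maps[[task]][[subj]],
                              list(cam_heatmap(stack)))
  }
  for (task in TASK_LABELS) {
    missing <- setdiff(as.character(unique(dataset$subject)),
                       names(maps[[task]]))
    if (length(missing))
      log_msg("task ", task, ": no correct trials for participant(s) ",
              paste(missing, collapse = ", "), "; excluded")
  }
  structure(list(maps = maps, n_correct = length(correct),
                 n_total = n_epochs(dataset), layer = layer,
                 score_from = score_from),
            class = "gradcam_groups")
}

#' Per-participant channel scores and baselines
#'
#' For each task and participant: average that participant's correct-trial
#' heatmaps, then average over the time axis, giving one score per
#' channel; the participant's baseline is the arithmetic mean of their 64
#' channel scores. With `keep_time = TRUE` the participant-mean maps are
#' retained for time-resolved testing.
#'
#' @param groups A `gradcam_groups` from [gradcam_for_correct_trials()].
#' @param keep_time Keep `participants x channels x time` mean maps.
#' @return A `channel_score_table`: per task, a list with `scores`
#'   (participants x 64 matrix), `baseline` (per-participant mean over
#'   channels), and optionally `time_scores`.
#' @export
channel_scores <- function(groups, keep_time = FALSE) {
  out <- list()
  for (task in names(groups$maps)) {
    g <- groups$maps[[task]]
    if (!length(g)) next
    subj <- names(g)
    mean_maps <- lapply(g, function(trials) Reduce(`+`, trials) / length(trials))
    scores <- t(vapply(mean_maps, rowMeans, numeric(64)))
    rownames(scores) <- subj
    entry <- list(scores = scores, baseline = rowMeans(scores),
                  participants = subj)
    if (keep_time) {
      Tn <- ncol(mean_maps[[1]])
      ts <- array(0, c(length(subj), 64, Tn), dimnames = list(subj))
      for (i in seq_along(subj)) ts[i, , ] <- mean_maps[[i]]
      entry$time_scores <- ts
    }
    out[[task]] <- entry
  }
  structure(out, class = "channel_score_table")
}

#' Channel (or channel-by-time) significance versus the baseline
#'
#' Channel axis: for each of the 64 channels, a Welch unpaired two-tailed
#' test of the participants' channel scores against the participants'
#' baselines, with Benjamini-Hochberg FDR control over the 64 tests per
#' task. Timepoint axis: the same test per channel per time point, with
#' the baseline computed per time point (mean over channels) and BH
#' control over the `64 x T` family per task (requires
#' `channel_scores(..., keep_time = TRUE)`).
#'
#' @param table A `channel_score_table`.
#' @param q FDR level (default 0.05).
#' @param axis `"channel"` or `"timepoint"`.
#' @param montage Optional montage for channel labels.
#' @return For the channel axis: a data frame with task, channel, t, df,
#'   p, rejected. For the timepoint axis: per task, a `64 x T` logical
#'   significance mask (plus the p-value matrix as an attribute).
#' @export
significance_vs_baseline <- function(table, q = 0.05,
                                     axis = c("channel", "timepoint"),
                                     montage = physionet_montage()) {
  axis <- match.arg(axis)
  if (axis == "channel") {
    rows <- list()
    for (task in names(table)) {
      e <- table[[task]]
      if (nrow(e$scores) < 2L)
        stop("need >= 2 participants for task ", task)
      tests <- lapply(seq_len(64), function(ch)
        welch_t_test(e$scores[, ch], e$baseline))
      p <- vapply(tests, function(r) r$p, 1)
      rows[[task]] <- data.frame(
        task = task, channel = seq_len(64),
        label = as.character(unclass(montage)),
        t = vapply(tests, function(r) r$t, 1),
        df = vapply(tests, function(r) r$df, 1),
        p = p, rejected = bh_fdr(p, q))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  masks <- list()
  for (task in names(table)) {
    e <- table[[task]]
    if (is.null(e$time_scores))
      stop("timepoint axis needs channel_scores(..., keep_time = TRUE)")
    if (nrow(e$scores) < 2L) stop("need >= 2 participants for task ", task)
    ts <- e$time_scores                      # P x 64 x T
    base_t <- apply(ts, c(1, 3), mean)       # P x T baseline per time point
    Tn <- dim(ts)[3]
    p <- matrix(1, 64, Tn)
    for (tp in seq_len(Tn)) {
      b <- base_t[, tp]
      for (ch in seq_len(64))
        p[ch, tp] <- welch_t_test(ts[, ch, tp], b)$p
    }
    rej <- matrix(bh_fdr(as.vector(p), q), 64, Tn)
    rownames(rej) <- as.character(unclass(montage))
    attr(rej, "p") <- p
    masks[[task]] <- rej
  }
  masks
}

#' Permutation null for the channel-significance tests
#'
#' Randomly permutes each participant's 64 channel scores within
#' participant (the baseline, a mean over channels, is invariant under
#' the permutation), destroying any consistent channel-baseline
#' alignment. Running [significance_vs_baseline()] on the permuted table
#' checks the specificity of the attribution statistics: no channel
#' should survive FDR control under this null.
#'
#' @param table A `channel_score_table`.
#' @param seed Permutation seed.
#' @return The permuted `channel_score_table` (time scores dropped).
#' @export
permute_channel_scores <- function(table, seed = 1L) {
  with_seed(derive_seed(seed, "perm-null"), {
    for (task in names(table)) {
      sc <- table[[task]]$scores
      for (i in seq_len(nrow(sc))) sc[i, ] <- sc[i, sample.int(64)]
      table[[task]]$scores <- sc
      table[[task]]$baseline <- rowMeans(sc)
      table[[task]]$time_scores <- NULL
    }
    table
  })
}
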