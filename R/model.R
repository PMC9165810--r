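#' Architectural hyperparameters of the residual block system
#'
#' Defaults follow the reference architecture: `F1 = 8` temporal filters,
#' depth multiplier `D = 2`, `F2 = F1 * D = 16` separable filters, three
#' output classes, ten residual temporal blocks (Conv2Dtype1) and five
#' residual depthwise-separable blocks (Conv2Dtype3), temporal kernel 64
#' samples, spatial kernel spanning all 64 channels, separable kernel 16,
#' average pools of width 4 and 8, dropout 25%, and a max-norm cap of 1 on
#' the spatial filters. Ablation toggles remove the identity shortcuts,
#' batch normalization or dropout without changing anything else.
#'
#' @param F1 Number of temporal filters.
#' @param D Depth multiplier of the spatial convolution.
#' @param F2 Number of separable filters (warned if not `F1 * D`).
#' @param n_class Number of output classes.
#' @param n_type1_blocks,n_type3_blocks Counts of the two residual block
#'   types (each `>= 1`).
#' @param temporal_kernel,separable_kernel Temporal kernel lengths in
#'   samples.
#' @param spatial_kernel Spatial kernel height = number of channels.
#' @param pool1,pool2 Average-pooling widths.
#' @param dropout_p Dropout probability in `[0, 1)`.
#' @param maxnorm_c Max-norm cap on the spatial convolution filters.
#' @param use_residual,use_batchnorm,use_dropout Ablation toggles.
#' @param elu_after_residual Insert an ELU after each residual add
#'   (off by default; the reference blocks carry no activation there).
#' @param bn_eps,bn_momentum Batch-normalization numerics.
#' @return A `model_config` list.
#' @export
model_config <- function(F1 = 8L, D = 2L, F2 = F1 * D, n_class = 3L,
                         n_type1_blocks = 10L, n_type3_blocks = 5L,
                         temporal_kernel = 64L, spatial_kernel = 64L,
                         separable_kernel = 16L, pool1 = 4L, pool2 = 8L,
                         dropout_p = 0.25, maxnorm_c = 1.0,
                         use_residual = TRUE, use_batchnorm = TRUE,
                         use_dropout = TRUE, elu_after_residual = FALSE,
                         bn_eps = 1e-5, bn_momentum = 0.1) {
  counts <- c(F1 = F1, D = D, F2 = F2, n_class = n_class,
              n_type1_blocks = n_type1_blocks, n_type3_blocks = n_type3_blocks,
              temporal_kernel = temporal_kernel, spatial_kernel = spatial_kernel,
              separable_kernel = separable_kernel, pool1 = pool1, pool2 = pool2)
  if (any(counts < 1))
    stop("all architectural counts must be >= 1: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must be in [0, 1)")
  if (maxnorm_c <= 0) stop("maxnorm_c must be > 0")
  if (F2 != F1 * D)
    warning("F2 (", F2, ") != F1 * D (", F1 * D, "); proceeding as given")
  structure(list(F1 = as.integer(F1), D = as.integer(D), F2 = as.integer(F2),
                 n_class = as.integer(n_class),
                 n_type1_blocks = as.integer(n_type1_blocks),
                 n_type3_blocks = as.integer(n_type3_blocks),
                 temporal_kernel = as.integer(temporal_kernel),
                 spatial_kernel = as.integer(spatial_kernel),
                 separable_kernel = as.integer(separable_kernel),
                 pool1 = as.integer(pool1), pool2 = as.integer(pool2),
                 dropout_p = dropout_p, maxnorm_c = maxnorm_c,
                 use_residual = isTRUE(use_residual),
                 use_batchnorm = isTRUE(use_batchnorm),
                 use_dropout = isTRUE(use_dropout),
                 elu_after_residual = isTRUE(elu_after_residual),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "model_config")
}

# Glorot-uniform weight matrix
glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Input temporal filters start as random Gabor atoms: unit-norm windowed
# sinusoids with centre frequencies log-uniform over the physiological
# range (4-30 Hz at 160 Hz sampling) and random phase. The filter bank
# spans band-limited features from the first step; training reshapes it.
gabor_bank <- function(n_filters, K, sfreq = 160) {
  taps <- seq_len(K) - (K + 1) / 2
  W <- matrix(0, n_filters, K)
  for (f in seq_len(n_filters)) {
    freq <- exp(runif(1, log(4), log(30)))
    phase <- runif(1, 0, 2 * pi)
    w <- sin(2 * pi * freq * taps / sfreq + phase) * exp(-(taps / (K / 3))^2)
    W[f, ] <- w / sqrt(sum(w^2))
  }
  W
}

same_pad <- function(K) (K - 1L) %/% 2L

new_bn <- function(F, cfg) {
  list(kind = "bn", gamma = rep(1, F), beta = rep(0, F),
       eps = cfg$bn_eps, momentum = cfg$bn_momentum,
       run_mean = rep(0, F), run_var = rep(1, F), nmaps = F)
}

#' Assemble the residual network
#'
#' Builds the forward-composable block stack: one temporal input block
#' (Conv2Dtype0: kernel `(1, temporal_kernel)`, 1 -> F1 maps, batch norm),
#' `n_type1_blocks` residual temporal blocks (same kernel, F1 -> F1, batch
#' norm, identity shortcut), one spatial dimension-reduction block
#' (Conv2Dtype2: kernel `(spatial_kernel, 1)` collapsing the channel axis,
#' F1 -> F1*D maps, max-norm constrained, batch norm, ELU, average pool
#' `pool1`, dropout), `n_type3_blocks` residual depthwise-separable blocks
#' (depthwise `(1, separable_kernel)` + pointwise `(1, 1)`, batch norm,
#' shortcut), one Conv2Dtype4 block (separable convolution, batch norm,
#' shortcut, ELU, average pool `pool2`, dropout) and a classifier
#' convolution spanning the full remaining temporal extent followed by
#' log-softmax. Temporal convolutions use same-length zero padding so the
#' temporal extent is preserved until the pooling stages; the classifier
#' kernel length is derived from the traced extent (a message is logged
#' when it differs from 23, the extent printed for the reference
#' architecture).
#'
#' @param config A [model_config()].
#' @param n_samples Temporal extent of the input epochs (default 720).
#' @param seed Seed for weight initialization (Glorot uniform; the input
#'   temporal block starts as a random Gabor filter bank).
#' @return An `eegnet_model`.
#' @export
build_model <- function(config = model_config(), n_samples = 720L, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  cfg <- config
  C <- cfg$spatial_kernel
  with_seed(derive_seed(seed, "init"), {
    blocks <- list()
    add_block <- function(name, layers, residual_at = NA_integer_) {
      if (!cfg$use_dropout)
        layers <- Filter(function(l) l$kind != "dropout", layers)
      if (!cfg$use_batchnorm) {
        bn_pos <- which(vapply(layers, function(l) l$kind, "") == "bn")
        if (length(bn_pos)) {
          if (!is.na(residual_at) && residual_at %in% bn_pos)
            residual_at <- residual_at - 1L   # shortcut joins after the conv
          layers <- layers[-bn_pos]
          if (!is.na(residual_at))
            residual_at <- residual_at - sum(bn_pos < residual_at)
        }
      }
      if (!cfg$use_residual) residual_at <- NA_integer_
      if (cfg$elu_after_residual && !is.na(residual_at)) {
        layers <- append(layers, list(list(kind = "elu")), after = residual_at)
      }
      blocks[[length(blocks) + 1L]] <<-
        list(name = name, layers = layers, residual_at = residual_at)
    }
    Kt <- cfg$temporal_kernel
    Ks <- cfg$separable_kernel
    # Conv2Dtype0: temporal convolution 1 -> F1 + BN (Gabor filter bank)
    add_block("type0", list(
      list(kind = "conv_time", K = Kt, pad = same_pad(Kt),
           W = gabor_bank(cfg$F1, Kt)),
      new_bn(cfg$F1, cfg)))
    # Conv2Dtype1 x n: temporal convolution F1 -> F1 + BN + shortcut
    for (i in seq_len(cfg$n_type1_blocks))
      add_block(paste0("type1.", i), list(
        list(kind = "conv_time", K = Kt, pad = same_pad(Kt),
             W = glorot(cfg$F1, cfg$F1 * Kt, cfg$F1 * Kt, cfg$F1 * Kt)),
        new_bn(cfg$F1, cfg)), residual_at = 2L)
    # Conv2Dtype2: spatial convolution collapsing channels, max-norm,
    # BN + ELU, average pool, dropout
    add_block("type2", list(
      list(kind = "conv_spatial", C = C, maxnorm = cfg$maxnorm_c,
           W = glorot(cfg$F2, cfg$F1 * C, cfg$F1 * C, cfg$F2)),
      new_bn(cfg$F2, cfg),
      list(kind = "elu"),
      list(kind = "pool", p = cfg$pool1),
      list(kind = "dropout", p = cfg$dropout_p)))
    # Conv2Dtype3 x n: depthwise + pointwise + BN + shortcut
    for (i in seq_len(cfg$n_type3_blocks))
      add_block(paste0("type3.", i), list(
        list(kind = "conv_dw", K = Ks, pad = same_pad(Ks),
             W = glorot(cfg$F2, Ks, Ks, Ks)),
        list(kind = "conv_pw", W = glorot(cfg$F2, cfg$F2, cfg$F2, cfg$F2)),
        new_bn(cfg$F2, cfg)), residual_at = 3L)
    # Conv2Dtype4: separable conv + BN + shortcut, then ELU, pool, dropout
    add_block("type4", list(
      list(kind = "conv_dw", K = Ks, pad = same_pad(Ks),
           W = glorot(cfg$F2, Ks, Ks, Ks)),
      list(kind = "conv_pw", W = glorot(cfg$F2, cfg$F2, cfg$F2, cfg$F2)),
      new_bn(cfg$F2, cfg),
      list(kind = "elu"),
      list(kind = "pool", p = cfg$pool2),
      list(kind = "dropout", p = cfg$dropout_p)), residual_at = 3L)
    # Classifier: full-extent temporal convolution + log-softmax
    t_fin <- (n_samples %/% cfg$pool1) %/% cfg$pool2
    if (t_fin < 1L) stop("input too short for the configured pooling")
    if (t_fin != 23L)
      log_msg("classifier kernel derived from traced extent: (1, ", t_fin,
              ") [reference architecture prints (1, 23)]")
    add_block("classifier", list(
      list(kind = "classifier", Tfin = t_fin,
           W = glorot(cfg$n_class, cfg$F2 * t_fin, cfg$F2 * t_fin, cfg$n_class),
           b = rep(0, cfg$n_class)),
      list(kind = "logsoftmax")))
    model <- structure(list(config = cfg, blocks = blocks,
                            n_channels = C, n_samples = as.integer(n_samples),
                            seed = seed),
                       class = "eegnet_model")
    model
  })
}

layer_nparams <- function(l) {
  switch(l$kind,
         conv_time = , conv_spatial = , conv_dw = , conv_pw = length(l$W),
         bn = 2L * l$nmaps,
         classifier = length(l$W) + length(l$b),
         0L)
}

#' Trace per-block geometry and parameter counts
#'
#' Walks the block stack for a given input geometry and reports, per
#' block, the input/output feature-map counts, the spatial (channel) and
#' temporal extents of the output, and the number of trainable
#' parameters.
#'
#' @param model An `eegnet_model` from [build_model()].
#' @param input_geometry Integer `(channels, samples)`; defaults to the
#'   geometry the model was built for.
#' @return A data frame with one row per block.
#' @export
model_summary <- function(model,
                          input_geometry = c(model$n_channels, model$n_samples)) {
  C <- input_geometry[1]; Tn <- input_geometry[2]; F <- 1L
  rows <- lapply(model$blocks, function(b) {
    f_in <- F
    for (l in b$layers) {
      if (l$kind %in% c("conv_time", "conv_dw", "conv_pw")) F <<- nrow(l$W)
      if (l$kind == "conv_spatial") { F <<- nrow(l$W); C <<- 1L }
      if (l$kind == "pool") Tn <<- Tn %/% l$p
      if (l$kind == "classifier") { F <<- nrow(l$W); Tn <<- 1L }
    }
    kinds <- vapply(b$layers, function(l) l$kind, "")
    data.frame(block = b$name,
               kind = paste(kinds, collapse = "+"),
               residual = !is.na(b$residual_at),
               maps_in = f_in, maps_out = F,
               channels_out = C, samples_out = Tn,
               n_params = sum(vapply(b$layers, layer_nparams, 0L)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.eegnet_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf("<eegnet_model> %d blocks, %s parameters (input %d x %d)\n",
              nrow(s), format(sum(s$n_params), big.mark = ","),
              x$n_channels, x$n_samples))
  print(s, ...)
  invisible(x)
}

#' Identity-shortcut addition
#'
#' The residual connection: element-wise sum of a block's input and its
#' transformed output. Shapes must match exactly (shortcuts are only
#' placed where input and output maps agree); there is no projection.
#'
#' @param block_input,block_output Conformable numeric arrays.
#' @return `block_input + block_output`.
#' @export
residual_add <- function(block_input, block_output) {
  if (!identical(dim(block_input), dim(block_output)) ||
      length(block_input) != length(block_output))
    stop("residual shortcut requires identical shapes")
  block_input + block_output
}

#' Project convolution filters onto a maximum-norm ball
#'
#' Rescales every filter (row of the weight matrix) whose Euclidean norm
#' exceeds `c` back to norm `c`; filters within the cap are unchanged.
#' Applied to the spatial-convolution weights after every optimizer step.
#'
#' @param weights Numeric matrix, one filter per row (a vector is treated
#'   as a single filter).
#' @param c Norm cap (default 1).
#' @return The projected weights.
#' @export
project_maxnorm <- function(weights, c = 1.0) {
  if (c <= 0) stop("max-norm cap must be > 0")
  w <- if (is.matrix(weights)) weights else matrix(weights, nrow = 1)
  norms <- sqrt(rowSums(w * w))
  scale <- ifelse(norms > c, c / norms, 1)
  out <- w * scale
  if (!is.matrix(weights)) out <- as.vector(out)
  out
}
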