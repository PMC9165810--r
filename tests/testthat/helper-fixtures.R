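# Shared fixtures: tiny model geometries, brute-force oracles, and an
# independent EDF+ writer used to exercise the reader.

options(reegnet.quiet = TRUE)

# A small architecture on a 4-channel, 40-sample geometry: fast enough
# for finite differences yet covering every block type.
tiny_config <- function(...) {
  model_config(F1 = 2, D = 2, F2 = 4, n_type1_blocks = 2, n_type3_blocks = 1,
               temporal_kernel = 5, spatial_kernel = 4, separable_kernel = 3,
               pool1 = 2, pool2 = 2, ...)
}

tiny_model <- function(seed = 7, n_samples = 40L, ...) {
  build_model(tiny_config(...), n_samples = n_samples, seed = seed)
}

# Dataset with arbitrary geometry (bypasses the 64-channel epoch checks;
# the model is geometry-agnostic).
tiny_dataset <- function(n_channels = 4L, n_samples = 40L, n_subjects = 4L,
                         trials_per_class = 2L, seed = 1L,
                         effect_channel = NULL, effect = 0) {
  set.seed(seed)
  N <- n_subjects * 3L * trials_per_class
  x <- array(rnorm(n_channels * n_samples * N), c(n_channels, n_samples, N))
  subject <- rep(seq_len(n_subjects), each = 3L * trials_per_class)
  label <- rep(rep(0:2, each = trials_per_class), n_subjects)
  if (!is.null(effect_channel)) {
    tt <- seq_len(n_samples)
    for (i in seq_len(N)) {
      amp <- if (label[i] == 1L) 1 - effect else 1
      x[effect_channel, , i] <- x[effect_channel, , i] +
        amp * sin(2 * pi * 0.1 * tt + runif(1, 0, 2 * pi)) * 3
    }
  }
  reegnet:::new_dataset(x, subject, rep(1L, N), label, 160)
}

# Direct triple-loop convolution oracles (cross-correlation, zero pad)
naive_conv_time <- function(A, W, Tn, K, pad) {
  Fin <- nrow(A); Fout <- nrow(W); B <- ncol(A) / Tn
  O <- matrix(0, Fout, ncol(A))
  for (b in seq_len(B)) for (t in seq_len(Tn)) for (k in seq_len(K)) {
    ts <- t + (k - 1) - pad
    if (ts < 1 || ts > Tn) next
    for (g in seq_len(Fin))
      O[, (b - 1) * Tn + t] <- O[, (b - 1) * Tn + t] +
        W[, g + Fin * (k - 1)] * A[g, (b - 1) * Tn + ts]
  }
  O
}

naive_conv_spatial <- function(A, W, Tn, C) {
  Fin <- nrow(A); N <- ncol(A) / (Tn * C)
  O <- matrix(0, nrow(W), Tn * N)
  for (n in seq_len(N)) for (t in seq_len(Tn)) for (c in seq_len(C))
    for (g in seq_len(Fin))
      O[, (n - 1) * Tn + t] <- O[, (n - 1) * Tn + t] +
        W[, (c - 1) * Fin + g] * A[g, ((n - 1) * C + c - 1) * Tn + t]
  O
}

# Exhaustive Benjamini-Hochberg step-up: try every cutoff k directly.
brute_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0
  for (k in seq_len(m)) if (p[ord[k]] <= k * q / m) k_max <- k
  rej <- logical(m)
  if (k_max > 0) rej[ord[seq_len(k_max)]] <- TRUE
  # ties share a decision
  if (k_max > 0) rej[p <= p[ord[k_max]]] <- TRUE
  rej
}

# Brute-force Grad-CAM pieces
brute_alpha <- function(grads) {
  K <- dim(grads)[3]
  sapply(seq_len(K), function(k) {
    s <- 0
    for (i in seq_len(dim(grads)[1])) for (j in seq_len(dim(grads)[2]))
      s <- s + grads[i, j, k]
    s / (dim(grads)[1] * dim(grads)[2])
  })
}

brute_cam <- function(maps, alphas) {
  L <- matrix(0, dim(maps)[1], dim(maps)[2])
  for (k in seq_along(alphas)) L <- L + alphas[k] * maps[, , k]
  pmax(L, 0)
}

# Independent EDF+C writer (built from the format definition, not from
# the package reader) for round-trip tests of read_edf().
write_test_edf <- function(path, signals, sfreq, annotations,
                           labels = rownames(signals)) {
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  nsig <- nrow(signals)
  spr <- sfreq                      # one-second records
  n_records <- ncol(signals) / spr
  stopifnot(n_records == round(n_records))
  ns <- nsig + 1L                   # + annotation channel
  ann_spr <- 60L                    # 120 bytes of TAL space per record
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad("0", 8)); wr(pad("test patient", 80)); wr(pad("test recording", 80))
  wr("01.01.20"); wr("00.00.00")
  wr(pad(256 * (ns + 1L), 8)); wr(pad("EDF+C", 44))
  wr(pad(n_records, 8)); wr(pad(1, 8)); wr(pad(ns, 4))
  all_labels <- c(labels, "EDF Annotations")
  for (l in all_labels) wr(pad(l, 16))
  for (l in all_labels) wr(pad("", 80))
  for (l in all_labels) wr(pad("uV", 8))
  for (l in all_labels) wr(pad("-32.768", 8))   # phys min
  for (l in all_labels) wr(pad("32.767", 8))    # phys max
  for (l in all_labels) wr(pad("-32768", 8))
  for (l in all_labels) wr(pad("32767", 8))
  for (l in all_labels) wr(pad("", 80))
  wr(paste0(vapply(c(rep(spr, nsig), ann_spr), pad, "", w = 8),
            collapse = ""))
  for (l in all_labels) wr(pad("", 32))
  dig <- matrix(as.integer(round(signals * 1000)), nsig)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(nsig))
      writeBin(dig[i, cols], con, size = 2, endian = "little")
    tal <- sprintf("+%d\x14\x14", r - 1L)
    if (r == 1L && nrow(annotations))
      tal <- paste0(tal, paste0(
        sprintf("+%g\x15%g\x14%s\x14", annotations$onset,
                annotations$duration, annotations$code), collapse = ""))
    talraw <- charToRaw(tal)
    writeBin(c(talraw, raw(2L * ann_spr - length(talraw))), con)
  }
  invisible(path)
}
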