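# File interfaces: EDF+ ingestion, the dataset array container with its
# JSON sidecar, and model checkpoints.

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF+ recording
#'
#' Minimal reader for European Data Format files with annotations
#' (EDF+C): fixed 256-byte header, per-signal header fields, 16-bit
#' little-endian samples scaled to physical units, and an optional
#' "EDF Annotations" channel parsed as time-stamped annotation lists
#' (onset, duration, code). This covers the PhysioNet motor-task
#' recordings.
#'
#' @param path Path to an `.edf` file.
#' @param subject_id,session_id Optional overrides; by default parsed
#'   from a PhysioNet-style `S<subject>R<run>` file name when present.
#' @return A recording list: `signals` (channels x samples matrix, physical
#'   units), `sfreq`, `channels`, `annotations` (data frame with `onset`,
#'   `duration`, `code`), `subject_id`, `session_id` — the shape
#'   [epoch_recording()] consumes.
#' @export
read_edf <- function(path, subject_id = NULL, session_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_ascii(con, 8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  invisible(readBin(con, "raw", 160))            # patient + recording ids
  invisible(readBin(con, "raw", 16))             # start date + time
  header_bytes <- as.integer(read_ascii(con, 8))
  invisible(readBin(con, "raw", 44))             # reserved ("EDF+C")
  n_records <- as.integer(read_ascii(con, 8))
  record_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- field(16)
  invisible(field(80))                           # transducer
  invisible(field(8))                            # physical dimension
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  invisible(field(80))                           # prefiltering
  spr <- as.integer(field(8))                    # samples per record
  invisible(field(32))                           # reserved
  seek(con, header_bytes)
  ann_idx <- which(labels == "EDF Annotations")
  sig_idx <- setdiff(seq_len(ns), ann_idx)
  sig <- lapply(sig_idx, function(i) numeric(0))
  ann_raw <- raw(0)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                      endian = "little")
      if (i %in% ann_idx) {
        ann_raw <- c(ann_raw, writeBin(vals, raw(), size = 2,
                                       endian = "little"))
      } else {
        j <- match(i, sig_idx)
        scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
        sig[[j]] <- c(sig[[j]], (vals - dig_min[i]) * scale + phys_min[i])
      }
    }
  }
  signals <- do.call(rbind, sig)
  rownames(signals) <- labels[sig_idx]
  annotations <- parse_tals(ann_raw)
  sfreq <- if (length(sig_idx)) spr[sig_idx[1]] / record_dur else NA_real_
  base <- basename(path)
  m <- regmatches(base, regexec("S(\\d+)R(\\d+)", base))[[1]]
  list(signals = signals, sfreq = sfreq, channels = labels[sig_idx],
       annotations = annotations,
       subject_id = subject_id %||%
         (if (length(m)) as.integer(m[2]) else 0L),
       session_id = session_id %||%
         (if (length(m)) as.integer(m[3]) else 1L))
}

# Parse EDF+ time-stamped annotation lists (TALs). A TAL is
# "<onset>[\x15<duration>]\x14<text>\x14...\x00"; timekeeping TALs (empty
# text) are dropped.
parse_tals <- function(bytes) {
  out <- data.frame(onset = numeric(), duration = numeric(),
                    code = character())
  if (!length(bytes)) return(out)
  txt <- rawToChar(bytes[bytes != as.raw(0)] )
  # re-split on TAL boundaries: each TAL ends with \x14 before the next onset
  tals <- strsplit(txt, "\x14\\+", perl = TRUE)[[1]]
  tals[-1] <- paste0("+", tals[-1])
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    head_part <- strsplit(parts[1], "\x15")[[1]]
    onset <- suppressWarnings(as.numeric(head_part[1]))
    if (is.na(onset)) next
    duration <- if (length(head_part) > 1)
      suppressWarnings(as.numeric(head_part[2])) else NA_real_
    notes <- parts[-1]
    notes <- notes[nzchar(notes)]
    for (code in notes)
      out[nrow(out) + 1L, ] <- list(onset, duration, code)
  }
  out
}

#' Write a dataset to an array-container directory
#'
#' The container is a directory holding `data.bin` (the
#' `64 x T x N` sample array as little-endian float64, channel-fastest)
#' and `sidecar.json` describing dims, per-trial subject/session/label
#' vectors, sampling rate, montage, and provenance (package version and,
#' for synthetic data, the full generator spec including planted
#' channels).
#'
#' @param dataset An `eeg_dataset`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(as.vector(dataset$x), con, size = 8, endian = "little")
  close(con)
  gt <- dataset$ground_truth
  sidecar <- list(
    format = "reegnet-dataset-v1",
    dims = dim(dataset$x),
    subject = dataset$subject, session = dataset$session,
    label = dataset$label, label_names = TASK_LABELS,
    sfreq = dataset$sfreq,
    montage = as.character(unclass(dataset$montage)),
    provenance = list(
      package = "reegnet",
      version = as.character(utils::packageVersion("reegnet")),
      synthetic_spec = if (!is.null(gt)) unclass(gt)))
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset from an array-container directory
#'
#' @param dir Directory written by [write_dataset()].
#' @return An `eeg_dataset`.
#' @export
read_dataset <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                                 simplifyVector = TRUE)
  if (!identical(sidecar$format, "reegnet-dataset-v1"))
    stop("not a reegnet dataset directory: ", dir)
  dims <- as.integer(sidecar$dims)
  con <- file(file.path(dir, "data.bin"), "rb")
  x <- readBin(con, "numeric", prod(dims), size = 8, endian = "little")
  close(con)
  gt <- sidecar$provenance$synthetic_spec
  if (!is.null(gt)) {
    gt$planted_channels <- lapply(gt$planted_channels, as.integer)
    gt <- structure(gt, class = "synthetic_spec")
  }
  new_dataset(array(x, dims), sidecar$subject, sidecar$session,
              sidecar$label, sidecar$sfreq,
              montage = build_montage(sidecar$montage), ground_truth = gt)
}

#' Save a fitted model (or bare model) checkpoint
#'
#' Writes the serialized object plus a JSON sidecar with the embedded
#' architectural configuration and training metadata, so a checkpoint is
#' self-describing.
#'
#' @param object An `eegnet_fit` or `eegnet_model`.
#' @param path Checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(object, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(object, path)
  cfg <- if (inherits(object, "eegnet_fit")) object$config else object$config
  meta <- list(package = "reegnet",
               version = as.character(utils::packageVersion("reegnet")),
               class = class(object)[1],
               model_config = unclass(cfg),
               train_config = if (inherits(object, "eegnet_fit"))
                 unclass(object$train_config),
               best_epoch = if (inherits(object, "eegnet_fit"))
                 object$best_epoch)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return The stored `eegnet_fit` or `eegnet_model`.
#' @export
load_model <- function(path) readRDS(path)
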