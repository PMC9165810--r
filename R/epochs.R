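#' Construct a single EEG epoch
#'
#' An epoch is one trial: a channels-by-samples matrix of real values
#' (microvolts before normalization, unitless after) plus subject, session
#' and task-label metadata.
#'
#' @param data Numeric matrix with exactly 64 rows (channels); columns are
#'   time samples (default trial geometry: 720 samples = 4.5 s at 160 Hz).
#' @param subject_id,session_id Integer identifiers.
#' @param label Task label: `"rest"`, `"left"`, `"right"` or its integer
#'   code 0/1/2.
#' @param sfreq Sampling rate in Hz.
#' @return An `eeg_epoch`: the data matrix with metadata attributes.
#' @export
eeg_epoch <- function(data, subject_id, session_id = 1L, label, sfreq = 160) {
  data <- as.matrix(data)
  if (nrow(data) != 64L)
    stop("epoch data must have 64 channel rows, got ", nrow(data))
  if (!all(is.finite(data))) stop("epoch contains non-finite values")
  structure(data,
            subject_id = as.integer(subject_id),
            session_id = as.integer(session_id),
            label = as_label_code(label),
            sfreq = sfreq,
            class = c("eeg_epoch", "matrix", "array"))
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> subject %d session %d label %s: 64 x %d @ %g Hz\n",
              attr(x, "subject_id"), attr(x, "session_id"),
              label_name(attr(x, "label")), ncol(x), attr(x, "sfreq")))
  invisible(x)
}

#' Bundle epochs into a dataset
#'
#' A dataset stores all trials in one `64 x T x N` array together with
#' per-trial subject, session and label vectors. All epochs must share the
#' same temporal extent and sampling rate.
#'
#' @param epochs List of [eeg_epoch()] objects.
#' @param montage Optional `eeg_montage`; defaults to [physionet_montage()].
#' @param ground_truth Optional generator spec for synthetic data.
#' @return An `eeg_dataset`.
#' @export
as_eeg_dataset <- function(epochs, montage = physionet_montage(),
                           ground_truth = NULL) {
  if (length(epochs) == 0L) stop("no epochs")
  Tn <- unique(vapply(epochs, ncol, 1L))
  sf <- unique(vapply(epochs, function(e) attr(e, "sfreq"), 1))
  if (length(Tn) != 1L || length(sf) != 1L)
    stop("epochs differ in length or sampling rate")
  x <- array(0, c(64L, Tn, length(epochs)))
  for (i in seq_along(epochs)) x[, , i] <- unclass(epochs[[i]])
  structure(list(
    x = x,
    subject = vapply(epochs, function(e) attr(e, "subject_id"), 1L),
    session = vapply(epochs, function(e) attr(e, "session_id"), 1L),
    label = vapply(epochs, function(e) attr(e, "label"), 1L),
    sfreq = sf,
    montage = montage,
    ground_truth = ground_truth), class = "eeg_dataset")
}

new_dataset <- function(x, subject, session, label, sfreq,
                        montage = physionet_montage(), ground_truth = NULL) {
  structure(list(x = x, subject = as.integer(subject),
                 session = as.integer(session), label = as.integer(label),
                 sfreq = sfreq, montage = montage,
                 ground_truth = ground_truth), class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  cat(sprintf("<eeg_dataset> %d epochs (64 x %d @ %g Hz), %d subjects\n",
              n_epochs(x), dim(x$x)[2], x$sfreq, length(unique(x$subject))))
  print(table(task = label_name(x$label)))
  invisible(x)
}

#' Number of epochs in a dataset
#' @param dataset An `eeg_dataset`.
#' @return Integer count.
#' @export
n_epochs <- function(dataset) dim(dataset$x)[3]

#' Subset a dataset by epoch index
#' @param x An `eeg_dataset`.
#' @param i Integer or logical index over epochs.
#' @param ... Unused.
#' @export
`[.eeg_dataset` <- function(x, i, ...) {
  new_dataset(x$x[, , i, drop = FALSE], x$subject[i], x$session[i],
              x$label[i], x$sfreq, x$montage, x$ground_truth)
}

#' Extract one epoch from a dataset
#' @param dataset An `eeg_dataset`.
#' @param i Epoch index.
#' @return An [eeg_epoch()].
#' @export
get_epoch <- function(dataset, i) {
  eeg_epoch(dataset$x[, , i], dataset$subject[i], dataset$session[i],
            dataset$label[i], dataset$sfreq)
}

#' Keep only the epochs of the given subjects
#' @param dataset An `eeg_dataset`.
#' @param subjects Integer subject ids.
#' @export
subset_subjects <- function(dataset, subjects) {
  dataset[dataset$subject %in% subjects]
}

#' Cut task epochs out of an annotated recording
#'
#' Each annotation whose window fits inside the recording yields one epoch
#' starting at the annotation onset sample (0-based, half-open window
#' `[start, start + round(duration_s * sfreq))`). Annotations running past
#' the end of the recording are skipped and counted. PhysioNet fist-movement
#' runs use codes T0 (rest), T1 (left fist), T2 (right fist).
#'
#' @param recording A list with elements `signals` (64 x S numeric matrix),
#'   `sfreq` (Hz), `channels` (labels), `annotations` (data frame with
#'   `onset` seconds, `duration` seconds, `code`), and optionally
#'   `subject_id` / `session_id`. [read_edf()] returns this shape.
#' @param duration_s Epoch duration in seconds (default 4.5).
#' @param code_map Named map from annotation codes to task labels.
#' @param expected_sfreq Required sampling rate; recordings at any other
#'   rate are rejected rather than resampled. `NULL` disables the check.
#' @return List with `epochs` (list of [eeg_epoch()]), `n_skipped`, and
#'   `skip_log` (data frame of skipped annotations).
#' @export
epoch_recording <- function(recording, duration_s = 4.5,
                            code_map = c(T0 = "rest", T1 = "left", T2 = "right"),
                            expected_sfreq = 160) {
  sfreq <- recording$sfreq
  if (!is.null(expected_sfreq) && !isTRUE(all.equal(sfreq, expected_sfreq)))
    stop("recording sampled at ", sfreq, " Hz; expected ", expected_sfreq,
         " Hz (resampling is not supported)")
  ann <- recording$annotations
  if (is.null(ann) || nrow(ann) == 0L) stop("recording has no annotations")
  unknown <- setdiff(unique(as.character(ann$code)), names(code_map))
  if (length(unknown))
    stop("unknown annotation code(s): ", paste(unknown, collapse = ", "))
  S <- ncol(recording$signals)
  L <- round(duration_s * sfreq)
  subject <- recording$subject_id %||% 0L
  session <- recording$session_id %||% 1L
  epochs <- list(); skipped <- list()
  for (r in seq_len(nrow(ann))) {
    start <- round(ann$onset[r] * sfreq)            # 0-based start sample
    if (start + L > S) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(onset = ann$onset[r], code = as.character(ann$code[r]))
      next
    }
    epochs[[length(epochs) + 1L]] <- eeg_epoch(
      recording$signals[, (start + 1L):(start + L), drop = FALSE],
      subject_id = subject, session_id = session,
      label = code_map[[as.character(ann$code[r])]], sfreq = sfreq)
  }
  skip_log <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(onset = numeric(), code = character())
  list(epochs = epochs, n_skipped = nrow(skip_log), skip_log = skip_log)
}
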