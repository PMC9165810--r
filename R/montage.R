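#' Build a 64-channel montage
#'
#' A montage fixes the ordering of the 64 scalp electrodes (international
#' 10-10 placement) used by every epoch in a dataset. The ordering is taken
#' verbatim from the input; for PhysioNet recordings this is the EDF header
#' order.
#'
#' @param channel_names Character vector of exactly 64 unique electrode
#'   labels. Trailing periods (as found in EDF headers, e.g. `"Fc5."`) are
#'   stripped.
#' @return An object of class `eeg_montage`: a character vector of labels
#'   with a lookup method via [channel_index()].
#' @seealso [physionet_montage()] for the standard 64-channel layout.
#' @export
build_montage <- function(channel_names) {
  labels <- sub("\\.+$", "", trimws(as.character(channel_names)))
  if (length(labels) != 64L)
    stop("a montage needs exactly 64 channel names, got ", length(labels))
  if (anyDuplicated(labels))
    stop("duplicate channel names: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  structure(labels, class = "eeg_montage")
}

#' Position of a channel label within a montage
#'
#' @param montage An `eeg_montage`.
#' @param label Character vector of channel labels (case-insensitive).
#' @return Integer 1-based positions.
#' @export
channel_index <- function(montage, label) {
  stopifnot(inherits(montage, "eeg_montage"))
  i <- match(toupper(label), toupper(unclass(montage)))
  if (anyNA(i))
    stop("channel not in montage: ", paste(label[is.na(i)], collapse = ", "))
  i
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> 64 channels:", paste(head(unclass(x), 6), collapse = ", "),
      "...", x[64], "\n")
  invisible(x)
}

#' The 64-channel PhysioNet motor-task montage
#'
#' Channel labels in the header order of the PhysioNet motor
#' movement/imagery recordings (10-10 system, 64 electrodes).
#'
#' @return An `eeg_montage`.
#' @export
physionet_montage <- function() {
  build_montage(c(
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FT8", "T7", "T8", "T9", "T10", "TP7", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "Iz"))
}
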