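#' Drop subjects with incomplete recordings
#'
#' Four participants of the PhysioNet motor dataset (#88, #89, #92, #100)
#' did not complete the experiment and are excluded by default.
#'
#' @param subject_ids Integer vector of subject ids.
#' @param excluded Ids to remove.
#' @return The set difference, with a log message naming which requested
#'   exclusions were actually present.
#' @export
exclude_subjects <- function(subject_ids, excluded = c(88L, 89L, 92L, 100L)) {
  present <- intersect(excluded, subject_ids)
  absent <- setdiff(excluded, subject_ids)
  if (length(present))
    log_msg("excluding subjects: ", paste(present, collapse = ", "))
  if (length(absent))
    log_msg("requested exclusions not present: ", paste(absent, collapse = ", "))
  setdiff(subject_ids, excluded)
}

#' Plan a subject-disjoint test split and k-fold partition
#'
#' Draws `n_test` subjects uniformly without replacement as a fixed test
#' set, then partitions the remaining subjects into `n_folds` validation
#' sets of near-equal size (seeded shuffle followed by contiguous
#' chunking). Each fold trains on all non-test subjects outside its
#' validation set, so training, validation and test participants never
#' overlap.
#'
#' @param subject_ids Integer vector of available subject ids (already
#'   filtered with [exclude_subjects()]).
#' @param n_test Number of held-out test subjects (default 20).
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `split_plan`: list with `test_subjects`, `folds` (each a list
#'   with `train` and `val`), and `seed`.
#' @export
make_split_plan <- function(subject_ids, n_test = 20L, n_folds = 5L, seed = 1L) {
  subject_ids <- sort(unique(as.integer(subject_ids)))
  if (n_test >= length(subject_ids))
    stop("n_test (", n_test, ") must be smaller than the number of subjects (",
         length(subject_ids), ")")
  if (n_folds < 1L || n_folds > length(subject_ids) - n_test)
    stop("invalid n_folds")
  with_seed(derive_seed(seed, "split"), {
    test <- sort(sample(subject_ids, n_test))
    rest <- sample(setdiff(subject_ids, test))   # shuffled remaining subjects
    sizes <- rep(length(rest) %/% n_folds, n_folds)
    extra <- length(rest) %% n_folds
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(1L, head(ends, -1L) + 1L)
    folds <- lapply(seq_len(n_folds), function(k) {
      val <- sort(rest[starts[k]:ends[k]])
      list(train = sort(setdiff(rest, val)), val = val)
    })
    structure(list(test_subjects = test, folds = folds, seed = seed),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d test subjects, %d folds (val sizes: %s), seed %d\n",
              length(x$test_subjects), length(x$folds),
              paste(vapply(x$folds, function(f) length(f$val), 1L),
                    collapse = "/"), x$seed))
  invisible(x)
}

# Internal leakage guard used by the training/evaluation pipeline.
check_disjoint <- function(plan) {
  for (f in plan$folds) {
    if (length(intersect(f$train, f$val)))
      stop("subject leakage: train and validation overlap")
    if (length(intersect(plan$test_subjects, c(f$train, f$val))))
      stop("subject leakage: test subjects appear in a fold")
  }
  invisible(TRUE)
}
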