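#' @useDynLib reegnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif pt sd var
#' @importFrom utils head modifyList
NULL

# Task label encoding is fixed across the whole pipeline: rest=0, left=1, right=2.
TASK_LABELS <- c("rest", "left", "right")

#' Task label codes
#'
#' The fixed three-class encoding used throughout: `rest = 0`, `left = 1`
#' (left-fist movement), `right = 2` (right-fist movement).
#'
#' @return Named integer vector of length 3.
#' @export
task_labels <- function() {
  structure(0:2, names = TASK_LABELS)
}

label_name <- function(code) TASK_LABELS[code + 1L]

as_label_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(!x %in% 0:2)) stop("task label codes must be in 0:2")
    return(x)
  }
  i <- match(tolower(as.character(x)), TASK_LABELS)
  if (anyNA(i)) stop("unknown task label: ", paste(x[is.na(i)], collapse = ", "))
  as.integer(i - 1L)
}

# Deterministic sub-seed for a named component, derived from one global seed.
# Keeps every derived seed in [1, 2^31 - 2].
derive_seed <- function(seed, component) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% m
  s <- (abs(as.numeric(seed)) %% m)
  as.integer(((s * 48271) %% m + h) %% (m - 1) + 1)
}

# Run expr with a local RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

log_msg <- function(...) {
  if (isTRUE(getOption("reegnet.quiet", FALSE))) return(invisible(NULL))
  message("[reegnet] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
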