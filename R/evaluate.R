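#' Confusion matrix, overall accuracy and per-subject accuracies
#'
#' @param preds Predicted labels (codes or names).
#' @param labels True labels.
#' @param subjects Optional per-trial subject ids for the per-subject
#'   accuracy table.
#' @return List with `confusion` (`n_class x n_class` counts,
#'   `counts[i, j]` = actual class i predicted as j), `accuracy`
#'   (trace/total), and `per_subject` (data frame, or NULL).
#' @export
confusion_and_accuracy <- function(preds, labels, subjects = NULL) {
  if (length(preds) == 0L) stop("empty input")
  preds <- as_label_code(preds); labels <- as_label_code(labels)
  if (length(preds) != length(labels)) stop("length mismatch")
  cm <- table(factor(labels, 0:2, TASK_LABELS),
              factor(preds, 0:2, TASK_LABELS))
  cm <- matrix(cm, 3, 3, dimnames = list(actual = TASK_LABELS,
                                         predicted = TASK_LABELS))
  per_subject <- NULL
  if (!is.null(subjects)) {
    acc <- tapply(preds == labels, subjects, mean)
    per_subject <- data.frame(subject = as.integer(names(acc)),
                              accuracy = as.numeric(acc),
                              n = as.integer(table(subjects)))
  }
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm),
       per_subject = per_subject)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided two-sample t-test without the equal-variance assumption:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom. Accepts either raw samples or
#' `(mean, sd, n)` summaries per group; raw samples are reduced to the
#' same summaries, so both routes give identical results.
#'
#' @param group_a,group_b Numeric sample vectors, or named vectors/lists
#'   with elements `mean`, `sd`, `n`.
#' @return A `stat_test_result`: list with `t`, `df`, `p` (two-tailed),
#'   `mean_diff`.
#' @export
welch_t_test <- function(group_a, group_b) {
  summ <- function(g) {
    if ((is.list(g) || !is.null(names(g))) &&
        all(c("mean", "sd", "n") %in% names(g)))
      return(list(m = as.numeric(g[["mean"]]), s = as.numeric(g[["sd"]]),
                  n = as.numeric(g[["n"]])))
    g <- as.numeric(g)
    list(m = mean(g), s = sd(g), n = length(g))
  }
  a <- summ(group_a); b <- summ(group_b)
  if (a$n < 2 || b$n < 2) stop("each group needs n >= 2")
  if (a$s < 0 || b$s < 0) stop("sd must be >= 0")
  se2 <- a$s^2 / a$n + b$s^2 / b$n
  if (se2 == 0) {
    t <- 0; df <- a$n + b$n - 2; p <- 1
  } else {
    t <- (a$m - b$m) / sqrt(se2)
    df <- se2^2 / ((a$s^2 / a$n)^2 / (a$n - 1) + (b$s^2 / b$n)^2 / (b$n - 1))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p = p, mean_diff = a$m - b$m),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4g (two-tailed)\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate decisions
#'
#' Step-up FDR control at level `q`: with the sorted p-values
#' `p_(1) <= ... <= p_(m)`, find the largest `k` with
#' `p_(k) <= k q / m` and reject hypotheses `1..k`. Tied p-values share a
#' decision and the result maps back to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1), default 0.05.
#' @return Logical vector of rejection flags, input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  stats::p.adjust(p, method = "BH") <= q
}

#' Compare model variants against a reference with Welch tests and FDR
#'
#' One Welch two-tailed test per variant against the reference (fold
#' accuracies, or `(mean, sd, n)` summary rows), with Benjamini-Hochberg
#' control over the family of comparisons. Both raw and adjusted
#' decisions are reported.
#'
#' @param variants Named list: each element either a numeric vector of
#'   per-fold accuracies or a `c(mean =, sd =, n =)` summary.
#' @param reference Name of the reference variant.
#' @param q FDR level.
#' @return Data frame with one row per non-reference variant: `t`, `df`,
#'   `p`, `p_adj`, `rejected`.
#' @export
compare_variants <- function(variants, reference = names(variants)[1],
                             q = 0.05) {
  if (length(variants) < 2L) stop("need at least two variants")
  if (!reference %in% names(variants))
    stop("unknown reference variant: ", reference)
  ref <- variants[[reference]]
  others <- setdiff(names(variants), reference)
  res <- lapply(others, function(nm) welch_t_test(ref, variants[[nm]]))
  p <- vapply(res, function(r) r$p, 1)
  out <- data.frame(variant = others,
                    t = vapply(res, function(r) r$t, 1),
                    df = vapply(res, function(r) r$df, 1),
                    p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    rejected = bh_fdr(p, q))
  attr(out, "reference") <- reference
  out
}

#' Subject-disjoint cross-validated evaluation
#'
#' For each fold of the split plan: train a freshly initialized model on
#' the fold's training subjects, select the best-validation checkpoint on
#' the fold's validation subjects, and evaluate on the fixed test
#' subjects. Subject leakage is checked before any training starts.
#'
#' @param config [model_config()].
#' @param train_cfg [train_config()]; fold `k` trains with seed
#'   `seed + k - 1` so folds are independent but reproducible.
#' @param dataset An `eeg_dataset` containing all subjects of the plan.
#' @param plan A [make_split_plan()] result.
#' @param augment [augment_params()].
#' @param ... Passed to [train_model()].
#' @return List of class `cv_results`: per-fold list (fit summary,
#'   test accuracy, confusion, per-subject accuracies) plus
#'   `mean_accuracy` and `sd_accuracy` across folds.
#' @export
run_cross_validation <- function(config, train_cfg, dataset, plan,
                                 augment = augment_params(), ...) {
  check_disjoint(plan)
  have <- unique(dataset$subject)
  need <- unique(c(plan$test_subjects, unlist(lapply(plan$folds, unlist))))
  if (!all(need %in% have))
    stop("plan subjects missing from dataset: ",
         paste(setdiff(need, have), collapse = ", "))
  test_set <- subset_subjects(dataset, plan$test_subjects)
  folds <- vector("list", length(plan$folds))
  for (k in seq_along(plan$folds)) {
    f <- plan$folds[[k]]
    cfg_k <- train_cfg
    cfg_k$seed <- train_cfg$seed + k - 1L
    model <- build_model(config, n_samples = dim(dataset$x)[2],
                         seed = cfg_k$seed)
    fit <- train_model(model, subset_subjects(dataset, f$train),
                       subset_subjects(dataset, f$val),
                       augment = augment, config = cfg_k, ...)
    preds <- predict(fit, test_set)
    ev <- confusion_and_accuracy(preds, test_set$label, test_set$subject)
    folds[[k]] <- list(fold = k, fit = fit, accuracy = ev$accuracy,
                       confusion = ev$confusion,
                       per_subject = ev$per_subject,
                       val_subjects = f$val, seed = cfg_k$seed)
    log_msg(sprintf("fold %d: test accuracy %.3f (best val %.3f @ epoch %d)",
                    k, ev$accuracy, fit$best_val_acc, fit$best_epoch))
  }
  acc <- vapply(folds, function(f) f$accuracy, 1)
  structure(list(folds = folds, accuracies = acc,
                 mean_accuracy = mean(acc), sd_accuracy = sd(acc),
                 plan = plan),
            class = "cv_results")
}

#' @export
print.cv_results <- function(x, ...) {
  cat(sprintf("<cv_results> %d folds: mean test accuracy %.3f +/- %.3f\n",
              length(x$folds), x$mean_accuracy, x$sd_accuracy))
  cat("fold accuracies:", paste(sprintf("%.3f", x$accuracies),
                                collapse = ", "), "\n")
  invisible(x)
}
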