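#' Four-class confusion matrix
#'
#' Rows are the predicted class, columns the true class, so column sums are
#' the per-class trial counts and the diagonal holds the correct decisions.
#'
#' @param y_true,y_pred integer class vectors (values in 1..4) of equal
#'   length.
#' @param n_classes number of classes (default 4).
#' @return object of class `confusion_matrix`: integer `n_classes x
#'   n_classes` matrix with attribute `n_total`.
#' @export
confusion <- function(y_true, y_pred, n_classes = 4L) {
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length")
  if (length(y_true) &&
      (any(y_true < 1L | y_true > n_classes) ||
       any(y_pred < 1L | y_pred > n_classes)))
    stop(sprintf("classes must lie in 1..%d", n_classes))
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(predicted = CLASS_NAMES[seq_len(n_classes)],
                               true = CLASS_NAMES[seq_len(n_classes)]))
  for (i in seq_along(y_true)) {
    cm[y_pred[i], y_true[i]] <- cm[y_pred[i], y_true[i]] + 1L
  }
  structure(cm, n_total = length(y_true), class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest metrics of a confusion matrix
#'
#' For each class treated as positive against the rest: accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, precision `PPV = TP/(TP+FP)`, sensitivity
#' `TPR = TP/(TP+FN)` and specificity `TNR = TN/(TN+FP)`. A zero denominator
#' yields an explicit `NA` ("n/a"), never silent NaN. The overall accuracy
#' is the diagonal sum over the total.
#'
#' @param cm a [confusion()] matrix.
#' @return list with `per_class` (data.frame of class, ACC, PPV, TPR, TNR)
#'   and `overall_acc`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix")
  C <- nrow(cm)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  per <- do.call(rbind, lapply(seq_len(C), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[k, -k])
    fn <- sum(cm[-k, k])
    tn <- total - tp - fp - fn
    data.frame(class = rownames(cm)[k],
               ACC = rate(tp + tn, total),
               PPV = rate(tp, tp + fp),
               TPR = rate(tp, tp + fn),
               TNR = rate(tn, tn + fp))
  }))
  list(per_class = per, overall_acc = sum(diag(cm)) / total)
}

#' Cohen's kappa from accuracy against chance 1/C
#'
#' `kappa = (ACC - 1/C) / (1 - 1/C)`: 0 at chance level, 1 at perfect
#' agreement.
#'
#' @param acc accuracy in `[0, 1]`.
#' @param n_classes number of classes, at least 2.
#' @return kappa coefficient.
#' @export
kappa_score <- function(acc, n_classes = 4L) {
  if (n_classes < 2L) stop("`n_classes` must be at least 2")
  if (any(acc < 0 | acc > 1)) stop("`acc` must lie in [0, 1]")
  (acc - 1 / n_classes) / (1 - 1 / n_classes)
}

#' Reduce window-level posteriors to trial-level decisions
#'
#' Averages the posteriors of each trial's windows and takes the argmax;
#' exact ties resolve deterministically to the lowest class index.
#'
#' @param posteriors window x class matrix.
#' @param trial_ids trial id per window.
#' @return data.frame with one row per trial: `trial_id`, `pred`.
#' @export
aggregate_trials <- function(posteriors, trial_ids) {
  stopifnot(is.matrix(posteriors), nrow(posteriors) == length(trial_ids))
  if (nrow(posteriors) == 0L) stop("no windows to aggregate")
  ids <- sort(unique(trial_ids))
  mean_post <- rowsum(posteriors, trial_ids) /
    as.vector(table(factor(trial_ids, levels = ids)))
  pred <- apply(mean_post, 1L, which.max)    # first max = lowest class index
  data.frame(trial_id = ids, pred = as.integer(pred))
}

#' Evaluate a trained network on one subject's test windows
#'
#' Runs the evaluation-mode forward pass, aggregates windows to trial
#' decisions, and computes the confusion matrix, per-class one-vs-rest
#' metrics, overall accuracy (trial level, with window-level alongside) and
#' kappa.
#'
#' @param net a trained `miattn_net`.
#' @param epochs_set the subject's labelled test `epoch_set`.
#' @return list of class `eval_report`: `confusion`, `metrics`,
#'   `acc` (trial level), `window_acc`, `kappa`, `n_trials`.
#' @export
evaluate_subject <- function(net, epochs_set) {
  post <- net_forward(net, epochs_set, train_mode = FALSE)
  agg <- aggregate_trials(unclass(post), epochs_set$trial_ids)
  truth <- epochs_set$labels[match(agg$trial_id, epochs_set$trial_ids)]
  cm <- confusion(truth, agg$pred, n_classes = net$spec$n_classes)
  met <- class_metrics(cm)
  win_acc <- mean(max.col(post, ties.method = "first") == epochs_set$labels)
  structure(list(confusion = cm, metrics = met$per_class,
                 acc = met$overall_acc, window_acc = win_acc,
                 kappa = kappa_score(met$overall_acc, net$spec$n_classes),
                 n_trials = sum(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d trials: ACC %.1f%%, kappa %.3f (window ACC %.1f%%)\n",
              x$n_trials, 100 * x$acc, x$kappa, 100 * x$window_acc))
  print(unclass(x$confusion))
  invisible(x)
}

#' Summarize per-subject results as mean and standard deviation
#'
#' Uses the population standard deviation (divisor n) by default; accuracies
#' are conventionally reported in percent to one decimal and kappa to three
#' decimals, with full precision retained in the returned values.
#'
#' @param per_subject_acc accuracies (proportions or percent) per subject.
#' @param per_subject_kappa optional kappas per subject.
#' @param sample_sd use the sample (divisor n-1) standard deviation instead.
#' @return list with `mean_acc`, `sd_acc` and, when kappas are given,
#'   `mean_kappa`, `sd_kappa`.
#' @export
summarize_subjects <- function(per_subject_acc, per_subject_kappa = NULL,
                               sample_sd = FALSE) {
  if (length(per_subject_acc) < 1L) stop("at least one subject is required")
  msd <- function(x) {
    m <- mean(x)
    dn <- if (sample_sd) length(x) - 1L else length(x)
    s <- if (dn > 0) sqrt(sum((x - m)^2) / dn) else 0
    c(mean = m, sd = s)
  }
  a <- msd(per_subject_acc)
  out <- list(mean_acc = unname(a["mean"]), sd_acc = unname(a["sd"]))
  if (!is.null(per_subject_kappa)) {
    k <- msd(per_subject_kappa)
    out$mean_kappa <- unname(k["mean"]); out$sd_kappa <- unname(k["sd"])
  }
  out
}
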