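# Validation of the cutoff classifiers against the logic-tree reference.
# Positive label is SEXUAL acquisition throughout: true positives are
# reference-sexual participants classified sexual by the cutoff, true
# negatives reference-vertical classified vertical. Participants left
# unclassified by either source are excluded before counting.

#' Confusion matrix of a cutoff classifier against the reference
#'
#' @param reference_labels character vector (the logic-tree labels) in
#'   `c("vertical", "sexual", "unclassified")`.
#' @param test_labels character vector, aligned to `reference_labels`, in
#'   `c("vertical", "sexual", "missing")`.
#' @return list of class `moha_confusion` with integer fields `tp`, `fn`,
#'   `fp`, `tn` and `n_evaluated = tp+fn+fp+tn`.
#' @export
#' @examples
#' confusion_matrix(c("sexual", "sexual", "vertical", "vertical"),
#'                  c("sexual", "vertical", "vertical", "vertical"))
confusion_matrix <- function(reference_labels, test_labels) {
  stopifnot(length(reference_labels) == length(test_labels))
  keep <- reference_labels %in% c("vertical", "sexual") &
    test_labels %in% c("vertical", "sexual")
  r <- reference_labels[keep]; t <- test_labels[keep]
  if (length(r) == 0) {
    .stop_moha("no participant is classified by both the reference and the test",
               "moha_empty_joint_error")
  }
  cm <- list(tp = sum(r == "sexual" & t == "sexual"),
             fn = sum(r == "sexual" & t == "vertical"),
             fp = sum(r == "vertical" & t == "sexual"),
             tn = sum(r == "vertical" & t == "vertical"))
  cm$n_evaluated <- cm$tp + cm$fn + cm$fp + cm$tn
  structure(cm, class = "moha_confusion")
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values, and the absolute difference between sensitivity and
#' specificity. PPV (NPV) is `NA` when no participant tests positive
#' (negative). Requires both reference classes non-empty.
#'
#' @param cm a `moha_confusion` (or list with `tp`, `fn`, `fp`, `tn`).
#' @return list with `sensitivity`, `specificity`, `abs_difference`, `ppv`,
#'   `npv`, `n_evaluated` (unrounded).
#' @export
diagnostic_metrics <- function(cm) {
  if (cm$tp + cm$fn == 0) {
    .stop_moha("reference sexual (positive) class is empty", "moha_empty_class_error")
  }
  if (cm$tn + cm$fp == 0) {
    .stop_moha("reference vertical (negative) class is empty", "moha_empty_class_error")
  }
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  list(sensitivity = sens,
       specificity = spec,
       abs_difference = abs(sens - spec),
       ppv = if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_,
       npv = if (cm$tn + cm$fn > 0) cm$tn / (cm$tn + cm$fn) else NA_real_,
       n_evaluated = cm$tp + cm$fn + cm$fp + cm$tn)
}

#' Two-point ROC AUC of a single-threshold classifier
#'
#' Trapezoidal area under the ROC polyline through (0,0),
#' (1 - specificity, sensitivity), (1,1) — the ROC of a binary test with one
#' operating point. Algebraically equal to `(sensitivity + specificity) / 2`.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return the AUC (unrounded).
#' @export
#' @examples
#' auc_single_threshold(0.589, 0.815)  # 0.702
auc_single_threshold <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  # trapezoid over x = 1 - specificity: [0, 1-spec] then [1-spec, 1]
  x1 <- 1 - specificity
  x1 * sensitivity / 2 + (1 - x1) * (sensitivity + 1) / 2
}

#' Validate every configured cutoff against the logic-tree reference
#'
#' Builds the per-cutoff confusion matrix over participants classified by
#' both sources, computes the diagnostic metrics and the two-point ROC AUC,
#' and flags the three optimal-cutoff criteria: maximum sensitivity, minimum
#' absolute difference between sensitivity and specificity, and maximum AUC.
#'
#' @param profiles a `moha_profiles` data.frame.
#' @param tree_allocations the matching [allocate_moha()] output.
#' @param config a [tree_config()].
#' @param digits decimal places for the reported metric columns (half-up;
#'   default 3). Internal arithmetic is unrounded.
#' @return data.frame of class `moha_diagnostics` with columns `cutoff`,
#'   `sensitivity`, `specificity`, `abs_difference`, `ppv`, `npv`, `auc`,
#'   `n`, and logical flags `max_sensitivity`, `min_abs_difference`,
#'   `max_auc`. ROC points (x = 1 - specificity, y = sensitivity, unrounded)
#'   are in the `roc_points` attribute.
#' @export
evaluate_cutoffs <- function(profiles, tree_allocations,
                             config = tree_config(), digits = 3) {
  ref <- tree_allocations$label[match(profiles$participant_id,
                                      tree_allocations$participant_id)]
  rows <- lapply(config$cutoff_ages, function(a) {
    test <- allocate_by_cutoff(profiles, a)$label
    cm <- confusion_matrix(ref, test)
    met <- diagnostic_metrics(cm)
    auc <- auc_single_threshold(met$sensitivity, met$specificity)
    data.frame(cutoff = a,
               sensitivity = met$sensitivity, specificity = met$specificity,
               abs_difference = met$abs_difference,
               ppv = met$ppv, npv = met$npv, auc = auc,
               n = met$n_evaluated)
  })
  out <- do.call(rbind, rows)
  roc <- data.frame(cutoff = out$cutoff,
                    fpr = 1 - out$specificity, tpr = out$sensitivity)
  out$max_sensitivity <- out$sensitivity == max(out$sensitivity)
  out$min_abs_difference <- out$abs_difference == min(out$abs_difference)
  out$max_auc <- out$auc == max(out$auc)
  for (col in c("sensitivity", "specificity", "abs_difference",
                "ppv", "npv", "auc")) {
    out[[col]] <- round_half_up(out[[col]], digits)
  }
  rownames(out) <- NULL
  attr(out, "roc_points") <- roc
  class(out) <- c("moha_diagnostics", "data.frame")
  out
}
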