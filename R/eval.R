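# Metrics and uncertainty analysis: confusion matrices, per-class
# sensitivity and average recall, Shannon entropy, ROC curves with policy
# operating points, proportion confidence intervals, paired proportion
# tests and patient-level management summaries.

#' Confusion matrix of diagnoses or actions
#'
#' Rows are ground-truth diagnoses in canonical order; columns are
#' predicted diagnoses or management actions. Proportions are normalized
#' by the row sums.
#'
#' @param truth Character vector of true diagnosis codes.
#' @param called Character vector of predicted diagnoses or actions, same
#'   length.
#' @param col_labels Column vocabulary; defaults to the diagnosis labels
#'   when every call is a diagnosis, otherwise to the management actions
#'   present in canonical action order.
#' @return Object of class `confusion_matrix`: integer `counts` and
#'   `row_normalized` proportion matrix (rows of empty classes are NA).
#' @export
confusion <- function(truth, called, col_labels = NULL) {
  if (length(truth) != length(called)) {
    stop("truth and called must have the same length")
  }
  stopifnot(all(truth %in% diagnosis_labels()))
  if (is.null(col_labels)) {
    col_labels <- if (all(called %in% diagnosis_labels())) {
      diagnosis_labels()
    } else {
      canonical_col_order(unique(called))
    }
  }
  if (!all(called %in% col_labels)) {
    stop("called labels outside the column vocabulary")
  }
  counts <- table(factor(truth, levels = diagnosis_labels()),
                  factor(called, levels = col_labels))
  counts <- matrix(as.integer(counts), nrow = 7,
                   dimnames = list(diagnosis_labels(), col_labels))
  rs <- rowSums(counts)
  norm <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(list(counts = counts, row_normalized = norm),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (row-normalized proportions)\n")
  print(round(x$row_normalized, 3))
  invisible(x)
}

#' Per-class sensitivity and average recall
#'
#' `class_sensitivity` is the row-normalized diagonal proportion of a
#' class: the fraction of its lesions that received the matching
#' prediction (for action matrices, use the action columns directly).
#' `average_recall` is the unweighted mean of per-class sensitivities
#' over nonempty classes -- the balanced "average accuracy" used for
#' imbalanced dermatoscopic test sets.
#'
#' @param cm A [confusion()] result with diagnosis columns.
#' @param c Diagnosis code.
#' @return Proportion in `[0, 1]`.
#' @export
class_sensitivity <- function(cm, c) {
  stopifnot(inherits(cm, "confusion_matrix"), c %in% rownames(cm$counts),
            c %in% colnames(cm$counts))
  if (sum(cm$counts[c, ]) == 0) {
    stop("class ", c, " has no lesions; sensitivity undefined")
  }
  cm$row_normalized[c, c]
}

#' @rdname class_sensitivity
#' @export
average_recall <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!identical(colnames(cm$counts), rownames(cm$counts))) {
    stop("average recall needs a square diagnosis-by-diagnosis matrix")
  }
  d <- diag(cm$row_normalized)
  mean(d[!is.na(d)])
}

#' Plain (overall) accuracy of a confusion matrix
#'
#' @param cm A square [confusion()] result.
#' @return Proportion of lesions on the diagonal.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"),
            identical(colnames(cm$counts), rownames(cm$counts)))
  sum(diag(cm$counts)) / sum(cm$counts)
}

#' Shannon entropy of predictive distributions, in bits
#'
#' `H = -sum_i p_i log2 p_i`, with `0 log 0 = 0`. Maximal (log2 7 for
#' seven classes) at the uniform distribution, 0 for a one-hot
#' prediction; used as a marker of model (un)certainty.
#'
#' @param p Probability vector, matrix with one distribution per row, or
#'   a lesion table.
#' @return Numeric vector of entropies.
#' @export
shannon_entropy <- function(p) {
  P <- as_prob_matrix(if (is.data.frame(p)) prob_matrix(p) else p,
                      tol = 1e-6)
  H <- -rowSums(ifelse(P > 0, P * log2(P), 0))
  unname(H)
}

#' Compare prediction entropies of two models
#'
#' Computes per-lesion Shannon entropies of two sets of predictive
#' distributions and summarizes their medians, quartiles, paired deltas
#' (B minus A) and a two-sided Wilcoxon test (signed-rank when paired).
#'
#' @param pA,pB Distribution matrices or lesion tables (equal length
#'   when paired).
#' @param paired Paired comparison (default TRUE).
#' @return List with `summary` (data.frame of median and quartiles per
#'   model), `delta` summary, `p.value` and the entropy vectors.
#' @export
entropy_comparison <- function(pA, pB, paired = TRUE) {
  hA <- shannon_entropy(pA)
  hB <- shannon_entropy(pB)
  if (paired && length(hA) != length(hB)) {
    stop("paired comparison needs equal numbers of predictions")
  }
  if (length(hA) < 2 || length(hB) < 2) stop("need at least 2 predictions")
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  test <- suppressWarnings(
    stats::wilcox.test(hB, hA, paired = paired, exact = FALSE)
  )
  delta <- if (paired) hB - hA else NULL
  list(summary = data.frame(model = c("A", "B"),
                            q25 = c(qs(hA)[1], qs(hB)[1]),
                            median = c(qs(hA)[2], qs(hB)[2]),
                            q75 = c(qs(hA)[3], qs(hB)[3])),
       delta = if (paired) {
         stats::setNames(qs(delta), c("q25", "median", "q75"))
       },
       p.value = test$p.value,
       entropy_A = hA, entropy_B = hB)
}

#' Empirical ROC curve of malignancy scores
#'
#' Sweeps the cut-off over every observed score (strict `>` calls a
#' positive, matching the threshold policy) plus `-Inf`, so the curve
#' runs from (0, 0) at a cut-off above the maximum to (1, 1) at `-Inf`.
#'
#' @param scores Numeric malignancy probabilities (or any scores).
#' @param truth Logical or 0/1 vector; TRUE = malignant.
#' @return Object of class `roc_points`: data.frame `cutoff`, `fpr`,
#'   `tpr` (sorted by descending cut-off) with an `auc` attribute
#'   (trapezoidal).
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  if (!any(truth) || all(truth)) {
    stop("ROC needs both malignant and benign lesions")
  }
  cuts <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  nP <- sum(truth); nN <- sum(!truth)
  tpr <- vapply(cuts, function(c) sum(scores[truth] > c) / nP, numeric(1))
  fpr <- vapply(cuts, function(c) sum(scores[!truth] > c) / nN, numeric(1))
  df <- data.frame(cutoff = cuts, fpr = fpr, tpr = tpr)
  df <- rbind(data.frame(cutoff = Inf, fpr = 0, tpr = 0), df)
  o <- order(df$fpr, df$tpr)
  auc <- sum(diff(df$fpr[o]) * (utils::head(df$tpr[o], -1) +
                                  utils::tail(df$tpr[o], -1)) / 2)
  structure(df, class = c("roc_points", "data.frame"), auc = auc)
}

#' Operating point of excise decisions
#'
#' TPR is the proportion of malignant lesions excised; FPR the
#' proportion of benign lesions excised.
#'
#' @param decisions Decisions table (from a policy function).
#' @param truth Logical malignancy indicator aligned with `decisions`.
#' @param label Point label (defaults to the policy name).
#' @return One-row data.frame `label`, `fpr`, `tpr`.
#' @export
operating_point <- function(decisions, truth, label = NULL) {
  truth <- as.logical(truth)
  stopifnot(nrow(decisions) == length(truth))
  exc <- decisions$action == "EXCISE"
  data.frame(label = label %||% decisions$policy[1],
             fpr = sum(exc & !truth) / sum(!truth),
             tpr = sum(exc & truth) / sum(truth),
             stringsAsFactors = FALSE)
}

#' ROC curve plus policy operating points
#'
#' @param p_mal Malignancy probabilities of the lesions.
#' @param truth Logical malignancy indicator.
#' @param decisions Named list of decisions tables, one per policy.
#' @return List with `curve` (a [roc_curve()]) and `points` (data.frame
#'   of operating points).
#' @export
roc_and_operating_points <- function(p_mal, truth, decisions = list()) {
  curve <- roc_curve(p_mal, truth)
  pts <- do.call(rbind, lapply(names(decisions), function(nm) {
    operating_point(decisions[[nm]], truth, label = nm)
  }))
  list(curve = curve, points = pts)
}

#' Wilson score interval for a proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `estimate`, `lower`, `upper`.
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(estimate = p, lower = max(0, mid - half), upper = min(1, mid + half))
}

#' Seeded bootstrap confidence interval for a summary statistic
#'
#' Percentile bootstrap for non-proportion summaries (medians, means of
#' rewards, entropy differences, ...). The seed is part of the call so
#' reports can record it.
#'
#' @param x Numeric vector.
#' @param statistic Function mapping a vector to one number.
#' @param n_boot Number of resamples (default 2000).
#' @param level Confidence level.
#' @param seed Integer seed for the resampling.
#' @return Named numeric vector `estimate`, `lower`, `upper`, `seed`.
#' @export
bootstrap_ci <- function(x, statistic = stats::median, n_boot = 2000L,
                         level = 0.95, seed = 1L) {
  stopifnot(length(x) >= 2, n_boot >= 100)
  set.seed(seed)
  est <- statistic(x)
  reps <- vapply(seq_len(n_boot), function(i) {
    statistic(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE)
  c(estimate = est, lower = q[1], upper = q[2], seed = seed)
}

#' McNemar test for paired proportions
#'
#' Continuity-corrected chi-square on the discordant counts; for small
#' discordant totals (`b + c < 25`) the exact binomial test is used
#' instead.
#'
#' @param b,c Discordant pair counts.
#' @return List `method`, `statistic`, `p.value`.
#' @export
paired_proportion_test <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) stop("no discordant pairs; test undefined")
  if (b + c < 25) {
    p <- stats::binom.test(b, b + c, 0.5)$p.value
    list(method = "exact binomial (McNemar)", statistic = NA_real_,
         p.value = p)
  } else {
    stat <- (abs(b - c) - 1)^2 / (b + c)
    list(method = "McNemar chi-square with continuity correction",
         statistic = stat,
         p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
}

#' Patient-level management summaries
#'
#' For the monitoring scenario: per-patient counts of excised benign
#' lesions, the number (and fraction) of patients with more than three
#' excised benign lesions, monitored benign counts, and the distribution
#' of actions over melanomas.
#'
#' @param cohort Cohort lesion table (`patient_id`, `true_label`,
#'   `lesion_id`).
#' @param decisions Decisions table covering every cohort lesion exactly
#'   once.
#' @return List of summaries; `action_counts` conserves the cohort size.
#' @export
patient_metrics <- function(cohort, decisions) {
  stopifnot(is.data.frame(cohort), is.data.frame(decisions))
  m <- match(cohort$lesion_id, decisions$lesion_id)
  if (anyNA(m)) stop("missing decisions for ",
                     sum(is.na(m)), " lesion(s)")
  act <- decisions$action[m]
  benign <- !is_malignant(cohort$true_label)
  mel <- cohort$true_label == "MEL"
  pat <- factor(cohort$patient_id)
  per_patient <- function(x) {
    v <- tapply(x, pat, sum)
    stats::setNames(as.vector(v), names(v))
  }
  excised_benign_by_patient <- per_patient(benign & act == "EXCISE")
  monitored_benign_by_patient <- per_patient(benign & act == "MONITOR")
  mel_actions <- table(factor(act[mel],
                              levels = c("DISMISS", "MONITOR",
                                         "TREAT_LOCALLY", "EXCISE")))
  list(n_patients = nlevels(pat),
       n_lesions = nrow(cohort),
       n_melanomas = sum(mel),
       excised_benign_by_patient = excised_benign_by_patient,
       n_patients_gt3_excised_benign = sum(excised_benign_by_patient > 3),
       monitored_benign_total = sum(benign & act == "MONITOR"),
       monitored_benign_fraction = sum(benign & act == "MONITOR") /
         sum(benign),
       monitored_benign_by_patient = monitored_benign_by_patient,
       melanoma_action_counts = mel_actions,
       melanoma_action_fractions = mel_actions / max(1, sum(mel)),
       action_counts = table(factor(act, levels = unique(act))))
}
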