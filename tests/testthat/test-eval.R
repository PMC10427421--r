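# Confusion matrices, entropy, ROC, proportion statistics, patient
# summaries.

test_that("confusion matrices count and row-normalize correctly", {
  cm <- confusion(c("MEL", "MEL", "NV"), c("MEL", "NV", "NV"))
  expect_identical(cm$counts["MEL", "MEL"], 1L)
  expect_identical(cm$counts["MEL", "NV"], 1L)
  expect_equal(unname(cm$row_normalized["MEL", c("MEL", "NV")]),
               c(0.5, 0.5))
  expect_equal(unname(cm$row_normalized["NV", "NV"]), 1)
  # nonempty rows sum to one
  rs <- rowSums(cm$row_normalized, na.rm = TRUE)
  expect_equal(unname(rs[c("MEL", "NV")]), c(1, 1))
  expect_error(confusion("MEL", c("MEL", "NV")), "same length")
  # perfect prediction gives the identity pattern
  truth <- rep(diagnosis_labels(), 3)
  cmp <- confusion(truth, truth)
  expect_equal(unname(cmp$row_normalized), unname(diag(7)))
})

test_that("sensitivity and average recall behave under imbalance", {
  cm <- confusion(c("MEL", "MEL", "NV"), c("MEL", "NV", "NV"))
  expect_equal(class_sensitivity(cm, "MEL"), 0.5)
  expect_error(class_sensitivity(cm, "DF"), "no lesions")
  # average recall invariant to duplicating a class's members
  set.seed(8)
  truth <- sample(diagnosis_labels(), 300, replace = TRUE)
  called <- ifelse(stats::runif(300) < 0.7, truth,
                   sample(diagnosis_labels(), 300, replace = TRUE))
  ar1 <- average_recall(confusion(truth, called))
  dup <- truth == "NV"
  ar2 <- average_recall(confusion(c(truth, truth[dup]),
                                  c(called, called[dup])))
  expect_equal(ar1, ar2)
})

test_that("shannon entropy has the right endpoints and bounds", {
  expect_equal(shannon_entropy(one_hot("MEL")), 0)
  two <- c(0.5, 0.5, 0, 0, 0, 0, 0)
  expect_equal(shannon_entropy(two), 1)
  expect_equal(shannon_entropy(rep(1 / 7, 7)), log2(7))
  set.seed(5)
  P <- matrix(stats::rexp(700), 100, 7)
  P <- P / rowSums(P)
  H <- shannon_entropy(P)
  expect_true(all(H >= 0 & H <= log2(7)))
  # strictly maximal only at uniform
  expect_true(all(H < log2(7)))
})

test_that("entropy comparison detects a flattened copy", {
  set.seed(6)
  A <- matrix(stats::rexp(200 * 7, rate = 0.2)^3, 200, 7)
  A <- A / rowSums(A)
  B <- A^(1 / 4); B <- B / rowSums(B) # flattened -> higher entropy
  ec <- entropy_comparison(A, B, paired = TRUE)
  expect_lt(ec$p.value, 0.01)
  expect_gt(ec$summary$median[2], ec$summary$median[1])
  expect_gt(ec$delta[["median"]], 0)
  # identical inputs give all-zero deltas
  ec0 <- entropy_comparison(A, A, paired = TRUE)
  expect_equal(unname(ec0$delta), c(0, 0, 0))
  # one-hot vs uniform delta is exactly log2(7)
  OH <- t(replicate(50, one_hot("NV")))
  U <- matrix(1 / 7, 50, 7)
  ecu <- entropy_comparison(OH, U, paired = TRUE)
  expect_equal(unname(ecu$delta[["median"]]), log2(7))
})

test_that("ROC endpoints, monotonicity and null AUC are correct", {
  set.seed(77)
  truth <- stats::runif(2000) < 0.3
  scores <- stats::runif(2000)
  rc <- roc_curve(scores, truth)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$tpr) >= 0))
  expect_true(all(diff(rc$fpr) >= 0))
  expect_lt(abs(attr(rc, "auc") - 0.5), 0.02)
  expect_error(roc_curve(scores, rep(TRUE, 2000)), "both")
})

test_that("ROC AUC agrees with pROC on informative scores", {
  skip_if_not_installed("pROC")
  set.seed(13)
  truth <- c(rep(TRUE, 150), rep(FALSE, 350))
  scores <- ifelse(truth, stats::rnorm(500, 1), stats::rnorm(500))
  rc <- roc_curve(scores, truth)
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
  expect_equal(attr(rc, "auc"), as.numeric(ref), tolerance = 1e-10)
})

test_that("threshold-policy operating points lie exactly on the ROC curve", {
  d <- sample_states(tiny_generator(seed = 17), 600)
  truth <- is_malignant(d$true_label)
  pmal <- malignancy_probability(prob_matrix(d))
  rc <- roc_curve(pmal, truth)
  bin <- scenario_spec("binary")
  for (cut in c(0.05, 0.2, 0.5, 0.8)) {
    ts <- threshold_spec(malignancy_excise = cut)
    dec <- threshold_policy(d, ts, bin, rules = "malignancy_excise")
    op <- operating_point(dec, truth)
    tpr_at <- sum(pmal[truth] > cut) / sum(truth)
    fpr_at <- sum(pmal[!truth] > cut) / sum(!truth)
    expect_identical(op$tpr, tpr_at)
    expect_identical(op$fpr, fpr_at)
    # and that point is on the computed curve
    on_curve <- any(rc$fpr == op$fpr & rc$tpr == op$tpr)
    expect_true(on_curve)
  }
})

test_that("Wilson interval matches prop.test and hits its endpoints", {
  expect_equal(proportion_ci(0, 20)[["lower"]], 0)
  expect_equal(proportion_ci(20, 20)[["upper"]], 1)
  ci <- proportion_ci(50, 100)
  expect_equal(ci[["estimate"]], 0.5)
  expect_equal(ci[["upper"]] - 0.5, 0.5 - ci[["lower"]])
  ref <- stats::prop.test(37, 120, correct = FALSE)$conf.int
  ours <- proportion_ci(37, 120)
  expect_equal(unname(ours[c("lower", "upper")]), as.numeric(ref),
               tolerance = 1e-10)
})

test_that("paired proportion test covers exact and chi-square branches", {
  expect_error(paired_proportion_test(0, 0), "discordant")
  ex <- paired_proportion_test(20, 0)
  expect_lt(ex$p.value, 0.001)
  expect_equal(ex$p.value, 2 * 0.5^20)
  sym <- paired_proportion_test(40, 40)
  expect_gt(sym$p.value, 0.9)
  expect_gte(sym$statistic, 0)
  small <- paired_proportion_test(1, 1)
  expect_identical(small$method, "exact binomial (McNemar)")
})

test_that("patient metrics match a hand tally and conserve lesions", {
  coh <- lesion_table_from_probs(
    rbind(one_hot("MEL"), one_hot("NV"), one_hot("NV"),
          one_hot("NV"), one_hot("BKL")),
    c("MEL", "NV", "NV", "NV", "BKL"),
    patient_id = c("A", "A", "A", "B", "B"))
  dec <- data.frame(lesion_id = coh$lesion_id, policy = "manual",
                    diagnosis_call = NA, action = c("EXCISE", "EXCISE",
                                                    "MONITOR", "DISMISS",
                                                    "EXCISE"))
  pm <- patient_metrics(coh, dec)
  expect_identical(pm$n_patients, 2L)
  expect_equal(unname(pm$excised_benign_by_patient[c("A", "B")]), c(1, 1))
  expect_identical(pm$n_patients_gt3_excised_benign, 0L)
  expect_identical(pm$monitored_benign_total, 1L)
  expect_equal(unname(pm$melanoma_action_counts[["EXCISE"]]), 1)
  expect_equal(sum(pm$action_counts), nrow(coh))
  # all-dismiss policy
  dec0 <- transform(dec, action = "DISMISS")
  pm0 <- patient_metrics(coh, dec0)
  expect_equal(sum(pm0$excised_benign_by_patient), 0)
  expect_equal(unname(pm0$melanoma_action_fractions[["DISMISS"]]), 1)
  # all-excise: every patient's excised-benign = its benign count
  dec1 <- transform(dec, action = "EXCISE")
  pm1 <- patient_metrics(coh, dec1)
  expect_equal(unname(pm1$excised_benign_by_patient[c("A", "B")]), c(2, 2))
  expect_error(patient_metrics(coh, dec[-1, ]), "missing decisions")
})

test_that("bootstrap CI is seeded, covering and ordered", {
  set.seed(10)
  x <- stats::rnorm(400, mean = 3)
  ci1 <- bootstrap_ci(x, statistic = mean, seed = 5)
  ci2 <- bootstrap_ci(x, statistic = mean, seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1[["lower"]], ci1[["estimate"]])
  expect_gt(ci1[["upper"]], ci1[["estimate"]])
  expect_lt(abs(ci1[["estimate"]] - 3), 0.2)
  # a different seed resamples differently but stays close
  ci3 <- bootstrap_ci(x, statistic = mean, seed = 6)
  expect_false(identical(ci1[["lower"]], ci3[["lower"]]))
  expect_lt(abs(ci3[["lower"]] - ci1[["lower"]]), 0.05)
})
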