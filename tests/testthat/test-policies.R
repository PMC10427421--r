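# Naive, threshold-hierarchy and expected-reward policies.

test_that("naive policy picks the top-1 class and its optimal management", {
  bin <- scenario_spec("binary")
  d <- lesion_table_from_probs(rbind(one_hot("MEL", 0.1), one_hot("NV", 0.1)),
                               c("MEL", "NV"))
  dec <- naive_policy(d, bin)
  expect_identical(dec$action, c("EXCISE", "DISMISS"))
  expect_identical(dec$diagnosis_call, c("MEL", "NV"))
  # exact MEL/NV tie resolves to MEL (lower canonical index) -> EXCISE
  tie <- c(0.5, 0, 0, 0, 0.5, 0, 0)
  dtie <- lesion_table_from_probs(tie, "NV")
  expect_identical(naive_policy(dtie, bin)$action, "EXCISE")
})

test_that("threshold hierarchy fires rules in order with strict exceedance", {
  mt <- scenario_spec("multiclass_therapy")
  ts <- threshold_spec(melanoma_excise = 0.25, malignancy_excise = 0.5,
                       bcc_excise = 0.3, akiec_local = 0.2)
  # rule 1
  p1 <- c(0.30, 0, 0, 0, 0.70, 0, 0)
  expect_identical(
    threshold_policy(lesion_table_from_probs(p1, "MEL"), ts, mt)$action,
    "EXCISE")
  # boundary: exactly at the cut-off does NOT fire (strict >)
  p_eq <- c(0.25, 0, 0, 0, 0.75, 0, 0)
  expect_identical(
    threshold_policy(lesion_table_from_probs(p_eq, "MEL"), ts, mt)$action,
    "DISMISS")
  # rule 4 reached when earlier rules fail
  p4 <- c(0.05, 0.04, 0.30, 0.11, 0.50, 0, 0)
  expect_identical(
    threshold_policy(lesion_table_from_probs(p4, "AKIEC"), ts, mt)$action,
    "TREAT_LOCALLY")
  # same probabilities in the binary scenario escalate AKIEC to excision
  expect_identical(
    threshold_policy(lesion_table_from_probs(p4, "AKIEC"), ts,
                     scenario_spec("binary"))$action,
    "EXCISE")
  # fallback
  p0 <- c(0.01, 0.01, 0.01, 0.3, 0.67, 0, 0)
  expect_identical(
    threshold_policy(lesion_table_from_probs(p0, "NV"), ts, mt)$action,
    "DISMISS")
})

test_that("monitor rule applies only in the patient scenario", {
  ts <- threshold_spec(melanoma_excise = 0.4, malignancy_excise = 0.5,
                       monitor = 0.1)
  p <- c(0.15, 0.02, 0.02, 0.2, 0.61, 0, 0)
  d <- lesion_table_from_probs(p, "NV")
  expect_identical(
    threshold_policy(d, ts, scenario_spec("patient_centered"))$action,
    "MONITOR")
  expect_identical(
    threshold_policy(d, ts, scenario_spec("binary"))$action,
    "DISMISS")
})

test_that("threshold configuration errors are raised", {
  ts <- threshold_spec(melanoma_excise = 0.2)
  d <- lesion_table_from_probs(one_hot("NV", 0.2), "NV")
  expect_error(threshold_policy(d, ts, scenario_spec("binary"),
                                rules = c("melanoma_excise", "bcc_excise")),
               "configuration error")
  all_na <- threshold_spec()
  expect_error(threshold_policy(d, all_na, scenario_spec("binary")),
               "configuration error")
})

test_that("bayes policy maximizes expected reward with safety tie-breaks", {
  rt <- reward_table(rbind(MEL = c(-6, 4), NV = c(1, -1)),
                     row_labels = c("MEL", "NV"),
                     col_labels = c("DISMISS", "EXCISE"))
  # embed into full 7-row table (other rows neutral)
  full <- matrix(0, 7, 2, dimnames = list(diagnosis_labels(),
                                          c("DISMISS", "EXCISE")))
  full["MEL", ] <- c(-6, 4); full["NV", ] <- c(1, -1)
  rt <- reward_table(full, col_labels = c("DISMISS", "EXCISE"))
  p <- c(0.6, 0, 0, 0, 0.4, 0, 0)
  d <- lesion_table_from_probs(p, "MEL")
  dec <- bayes_policy(d, rt)
  # E[EXCISE] = .6*4 - .4 = 2.0 ; E[DISMISS] = -.6*6 + .4 = -3.2
  expect_identical(dec$action, "EXCISE")
  expect_equal(dec$auxiliary, 2.0)
  # one-hot NV with identity-style rewards dismisses
  id <- matrix(0, 7, 2, dimnames = list(diagnosis_labels(),
                                        c("DISMISS", "EXCISE")))
  id[, "DISMISS"] <- ifelse(is_malignant(diagnosis_labels()), -1, 1)
  id[, "EXCISE"] <- ifelse(is_malignant(diagnosis_labels()), 1, -1)
  rt_id <- reward_table(id, col_labels = c("DISMISS", "EXCISE"))
  expect_identical(
    bayes_policy(lesion_table_from_probs(one_hot("NV"), "NV"), rt_id)$action,
    "DISMISS")
  # cell-wise dominance forces the dominating action for any p
  dom <- reward_table(cbind(DISMISS = rep(0, 7), EXCISE = rep(1, 7)),
                      col_labels = c("DISMISS", "EXCISE"))
  set.seed(1)
  for (i in 1:20) {
    p <- stats::runif(7); p <- p / sum(p)
    expect_identical(bayes_policy(lesion_table_from_probs(p, "NV"),
                                  dom)$action, "EXCISE")
  }
  # exact tie between actions resolves to the safer (EXCISE)
  tie <- reward_table(matrix(1, 7, 2,
                             dimnames = list(diagnosis_labels(),
                                             c("DISMISS", "EXCISE"))),
                      col_labels = c("DISMISS", "EXCISE"))
  expect_identical(bayes_policy(lesion_table_from_probs(rep(1 / 7, 7), "NV"),
                                tie)$action, "EXCISE")
})

test_that("binary reward threshold matches the closed form", {
  r2 <- rbind(MALIGNANT = c(DISMISS = -1, EXCISE = 1),
              BENIGN = c(DISMISS = 1, EXCISE = -1))
  expect_equal(binary_reward_threshold(r2), 0.5)
  r3 <- rbind(MALIGNANT = c(DISMISS = -6, EXCISE = 4),
              BENIGN = c(DISMISS = 1, EXCISE = -1))
  expect_equal(binary_reward_threshold(r3), 2 / 12)
  # doubling the missed-malignancy penalty lowers the cut-off
  r4 <- r3; r4["MALIGNANT", "DISMISS"] <- -12
  expect_lt(binary_reward_threshold(r4), binary_reward_threshold(r3))
  # degenerate: excision never preferable
  r5 <- rbind(MALIGNANT = c(DISMISS = 1, EXCISE = 0),
              BENIGN = c(DISMISS = 1, EXCISE = 2))
  expect_error(binary_reward_threshold(r5), "degenerate")
})

test_that("bayes switch point equals the closed-form threshold", {
  # property: over random 2x2 tables, the probability at which the
  # expected-reward policy switches to excision equals the closed form
  set.seed(99)
  mk_lesion <- function(pmal) {
    lesion_table_from_probs(c(pmal, 0, 0, 0, 1 - pmal, 0, 0), "NV")
  }
  for (i in 1:200) {
    vals <- matrix(0, 7, 2, dimnames = list(diagnosis_labels(),
                                            c("DISMISS", "EXCISE")))
    mal_exc <- stats::runif(1, 0.5, 6); mal_dis <- stats::runif(1, -6, -0.5)
    ben_dis <- stats::runif(1, 0.5, 3); ben_exc <- stats::runif(1, -4, -0.1)
    vals[is_malignant(diagnosis_labels()), ] <-
      rep(c(mal_dis, mal_exc), each = 3)
    vals[!is_malignant(diagnosis_labels()), ] <-
      rep(c(ben_dis, ben_exc), each = 4)
    rt <- reward_table(vals, col_labels = c("DISMISS", "EXCISE"))
    pstar <- binary_reward_threshold(collapse_reward_table(rt))
    # bisection on the implementation's decision boundary
    lo <- 0; hi <- 1
    for (b in 1:40) {
      mid <- (lo + hi) / 2
      if (bayes_policy(mk_lesion(mid), rt)$action == "EXCISE") hi <- mid
      else lo <- mid
    }
    expect_lt(abs(hi - pstar), 1e-9)
  }
})

test_that("naive equals bayes under 0/1 diagnosis rewards + optimal map", {
  rt01 <- reward_table(diag(7), col_labels = diagnosis_labels())
  d <- sample_states(tiny_generator(seed = 31), 300)
  mt <- scenario_spec("multiclass_therapy")
  nv <- naive_policy(d, mt)
  by <- bayes_policy(d, rt01)
  expect_identical(optimal_management(by$action, mt), nv$action)
})
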