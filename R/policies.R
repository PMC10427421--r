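# Baseline and oracle decision policies: naive top-1, the
# preference-based threshold hierarchy, and the analytic expected-reward
# (Bayes) policy used as the oracle for the reinforcement-learning model
# on calibrated data.

decision_frame <- function(records, policy_name, action,
                           diagnosis_call = NA_character_,
                           auxiliary = NA_real_) {
  data.frame(lesion_id = records$lesion_id,
             policy = policy_name,
             diagnosis_call = diagnosis_call,
             action = action,
             auxiliary = auxiliary,
             stringsAsFactors = FALSE)
}

#' Naive top-1 policy
#'
#' Chooses the optimal management strategy for the top-1 class prediction
#' of the classifier: the called diagnosis is the probability argmax
#' (ties toward the lower canonical class index) and the action is
#' [optimal_management()] of that call. In the diagnosisRL scenario the
#' action is the diagnosis call itself.
#'
#' @param records Lesion table (or probability matrix/vector).
#' @param scenario A [scenario_spec()].
#' @return Decisions table: `lesion_id`, `policy`, `diagnosis_call`,
#'   `action`, `auxiliary` (the winning probability).
#' @export
naive_policy <- function(records, scenario) {
  P <- as_prob_matrix(if (is.data.frame(records)) prob_matrix(records)
                      else records)
  if (!is.data.frame(records)) {
    records <- data.frame(lesion_id = sprintf("row%d", seq_len(nrow(P))))
  }
  j <- max.col(P, ties.method = "first")
  call <- diagnosis_labels()[j]
  action <- if (scenario$name == "diagnosisRL") call
            else optimal_management(call, scenario)
  decision_frame(records, "naive", action, diagnosis_call = call,
                 auxiliary = P[cbind(seq_len(nrow(P)), j)])
}

#' Preference-based threshold hierarchy policy
#'
#' Rules are evaluated in fixed order with strict `>` comparisons
#' ("exceeds"):
#' \enumerate{
#'   \item melanoma probability > `melanoma_excise` -> EXCISE
#'   \item overall malignancy probability > `malignancy_excise` -> EXCISE
#'   \item BCC probability > `bcc_excise` -> EXCISE
#'   \item AKIEC probability > `akiec_local` -> TREAT_LOCALLY when the
#'     scenario offers it, otherwise EXCISE
#'   \item (patient-centered only) malignancy probability > `monitor`
#'     -> MONITOR
#' }
#' Otherwise the fallback action (DISMISS by default). A cut-off left
#' `NA` in the [threshold_spec()] disables its rule; requesting a rule
#' whose cut-off is undefined via `rules` is a configuration error, and
#' so is a spec in which every rule is disabled.
#'
#' @param records Lesion table (or probability matrix).
#' @param thresholds A [threshold_spec()].
#' @param scenario A [scenario_spec()] with a management action set.
#' @param rules Optional character vector naming the rules to apply
#'   (default: all rules whose cut-off is defined).
#' @return Decisions table; `auxiliary` is the probability consulted at
#'   the decisive rule.
#' @export
threshold_policy <- function(records, thresholds, scenario, rules = NULL) {
  stopifnot(inherits(thresholds, "threshold_spec"),
            inherits(scenario, "scenario_spec"))
  if (scenario$name == "diagnosisRL") {
    stop("the threshold policy produces management actions, not diagnoses")
  }
  P <- as_prob_matrix(if (is.data.frame(records)) prob_matrix(records)
                      else records)
  if (!is.data.frame(records)) {
    records <- data.frame(lesion_id = sprintf("row%d", seq_len(nrow(P))))
  }
  pmal <- malignancy_probability(P)
  all_rules <- c("melanoma_excise", "malignancy_excise", "bcc_excise",
                 "akiec_local", "monitor")
  if (!(scenario$name == "patient_centered")) {
    all_rules <- setdiff(all_rules, "monitor")
  }
  if (is.null(rules)) {
    rules <- all_rules[vapply(all_rules,
                              function(f) !is.na(thresholds[[f]]),
                              logical(1))]
  } else {
    bad <- setdiff(rules, all_rules)
    if (length(bad) > 0) stop("unknown rule(s): ", paste(bad, collapse = ", "))
    undef <- rules[vapply(rules, function(f) is.na(thresholds[[f]]),
                          logical(1))]
    if (length(undef) > 0) {
      stop("configuration error: no cut-off defined for consulted rule(s): ",
           paste(undef, collapse = ", "))
    }
    rules <- all_rules[all_rules %in% rules]
  }
  if (length(rules) == 0) {
    stop("configuration error: every threshold rule is disabled")
  }
  akiec_action <- if ("TREAT_LOCALLY" %in% scenario$action_set)
    "TREAT_LOCALLY" else "EXCISE"
  n <- nrow(P)
  action <- rep(thresholds$fallback_action, n)
  aux <- rep(NA_real_, n)
  undecided <- rep(TRUE, n)
  apply_rule <- function(prob, cut, act) {
    hit <- undecided & (prob > cut)
    action[hit] <<- act
    aux[hit] <<- prob[hit]
    undecided[hit] <<- FALSE
  }
  for (rule in rules) {
    switch(rule,
      melanoma_excise  = apply_rule(P[, "MEL"], thresholds$melanoma_excise,
                                    "EXCISE"),
      malignancy_excise = apply_rule(pmal, thresholds$malignancy_excise,
                                     "EXCISE"),
      bcc_excise       = apply_rule(P[, "BCC"], thresholds$bcc_excise,
                                    "EXCISE"),
      akiec_local      = apply_rule(P[, "AKIEC"], thresholds$akiec_local,
                                    akiec_action),
      monitor          = apply_rule(pmal, thresholds$monitor, "MONITOR")
    )
  }
  if (!all(action %in% scenario$action_set)) {
    stop("threshold policy produced an action outside the scenario action set")
  }
  decision_frame(records, "threshold", action, auxiliary = aux)
}

#' Analytic expected-reward (Bayes) policy
#'
#' Chooses the action maximizing the expected reward
#' `sum_d p[d] * rewards[d, a]` under the predictive class distribution.
#' On calibrated probabilities this is the Bayes-optimal decision rule
#' and serves as the oracle against which a converged Q-policy is
#' checked. Ties are broken toward the higher safety rank (management
#' tables) or the lower canonical class index (diagnosis tables).
#'
#' @param records Lesion table (or probability matrix/vector).
#' @param rewards A [reward_table()] with action (or diagnosis) columns.
#' @return Decisions table; `auxiliary` is the maximal expected reward.
#' @export
bayes_policy <- function(records, rewards) {
  stopifnot(inherits(rewards, "reward_table"))
  P <- as_prob_matrix(if (is.data.frame(records)) prob_matrix(records)
                      else records)
  if (!is.data.frame(records)) {
    records <- data.frame(lesion_id = sprintf("row%d", seq_len(nrow(P))))
  }
  R <- rewards$values[diagnosis_labels(), , drop = FALSE]
  ER <- P %*% R
  actions <- colnames(R)
  act <- argmax_actions(ER, actions)
  decision_frame(records, "bayes", act,
                 auxiliary = apply(ER, 1, max))
}

#' Collapse a 7-row two-action reward table to benign/malignant rows
#'
#' Rows are averaged within the malignant (MEL, BCC, AKIEC) and benign
#' groups, weighted by class priors renormalized within each group.
#'
#' @param rewards A [reward_table()] with columns DISMISS, EXCISE.
#' @param class_priors Probability vector over the 7 classes used as
#'   collapse weights (default uniform).
#' @return 2 x 2 numeric matrix with rows `MALIGNANT`, `BENIGN`.
#' @export
collapse_reward_table <- function(rewards, class_priors = rep(1 / 7, 7)) {
  stopifnot(inherits(rewards, "reward_table"),
            setequal(reward_cols(rewards), c("DISMISS", "EXCISE")))
  R <- rewards$values[diagnosis_labels(), c("DISMISS", "EXCISE")]
  w <- class_priors / sum(class_priors)
  mal <- is_malignant(diagnosis_labels())
  rbind(MALIGNANT = colSums(R[mal, , drop = FALSE] * w[mal]) / sum(w[mal]),
        BENIGN = colSums(R[!mal, , drop = FALSE] * w[!mal]) / sum(w[!mal]))
}

#' Closed-form excision cut-off of a binary reward table
#'
#' For a two-row (malignant/benign), two-action (DISMISS/EXCISE) reward
#' table, the expected-reward policy excises exactly when the malignancy
#' probability reaches
#' `p* = (R[ben,DIS] - R[ben,EXC]) /
#'       (R[mal,EXC] - R[mal,DIS] + R[ben,DIS] - R[ben,EXC])`.
#'
#' @param rewards2 2 x 2 numeric matrix with rows `MALIGNANT`, `BENIGN`
#'   and columns `DISMISS`, `EXCISE` (e.g. from
#'   [collapse_reward_table()]).
#' @return The switch probability `p*`.
#' @export
binary_reward_threshold <- function(rewards2) {
  rewards2 <- as.matrix(rewards2)
  stopifnot(setequal(rownames(rewards2), c("MALIGNANT", "BENIGN")),
            setequal(colnames(rewards2), c("DISMISS", "EXCISE")))
  num <- rewards2["BENIGN", "DISMISS"] - rewards2["BENIGN", "EXCISE"]
  den <- rewards2["MALIGNANT", "EXCISE"] - rewards2["MALIGNANT", "DISMISS"] +
    num
  if (den <= 0) {
    stop("degenerate reward table: expected rewards never cross ",
         "(denominator <= 0)")
  }
  num / den
}

#' Run a set of policies over a lesion table
#'
#' Convenience batch runner producing one tidy decisions table for any
#' mix of naive, threshold, Bayes and trained RL policies.
#'
#' @param records Lesion table.
#' @param scenario A [scenario_spec()].
#' @param thresholds Optional [threshold_spec()] (adds the threshold
#'   policy).
#' @param rewards Optional [reward_table()] with action columns (adds the
#'   Bayes policy).
#' @param rl Optional [train_q()] policy (adds its greedy decisions as
#'   policy `"rl"`).
#' @return Decisions table with one row per lesion and policy.
#' @export
run_policy_batch <- function(records, scenario, thresholds = NULL,
                             rewards = NULL, rl = NULL) {
  out <- list(naive_policy(records, scenario))
  if (!is.null(thresholds)) {
    out <- c(out, list(threshold_policy(records, thresholds, scenario)))
  }
  if (!is.null(rewards)) {
    out <- c(out, list(bayes_policy(records, rewards)))
  }
  if (!is.null(rl)) {
    act <- greedy_action(rl, records)
    out <- c(out, list(decision_frame(records, "rl", act)))
  }
  do.call(rbind, out)
}
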