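# Trained policies shared across acceptance tests (training is the
# expensive step; identical conditions are trained once per session).

.policy_cache <- new.env(parent = emptyenv())

acceptance_generator <- function() generator_config()

cached_policy <- function(rewards, seed = 101L, n_train = 10000L,
                          key = NULL, cfg = NULL) {
  key <- key %||% paste0(rewards$provenance, "|", seed, "|", n_train)
  if (is.null(.policy_cache[[key]])) {
    train <- sample_states(acceptance_generator(), n_train,
                           seed = 1000L + seed)
    cfg <- cfg %||% train_config(seed = seed)
    .policy_cache[[key]] <- train_q(train, rewards,
                                    scenario_spec("diagnosisRL"), cfg)
  }
  .policy_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The three diagnosis reward tables used in the oracle-equivalence
# checks: symmetric, melanoma-asymmetric (the packaged consensus table)
# and one action dominating cell-wise.
symmetric_reward_table <- function() {
  reward_table(2 * diag(7) - 1, col_labels = diagnosis_labels(),
               provenance = "symmetric +1/-1")
}

dominance_reward_table <- function() {
  vals <- matrix(0, 7, 7)
  vals[, 1] <- 1
  reward_table(vals, col_labels = diagnosis_labels(),
               provenance = "MEL-dominant")
}

identity_reward_table <- function() {
  reward_table(diag(7), col_labels = diagnosis_labels(),
               provenance = "0/1 identity")
}
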