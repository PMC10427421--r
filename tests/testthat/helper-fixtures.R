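# Shared fixtures: tiny generator configs and hand-built lesion tables.

tiny_generator <- function(seed = 1L, ...) {
  generator_config(feature_dim = 8, seed = seed, ...)
}

# A lesion table built directly from given probability rows (features and
# logits synthesized consistently: logits = log(p), features zero-padded).
lesion_table_from_probs <- function(P, true_label, patient_id = NA_character_,
                                    feature_dim = 8) {
  P <- matrix(P, ncol = 7)
  n <- nrow(P)
  logits <- log(pmax(P, 1e-12))
  feats <- matrix(0, n, feature_dim)
  colnames(feats) <- sprintf("f_%d", seq_len(feature_dim))
  colnames(P) <- paste0("p_", diagnosis_labels())
  colnames(logits) <- paste0("logit_", diagnosis_labels())
  data.frame(lesion_id = sprintf("T%04d", seq_len(n)),
             patient_id = patient_id,
             true_label = true_label,
             P, logits, feats,
             stringsAsFactors = FALSE, check.names = FALSE)
}

one_hot <- function(label, eps = 0) {
  p <- rep(eps / 6, 7)
  p[match(label, diagnosis_labels())] <- 1 - eps
  p
}

expect_simplex <- function(P, tol = 1e-8) {
  P <- matrix(P, ncol = 7)
  expect_true(all(P >= -tol))
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
}
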