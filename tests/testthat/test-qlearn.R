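# State construction, episode ordering, replay buffer, network mechanics
# and policy querying. Full-convergence checks live in test-acceptance.R.

test_that("lesion states concatenate features, logits and probabilities", {
  d <- sample_states(tiny_generator(seed = 1), 10)
  S <- build_state(d, "lesion")
  expect_identical(ncol(S), 8L + 7L + 7L)
  expect_equal(unname(S[, 1:8]), unname(feature_matrix(d)))
  expect_equal(unname(S[, 9:15]), unname(logit_matrix(d)))
  expect_equal(unname(S[, 16:22]), unname(prob_matrix(d)))
})

test_that("patient normalization divides by the per-position patient mean", {
  d <- sample_states(tiny_generator(seed = 2), 4)
  d$patient_id <- "P1"
  # identical lesions -> all-ones
  d_same <- d[rep(1, 3), ]; d_same$lesion_id <- paste0("L", 1:3)
  S <- build_state(d_same, "patient_normalized")
  expect_equal(unname(S), matrix(1, 3, ncol(S)), ignore_attr = "block_dims")
  # single lesion patient -> all ones
  S1 <- build_state(d[1, ], "patient_normalized")
  expect_equal(unname(S1), matrix(1, 1, ncol(S1)),
               ignore_attr = "block_dims")
  # two lesions with a position at 2 and 4 -> 2/3 and 4/3
  d2 <- d[1:2, ]
  d2$f_1 <- c(2, 4)
  S2 <- build_state(d2, "patient_normalized")
  expect_equal(unname(S2[, 1]), c(2 / 3, 4 / 3))
  # explicit context overrides grouping
  S3 <- build_state(d2[1, ], "patient_normalized", patient_context = d2)
  expect_equal(unname(S3[, 1]), 2 / 3)
  # near-zero mean positions are left unscaled
  d3 <- d[1:2, ]
  d3$f_2 <- c(1e-12, -1e-12)
  S4 <- build_state(d3, "patient_normalized")
  expect_equal(unname(S4[, 2]), c(1e-12, -1e-12))
})

test_that("episode ordering sorts by malignancy probability, stably", {
  p <- rbind(c(0.1, 0, 0, 0, 0.9, 0, 0),
             c(0.9, 0, 0, 0, 0.1, 0, 0),
             c(0.5, 0, 0, 0, 0.5, 0, 0))
  d <- lesion_table_from_probs(p, c("NV", "MEL", "NV"))
  expect_identical(order_episode(d)$lesion_id, d$lesion_id[c(2, 3, 1)])
  # ties preserve input order
  dt <- lesion_table_from_probs(p[c(3, 3, 3), ], rep("NV", 3))
  expect_identical(order_episode(dt)$lesion_id, dt$lesion_id)
  expect_identical(nrow(order_episode(d[2, ])), 1L)
})

test_that("replay buffer is a bounded FIFO", {
  buf <- replay_buffer(5)
  for (i in 1:8) buffer_push(buf, i, 1L, i / 10, i + 1L, FALSE)
  expect_identical(buffer_size(buf), 5L)
  tr <- buffer_transitions(buf)
  # after capacity + 3 insertions the first 3 transitions are gone
  expect_identical(tr$state, 4:8)
  expect_false(any(1:3 %in% tr$state))
  # sampling returns stored transitions
  s <- buffer_sample(buf, 3)
  expect_true(all(s$state %in% 4:8))
  expect_identical(nrow(s), 3L)
})

test_that("all-zero rewards yield zero training reward throughout", {
  d <- sample_states(tiny_generator(seed = 3), 150)
  rt0 <- reward_table(matrix(0, 7, 7), col_labels = diagnosis_labels())
  cfg <- train_config(max_steps = 1200L, eval_period = 300L, seed = 4)
  pol <- train_q(d, rt0, scenario_spec("diagnosisRL"), cfg)
  expect_true(all(pol$history$mean_valid_reward == 0))
})

test_that("training is deterministic given data, config and seed", {
  d <- sample_states(tiny_generator(seed = 5), 200)
  rt <- default_reward_table("binary")
  cfg <- train_config(max_steps = 1500L, eval_period = 500L, seed = 11)
  p1 <- train_q(d, rt, scenario_spec("binary"), cfg)
  p2 <- train_q(d, rt, scenario_spec("binary"), cfg)
  expect_identical(p1$par, p2$par)
  expect_identical(p1$history, p2$history)
})

test_that("reward-table / scenario mismatch is caught before training", {
  d <- sample_states(tiny_generator(seed = 5), 50)
  rt <- default_reward_table("patient_centered")
  expect_error(train_q(d, rt, scenario_spec("binary"), train_config()),
               "do not match")
})

test_that("q_values and greedy_action have the right shape and rules", {
  d <- sample_states(tiny_generator(seed = 6), 120)
  rt <- default_reward_table("binary")
  cfg <- train_config(max_steps = 2000L, eval_period = 500L, seed = 2)
  pol <- train_q(d, rt, scenario_spec("binary"), cfg)
  Q <- q_values(pol, d[1:5, ])
  expect_identical(dim(Q), c(5L, 2L))
  expect_identical(colnames(Q), c("DISMISS", "EXCISE"))
  expect_true(all(is.finite(Q)))
  # inference is deterministic: duplicate states give identical rows
  Q2 <- q_values(pol, d[c(1, 1), ])
  expect_identical(Q2[1, ], Q2[2, ])
  act <- greedy_action(pol, d[1:5, ])
  expect_identical(unname(act),
                   unname(colnames(Q)[max.col(Q, ties.method = "last")]))
  # dimension mismatch is rejected
  d12 <- sample_states(generator_config(feature_dim = 12, seed = 1), 3)
  expect_error(q_values(pol, d12), "dimension mismatch")
})

test_that("argmax tie-breaking favors safety rank or canonical index", {
  # direct unit check of the tie-break helper on constructed Q rows
  Q <- rbind(c(0.5, 0.5), c(0.2, 0.9))
  expect_identical(dermpolicy:::argmax_actions(Q, c("DISMISS", "EXCISE")),
                   c("EXCISE", "EXCISE"))
  Q7 <- matrix(0, 1, 7)
  expect_identical(dermpolicy:::argmax_actions(Q7, diagnosis_labels()),
                   "MEL")
  Q3 <- matrix(c(1, 1, 1), 1, 3)
  expect_identical(
    dermpolicy:::argmax_actions(Q3, c("DISMISS", "MONITOR", "EXCISE")),
    "EXCISE")
})

test_that("predictive distribution is a softmax over diagnosis Q-values", {
  d <- sample_states(tiny_generator(seed = 7), 150)
  rt <- default_reward_table("diagnosisRL")
  cfg <- train_config(max_steps = 1500L, eval_period = 500L, seed = 3)
  pol <- train_q(d, rt, scenario_spec("diagnosisRL"), cfg)
  P <- predictive_distribution(pol, d[1:10, ])
  expect_simplex(P)
  Q <- q_values(pol, d[1:10, ])
  expect_equal(P, exp(Q - apply(Q, 1, max)) /
                 rowSums(exp(Q - apply(Q, 1, max))))
  # management policies refuse
  polb <- train_q(d, default_reward_table("binary"),
                  scenario_spec("binary"),
                  train_config(max_steps = 800L, eval_period = 400L,
                               seed = 3))
  expect_error(predictive_distribution(polb, d[1, ]), "diagnosisRL")
})

test_that("policies survive a serialization round-trip", {
  d <- sample_states(tiny_generator(seed = 8), 120)
  rt <- default_reward_table("binary")
  pol <- train_q(d, rt, scenario_spec("binary"),
                 train_config(max_steps = 1000L, eval_period = 500L,
                              seed = 9))
  f <- tempfile(fileext = ".json")
  write_policy(pol, f)
  back <- read_policy(f)
  expect_equal(back$par, pol$par, tolerance = 0)
  expect_identical(q_values(back, d[1:4, ]), q_values(pol, d[1:4, ]))
  # tampered class order is refused
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$class_order <- rev(obj$class_order)
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  expect_error(read_policy(f), "class order")
  unlink(f)
})

test_that("patient episodes: return at gamma 0 equals summed lesion rewards", {
  cc <- cohort_config(composition = "stochastic", n_patients = 8,
                      melanoma_rate = 0.1, generator = tiny_generator(),
                      seed = 12)
  coh <- sample_cohort(cc)
  rt <- default_reward_table("patient_centered")
  R <- rt$values
  # for any per-lesion action assignment, the episode return under gamma=0
  # is additive in per-lesion rewards
  set.seed(1)
  for (pid in unique(coh$patient_id)[1:3]) {
    lesions <- coh[coh$patient_id == pid, ]
    acts <- sample(colnames(R), nrow(lesions), replace = TRUE)
    ret <- sum(R[cbind(lesions$true_label, acts)])
    expect_equal(ret, sum(vapply(seq_len(nrow(lesions)), function(i) {
      R[lesions$true_label[i], acts[i]]
    }, numeric(1))))
  }
})

test_that("target network equals the online network exactly at sync steps", {
  # instrumented miniature of the training loop
  spec <- qnetwork_spec(4, 2, n_linear = 2, width = 8, dropout = 0)
  set.seed(1)
  par <- dermpolicy:::qnet_init(spec)
  target <- par
  adam <- dermpolicy:::adam_init(par)
  sync <- 10L
  mism <- 0L
  for (step in 1:40) {
    Xf <- matrix(stats::rnorm(8), 2, 4)
    Xl <- matrix(stats::rnorm(4), 2, 2)
    upd <- dermpolicy:::qnet_update(par, adam, Xf, Xl, c(1L, 2L),
                                    c(0.3, -0.2), spec, 1, 0.01)
    par <- upd$par; adam <- upd$adam
    if (step %% sync == 0) {
      target <- par
      expect_identical(target, par)
    } else if (!identical(target, par)) {
      mism <- mism + 1L
    }
  }
  # the target differs from the online network between syncs
  expect_gt(mism, 30)
})

test_that("raising the melanoma-miss penalty does not hurt melanoma
           sensitivity (one-sided, across seeds)", {
  # property-style check at reduced problem size: train twice per seed,
  # with a mild and a severe penalty for calling a true melanoma benign
  mk_table <- function(penalty) {
    vals <- 2 * diag(7) - 1
    vals[1, 4:7] <- penalty
    reward_table(vals, col_labels = diagnosis_labels(),
                 provenance = sprintf("mel penalty %g", penalty))
  }
  cfg <- generator_config()
  tol <- 0.02 # one-sided tolerance for training noise
  for (seed in 1:3) {
    train <- sample_states(cfg, 3000, seed = 500 + seed)
    test <- sample_states(cfg, 1500, seed = 600 + seed)
    sens <- vapply(c(-1, -8), function(pen) {
      pol <- train_q(train, mk_table(pen), scenario_spec("diagnosisRL"),
                     train_config(seed = seed, max_steps = 30000L,
                                  eval_period = 3000L))
      cm <- confusion(test$true_label, greedy_action(pol, test))
      class_sensitivity(cm, "MEL")
    }, numeric(1))
    expect_gte(sens[2], sens[1] - tol)
  }
})
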