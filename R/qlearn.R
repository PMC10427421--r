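# Deep Q-learning core: state construction, patient-centered
# normalization and episode assembly, replay-buffer training with a
# target network, and policy querying.
#
# The Q-network is a small multilayer perceptron: a 256-unit fully
# connected layer with ReLU activation processes the feature vector, its
# output is concatenated with the classifier logits and probabilities,
# and a linear output layer maps the concatenation to one Q-value per
# action. Training
# follows the standard deep Q-learning recipe: epsilon-greedy
# exploration, a FIFO replay buffer, a target network synchronized at a
# lower rate, Huber loss on the temporal-difference residual, and Adam
# updates. All of it is implemented here in plain matrix algebra so the
# learned Q-function is fully inspectable.

# -- state construction -------------------------------------------------

state_block_dims <- function(records) {
  F <- ncol(feature_matrix(records))
  c(features = F, logits = 7L, probabilities = 7L)
}

#' Build RL state vectors from classifier outputs
#'
#' The state of a lesion is the concatenation of its classifier feature
#' vector, logits and class probabilities (in that order). In
#' `patient_normalized` mode -- used by the patient-centered monitoring
#' scenario -- each position of the lesion state vector is divided by the
#' mean of that position across all lesion vectors of the same patient,
#' so a lesion is represented relative to its patient's other lesions
#' ("ugly duckling" context). Positions whose cross-lesion mean magnitude
#' is below `1e-8` are left unscaled.
#'
#' @param records Lesion table (one or more rows).
#' @param mode `"lesion"` or `"patient_normalized"`.
#' @param patient_context Optional lesion table providing the patient
#'   context in `patient_normalized` mode; when omitted, rows are grouped
#'   by their `patient_id` column.
#' @return Numeric matrix, one row per lesion, with attribute
#'   `"block_dims"` recording the feature/logit/probability widths.
#' @export
build_state <- function(records, mode = c("lesion", "patient_normalized"),
                        patient_context = NULL) {
  mode <- match.arg(mode)
  S <- cbind(feature_matrix(records), logit_matrix(records),
             prob_matrix(records))
  if (mode == "patient_normalized") {
    if (!is.null(patient_context)) {
      C <- cbind(feature_matrix(patient_context),
                 logit_matrix(patient_context),
                 prob_matrix(patient_context))
      if (ncol(C) != ncol(S)) {
        stop("patient context dimensions do not match the lesion state")
      }
      S <- normalize_by_mean(S, colMeans(C))
    } else {
      if (!("patient_id" %in% names(records)) || anyNA(records$patient_id)) {
        stop("patient_normalized mode needs patient_context or patient_id")
      }
      for (idx in split(seq_len(nrow(S)), records$patient_id)) {
        S[idx, ] <- normalize_by_mean(S[idx, , drop = FALSE],
                                      colMeans(S[idx, , drop = FALSE]))
      }
    }
  }
  attr(S, "block_dims") <- state_block_dims(records)
  S
}

# Positions with near-zero patient means are left unscaled, and the
# normalized values are clipped to a bounded range: rare-class
# probability positions can have per-patient means orders of magnitude
# below a single suspicious lesion's value, and the raw ratio would
# dwarf every other state position (and blow up the training loss)
# while carrying no more information than "far above the patient mean".
normalize_by_mean <- function(M, m, guard = 1e-8, clip = 20) {
  d <- ifelse(abs(m) < guard, 1, m)
  pmin(pmax(sweep(M, 2, d, `/`), -clip), clip)
}

#' Order lesions within a patient episode
#'
#' Lesions are sorted by overall malignancy probability, most suspicious
#' first; ties preserve the input order.
#'
#' @param records Lesion table (nonempty).
#' @return The reordered lesion table.
#' @export
order_episode <- function(records) {
  stopifnot(nrow(records) >= 1)
  mp <- malignancy_probability(prob_matrix(records))
  records[order(-mp), , drop = FALSE]
}

# -- replay buffer ------------------------------------------------------

#' FIFO replay buffer
#'
#' Bounded first-in-first-out store of transitions
#' `(state, action, reward, next_state, terminal)`; insertion beyond
#' capacity evicts the oldest transition. States are referenced by their
#' row index in the training pool.
#'
#' @param capacity Maximum number of stored transitions.
#' @return A replay-buffer object (environment).
#' @export
replay_buffer <- function(capacity) {
  stopifnot(capacity >= 1)
  buf <- new.env(parent = emptyenv())
  buf$capacity <- as.integer(capacity)
  buf$n <- 0L         # number currently stored
  buf$head <- 0L      # next write slot (ring)
  buf$state <- integer(capacity)
  buf$action <- integer(capacity)
  buf$reward <- numeric(capacity)
  buf$next_state <- integer(capacity)
  buf$terminal <- logical(capacity)
  class(buf) <- "replay_buffer"
  buf
}

#' @rdname replay_buffer
#' @param buf A replay buffer.
#' @param state,action,reward,next_state,terminal One transition; `state`
#'   and `next_state` are pool row indices (`next_state` ignored when
#'   `terminal`).
#' @export
buffer_push <- function(buf, state, action, reward, next_state, terminal) {
  buf$head <- buf$head %% buf$capacity + 1L
  buf$state[buf$head] <- state
  buf$action[buf$head] <- action
  buf$reward[buf$head] <- reward
  buf$next_state[buf$head] <- if (terminal) NA_integer_ else next_state
  buf$terminal[buf$head] <- terminal
  buf$n <- min(buf$n + 1L, buf$capacity)
  invisible(buf)
}

#' @rdname replay_buffer
#' @export
buffer_size <- function(buf) buf$n

#' @rdname replay_buffer
#' @param k Minibatch size.
#' @export
buffer_sample <- function(buf, k) {
  stopifnot(buf$n >= 1)
  idx <- sample.int(buf$n, k, replace = k > buf$n)
  buffer_get(buf, idx)
}

# Transitions in insertion order, oldest first (mainly for inspection).
#' @rdname replay_buffer
#' @export
buffer_transitions <- function(buf) {
  if (buf$n == 0) {
    idx <- integer(0)
  } else if (buf$n < buf$capacity) {
    idx <- seq_len(buf$n)
  } else {
    idx <- c(seq(buf$head %% buf$capacity + 1L, buf$capacity),
             seq_len(buf$head))[seq_len(buf$capacity)]
  }
  buffer_get_slots(buf, idx)
}

buffer_get <- function(buf, idx) {
  # idx in 1..n, mapped to slots (oldest-first only matters for
  # buffer_transitions; for sampling any bijection works)
  buffer_get_slots(buf, idx)
}

buffer_get_slots <- function(buf, slots) {
  data.frame(state = buf$state[slots], action = buf$action[slots],
             reward = buf$reward[slots], next_state = buf$next_state[slots],
             terminal = buf$terminal[slots])
}

# -- Q-network ----------------------------------------------------------

#' Q-network architecture specification
#'
#' A 256-unit fully connected ReLU branch processes the classifier
#' feature vector; its output is concatenated with the linear head
#' inputs -- the classifier logits and class probabilities -- and a
#' linear output layer maps the concatenation to one Q-value per action.
#' Carrying the probabilities alongside the logits in the head makes the
#' expected-reward surface (which is linear in the class probabilities)
#' exactly representable, so on calibrated inputs a converged Q-policy
#' can coincide with the Bayes policy.
#'
#' @param feature_dim Width of the classifier feature vector.
#' @param output_dim Number of actions.
#' @param n_linear Number of linear head inputs (7 logits + 7
#'   probabilities).
#' @param width Hidden feature-branch width (default 256, ReLU).
#' @param dropout Dropout probability on the hidden layer, active only
#'   during training (default 0.05).
#' @return Object of class `qnetwork_spec`.
#' @export
qnetwork_spec <- function(feature_dim, output_dim, n_linear = 14L,
                          width = 256L, dropout = 0.05) {
  stopifnot(feature_dim >= 1, output_dim >= 2, width >= 1,
            dropout >= 0, dropout < 1)
  structure(list(feature_dim = as.integer(feature_dim),
                 output_dim = as.integer(output_dim),
                 n_linear = as.integer(n_linear),
                 width = as.integer(width), dropout = dropout),
            class = "qnetwork_spec")
}

qnet_init <- function(spec) {
  # He initialization for the ReLU branch, Glorot-ish for the linear head
  list(W1 = matrix(stats::rnorm(spec$feature_dim * spec$width,
                                sd = sqrt(2 / spec$feature_dim)),
                   spec$feature_dim, spec$width),
       b1 = numeric(spec$width),
       W2 = matrix(stats::rnorm((spec$width + spec$n_linear) * spec$output_dim,
                                sd = sqrt(1 / (spec$width + spec$n_linear))),
                   spec$width + spec$n_linear, spec$output_dim),
       b2 = numeric(spec$output_dim))
}

addbias <- function(M, b) M + rep(b, each = nrow(M))

qnet_forward <- function(par, Xf, Xl) {
  H <- pmax(addbias(Xf %*% par$W1, par$b1), 0)
  addbias(cbind(H, Xl) %*% par$W2, par$b2)
}

qnet_single <- function(par, xf, xl) {
  h <- pmax(drop(xf %*% par$W1) + par$b1, 0)
  drop(c(h, xl) %*% par$W2) + par$b2
}

# Forward with dropout + backward pass for one minibatch; returns the
# mean Huber loss and the Adam-updated parameters.
qnet_update <- function(par, adam, Xf, Xl, act, y, spec, delta, lr) {
  n <- nrow(Xf)
  pre <- addbias(Xf %*% par$W1, par$b1)
  H0 <- pmax(pre, 0)
  if (spec$dropout > 0) {
    mask <- matrix(stats::runif(n * spec$width) >= spec$dropout, n, spec$width)
    H <- H0 * mask / (1 - spec$dropout)
  } else {
    mask <- NULL
    H <- H0
  }
  Z <- cbind(H, Xl)
  Q <- addbias(Z %*% par$W2, par$b2)
  sel <- cbind(seq_len(n), act)
  e <- Q[sel] - y
  loss <- mean(ifelse(abs(e) <= delta, 0.5 * e^2,
                      delta * (abs(e) - 0.5 * delta)))
  g <- pmin(pmax(e, -delta), delta) / n
  dQ <- matrix(0, n, spec$output_dim)
  dQ[sel] <- g
  gW2 <- crossprod(Z, dQ)
  gb2 <- colSums(dQ)
  dZ <- dQ %*% t(par$W2)
  dH <- dZ[, seq_len(spec$width), drop = FALSE]
  if (!is.null(mask)) dH <- dH * mask / (1 - spec$dropout)
  dpre <- dH * (pre > 0)
  gW1 <- crossprod(Xf, dpre)
  gb1 <- colSums(dpre)
  grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  for (nm in names(par)) {
    adam$t[[nm]] <- adam$t[[nm]] + 1
    adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * grads[[nm]]
    adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * grads[[nm]]^2
    mhat <- adam$m[[nm]] / (1 - 0.9^adam$t[[nm]])
    vhat <- adam$v[[nm]] / (1 - 0.999^adam$t[[nm]])
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
  }
  list(par = par, adam = adam, loss = loss)
}

adam_init <- function(par) {
  zero <- lapply(par, function(p) p * 0)
  list(m = zero, v = zero, t = lapply(par, function(p) 0))
}

# Column preference order for tie-breaking: management actions by
# descending safety rank (cautious first), diagnoses by canonical index.
action_preference <- function(actions) {
  if (all(actions %in% names(management_actions()))) {
    order(-safety_rank(actions))
  } else {
    seq_along(actions)
  }
}

argmax_actions <- function(Q, actions) {
  pref <- action_preference(actions)
  j <- max.col(Q[, pref, drop = FALSE], ties.method = "first")
  actions[pref[j]]
}

# -- training configuration ---------------------------------------------

#' Training configuration for deep Q-learning
#'
#' Defaults follow the published lesion-level setup: Adam with learning
#' rate 0.025, Huber loss (transition width 1), replay capacity 10,000, a
#' gradient update every 4 environment steps, target-network sync every
#' 8,000 steps, constant epsilon 0.2 and a discount of 0 (the reward of a
#' management decision is immediate; the action taken does not influence
#' which lesion is shown next). For the patient-centered scenario the
#' published update cadences are 35 and 5,800 steps
#' ([patient_train_config()]).
#'
#' Training monitors the greedy-policy mean reward on a held-out 20%
#' validation split; the returned policy carries the parameters that
#' scored best there (plateau early stopping after `patience`
#' evaluations without improvement).
#'
#' @param learning_rate Adam step size.
#' @param huber_delta Quadratic-to-linear transition width of the loss.
#'   The default `NULL` resolves at training time to the largest reward
#'   magnitude in the table, so the loss is quadratic over the whole
#'   attainable residual range and the fitted Q-value estimates the
#'   conditional mean reward (making the greedy policy Bayes-consistent
#'   on calibrated data); set a smaller width for robust fitting.
#' @param replay_capacity Replay-buffer size.
#' @param q_update_period Environment steps between gradient updates.
#' @param target_sync_period Environment steps between target-network
#'   copies.
#' @param epsilon Constant exploration probability.
#' @param episode_length Lesions per episode in lesion-level scenarios
#'   (patient episodes always span one patient's lesions).
#' @param discount Discount factor gamma in `[0, 1]`.
#' @param minibatch_size Transitions per gradient update.
#' @param max_steps Total environment steps.
#' @param eval_period Steps between validation evaluations.
#' @param patience Validation evaluations without improvement before
#'   stopping early. The default (100) effectively runs all `max_steps`,
#'   which lets the tail average mature; lower it for quick exploratory
#'   fits.
#' @param min_delta Minimum improvement in validation mean reward.
#' @param validation_fraction Held-out fraction of the 80/20 split.
#' @param polyak_start Fraction of `max_steps` after which network
#'   parameters are accumulated into a tail (Polyak) average; at the end
#'   of training the final, best-on-validation and tail-averaged
#'   parameter sets are compared on the validation split and the best
#'   one is returned. Set to `NA` to disable averaging.
#' @param seed Integer seed for initialization, exploration, replay
#'   sampling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.025, huber_delta = NULL,
                         replay_capacity = 10000L, q_update_period = 4L,
                         target_sync_period = 8000L, epsilon = 0.2,
                         episode_length = 50L, discount = 0,
                         minibatch_size = 32L, max_steps = 100000L,
                         eval_period = 2000L, patience = 100L,
                         min_delta = 1e-4, validation_fraction = 0.2,
                         polyak_start = 0.4, seed = 1L) {
  stopifnot(learning_rate > 0,
            is.null(huber_delta) || is.na(huber_delta) || huber_delta > 0,
            replay_capacity >= 1,
            q_update_period >= 1, target_sync_period >= 1,
            epsilon >= 0, epsilon <= 1,
            episode_length >= 1, discount >= 0, discount <= 1,
            minibatch_size >= 1, replay_capacity >= minibatch_size,
            max_steps >= 1, validation_fraction > 0,
            validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 huber_delta = huber_delta %||% NA_real_,
                 replay_capacity = as.integer(replay_capacity),
                 q_update_period = as.integer(q_update_period),
                 target_sync_period = as.integer(target_sync_period),
                 epsilon = epsilon,
                 episode_length = as.integer(episode_length),
                 discount = discount,
                 minibatch_size = as.integer(minibatch_size),
                 max_steps = as.integer(max_steps),
                 eval_period = as.integer(eval_period),
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 validation_fraction = validation_fraction,
                 polyak_start = polyak_start,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed on to [train_config()].
#' @export
patient_train_config <- function(...) {
  defaults <- list(q_update_period = 35L, target_sync_period = 5800L)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

# -- training -----------------------------------------------------------

#' Train a deep Q-learning policy on classifier states
#'
#' Runs epsilon-greedy interaction over episodes drawn from the training
#' pool. In lesion-level scenarios an episode is `episode_length` lesions
#' drawn at random; in the patient-centered scenario each episode is all
#' lesions of one patient, state vectors normalized by the patient mean
#' and ordered by descending malignancy probability. Each step earns
#' `rewards[true diagnosis, action]`; transitions enter a FIFO replay
#' buffer; every `q_update_period` steps one minibatch gradient update
#' minimizes the Huber loss of the temporal-difference residual against
#' the target network, which is itself copied from the online network
#' every `target_sync_period` steps.
#'
#' @param data Lesion table; for the patient-centered scenario it must
#'   carry `patient_id`.
#' @param rewards A [reward_table()] whose columns match the scenario's
#'   action set.
#' @param scenario A [scenario_spec()].
#' @param cfg A [train_config()].
#' @param spec Optional [qnetwork_spec()]; derived from the data and
#'   scenario when omitted.
#' @return Object of class `trained_policy`: network parameters,
#'   architecture and training configuration, scenario, class order and
#'   the training history (step, validation mean reward, loss).
#' @export
train_q <- function(data, rewards, scenario, cfg = train_config(),
                    spec = NULL) {
  stopifnot(inherits(rewards, "reward_table"),
            inherits(scenario, "scenario_spec"),
            inherits(cfg, "train_config"),
            is.data.frame(data), nrow(data) > 0)
  actions <- scenario$action_set
  if (length(actions) == 0) stop("empty action set")
  if (!setequal(reward_cols(rewards), actions)) {
    stop("reward-table columns do not match the ", scenario$name,
         " action set")
  }
  R <- rewards$values[diagnosis_labels(), actions, drop = FALSE]
  delta <- if (is.na(cfg$huber_delta)) max(abs(R), 1e-8) else cfg$huber_delta
  patient_mode <- scenario$name == "patient_centered"

  set.seed(cfg$seed)
  S <- build_state(data,
                   mode = if (patient_mode) "patient_normalized" else "lesion")
  bd <- attr(S, "block_dims")
  Fd <- bd[["features"]]
  Xf <- S[, seq_len(Fd), drop = FALSE]
  Xl <- S[, Fd + seq_len(14L), drop = FALSE] # logits + probabilities
  lab <- match(data$true_label, diagnosis_labels())
  if (anyNA(lab)) stop("unknown true_label values in training data")
  if (is.null(spec)) {
    spec <- qnetwork_spec(feature_dim = Fd, output_dim = length(actions))
  }
  stopifnot(spec$output_dim == length(actions), spec$feature_dim == Fd)

  # 80/20 split: lesions (or whole patients) held out for validation
  n <- nrow(data)
  if (patient_mode) {
    pats <- split(seq_len(n), data$patient_id)
    # patient episodes: normalized states, ordered by malignancy
    mp <- malignancy_probability(prob_matrix(data))
    pats <- lapply(pats, function(idx) idx[order(-mp[idx])])
    vp <- sample(length(pats), max(1, round(cfg$validation_fraction *
                                              length(pats))))
    valid_idx <- unlist(pats[vp], use.names = FALSE)
    train_eps <- pats[-vp]
  } else {
    valid_idx <- sample(n, max(1, round(cfg$validation_fraction * n)))
    train_pool <- setdiff(seq_len(n), valid_idx)
    train_eps <- NULL
  }

  par <- qnet_init(spec)
  target <- par
  adam <- adam_init(par)
  buf <- replay_buffer(cfg$replay_capacity)
  A <- length(actions)
  pref <- action_preference(actions)

  evaluate <- function(p) {
    Q <- qnet_forward(p, Xf[valid_idx, , drop = FALSE],
                      Xl[valid_idx, , drop = FALSE])
    j <- max.col(Q[, pref, drop = FALSE], ties.method = "first")
    mean(R[cbind(lab[valid_idx], pref[j])])
  }

  history <- list()
  best <- list(par = par, score = -Inf)
  stale <- 0L
  loss_acc <- c(0, 0)
  step <- 0L
  done <- FALSE
  avg_from <- if (is.na(cfg$polyak_start)) Inf else
    floor(cfg$polyak_start * cfg$max_steps)
  avg <- NULL
  n_avg <- 0L

  while (!done) {
    ep <- if (patient_mode) {
      train_eps[[sample.int(length(train_eps), 1)]]
    } else {
      sample(train_pool, cfg$episode_length, replace = TRUE)
    }
    len <- length(ep)
    for (t in seq_len(len)) {
      i <- ep[t]
      a <- if (stats::runif(1) < cfg$epsilon) {
        sample.int(A, 1)
      } else {
        q <- qnet_single(par, Xf[i, ], Xl[i, ])
        pref[which.max(q[pref])]
      }
      terminal <- t == len
      buffer_push(buf, i, a, R[lab[i], a],
                  if (terminal) NA_integer_ else ep[t + 1L], terminal)
      step <- step + 1L

      if (step %% cfg$q_update_period == 0L &&
          buffer_size(buf) >= cfg$minibatch_size) {
        tr <- buffer_sample(buf, cfg$minibatch_size)
        y <- tr$reward
        if (cfg$discount > 0) {
          live <- !tr$terminal
          if (any(live)) {
            ns <- tr$next_state[live]
            Qn <- qnet_forward(target, Xf[ns, , drop = FALSE],
                               Xl[ns, , drop = FALSE])
            y[live] <- y[live] +
              cfg$discount * apply(Qn, 1, max)
          }
        }
        upd <- qnet_update(par, adam, Xf[tr$state, , drop = FALSE],
                           Xl[tr$state, , drop = FALSE],
                           tr$action, y, spec, delta,
                           cfg$learning_rate)
        par <- upd$par
        adam <- upd$adam
        loss_acc <- loss_acc + c(upd$loss, 1)
        if (step >= avg_from) {
          n_avg <- n_avg + 1L
          if (is.null(avg)) {
            avg <- par
          } else {
            for (nm in names(par)) {
              avg[[nm]] <- avg[[nm]] + (par[[nm]] - avg[[nm]]) / n_avg
            }
          }
        }
      }
      if (step %% cfg$target_sync_period == 0L) target <- par
      if (step %% cfg$eval_period == 0L) {
        score <- evaluate(par)
        history[[length(history) + 1L]] <-
          c(step = step, mean_valid_reward = score,
            mean_loss = if (loss_acc[2] > 0) loss_acc[1] / loss_acc[2]
                        else NA_real_)
        loss_acc <- c(0, 0)
        if (score > best$score + cfg$min_delta) {
          best <- list(par = par, score = score)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= cfg$patience) done <- TRUE
        }
      }
      if (step >= cfg$max_steps) done <- TRUE
      if (done) break
    }
  }
  # model selection on the validation split: final parameters vs the tail
  # (Polyak) average, which cancels the stationary optimizer noise of a
  # constant learning rate. The best single checkpoint is only a fallback
  # for early-stopped runs where the average never matured: as the max
  # over many noisy validation evaluations it suffers winner's curse and
  # can hide locally broken action columns behind an inflated score.
  candidates <- list(final = par)
  if (!is.null(avg) && n_avg >= 10L) {
    candidates$polyak <- avg
  } else if (is.finite(best$score)) {
    candidates$best <- best$par
  }
  scores <- vapply(candidates, evaluate, numeric(1))
  par <- lapply(candidates[[which.max(scores)]], unname)

  structure(list(par = par, spec = spec, cfg = cfg,
                 scenario = scenario, actions = actions,
                 class_order = diagnosis_labels(),
                 state_mode = if (patient_mode) "patient_normalized"
                              else "lesion",
                 history = as.data.frame(do.call(rbind, history)),
                 selected = names(candidates)[which.max(scores)],
                 best_valid_reward = max(scores)),
            class = "trained_policy")
}

#' @export
print.trained_policy <- function(x, ...) {
  cat("<trained_policy>", x$scenario$name, "| actions:",
      paste(x$actions, collapse = ", "), "\n")
  cat("  feature dim:", x$spec$feature_dim,
      "| hidden width:", x$spec$width, "\n")
  if (is.finite(x$best_valid_reward)) {
    cat("  best validation mean reward:",
        format(x$best_valid_reward, digits = 4), "\n")
  }
  invisible(x)
}

policy_state_parts <- function(policy, records, context = NULL) {
  S <- build_state(records, mode = policy$state_mode,
                   patient_context = context)
  Fd <- policy$spec$feature_dim
  if (ncol(S) != Fd + 14L) {
    stop("state dimension mismatch: policy expects feature dim ", Fd)
  }
  list(Xf = S[, seq_len(Fd), drop = FALSE],
       Xl = S[, Fd + seq_len(14L), drop = FALSE])
}

#' Q-values of a trained policy
#'
#' Evaluates the Q-network (dropout disabled) for each lesion in
#' `records`. For a patient-normalized policy, supply either a
#' `patient_id` column or `context` (the lesion table of the same
#' patient).
#'
#' @param policy A [train_q()] result.
#' @param records Lesion table.
#' @param context Optional patient-context lesion table.
#' @return Numeric matrix, one row per lesion, one column per action.
#' @export
q_values <- function(policy, records, context = NULL) {
  stopifnot(inherits(policy, "trained_policy"))
  sp <- policy_state_parts(policy, records, context)
  Q <- qnet_forward(policy$par, sp$Xf, sp$Xl)
  colnames(Q) <- policy$actions
  rownames(Q) <- records$lesion_id
  Q
}

#' Greedy action of a trained policy
#'
#' Argmax of the Q-values; ties are broken toward the higher safety rank
#' in management scenarios and toward the lower canonical class index in
#' the diagnosis scenario.
#'
#' @inheritParams q_values
#' @return Character vector of action codes, one per lesion.
#' @export
greedy_action <- function(policy, records, context = NULL) {
  Q <- q_values(policy, records, context)
  argmax_actions(Q, policy$actions)
}

#' Predictive diagnosis distribution of a diagnosis policy
#'
#' Normalized exponential (softmax) of the Q-vector of a diagnosisRL
#' policy, giving a probability distribution over the seven diagnoses.
#'
#' @inheritParams q_values
#' @return Numeric matrix on the simplex, columns in canonical class
#'   order.
#' @export
predictive_distribution <- function(policy, records, context = NULL) {
  stopifnot(inherits(policy, "trained_policy"))
  if (policy$scenario$name != "diagnosisRL") {
    stop("predictive distributions are defined only for diagnosisRL policies")
  }
  Q <- q_values(policy, records, context)
  Z <- Q - apply(Q, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# -- serialization ------------------------------------------------------

#' Save / load a trained policy
#'
#' The archive is self-describing JSON: parameters, architecture,
#' training configuration, scenario, state mode and the canonical class
#' order. Loading refuses an archive whose class order differs from this
#' package's canonical order.
#'
#' @param policy A `trained_policy`.
#' @param path JSON file path.
#' @return `path` invisibly (write); the policy (read).
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "trained_policy"))
  obj <- list(par = policy$par,
              spec = unclass(policy$spec),
              cfg = unclass(policy$cfg),
              scenario = policy$scenario$name,
              actions = policy$actions,
              class_order = policy$class_order,
              state_mode = policy$state_mode,
              best_valid_reward = policy$best_valid_reward,
              history = policy$history)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(obj$class_order), diagnosis_labels())) {
    stop("policy archive uses a different class order; refusing to load")
  }
  spec <- do.call(qnetwork_spec, obj$spec[c("feature_dim", "output_dim",
                                            "n_linear", "width", "dropout")])
  cfg_fields <- setdiff(names(obj$cfg), character(0))
  cfg <- do.call(train_config, obj$cfg[cfg_fields])
  par <- list(W1 = matrix(obj$par$W1, spec$feature_dim, spec$width),
              b1 = as.numeric(obj$par$b1),
              W2 = matrix(obj$par$W2, spec$width + spec$n_linear,
                          spec$output_dim),
              b2 = as.numeric(obj$par$b2))
  structure(list(par = par, spec = spec, cfg = cfg,
                 scenario = scenario_spec(obj$scenario),
                 actions = as.character(obj$actions),
                 class_order = diagnosis_labels(),
                 state_mode = obj$state_mode,
                 history = as.data.frame(obj$history),
                 best_valid_reward = obj$best_valid_reward %||% NA_real_),
            class = "trained_policy")
}
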