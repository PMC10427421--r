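# Scenario orchestration: configuration, packaged expert-input files,
# end-to-end runs (simulate -> train -> decide -> evaluate) and
# patient-grouped cross-validation.

#' Packaged synthetic expert inputs
#'
#' The package ships editable reward-table and threshold files under
#' `inst/extdata/`. Their numeric values are synthetic stand-ins written
#' by the package authors (real expert elicitations are not publicly
#' printed); they follow the documented qualitative structure --
#' overlooking a melanoma carries the largest penalty, monitoring a
#' melanoma a moderate one, excising a benign lesion a mild one. Replace
#' them with your own elicited tables for real use.
#'
#' @param scenario Scenario name (see [scenario_spec()]).
#' @return `default_reward_table`: a [reward_table()];
#'   `default_threshold_specs`: list of ten per-expert
#'   [threshold_spec()]s to pass through [aggregate_expert_inputs()].
#' @export
default_reward_table <- function(scenario = c("diagnosisRL", "binary",
                                              "multiclass_therapy",
                                              "patient_centered")) {
  scenario <- match.arg(scenario)
  file <- switch(scenario,
    diagnosisRL        = "reward_diagnosis_consensus_synthetic.csv",
    binary             = "reward_binary_synthetic.csv",
    multiclass_therapy = "reward_multiclass_therapy_synthetic.csv",
    patient_centered   = "reward_patient_monitoring_synthetic.csv"
  )
  path <- system.file("extdata", file, package = "dermpolicy")
  load_reward_table(path, expected_columns = scenario_spec(scenario)$action_set,
                    provenance = paste0("synthetic packaged table (",
                                        scenario, ")"))
}

#' @rdname default_reward_table
#' @export
default_threshold_specs <- function() {
  path <- system.file("extdata", "thresholds_experts_synthetic.csv",
                      package = "dermpolicy")
  load_threshold_specs(path)
}

#' Run configuration
#'
#' Bundles everything an end-to-end scenario run needs. A single global
#' seed fans out to named substreams (data generation, training,
#' evaluation) so each stage is independently reproducible.
#'
#' @param scenario Scenario name.
#' @param generator [generator_config()] for lesion-level scenarios.
#' @param cohort [cohort_config()] for the patient-centered scenario.
#' @param rewards A [reward_table()], a file path, or a list of expert
#'   tables to aggregate.
#' @param thresholds A [threshold_spec()], a file path, or a list of
#'   expert specs to aggregate.
#' @param aggregate Expert aggregation method (`"median"` or
#'   `"minimum"`).
#' @param train A [train_config()].
#' @param n_train Training-pool size for lesion-level scenarios (the
#'   test set is always the ISIC-composition fixture).
#' @param folds Cross-validation folds for the patient-centered
#'   scenario.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param seed Global integer seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scenario = "diagnosisRL",
                       generator = generator_config(),
                       cohort = cohort_config(),
                       rewards = NULL,
                       thresholds = NULL,
                       aggregate = "median",
                       train = train_config(),
                       n_train = 4000L,
                       folds = 20L,
                       out_dir = NULL,
                       seed = 1L) {
  scen <- scenario_spec(scenario)
  structure(list(scenario = scen, generator = generator, cohort = cohort,
                 rewards = rewards, thresholds = thresholds,
                 aggregate = aggregate, train = train,
                 n_train = as.integer(n_train), folds = as.integer(folds),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

resolve_rewards <- function(rewards, scenario, aggregate = "median") {
  if (is.null(rewards)) return(default_reward_table(scenario$name))
  if (inherits(rewards, "reward_table")) return(rewards)
  if (is.character(rewards)) {
    return(load_reward_table(rewards,
                             expected_columns = scenario$action_set))
  }
  if (is.list(rewards)) return(aggregate_expert_inputs(rewards, aggregate))
  stop("cannot interpret the rewards argument")
}

resolve_thresholds <- function(thresholds, aggregate = "median") {
  if (is.null(thresholds)) thresholds <- default_threshold_specs()
  if (inherits(thresholds, "threshold_spec")) return(thresholds)
  if (is.character(thresholds)) thresholds <- load_threshold_specs(thresholds)
  if (is.list(thresholds)) {
    return(aggregate_expert_inputs(thresholds, aggregate))
  }
  stop("cannot interpret the thresholds argument")
}

config_fingerprint <- function(cfg) {
  strip <- function(x) {
    if (inherits(x, "scenario_spec")) return(x$name)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(strip(unclass(cfg)), tf, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

substream_seeds <- function(seed, n = 4) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run one clinical scenario end to end
#'
#' Generates (or accepts) data, trains the reinforcement-learning
#' policy, runs the naive, threshold and expected-reward baselines, and
#' computes the scenario's evaluation bundle. Fully reproducible from
#' the configuration and its seed; every artifact records the seed,
#' configuration hash and class-order fingerprint.
#'
#' @param cfg A [run_config()].
#' @return A report list; contents depend on the scenario (see the
#'   package vignette).
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  scen <- cfg$scenario
  seeds <- substream_seeds(cfg$seed, 4)
  rewards <- resolve_rewards(cfg$rewards, scen, cfg$aggregate)
  if (scen$name == "patient_centered") {
    return(run_patient_cv(cfg, rewards = rewards, seeds = seeds))
  }
  thresholds <- if (scen$name != "diagnosisRL") {
    resolve_thresholds(cfg$thresholds, cfg$aggregate)
  }
  train_data <- sample_states(cfg$generator, cfg$n_train, seed = seeds[1])
  test_data <- make_isic_fixture(cfg$generator, seed = seeds[2])
  tc <- cfg$train
  tc$seed <- seeds[3]
  policy <- train_q(train_data, rewards, scen, tc)

  decisions <- list(
    naive = naive_policy(test_data, scen),
    bayes = if (scen$name != "diagnosisRL") bayes_policy(test_data, rewards),
    threshold = if (!is.null(thresholds)) {
      threshold_policy(test_data, thresholds, scen)
    },
    rl = {
      act <- greedy_action(policy, test_data)
      decision_frame(test_data, "rl", act)
    }
  )
  decisions <- Filter(Negate(is.null), decisions)

  truth <- test_data$true_label
  report <- list(scenario = scen$name, seed = cfg$seed,
                 config_hash = config_fingerprint(cfg),
                 class_order = paste(diagnosis_labels(), collapse = ","),
                 n_train = nrow(train_data), n_test = nrow(test_data),
                 rewards = rewards, thresholds = thresholds,
                 policy = policy, decisions = decisions)

  if (scen$name == "diagnosisRL") {
    cm_sl <- confusion(truth, decisions$naive$diagnosis_call)
    cm_rl <- confusion(truth, decisions$rl$action)
    report$confusion <- list(sl = cm_sl, rl = cm_rl)
    report$metrics <- data.frame(
      model = c("sl", "rl"),
      mel_sensitivity = c(class_sensitivity(cm_sl, "MEL"),
                          class_sensitivity(cm_rl, "MEL")),
      bcc_sensitivity = c(class_sensitivity(cm_sl, "BCC"),
                          class_sensitivity(cm_rl, "BCC")),
      average_recall = c(average_recall(cm_sl), average_recall(cm_rl)),
      overall_accuracy = c(overall_accuracy(cm_sl),
                           overall_accuracy(cm_rl)))
    report$entropy <- entropy_comparison(
      prob_matrix(test_data),
      predictive_distribution(policy, test_data), paired = TRUE)
  } else {
    mal <- is_malignant(truth)
    if (scen$name == "binary") {
      report$roc <- roc_and_operating_points(
        malignancy_probability(prob_matrix(test_data)), mal, decisions)
    }
    report$action_confusion <- lapply(decisions, function(d) {
      confusion(truth, d$action, col_labels = scen$action_set)
    })
    opt <- optimal_management(truth, scen)
    report$metrics <- do.call(rbind, lapply(names(decisions), function(nm) {
      d <- decisions[[nm]]
      data.frame(policy = nm,
                 optimal_rate = mean(d$action == opt),
                 malignant_mismanaged = mean(d$action[mal] != opt[mal]),
                 tpr = sum(d$action == "EXCISE" & mal) / sum(mal),
                 fpr = sum(d$action == "EXCISE" & !mal) / sum(!mal))
    }))
  }
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Patient-grouped cross-validation for the monitoring scenario
#'
#' Patients are partitioned into folds (no patient spans folds); the
#' policy is trained on the out-of-fold patients and decides the in-fold
#' lesions; decisions are pooled over folds before computing
#' patient-level metrics. Baseline policies need no training and decide
#' the whole cohort once.
#'
#' @param cfg A [run_config()] with scenario `"patient_centered"`.
#' @param rewards,seeds Internal (resolved by [run_scenario()]); may be
#'   omitted when calling directly.
#' @return Report list with pooled decisions and [patient_metrics()] per
#'   policy.
#' @export
run_patient_cv <- function(cfg, rewards = NULL, seeds = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  scen <- cfg$scenario
  stopifnot(scen$name == "patient_centered")
  if (is.null(seeds)) seeds <- substream_seeds(cfg$seed, 4)
  rewards <- rewards %||% resolve_rewards(cfg$rewards, scen, cfg$aggregate)
  thresholds <- resolve_thresholds(cfg$thresholds, cfg$aggregate)
  cohort <- sample_cohort(cfg$cohort, seed = seeds[1])
  patients <- unique(cohort$patient_id)
  folds <- cfg$folds
  if (folds > length(patients)) {
    stop("more folds than patients (", length(patients), ")")
  }
  set.seed(seeds[2])
  assignment <- sample(rep(seq_len(folds), length.out = length(patients)))
  names(assignment) <- patients

  rl_decisions <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_p <- patients[assignment == f]
    train_rows <- cohort[!(cohort$patient_id %in% test_p), , drop = FALSE]
    test_rows <- cohort[cohort$patient_id %in% test_p, , drop = FALSE]
    tc <- cfg$train
    tc$seed <- (seeds[3] + f) %% .Machine$integer.max
    pol <- train_q(train_rows, rewards, scen, tc)
    act <- greedy_action(pol, test_rows)
    rl_decisions[[f]] <- decision_frame(test_rows, "rl", act)
  }
  decisions <- list(
    naive = naive_policy(cohort, scen),
    threshold = threshold_policy(cohort, thresholds, scen),
    bayes = bayes_policy(cohort, rewards),
    rl = do.call(rbind, rl_decisions)
  )
  report <- list(scenario = scen$name, seed = cfg$seed,
                 config_hash = config_fingerprint(cfg),
                 class_order = paste(diagnosis_labels(), collapse = ","),
                 folds = folds, fold_assignment = assignment,
                 cohort = cohort, rewards = rewards,
                 thresholds = thresholds, decisions = decisions,
                 metrics = lapply(decisions, function(d) {
                   patient_metrics(cohort, d)
                 }))
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$decisions)) {
    utils::write.csv(report$decisions[[nm]],
                     file.path(out_dir, paste0("decisions_", nm, ".csv")),
                     row.names = FALSE)
  }
  meta <- list(scenario = report$scenario, seed = report$seed,
               config_hash = report$config_hash,
               class_order = report$class_order)
  if (!is.null(report$metrics)) {
    if (is.data.frame(report$metrics)) {
      utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
    } else {
      jsonlite::write_json(
        lapply(report$metrics, function(m) {
          lapply(m, function(v) {
            if (is.table(v) || is.array(v)) as.list(as.vector(v)) else v
          })
        }),
        file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
        force = TRUE)
    }
  }
  jsonlite::write_json(meta, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
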