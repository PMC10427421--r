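# Synthetic classifier-output simulator: class-conditional Gaussian
# features with analytic posterior probabilities, plus fixture and cohort
# generators matching published dataset compositions.

#' Generator configuration for synthetic classifier states
#'
#' The simulator emulates the outputs of a multiclass lesion classifier
#' without needing images: each class has an isotropic Gaussian
#' feature-vector distribution, and the emitted logits are the exact
#' Gaussian log-posteriors of the generative model, so with
#' `temperature = 1` and `label_noise = 0` the emitted probabilities are
#' perfectly calibrated and the Bayes-optimal action under any reward
#' table is computable in closed form.
#'
#' Class-conditional means sit at `class_separation` along orthogonal
#' coordinate directions; `confusion_pairs` pulls selected pairs of means
#' toward their midpoint (overlap factor 0 = untouched, 1 = identical),
#' which is how the hard melanoma-versus-nevus boundary of dermatoscopic
#' classifiers is emulated. Default priors follow the class frequencies of
#' a benign-dominated dermatoscopic test population.
#'
#' @param class_priors Probability vector over the 7 classes (canonical
#'   order); defaults to the ISIC-2018-test-like composition.
#' @param feature_dim Feature-vector width, at least 7.
#' @param class_separation Distance of each class mean from the origin.
#' @param confusion_pairs List of `list(a, b, overlap)` triples.
#' @param temperature Softmax temperature applied to the logits; 1 emits
#'   calibrated probabilities, >1 flattens, <1 sharpens.
#' @param label_noise Probability that a record's true label is resampled
#'   uniformly among the other classes (the state is left untouched, so
#'   calibration is deliberately broken).
#' @param seed Integer seed for the generator.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(class_priors = c(171, 93, 43, 217, 908, 44, 35) / 1511,
                             feature_dim = 16,
                             class_separation = 3.1,
                             confusion_pairs = list(list("MEL", "NV", 0.5)),
                             temperature = 1,
                             label_noise = 0,
                             seed = 1L) {
  stopifnot(length(class_priors) == 7, all(class_priors >= 0),
            abs(sum(class_priors) - 1) < 1e-6,
            feature_dim >= 7, class_separation >= 0,
            temperature > 0, label_noise >= 0, label_noise <= 1)
  for (cp in confusion_pairs) {
    stopifnot(length(cp) == 3, cp[[1]] %in% diagnosis_labels(),
              cp[[2]] %in% diagnosis_labels(),
              cp[[3]] >= 0, cp[[3]] <= 1)
  }
  structure(list(class_priors = as.numeric(class_priors),
                 feature_dim = as.integer(feature_dim),
                 class_separation = class_separation,
                 confusion_pairs = confusion_pairs,
                 temperature = temperature,
                 label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Class means: class_separation along the first 7 coordinate axes, then
# confusion pairs contracted toward their midpoints.
class_means <- function(config) {
  mu <- matrix(0, 7, config$feature_dim,
               dimnames = list(diagnosis_labels(), NULL))
  for (i in 1:7) mu[i, i] <- config$class_separation
  for (cp in config$confusion_pairs) {
    a <- cp[[1]]; b <- cp[[2]]; w <- cp[[3]]
    mid <- (mu[a, ] + mu[b, ]) / 2
    mu[a, ] <- mu[a, ] + w * (mid - mu[a, ])
    mu[b, ] <- mu[b, ] + w * (mid - mu[b, ])
  }
  mu
}

#' Analytic class posterior of the generative model
#'
#' For unit-variance isotropic Gaussian class-conditionals the
#' log-posterior of class c given feature vector x is
#' `log prior_c - ||x - mu_c||^2 / 2` up to an additive constant.
#'
#' @param X Feature matrix (rows = lesions).
#' @param config A [generator_config()].
#' @return List with `logits` (n x 7) and `probabilities` (n x 7,
#'   temperature-scaled softmax of the logits).
#' @export
generative_posterior <- function(X, config) {
  mu <- class_means(config)
  n <- nrow(X)
  sq <- matrix(0, n, 7)
  for (c in 1:7) {
    d <- sweep(X, 2, mu[c, ])
    sq[, c] <- rowSums(d * d)
  }
  logits <- sweep(-sq / 2, 2, log(config$class_priors), `+`)
  colnames(logits) <- diagnosis_labels()
  z <- logits / config$temperature
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  colnames(probs) <- diagnosis_labels()
  list(logits = logits, probabilities = probs)
}

sample_states_for_labels <- function(config, labels, patient_id = NA_character_,
                                     id_prefix = "L") {
  n <- length(labels)
  mu <- class_means(config)
  X <- mu[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * config$feature_dim), n, config$feature_dim)
  post <- generative_posterior(X, config)
  if (config$label_noise > 0) {
    flip <- stats::runif(n) < config$label_noise
    if (any(flip)) {
      labels[flip] <- vapply(labels[flip], function(l) {
        sample(setdiff(diagnosis_labels(), l), 1)
      }, character(1))
    }
  }
  colnames(X) <- sprintf("f_%d", seq_len(config$feature_dim))
  probs <- post$probabilities
  logits <- post$logits
  colnames(probs) <- paste0("p_", diagnosis_labels())
  colnames(logits) <- paste0("logit_", diagnosis_labels())
  rownames(X) <- rownames(probs) <- rownames(logits) <- NULL
  data.frame(lesion_id = sprintf("%s%06d", id_prefix, seq_len(n)),
             patient_id = patient_id,
             true_label = unname(labels),
             probs, logits, X,
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Sample synthetic classifier states
#'
#' Draws `n` lesion records: a true label from the class priors, a feature
#' vector from that class's Gaussian, and the analytic logits and
#' (temperature-scaled) posterior probabilities.
#'
#' @param config A [generator_config()].
#' @param n Number of lesions (>= 1).
#' @param seed Optional seed overriding `config$seed`.
#' @return A lesion table: `lesion_id`, `patient_id`, `true_label`,
#'   probability columns `p_MEL..p_VASC`, logit columns, feature columns.
#' @export
sample_states <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "generator_config"), n >= 1)
  set.seed(seed %||% config$seed)
  labels <- sample(diagnosis_labels(), n, replace = TRUE,
                   prob = config$class_priors)
  sample_states_for_labels(config, labels)
}

#' ISIC-2018-test-composition fixture
#'
#' Generates a lesion table with exactly the published per-class counts of
#' the 1,511-image independent test set (MEL 171, BCC 93, AKIEC 43,
#' BKL 217, NV 908, DF 44, VASC 35), states sampled from the generator.
#'
#' @param config A [generator_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Lesion table with 1,511 rows.
#' @export
make_isic_fixture <- function(config = generator_config(), seed = NULL) {
  counts <- c(MEL = 171L, BCC = 93L, AKIEC = 43L, BKL = 217L,
              NV = 908L, DF = 44L, VASC = 35L)
  set.seed(seed %||% config$seed)
  labels <- sample(rep(names(counts), counts))
  sample_states_for_labels(config, labels)
}

#' Class priors of the high-risk monitoring population
#'
#' The lesion mix seen in sequential monitoring of patients with many
#' nevi: dominated by nevi, with rare noninvasive melanomas and no
#' BCC/AKIEC referrals (floored at a small value so log-priors stay
#' finite). Used as the default generator priors for [sample_cohort()],
#' so that emitted posteriors are calibrated for the monitoring
#' population rather than for a referral test-set mix.
#'
#' @param floor Minimum prior mass per class.
#' @return Probability vector over the 7 classes.
#' @export
monitoring_priors <- function(floor = 1e-4) {
  p <- c(MEL = 55, BCC = 0, AKIEC = 0, BKL = 56, NV = 7213, DF = 31,
         VASC = 20) / 7375
  p <- pmax(p, floor)
  unname(p / sum(p))
}

#' Cohort configuration for the patient-centered monitoring scenario
#'
#' @param composition `"exact_paper"` reproduces the published monitoring
#'   cohort exactly: 524 patients, 7,375 lesions (55 noninvasive or
#'   microinvasive melanomas; benign lesions dominated by nevi), with
#'   per-patient lesion counts in `[6, 51]` and median near 12.
#'   `"stochastic"` draws patient and class counts from the configured
#'   distributions.
#' @param n_patients Number of patients (stochastic mode).
#' @param melanoma_rate Per-lesion melanoma probability (stochastic mode).
#' @param benign_mix Probability vector over the four benign classes
#'   (BKL, NV, DF, VASC order), conditioned on a lesion being benign.
#' @param lesions_range Per-patient lesion-count truncation range.
#' @param nb_size,nb_mu Negative-binomial shape and mean for per-patient
#'   lesion counts before truncation.
#' @param generator A [generator_config()] for the lesion states.
#' @param seed Integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(composition = c("exact_paper", "stochastic"),
                          n_patients = 524L,
                          melanoma_rate = 55 / 7375,
                          benign_mix = c(56, 7213, 31, 20) / 7320,
                          lesions_range = c(6L, 51L),
                          nb_size = 2.6, nb_mu = 14.1,
                          generator = generator_config(
                            class_priors = monitoring_priors()),
                          seed = 1L) {
  composition <- match.arg(composition)
  stopifnot(n_patients >= 1, melanoma_rate >= 0, melanoma_rate <= 1,
            length(benign_mix) == 4, abs(sum(benign_mix) - 1) < 1e-6,
            lesions_range[1] >= 1, lesions_range[2] >= lesions_range[1])
  structure(list(composition = composition,
                 n_patients = as.integer(n_patients),
                 melanoma_rate = melanoma_rate,
                 benign_mix = as.numeric(benign_mix),
                 lesions_range = as.integer(lesions_range),
                 nb_size = nb_size, nb_mu = nb_mu,
                 generator = generator, seed = as.integer(seed)),
            class = "cohort_config")
}

# Truncated negative-binomial per-patient lesion counts, adjusted by
# single-lesion increments/decrements to hit an exact total while staying
# inside the truncation range.
draw_patient_counts <- function(cc, total = NULL) {
  lo <- cc$lesions_range[1]; hi <- cc$lesions_range[2]
  draw1 <- function(k) {
    x <- stats::rnbinom(k, size = cc$nb_size, mu = cc$nb_mu)
    x[x >= lo & x <= hi]
  }
  counts <- integer(0)
  while (length(counts) < cc$n_patients) {
    counts <- c(counts, draw1(2L * cc$n_patients))
  }
  counts <- counts[seq_len(cc$n_patients)]
  if (!is.null(total)) {
    if (total < cc$n_patients * lo || total > cc$n_patients * hi) {
      stop("infeasible exact composition: ", total, " lesions cannot be ",
           "split over ", cc$n_patients, " patients within [", lo, ", ",
           hi, "]")
    }
    while (sum(counts) != total) {
      if (sum(counts) > total) {
        i <- sample(which(counts > lo), 1)
        counts[i] <- counts[i] - 1L
      } else {
        i <- sample(which(counts < hi), 1)
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}

#' Sample a patient cohort for the monitoring scenario
#'
#' In `exact_paper` mode the published composition is reproduced exactly:
#' 524 patients, 7,375 lesions of which 55 are melanomas and the benign
#' remainder is 98.5% nevi (7,213 NV, 56 BKL, 31 DF, 20 VASC; the three
#' published "other benign" lesions are mapped to BKL so labels stay in
#' the 7-class vocabulary). In `stochastic` mode counts and labels are
#' drawn from the configured distributions.
#'
#' @param cc A [cohort_config()].
#' @param seed Optional seed overriding `cc$seed`.
#' @return Lesion table with `patient_id` filled (one row per lesion).
#' @export
sample_cohort <- function(cc = cohort_config(), seed = NULL) {
  stopifnot(inherits(cc, "cohort_config"))
  set.seed(seed %||% cc$seed)
  if (cc$composition == "exact_paper") {
    class_counts <- c(MEL = 55L, BCC = 0L, AKIEC = 0L, BKL = 56L,
                      NV = 7213L, DF = 31L, VASC = 20L)
    total <- sum(class_counts)
    counts <- draw_patient_counts(cc, total = total)
    labels <- sample(rep(names(class_counts), class_counts))
  } else {
    counts <- draw_patient_counts(cc, total = NULL)
    total <- sum(counts)
    mal <- stats::runif(total) < cc$melanoma_rate
    labels <- character(total)
    labels[mal] <- "MEL"
    labels[!mal] <- sample(c("BKL", "NV", "DF", "VASC"), sum(!mal),
                           replace = TRUE, prob = cc$benign_mix)
  }
  patient_id <- rep(sprintf("P%04d", seq_along(counts)), counts)
  df <- sample_states_for_labels(cc$generator, labels,
                                 patient_id = patient_id)
  df
}

#' Split a cohort lesion table by patient
#'
#' @param cohort Lesion table with a `patient_id` column.
#' @return Named list of per-patient lesion tables.
#' @export
split_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), "patient_id" %in% names(cohort),
            !anyNA(cohort$patient_id))
  split(cohort, cohort$patient_id)
}

# -- lesion-table column accessors and I/O ------------------------------

#' Extract the probability / logit / feature matrices of a lesion table
#'
#' @param records Lesion table as produced by [sample_states()].
#' @return Numeric matrix.
#' @export
prob_matrix <- function(records) {
  cols <- paste0("p_", diagnosis_labels())
  stopifnot(all(cols %in% names(records)))
  m <- as.matrix(records[, cols])
  colnames(m) <- diagnosis_labels()
  m
}

#' @rdname prob_matrix
#' @export
logit_matrix <- function(records) {
  cols <- paste0("logit_", diagnosis_labels())
  stopifnot(all(cols %in% names(records)))
  m <- as.matrix(records[, cols])
  colnames(m) <- diagnosis_labels()
  m
}

#' @rdname prob_matrix
#' @export
feature_matrix <- function(records) {
  cols <- grep("^f_\\d+$", names(records), value = TRUE)
  stopifnot(length(cols) > 0)
  as.matrix(records[, cols[order(as.integer(sub("^f_", "", cols)))]])
}

#' Write / read a lesion table as CSV
#'
#' Numeric columns are written with full double precision so a write/read
#' round-trip is bit-exact; the same schema accepts real classifier
#' outputs.
#'
#' @param records Lesion table.
#' @param path CSV file path.
#' @return `path` invisibly (write); lesion table (read).
#' @export
write_lesion_table <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lesion_table
#' @export
read_lesion_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  num <- setdiff(names(df), c("lesion_id", "patient_id", "true_label"))
  for (j in num) df[[j]] <- as.numeric(df[[j]])
  if ("patient_id" %in% names(df)) df$patient_id <- as.character(df$patient_id)
  df
}
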