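# Domain vocabulary: the seven-class skin lesion taxonomy, management
# actions, reward tables, threshold specifications and scenario definitions.

#' Canonical diagnosis labels
#'
#' The seven lesion classes in their fixed canonical order. This order is
#' used for every probability vector, logit vector, reward-table row and
#' confusion-matrix axis in the package: melanoma (MEL), basal cell
#' carcinoma (BCC), actinic keratosis / intraepidermal carcinoma (AKIEC),
#' benign keratinocytic lesion (BKL), melanocytic nevus (NV),
#' dermatofibroma (DF) and vascular lesion (VASC).
#'
#' @return Character vector of length 7.
#' @export
diagnosis_labels <- function() {
  c("MEL", "BCC", "AKIEC", "BKL", "NV", "DF", "VASC")
}

#' Malignant-or-premalignant diagnosis labels
#'
#' MEL, BCC and AKIEC require treatment; the remaining four classes are
#' benign.
#'
#' @return Character vector of length 3.
#' @export
malignant_labels <- function() {
  c("MEL", "BCC", "AKIEC")
}

#' Is a diagnosis malignant (requires treatment)?
#'
#' @param label Character vector of diagnosis codes.
#' @return Logical vector.
#' @export
is_malignant <- function(label) {
  stopifnot(all(label %in% diagnosis_labels()))
  label %in% malignant_labels()
}

#' Management actions and safety ranks
#'
#' Actions are ordered by increasing invasiveness ("safety rank"):
#' DISMISS (0) < MONITOR (1) < TREAT_LOCALLY (2) < EXCISE (3). Ties between
#' equal Q-values or expected rewards are broken toward the higher safety
#' rank, i.e. toward the more cautious action.
#'
#' @return Named integer vector mapping action code to safety rank.
#' @export
management_actions <- function() {
  c(DISMISS = 0L, MONITOR = 1L, TREAT_LOCALLY = 2L, EXCISE = 3L)
}

#' Safety rank of management actions
#'
#' @param action Character vector of action codes.
#' @return Integer vector of safety ranks.
#' @export
safety_rank <- function(action) {
  ranks <- management_actions()
  bad <- setdiff(action, names(ranks))
  if (length(bad) > 0) {
    stop("unknown management action(s): ", paste(bad, collapse = ", "))
  }
  unname(ranks[action])
}

#' Scenario definitions
#'
#' Builds the specification of one of the four supported scenarios:
#' \describe{
#'   \item{diagnosisRL}{actions are the 7 diagnosis labels themselves
#'     (the policy predicts a diagnosis).}
#'   \item{binary}{actions DISMISS / EXCISE.}
#'   \item{multiclass_therapy}{actions DISMISS / TREAT_LOCALLY / EXCISE.}
#'   \item{patient_centered}{actions DISMISS / MONITOR / EXCISE, decided
#'     per lesion within a patient context.}
#' }
#' Management scenarios carry an optimal-action map: excision for melanoma
#' and basal cell carcinoma, local therapy for AKIEC where available
#' (excision otherwise), dismissal for the four benign classes.
#'
#' @param name One of `"diagnosisRL"`, `"binary"`, `"multiclass_therapy"`,
#'   `"patient_centered"`.
#' @return An object of class `scenario_spec`: list with `name`,
#'   `action_set` and (management scenarios) `optimal_action_map`.
#' @export
scenario_spec <- function(name = c("diagnosisRL", "binary",
                                   "multiclass_therapy", "patient_centered")) {
  name <- match.arg(name)
  action_set <- switch(name,
    diagnosisRL        = diagnosis_labels(),
    binary             = c("DISMISS", "EXCISE"),
    multiclass_therapy = c("DISMISS", "TREAT_LOCALLY", "EXCISE"),
    patient_centered   = c("DISMISS", "MONITOR", "EXCISE")
  )
  map <- NULL
  if (name != "diagnosisRL") {
    akiec <- if ("TREAT_LOCALLY" %in% action_set) "TREAT_LOCALLY" else "EXCISE"
    map <- c(MEL = "EXCISE", BCC = "EXCISE", AKIEC = akiec,
             BKL = "DISMISS", NV = "DISMISS", DF = "DISMISS",
             VASC = "DISMISS")
  }
  structure(list(name = name, action_set = action_set,
                 optimal_action_map = map),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$name, "\n  actions:",
      paste(x$action_set, collapse = ", "), "\n")
  invisible(x)
}

#' Optimal management for a diagnosis under a scenario
#'
#' MEL and BCC map to EXCISE; AKIEC maps to TREAT_LOCALLY where the
#' scenario offers it, otherwise EXCISE; every benign diagnosis maps to
#' DISMISS.
#'
#' @param d Character vector of diagnosis codes.
#' @param scenario A [scenario_spec()] with a management action set.
#' @return Character vector of action codes.
#' @export
optimal_management <- function(d, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (scenario$name == "diagnosisRL") {
    stop("the diagnosisRL scenario has no management mapping")
  }
  stopifnot(all(d %in% diagnosis_labels()))
  unname(scenario$optimal_action_map[d])
}

# -- probability vectors ------------------------------------------------

#' Validate a 7-class probability vector or matrix
#'
#' @param p Numeric vector of length 7 or matrix with 7 columns
#'   (canonical class order).
#' @param tol Allowed deviation of each row sum from 1.
#' @return `p` as a matrix with canonical column names, invisibly checked.
#' @keywords internal
as_prob_matrix <- function(p, tol = 1e-6) {
  if (is.data.frame(p)) p <- prob_matrix(p)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) != 7) stop("probability input must have 7 columns")
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("invalid distribution: negative or non-finite probabilities")
  }
  s <- rowSums(p)
  if (any(abs(s - 1) > tol)) {
    stop("invalid distribution: row sums deviate from 1 by more than ", tol)
  }
  colnames(p) <- diagnosis_labels()
  p
}

#' Overall malignancy probability
#'
#' Sum of the melanoma, basal cell carcinoma and AKIEC probabilities.
#'
#' @param p Probability vector of length 7, matrix with 7 columns, or a
#'   lesion table with `p_*` columns; canonical class order.
#' @return Numeric vector of malignancy probabilities.
#' @export
malignancy_probability <- function(p) {
  p <- as_prob_matrix(p)
  unname(rowSums(p[, malignant_labels(), drop = FALSE]))
}

# -- reward tables ------------------------------------------------------

canonical_col_order <- function(cols) {
  if (all(cols %in% diagnosis_labels())) {
    intersect(diagnosis_labels(), cols)
  } else if (all(cols %in% names(management_actions()))) {
    intersect(names(management_actions()), cols)
  } else {
    stop("unknown column label(s): ",
         paste(setdiff(cols, c(diagnosis_labels(),
                               names(management_actions()))), collapse = ", "))
  }
}

#' Construct a reward table
#'
#' A reward table assigns a real-valued reward (benefit) or penalty to each
#' combination of true diagnosis (rows) and predicted diagnosis or
#' management action (columns). Penalties are asymmetric by design:
#' overlooking a melanoma typically carries a far larger penalty than
#' excising a nevus.
#'
#' @param values Numeric matrix, `length(row_labels)` x `length(col_labels)`.
#' @param row_labels Ground-truth diagnosis codes (default: all 7).
#' @param col_labels Prediction or action codes; must be entirely diagnosis
#'   codes or entirely management-action codes.
#' @param provenance Free-text origin of the table (e.g. an expert id).
#' @return Object of class `reward_table`, rows and columns canonicalized
#'   to the fixed orders.
#' @export
reward_table <- function(values, row_labels = diagnosis_labels(),
                         col_labels, provenance = "") {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("reward table entries must be finite numbers")
  }
  if (nrow(values) != length(row_labels) ||
      ncol(values) != length(col_labels)) {
    stop("reward table shape does not match its labels")
  }
  bad <- setdiff(row_labels, diagnosis_labels())
  if (length(bad) > 0) stop("unknown row label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels)) {
    stop("duplicated labels in reward table")
  }
  col_order <- canonical_col_order(col_labels)
  row_order <- intersect(diagnosis_labels(), row_labels)
  dimnames(values) <- list(row_labels, col_labels)
  values <- values[row_order, col_order, drop = FALSE]
  structure(list(values = values, provenance = provenance),
            class = "reward_table")
}

#' @export
print.reward_table <- function(x, ...) {
  cat("<reward_table>", if (nzchar(x$provenance)) paste0("(", x$provenance, ")"),
      "\n")
  print(x$values)
  invisible(x)
}

reward_rows <- function(rt) rownames(rt$values)
reward_cols <- function(rt) colnames(rt$values)

check_expected_columns <- function(cols, expected_columns) {
  if (!is.null(expected_columns) && !setequal(cols, expected_columns)) {
    stop("scenario mismatch: reward-table columns {",
         paste(sort(cols), collapse = ", "), "} do not match expected {",
         paste(sort(expected_columns), collapse = ", "), "}")
  }
}

#' Read a reward table from CSV or JSON
#'
#' CSV layout: header row of column labels, first field of each row a
#' ground-truth diagnosis code. JSON layout: object with fields
#' `row_labels`, `col_labels`, `values` (row-major nested array) and
#' optional `provenance`.
#'
#' @param source Path to a `.csv` or `.json` file.
#' @param expected_columns Optional label set; a mismatch with the file's
#'   columns raises a scenario-mismatch error.
#' @param provenance Overrides the provenance recorded in the object.
#' @return A [reward_table()].
#' @export
load_reward_table <- function(source, expected_columns = NULL,
                              provenance = NULL) {
  if (!file.exists(source)) stop("no such file: ", source)
  if (grepl("\\.json$", source, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(source, simplifyVector = TRUE)
    vals <- obj$values
    if (is.list(vals)) vals <- do.call(rbind, vals)
    vals <- as.matrix(vals)
    if (!is.numeric(vals) || anyNA(vals)) {
      stop("parse error: non-numeric or missing reward cell in ", source)
    }
    rt <- reward_table(vals, row_labels = obj$row_labels,
                       col_labels = obj$col_labels,
                       provenance = provenance %||% (obj$provenance %||% source))
  } else {
    df <- utils::read.csv(source, check.names = FALSE, stringsAsFactors = FALSE)
    rows <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    if (anyNA(vals)) {
      stop("parse error: non-numeric or missing reward cell in ", source)
    }
    rt <- reward_table(vals, row_labels = rows,
                       col_labels = colnames(df)[-1],
                       provenance = provenance %||% source)
  }
  check_expected_columns(reward_cols(rt), expected_columns)
  rt
}

#' Write a reward table to CSV or JSON
#'
#' Values are written with full double precision so that a write/load
#' round-trip is bit-exact.
#'
#' @param rt A [reward_table()].
#' @param path Destination `.csv` or `.json` file.
#' @return `path`, invisibly.
#' @export
write_reward_table <- function(rt, path) {
  stopifnot(inherits(rt, "reward_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(row_labels = reward_rows(rt), col_labels = reward_cols(rt),
                values = rt$values, provenance = rt$provenance)
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                         matrix = "rowmajor")
  } else {
    vals <- apply(rt$values, c(1, 2), function(v) sprintf("%.17g", v))
    df <- data.frame(label = reward_rows(rt), vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- ""
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# -- threshold specifications -------------------------------------------

#' Construct a threshold specification
#'
#' Probability cut-offs that drive the preference-based threshold
#' hierarchy: the melanoma-probability excision cut-off is consulted first,
#' then the overall-malignancy cut-off, then basal cell carcinoma, then the
#' AKIEC local-therapy cut-off; in the patient-centered scenario a lesion
#' whose malignancy probability exceeds the `monitor` cut-off (but no
#' excision cut-off) is monitored. A cut-off left `NA` disables its rule.
#'
#' @param melanoma_excise,malignancy_excise,bcc_excise,akiec_local,monitor
#'   Probabilities in `[0, 1]` or `NA`.
#' @param fallback_action Action taken when no cut-off is exceeded
#'   (default DISMISS).
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(melanoma_excise = NA_real_,
                           malignancy_excise = NA_real_,
                           bcc_excise = NA_real_,
                           akiec_local = NA_real_,
                           monitor = NA_real_,
                           fallback_action = "DISMISS") {
  vals <- c(melanoma_excise = melanoma_excise,
            malignancy_excise = malignancy_excise,
            bcc_excise = bcc_excise,
            akiec_local = akiec_local,
            monitor = monitor)
  ok <- is.na(vals) | (vals >= 0 & vals <= 1)
  if (!all(ok)) {
    stop("thresholds must lie in [0, 1]: ",
         paste(names(vals)[!ok], collapse = ", "))
  }
  if (!is.na(monitor) && !is.na(malignancy_excise) &&
      monitor > malignancy_excise) {
    stop("monitor cut-off must not exceed the malignancy excision cut-off")
  }
  stopifnot(fallback_action %in% names(management_actions()))
  structure(c(as.list(vals), list(fallback_action = fallback_action)),
            class = "threshold_spec")
}

threshold_fields <- function() {
  c("melanoma_excise", "malignancy_excise", "bcc_excise",
    "akiec_local", "monitor")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("<threshold_spec>\n")
  for (f in threshold_fields()) {
    cat(sprintf("  %-18s %s\n", f,
                if (is.na(x[[f]])) "(disabled)" else format(x[[f]])))
  }
  cat("  fallback:", x$fallback_action, "\n")
  invisible(x)
}

#' Read threshold specifications from CSV or JSON
#'
#' CSV: header of field names, one row per expert. JSON: a single object
#' or an array of objects keyed by field name. Always returns a list, one
#' [threshold_spec()] per expert; aggregate with
#' [aggregate_expert_inputs()].
#'
#' @param source Path to a `.csv` or `.json` file.
#' @return List of `threshold_spec` objects.
#' @export
load_threshold_specs <- function(source) {
  if (!file.exists(source)) stop("no such file: ", source)
  if (grepl("\\.json$", source, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(source, simplifyVector = FALSE)
    if (!is.null(names(obj))) obj <- list(obj)
    rows <- lapply(obj, function(o) as.data.frame(o, stringsAsFactors = FALSE))
    df <- do.call(rbind, lapply(rows, function(r) {
      for (f in threshold_fields()) if (is.null(r[[f]])) r[[f]] <- NA_real_
      r[, c(threshold_fields(),
            intersect("fallback_action", names(r))), drop = FALSE]
    }))
  } else {
    df <- utils::read.csv(source, stringsAsFactors = FALSE)
  }
  bad <- setdiff(names(df), c(threshold_fields(), "fallback_action", "expert"))
  if (length(bad) > 0) stop("unknown threshold field(s): ",
                            paste(bad, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    args <- as.list(df[i, intersect(threshold_fields(), names(df)),
                       drop = FALSE])
    args <- lapply(args, as.numeric)
    if ("fallback_action" %in% names(df)) {
      args$fallback_action <- df$fallback_action[i]
    }
    do.call(threshold_spec, args)
  })
}

# -- expert aggregation -------------------------------------------------

#' Aggregate expert reward tables or threshold specifications
#'
#' Cell-wise (reward tables) or field-wise (threshold specs) median or
#' minimum across experts. The median of an even number of experts is the
#' midpoint of the two central values. The minimum variant implements the
#' low-threshold policy configuration.
#'
#' @param inputs Non-empty list of [reward_table()] objects with identical
#'   labels, or of [threshold_spec()] objects with identical defined
#'   fields.
#' @param method `"median"` or `"minimum"`.
#' @return A single aggregated object of the same class.
#' @export
aggregate_expert_inputs <- function(inputs, method = c("median", "minimum")) {
  method <- match.arg(method)
  if (!is.list(inputs) || length(inputs) == 0) {
    stop("need a non-empty list of expert inputs")
  }
  agg <- if (method == "median") stats::median else min
  if (inherits(inputs[[1]], "reward_table")) {
    ok <- vapply(inputs, inherits, logical(1), "reward_table")
    if (!all(ok)) stop("mixed input types")
    r0 <- reward_rows(inputs[[1]]); c0 <- reward_cols(inputs[[1]])
    for (rt in inputs[-1]) {
      if (!identical(reward_rows(rt), r0) || !identical(reward_cols(rt), c0)) {
        stop("expert reward tables have mismatched shapes or labels")
      }
    }
    stack <- array(unlist(lapply(inputs, function(rt) rt$values)),
                   dim = c(length(r0), length(c0), length(inputs)))
    vals <- apply(stack, c(1, 2), agg)
    reward_table(vals, row_labels = r0, col_labels = c0,
                 provenance = sprintf("%s of %d expert tables",
                                      method, length(inputs)))
  } else if (inherits(inputs[[1]], "threshold_spec")) {
    ok <- vapply(inputs, inherits, logical(1), "threshold_spec")
    if (!all(ok)) stop("mixed input types")
    fields <- threshold_fields()
    def0 <- vapply(fields, function(f) !is.na(inputs[[1]][[f]]), logical(1))
    out <- list()
    for (f in fields) {
      vals <- vapply(inputs, function(t) t[[f]], numeric(1))
      def <- !is.na(vals)
      if (any(def) && !all(def)) {
        stop("field ", f, " defined for some experts but not others")
      }
      out[[f]] <- if (all(def)) agg(vals) else NA_real_
    }
    out$fallback_action <- inputs[[1]]$fallback_action
    do.call(threshold_spec, out)
  } else {
    stop("inputs must be reward tables or threshold specs")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
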