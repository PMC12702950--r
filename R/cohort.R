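#' Construct a cohort table from a data frame
#'
#' A cohort is a tibble with one row per athlete: the schema's feature
#' columns in schema order, then the optional columns `event_label`
#' (binary adverse-event outcome), `true_state` (latent state label, only
#' meaningful for synthetic cohorts) and `athlete_id`. The schema travels
#' with the tibble as an attribute so downstream calls never need it
#' re-supplied.
#'
#' @param data A data frame holding at least the schema's feature columns.
#' @param schema A `cs_schema` describing the feature blocks.
#' @return A `cs_cohort` tibble.
#' @export
as_cohort <- function(data, schema) {
  stopifnot(inherits(schema, "cs_schema"))
  data <- as_tibble(data)
  missing_cols <- setdiff(schema$column_names, names(data))
  if (length(missing_cols)) {
    cs_abort_data(sprintf(
      "cohort is missing feature column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in schema$column_names) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      cs_abort_data(sprintf("feature column `%s` is not numeric", col))
    }
    if (any(!is.finite(v))) {
      cs_abort_data(sprintf(
        "feature column `%s` has a non-finite value at row %d",
        col, which(!is.finite(v))[[1]]
      ))
    }
  }
  extra <- intersect(c("event_label", "true_state", "athlete_id"), names(data))
  if ("event_label" %in% extra) {
    y <- data$event_label
    if (!all(y %in% c(0, 1) | is.na(y))) {
      cs_abort_data("`event_label` must be 0/1 where present")
    }
    data$event_label <- as.integer(y)
  }
  if ("athlete_id" %in% extra) {
    data$athlete_id <- as.character(data$athlete_id)
    if (anyDuplicated(data$athlete_id)) cs_abort_data("athlete_ids must be unique")
  } else {
    data$athlete_id <- sprintf("ath_%05d", seq_len(nrow(data)))
    extra <- c(extra, "athlete_id")
  }
  if ("true_state" %in% extra) data$true_state <- as.character(data$true_state)
  out <- data[, c(schema$column_names,
                  intersect(c("event_label", "true_state", "athlete_id"),
                            names(data)))]
  attr(out, "schema") <- schema
  class(out) <- c("cs_cohort", class(out))
  out
}

#' Retrieve the schema attached to a cohort
#' @param cohort A `cs_cohort`.
#' @return The `cs_schema` the cohort was built with.
#' @export
cohort_schema <- function(cohort) {
  sch <- attr(cohort, "schema")
  if (is.null(sch)) cs_abort_data("object carries no feature schema")
  sch
}

# n x d numeric matrix of the feature columns, schema order
cohort_matrix <- function(cohort, schema = cohort_schema(cohort)) {
  as.matrix(cohort[, schema$column_names, drop = FALSE])
}

#' Read and write cohort files
#'
#' Cohorts are stored as plain comma-delimited text with a header row: the
#' schema's feature columns first (in schema order), then whichever of
#' `event_label`, `true_state`, `athlete_id` are present. `write_cohort()`
#' and `read_cohort()` are exact inverses, and writing is deterministic, so
#' write/read/write produces byte-identical files.
#'
#' @param path File path of the delimited text file.
#' @param schema A `cs_schema`; the file's feature columns must match it.
#' @param cohort A `cs_cohort`.
#' @return `read_cohort()` returns a `cs_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path, schema) {
  if (!file.exists(path)) cs_abort_data(sprintf("no such cohort file: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(schema$column_names, names(raw))
  if (length(missing_cols)) {
    cs_abort_data(sprintf(
      "cohort file is missing feature column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in schema$column_names) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad)) {
      cs_abort_data(sprintf(
        "non-numeric value in column `%s` at row %d", col, bad[[1]]
      ))
    }
    if (anyNA(parsed)) {
      cs_abort_data(sprintf(
        "missing feature value in column `%s` at row %d", col, which(is.na(parsed))[[1]]
      ))
    }
    raw[[col]] <- parsed
  }
  if ("event_label" %in% names(raw)) {
    raw$event_label <- as.integer(raw$event_label)
  }
  as_cohort(raw, schema)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  schema <- cohort_schema(cohort)
  cols <- c(schema$column_names,
            intersect(c("event_label", "true_state", "athlete_id"), names(cohort)))
  out <- as_tibble(cohort)[, cols]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Evaluate compatibility rules over a cohort
#'
#' The compatibility constraint \eqn{C(x, z)} gates each latent state on
#' clinical plausibility: an athlete is compatible with a state iff every
#' threshold test in that state's rule holds. States with no rule are
#' compatible by default, so an empty rule set yields an all-ones mask.
#'
#' @param data A `cs_cohort`, a plain data frame with the schema's feature
#'   columns, or a single named numeric vector.
#' @param rules A `cs_rules` tibble (may be empty).
#' @param states A `cs_states` state space.
#' @param schema Optional schema; defaults to the one attached to `data`.
#' @return An `n x |Z|` integer matrix of 0/1 entries with states as
#'   columns.
#' @examples
#' sch <- feature_schema(c(h = 1, f = 1, e = 2, s = 1, m = 1))
#' st <- latent_states(c("normal", "pathological"), c(0.01, 0.3))
#' ru <- compat_rules(data.frame(
#'   state = "pathological", column = "e_2", op = ">", value = 0.2
#' ), sch)
#' x <- stats::setNames(c(0, 0, 0.1, 0, 0), sch$column_names)
#' compatibility_mask(x, ru, st, sch)
#' @export
compatibility_mask <- function(data, rules, states, schema = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- as_tibble(as.list(data))
  }
  if (is.null(schema)) schema <- attr(data, "schema")
  nz <- n_states(states)
  n <- nrow(data)
  mask <- matrix(1L, n, nz, dimnames = list(NULL, states$state))
  if (nrow(rules) == 0) return(mask)
  bad_states <- setdiff(unique(rules$state), states$state)
  if (length(bad_states)) {
    cs_abort_config(sprintf(
      "rules reference unknown state(s): %s", paste(bad_states, collapse = ", ")
    ))
  }
  if (!is.null(schema)) schema_column_index(schema, unique(rules$column))
  missing_cols <- setdiff(unique(rules$column), names(data))
  if (length(missing_cols)) {
    cs_abort_data(sprintf(
      "rules reference absent column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  for (i in seq_len(nrow(rules))) {
    j <- match(rules$state[[i]], states$state)
    v <- data[[rules$column[[i]]]]
    holds <- switch(rules$op[[i]],
      "<" = v < rules$value[[i]],
      ">" = v > rules$value[[i]],
      "<=" = v <= rules$value[[i]],
      ">=" = v >= rules$value[[i]]
    )
    mask[, j] <- mask[, j] * as.integer(holds)
  }
  mask
}

#' Evaluate guideline prior indicators
#'
#' Guideline priors are indicator functions of conjunctions of threshold
#' tests over feature columns -- e.g. an ECG feature exceeding a
#' guideline-based cutoff while an echocardiographic feature stays below
#' another. They share the rule format, with `state` playing the role of
#' the indicator's name; they feed reporting and the construction of
#' compatibility rules.
#'
#' @param data A cohort, data frame of features, or named numeric vector.
#' @param priors A `cs_rules`-shaped tibble; rows sharing a `state` name
#'   are conjoined into one indicator.
#' @param schema Optional schema for column validation.
#' @return An `n x K` integer matrix, one column per indicator; `K = 0`
#'   columns for an empty prior set.
#' @export
evaluate_guideline_priors <- function(data, priors, schema = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- as_tibble(as.list(data))
  }
  if (is.null(schema)) schema <- attr(data, "schema")
  priors <- as_tibble(priors)
  n <- nrow(data)
  if (nrow(priors) == 0) {
    return(matrix(integer(0), nrow = n, ncol = 0))
  }
  if (!is.null(schema)) schema_column_index(schema, unique(priors$column))
  ids <- unique(priors$state)
  out <- matrix(1L, n, length(ids), dimnames = list(NULL, ids))
  for (i in seq_len(nrow(priors))) {
    j <- match(priors$state[[i]], ids)
    v <- data[[priors$column[[i]]]]
    holds <- switch(priors$op[[i]],
      "<" = v < priors$value[[i]],
      ">" = v > priors$value[[i]],
      "<=" = v <= priors$value[[i]],
      ">=" = v >= priors$value[[i]]
    )
    out[, j] <- out[, j] * as.integer(holds)
  }
  out
}
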