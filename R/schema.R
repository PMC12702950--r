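#' Define the block structure of an athlete feature vector
#'
#' An athlete profile is a numeric vector partitioned into five named blocks:
#' hereditary/family history (`h`), physical examination (`f`), ECG (`e`),
#' echocardiography (`s`) and metadata such as age, sex and training load
#' (`m`). The schema records the block sizes and the per-feature column
#' names used throughout cohort files, compatibility rules and models.
#'
#' Default column names are `"<block>_<i>"` with `i` counted 1-based within
#' each block, so `"e_12"` is the 12th ECG feature.
#'
#' @param blocks Named integer vector of block sizes, e.g.
#'   `c(h = 3, f = 3, e = 8, s = 4, m = 2)`. Every block must be nonempty.
#' @param column_names Optional character vector of length `sum(blocks)`
#'   overriding the default names. Must be unique.
#'
#' @return A `cs_schema` object with fields `block_names`, `block_sizes`,
#'   `column_names` and `total_dim`.
#' @examples
#' sch <- feature_schema(c(h = 2, f = 2, e = 3, s = 2, m = 1))
#' sch$total_dim
#' @export
feature_schema <- function(blocks, column_names = NULL) {
  if (is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    cs_abort_config("`blocks` must be a named vector of block sizes")
  }
  sizes <- as.integer(blocks)
  if (any(is.na(sizes)) || any(sizes < 1L)) {
    cs_abort_config("every block must have a positive integer size")
  }
  if (anyDuplicated(names(blocks))) {
    cs_abort_config("block names must be unique")
  }
  d <- sum(sizes)
  if (is.null(column_names)) {
    column_names <- unlist(purrr::map2(
      names(blocks), sizes,
      function(b, k) paste0(b, "_", seq_len(k))
    ), use.names = FALSE)
  }
  if (length(column_names) != d || anyDuplicated(column_names)) {
    cs_abort_config("`column_names` must be unique and match the total dimension")
  }
  structure(
    list(
      block_names = names(blocks),
      block_sizes = setNames(sizes, names(blocks)),
      column_names = column_names,
      total_dim = d
    ),
    class = "cs_schema"
  )
}

#' @export
print.cs_schema <- function(x, ...) {
  cat("<feature schema> d =", x$total_dim, "\n")
  for (b in x$block_names) {
    cat(sprintf("  %s: %d features\n", b, x$block_sizes[[b]]))
  }
  invisible(x)
}

# block id of every column, aligned with schema$column_names
schema_blocks_of_columns <- function(schema) {
  rep(schema$block_names, schema$block_sizes)
}

schema_column_index <- function(schema, column) {
  idx <- match(column, schema$column_names)
  if (anyNA(idx)) {
    cs_abort_config(sprintf(
      "unknown feature column(s): %s",
      paste(column[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}

#' Serialize or restore a feature schema
#'
#' Schemas are stored as small YAML documents listing the block sizes and
#' column names, alongside cohort files.
#'
#' @param schema A `cs_schema`.
#' @param path File path.
#' @return `write_schema()` returns `path` invisibly; `read_schema()` the
#'   restored `cs_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "cs_schema"))
  yaml::write_yaml(
    list(
      blocks = as.list(schema$block_sizes),
      column_names = schema$column_names
    ),
    path
  )
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$blocks)) cs_abort_config("schema file lacks a `blocks` field")
  feature_schema(
    unlist(doc$blocks),
    column_names = if (!is.null(doc$column_names)) as.character(doc$column_names)
  )
}

#' Define the latent clinical state space
#'
#' Screening reasons over a small ordered set of latent clinical states --
#' canonically "normal", "physiological remodeling", "borderline abnormality"
#' and "pathological". Each state carries an event prior \eqn{\pi(z)}, the
#' probability of a cardiovascular adverse event conditional on the state,
#' and an exertion-adjusted risk level \eqn{\rho(z)} used by the embedding
#' layer's risk score. Both live in \eqn{[0, 1]}.
#'
#' @param labels Character vector of unique state names, in order.
#' @param event_prior Numeric vector of per-state event probabilities.
#' @param exertion_risk Numeric vector of per-state exertion risk levels;
#'   defaults to `event_prior`.
#' @return A `cs_states` tibble with columns `state`, `event_prior`,
#'   `exertion_risk`.
#' @examples
#' latent_states(c("normal", "pathological"), c(0.01, 0.30))
#' @export
latent_states <- function(labels, event_prior, exertion_risk = event_prior) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) cs_abort_config("state labels must be unique")
  if (length(event_prior) != length(labels) ||
      length(exertion_risk) != length(labels)) {
    cs_abort_config("`event_prior` and `exertion_risk` must match the number of states")
  }
  if (any(event_prior < 0 | event_prior > 1) ||
      any(exertion_risk < 0 | exertion_risk > 1)) {
    cs_abort_config("state priors and exertion risks must lie in [0, 1]")
  }
  out <- tibble(
    state = labels,
    event_prior = as.numeric(event_prior),
    exertion_risk = as.numeric(exertion_risk)
  )
  class(out) <- c("cs_states", class(out))
  out
}

n_states <- function(states) nrow(states)

state_index <- function(states, label) {
  idx <- match(label, states$state)
  if (anyNA(idx)) {
    cs_abort_data(sprintf(
      "unknown state label(s): %s",
      paste(unique(label[is.na(idx)]), collapse = ", ")
    ))
  }
  idx
}

#' Clinical compatibility rules
#'
#' A compatibility rule gates a latent state on a conjunction of threshold
#' tests over named feature columns: a profile is compatible with a state
#' only if every test of that state's rule holds. States without a rule are
#' compatible by default. Comparators are taken literally, so ties at a
#' strict threshold fail the test.
#'
#' @param rules A data frame with columns `state`, `column`,
#'   `op` (one of `"<"`, `">"`, `"<="`, `">="`) and `value`, one row per
#'   threshold test; tests sharing a `state` are conjoined.
#' @param schema Optional `cs_schema`; when given, referenced columns are
#'   validated against it at construction.
#' @return A `cs_rules` tibble.
#' @examples
#' sch <- feature_schema(c(h = 1, f = 1, e = 12, s = 3, m = 1))
#' compat_rules(
#'   data.frame(state = "pathological", column = "e_12", op = ">", value = 0.2),
#'   schema = sch
#' )
#' @export
compat_rules <- function(rules, schema = NULL) {
  rules <- as_tibble(rules)
  needed <- c("state", "column", "op", "value")
  if (!all(needed %in% names(rules))) {
    cs_abort_config("rules need columns state, column, op, value")
  }
  if (nrow(rules) == 0) {
    out <- tibble(
      state = character(), column = character(),
      op = character(), value = numeric()
    )
    class(out) <- c("cs_rules", class(out))
    return(out)
  }
  ok_ops <- c("<", ">", "<=", ">=")
  if (!all(rules$op %in% ok_ops)) {
    cs_abort_config("rule comparators must be one of <, >, <=, >=")
  }
  if (!is.numeric(rules$value) || any(!is.finite(rules$value))) {
    cs_abort_config("rule thresholds must be finite numbers")
  }
  if (!is.null(schema)) schema_column_index(schema, unique(rules$column))
  out <- select(rules, dplyr::all_of(needed))
  class(out) <- c("cs_rules", class(out))
  out
}

#' Read or write compatibility rules as YAML
#'
#' The on-disk form is a list of `{state, tests: [{column, op, value}]}`
#' entries, one per state.
#'
#' @param rules A `cs_rules` tibble.
#' @param path File path.
#' @param schema Optional schema used to validate columns on read.
#' @return `read_rules()` returns a `cs_rules` tibble.
#' @export
write_rules <- function(rules, path) {
  split_rules <- split(rules, rules$state)
  doc <- unname(purrr::map(split_rules, function(r) {
    list(
      state = r$state[[1]],
      tests = purrr::pmap(
        list(r$column, r$op, r$value),
        function(column, op, value) list(column = column, op = op, value = value)
      )
    )
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path, schema = NULL) {
  doc <- yaml::read_yaml(path)
  rows <- purrr::map_dfr(doc, function(entry) {
    if (is.null(entry$state) || is.null(entry$tests) || !length(entry$tests)) {
      cs_abort_config("each rule entry needs a state and at least one test")
    }
    purrr::map_dfr(entry$tests, function(tst) {
      tibble(
        state = entry$state,
        column = as.character(tst$column),
        op = as.character(tst$op),
        value = as.numeric(tst$value)
      )
    })
  })
  compat_rules(rows, schema = schema)
}
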