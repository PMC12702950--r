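#' Direct logistic risk baseline (latent-layer ablation)
#'
#' The `no_latent` ablation bypasses the latent-state machinery entirely
#' and regresses the adverse-event label directly on the features with a
#' plain logistic model. Used to quantify what the structured layers add.
#'
#' @param cohort A `cs_cohort` with `event_label`.
#' @return A `cs_logistic_model` wrapping the [stats::glm()] fit.
#' @export
fit_logistic_baseline <- function(cohort) {
  if (!"event_label" %in% names(cohort) || anyNA(cohort$event_label)) {
    cs_abort_data("the logistic baseline needs complete `event_label`s")
  }
  schema <- cohort_schema(cohort)
  df <- as.data.frame(cohort_matrix(cohort, schema))
  df$.y <- cohort$event_label
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  structure(
    list(coef = stats::coef(fit), schema = schema),
    class = "cs_logistic_model"
  )
}

#' @rdname fit_logistic_baseline
#' @param model A `cs_logistic_model`.
#' @param data Cohort or feature matrix to score.
#' @return `predict_logistic_baseline()` returns per-athlete event
#'   probabilities.
#' @export
predict_logistic_baseline <- function(model, data) {
  X <- features_as_matrix(data, model$schema)
  beta <- model$coef
  beta[is.na(beta)] <- 0
  eta <- beta[[1]] + as.vector(X %*% beta[-1])
  stats::plogis(eta)
}

write_logistic_model <- function(model, path) {
  doc <- list(
    type = "cs_logistic_model",
    coef = as.numeric(ifelse(is.na(model$coef), 0, model$coef)),
    terms = names(model$coef),
    schema = list(blocks = as.list(model$schema$block_sizes),
                  column_names = model$schema$column_names)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_logistic_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "cs_logistic_model")) {
    cs_abort_data("file is not a serialized logistic baseline")
  }
  structure(
    list(
      coef = setNames(as.numeric(doc$coef), doc$terms),
      schema = feature_schema(unlist(doc$schema$blocks),
                              doc$schema$column_names)
    ),
    class = "cs_logistic_model"
  )
}
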