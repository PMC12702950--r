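#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise ungroup
#' @importFrom stats rnorm rbinom setNames
NULL

# condition helpers: classed errors so the CLI can map them to exit codes
cs_abort_config <- function(msg, class = NULL) {
  abort(msg, class = c(class, "cs_config_error"))
}
cs_abort_data <- function(msg, class = NULL) {
  abort(msg, class = c(class, "cs_data_error"))
}
cs_abort_numeric <- function(msg, class = NULL) {
  abort(msg, class = c(class, "cs_numeric_error"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Evaluate a function with a locally seeded RNG, restoring the caller's
# RNG state afterwards so package calls never disturb the global stream.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    cs_abort_data(sprintf("non-finite values in %s", what))
  }
  invisible(x)
}
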