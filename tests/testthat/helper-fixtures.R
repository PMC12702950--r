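# small schema / state space / cohort builders used across tests

tiny_schema <- function() {
  feature_schema(c(h = 1, f = 1, e = 2, s = 1, m = 1))
}

four_states <- function() {
  latent_states(
    c("normal", "remodeling", "borderline", "pathological"),
    event_prior = c(0.01, 0.02, 0.10, 0.30),
    exertion_risk = c(0.05, 0.10, 0.40, 0.90)
  )
}

# labeled two-state cohort with class means symmetric about the origin
# (the bilinear scoring function is strictly linear in x, so a
# through-origin boundary must be optimal for the fit examples)
two_state_cohort <- function(n = 500, sep = 4, seed = 42) {
  sch <- tiny_schema()
  st <- latent_states(c("benign", "athigh"), c(0.05, 0.40))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    z <- sample(1:2, n, replace = TRUE)
    X <- matrix(rnorm(n * sch$total_dim), n, sch$total_dim)
    X[, 3] <- X[, 3] + ifelse(z == 2, sep / 2, -sep / 2)
    colnames(X) <- sch$column_names
    df <- tibble::as_tibble(as.data.frame(X))
    df$true_state <- st$state[z]
    list(cohort = as_cohort(df, sch), states = st, z = z)
  })
}

# independent oracle for the capped sparsemax: enumerate every feasible
# support of size <= s, solve the equality-constrained minimizer on it,
# and keep the best feasible solution
sparsemax_qp_oracle <- function(scores, s, mask = rep(1, length(scores))) {
  alive <- which(mask > 0)
  best_obj <- -Inf
  best_q <- NULL
  for (size in seq_len(min(s, length(alive)))) {
    # note: combn() treats a scalar first argument as 1:n
    supports <- if (length(alive) == 1) list(alive) else
      utils::combn(alive, size, simplify = FALSE)
    for (S in supports) {
      z <- scores[S]
      q_S <- z + (1 - sum(z)) / length(S)
      if (any(q_S < -1e-12)) next
      q <- numeric(length(scores))
      q[S] <- pmax(q_S, 0)
      obj <- sum(q * scores) - 0.5 * sum(q^2)
      if (obj > best_obj + 1e-15) {
        best_obj <- obj
        best_q <- q
      }
    }
  }
  best_q
}

# subset a cohort preserving its class and schema
cohort_slice <- function(cohort, idx) {
  out <- cohort[idx, ]
  attr(out, "schema") <- attr(cohort, "schema")
  class(out) <- class(cohort)
  out
}
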