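#' Low-rank bilinear scoring model
#'
#' The scoring function \eqn{F(x, z_j) = x^\top U V_{j\cdot}} couples an
#' athlete's feature vector with each latent state through a rank-`r`
#' factorization \eqn{\Theta = U V^\top} of the joint parameter matrix.
#' The low rank ties states together so that under-observed states borrow
#' strength from related ones.
#'
#' @param U `d x r` numeric matrix.
#' @param V `|Z| x r` numeric matrix (one row per state).
#' @param states A `cs_states` state space (row order of `V`).
#' @param schema Optional `cs_schema` the model was built against.
#' @return A `cs_scoring_model`.
#' @export
scoring_model <- function(U, V, states, schema = NULL) {
  U <- as.matrix(U); V <- as.matrix(V)
  if (ncol(U) != ncol(V)) cs_abort_config("U and V must share the rank dimension")
  if (nrow(V) != n_states(states)) {
    cs_abort_config("V must have one row per latent state")
  }
  r <- ncol(U)
  if (r > min(nrow(U), nrow(V))) {
    cs_abort_config("rank must not exceed min(d, |Z|)")
  }
  assert_finite(U, "U"); assert_finite(V, "V")
  structure(
    list(U = U, V = V, rank = r, states = states$state, schema = schema),
    class = "cs_scoring_model"
  )
}

#' @export
print.cs_scoring_model <- function(x, ...) {
  cat(sprintf("<scoring model> d = %d, |Z| = %d, rank = %d\n",
              nrow(x$U), nrow(x$V), x$rank))
  if (!is.null(x$fit)) {
    cat(sprintf("  fitted: %d iteration(s), final loss %.6f\n",
                x$fit$iterations, x$fit$loss))
  }
  invisible(x)
}

#' Score every latent state for a set of athletes
#'
#' Evaluates the bilinear scores \eqn{(x^\top U) V^\top}, linear in the
#' features.
#'
#' @param data A `cs_cohort`, a data frame with the model's feature
#'   columns, a numeric matrix (`n x d`), or a single numeric vector.
#' @param model A `cs_scoring_model`.
#' @return An `n x |Z|` numeric matrix of scores with states as columns.
#' @export
score_states <- function(data, model) {
  X <- features_as_matrix(data, model$schema)
  if (ncol(X) != nrow(model$U)) {
    cs_abort_data(sprintf(
      "feature dimension %d does not match model dimension %d",
      ncol(X), nrow(model$U)
    ))
  }
  S <- (X %*% model$U) %*% t(model$V)
  colnames(S) <- model$states
  S
}

features_as_matrix <- function(data, schema = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    matrix(data, nrow = 1)
  } else if (is.matrix(data)) {
    data
  } else {
    sch <- attr(data, "schema") %||% schema
    if (is.null(sch)) {
      as.matrix(as_tibble(data)[, vapply(data, is.numeric, logical(1))])
    } else {
      cohort_matrix(data, sch)
    }
  }
}

# penalized multinomial surrogate: mean log softmax prob of the labeled
# state minus (lambda/2) * ||Theta||_F^2.  Concave in Theta.
surrogate_objective <- function(Theta, X, y_idx, lambda) {
  S <- X %*% Theta
  m <- apply(S, 1, max)
  lse <- m + log(rowSums(exp(S - m)))
  ll <- mean(S[cbind(seq_len(nrow(X)), y_idx)] - lse)
  ll - lambda / 2 * sum(Theta^2)
}

surrogate_grad_Theta <- function(Theta, X, y_idx, lambda) {
  n <- nrow(X)
  S <- X %*% Theta
  P <- exp(S - apply(S, 1, max))
  P <- P / rowSums(P)
  Y <- matrix(0, n, ncol(Theta))
  Y[cbind(seq_len(n), y_idx)] <- 1
  crossprod(X, Y - P) / n - lambda * Theta
}

#' Fit the low-rank scoring model on a labeled cohort
#'
#' Maximizes the mean log softmax probability of each athlete's labeled
#' latent state under the bilinear scores, with a ridge penalty
#' \eqn{\tfrac\lambda2 \|UV^\top\|_F^2}, by gradient ascent with
#' backtracking line search from a seeded random start. The softmax is a
#' smooth surrogate for the piecewise-linear sparsemax used at inference
#' time; the fitted \eqn{\Theta = UV^\top} then drives the capped sparse
#' posterior. Accepted steps never decrease the objective, so the recorded
#' loss trace (negative objective) is monotone non-increasing.
#'
#' With `rank = NULL` the unfactorized matrix \eqn{\Theta} is optimized
#' directly (the problem is then concave); this dense fit is the reference
#' the full-rank factorized fit reproduces.
#'
#' @param cohort A labeled `cs_cohort`: every row must carry `true_state`.
#' @param states A `cs_states` state space.
#' @param rank Factorization rank `r <= min(d, |Z|)`, or `NULL` for a
#'   dense fit.
#' @param lambda Ridge weight on \eqn{\|\Theta\|_F^2} (default `1e-3`).
#' @param max_iter Iteration budget.
#' @param tol Stop when the objective improves by less than this.
#' @param seed Integer seed for the random start.
#' @param init_sd Standard deviation of the random start.
#' @return A fitted `cs_scoring_model`; `$fit` holds the loss trace,
#'   iteration count and convergence flag.
#' @export
fit_scoring_model <- function(cohort, states, rank = 2L, lambda = 1e-3,
                              max_iter = 5000L, tol = 1e-12, seed = 1L,
                              init_sd = 0.1) {
  if (!"true_state" %in% names(cohort)) {
    cs_abort_data("fitting requires a `true_state` label on every athlete")
  }
  if (anyNA(cohort$true_state)) {
    cs_abort_data("`true_state` contains missing labels")
  }
  schema <- cohort_schema(cohort)
  X <- cohort_matrix(cohort, schema)
  n <- nrow(X); d <- ncol(X); nz <- n_states(states)
  if (n < nz) cs_abort_data("need at least |Z| labeled athletes")
  y_idx <- state_index(states, cohort$true_state)
  dense <- is.null(rank)
  r <- if (dense) min(d, nz) else as.integer(rank)
  if (r < 1 || r > min(d, nz)) cs_abort_config("rank must satisfy 1 <= r <= min(d, |Z|)")

  params <- with_local_seed(seed, {
    if (dense) {
      list(Theta = matrix(rnorm(d * nz, sd = init_sd), d, nz))
    } else {
      list(U = matrix(rnorm(d * r, sd = init_sd), d, r),
           V = matrix(rnorm(nz * r, sd = init_sd), nz, r))
    }
  })

  obj_of <- function(p) {
    Theta <- if (dense) p$Theta else p$U %*% t(p$V)
    surrogate_objective(Theta, X, y_idx, lambda)
  }
  obj <- obj_of(params)
  if (!is.finite(obj)) cs_abort_numeric("non-finite loss at initialization")
  trace <- numeric(max_iter + 1)
  trace[1] <- -obj
  step <- 1
  iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Theta <- if (dense) params$Theta else params$U %*% t(params$V)
    G <- surrogate_grad_Theta(Theta, X, y_idx, lambda)
    if (dense) {
      dir <- list(Theta = G)
      gnorm2 <- sum(G^2)
    } else {
      dir <- list(U = G %*% params$V, V = t(G) %*% params$U)
      gnorm2 <- sum(dir$U^2) + sum(dir$V^2)
    }
    if (gnorm2 < 1e-18) { converged <- TRUE; iter <- it - 1L; break }
    # backtracking: accept the first step that improves the objective
    accepted <- FALSE
    step_try <- min(step * 2, 1e3)
    for (bt in 1:60) {
      cand <- if (dense) {
        list(Theta = params$Theta + step_try * dir$Theta)
      } else {
        list(U = params$U + step_try * dir$U, V = params$V + step_try * dir$V)
      }
      obj_new <- obj_of(cand)
      if (!is.finite(obj_new)) {
        cs_abort_numeric(sprintf("non-finite loss at iteration %d", it))
      }
      if (obj_new > obj + 1e-4 * step_try * gnorm2) {
        accepted <- TRUE
        break
      }
      step_try <- step_try / 2
    }
    if (!accepted) { converged <- TRUE; iter <- it - 1L; break }
    improvement <- obj_new - obj
    params <- cand
    obj <- obj_new
    step <- step_try
    trace[it + 1] <- -obj
    iter <- it
    if (improvement < tol) { converged <- TRUE; break }
  }
  if (dense) {
    # exact factorization of the dense optimum (r = min(d, |Z|))
    sv <- svd(params$Theta, nu = r, nv = r)
    U <- sv$u %*% diag(sqrt(sv$d[seq_len(r)]), r)
    V <- sv$v %*% diag(sqrt(sv$d[seq_len(r)]), r)
  } else {
    U <- params$U; V <- params$V
  }
  out <- scoring_model(U, V, states, schema = schema)
  out$fit <- list(
    loss = -obj,
    loss_trace = trace[seq_len(iter + 1)],
    iterations = iter,
    converged = converged,
    lambda = lambda,
    dense = dense,
    seed = as.integer(seed)
  )
  out
}

#' Screen a single athlete profile
#'
#' Composes the full inference pipeline for one athlete: compatibility
#' mask, bilinear state scores, capped sparsemax posterior, posterior-
#' weighted risk, thresholded flag and rationalization set.
#'
#' @param profile A named numeric feature vector or 1-row cohort.
#' @param model A `cs_scoring_model`.
#' @param states A `cs_states` state space.
#' @param rules A `cs_rules` tibble (empty rules = no masking).
#' @param s Support cap (default 2).
#' @param tau Screening threshold.
#' @param eps_r Rationalization mass cutoff.
#' @return A `cs_decision`: list with `risk`, `flag`, `tau`,
#'   `rationalization` and the underlying `posterior`.
#' @export
screen_profile <- function(profile, model, states, rules = NULL,
                           s = 2L, tau = 0.5, eps_r = 0.05) {
  rules <- rules %||% compat_rules(data.frame(
    state = character(), column = character(), op = character(), value = numeric()
  ))
  sch <- model$schema
  feats <- if (is.numeric(profile) && is.null(dim(profile))) {
    if (is.null(names(profile)) && !is.null(sch)) names(profile) <- sch$column_names
    profile
  } else profile
  mask <- compatibility_mask(feats, rules, states, schema = sch)[1, ]
  scores <- score_states(feats, model)[1, ]
  post <- sparse_posterior(scores, s = s, mask = mask, labels = states$state)
  risk <- expected_risk(post, states)
  structure(
    list(
      risk = risk,
      flag = classify(risk, tau),
      tau = tau,
      rationalization = rationalize(post, eps_r),
      posterior = post
    ),
    class = "cs_decision"
  )
}

#' @export
print.cs_decision <- function(x, ...) {
  cat(sprintf("<screening decision> risk %.4f, flag %d (tau = %g)\n",
              x$risk, x$flag, x$tau))
  cat("  rationalization:", paste(x$rationalization, collapse = " > "), "\n")
  invisible(x)
}

#' Screen an entire cohort
#'
#' Runs the screening pipeline over every athlete and returns one tidy row
#' per athlete. The posterior engine is selectable: the structured-sparse
#' scores-to-sparsemax route, or the embedding layer's Mahalanobis-softmax
#' route (`posterior_source = "rsee"`, which requires `embedding` and
#' `prototypes`). Ablation switches mirror the model's component study:
#' `no_sparse_posterior` swaps the capped sparsemax for a dense softmax,
#' `no_compat` ignores compatibility rules.
#'
#' @param cohort A `cs_cohort`.
#' @param model A `cs_scoring_model` (used when
#'   `posterior_source = "cardiospectra"`).
#' @param states A `cs_states`.
#' @param rules Optional `cs_rules`.
#' @param s Support cap.
#' @param tau Screening threshold.
#' @param eps_r Rationalization cutoff.
#' @param posterior_source `"cardiospectra"` or `"rsee"`.
#' @param embedding,prototypes Embedding model and prototypes for the
#'   `"rsee"` route.
#' @param no_sparse_posterior,no_compat Ablation switches.
#' @param on_incompatible `"error"` (default) or `"refer"`: athletes whose
#'   every state is masked out either raise an error or are returned with
#'   `NA` risk, flag 1 and an empty rationalization (flagged for expert
#'   review).
#' @param risk_source `"event_prior"` weights the posterior by
#'   \eqn{\pi(z)}; `"exertion"` by \eqn{\rho(z)}.
#' @return A tibble with one row per athlete: `athlete_id`, `risk`,
#'   `flag`, `n_support`, `rationalization` (list-column), `referred`.
#' @export
screen_cohort <- function(cohort, model = NULL, states, rules = NULL,
                          s = 2L, tau = 0.5, eps_r = 0.05,
                          posterior_source = c("cardiospectra", "rsee"),
                          embedding = NULL, prototypes = NULL,
                          no_sparse_posterior = FALSE, no_compat = FALSE,
                          on_incompatible = c("error", "refer"),
                          risk_source = c("event_prior", "exertion")) {
  posterior_source <- match.arg(posterior_source)
  on_incompatible <- match.arg(on_incompatible)
  risk_source <- match.arg(risk_source)
  n <- nrow(cohort)
  nz <- n_states(states)
  rules <- rules %||% compat_rules(data.frame(
    state = character(), column = character(), op = character(), value = numeric()
  ))
  mask <- if (no_compat) {
    matrix(1L, n, nz)
  } else {
    compatibility_mask(cohort, rules, states)
  }
  scores <- if (posterior_source == "cardiospectra") {
    if (is.null(model)) cs_abort_config("the cardiospectra route needs `model`")
    score_states(cohort, model)
  } else {
    if (is.null(embedding) || is.null(prototypes)) {
      cs_abort_config("the rsee route needs `embedding` and `prototypes`")
    }
    alignment_scores(embed(cohort, embedding), prototypes)
  }
  weights <- switch(risk_source,
    event_prior = states$event_prior,
    exertion = states$exertion_risk
  )
  risk <- numeric(n); flag <- integer(n); n_support <- integer(n)
  referred <- logical(n)
  rat <- vector("list", n)
  for (i in seq_len(n)) {
    post <- tryCatch(
      {
        if (no_sparse_posterior) {
          softmax_posterior(scores[i, ], mask = mask[i, ], labels = states$state)
        } else if (posterior_source == "rsee") {
          rsee_posterior(scores[i, ], s = s, mask = mask[i, ], labels = states$state)
        } else {
          sparse_posterior(scores[i, ], s = s, mask = mask[i, ], labels = states$state)
        }
      },
      cs_no_compatible_state = function(e) {
        if (on_incompatible == "error") {
          cs_abort_data(sprintf(
            "athlete %s is compatible with no state", cohort$athlete_id[[i]]
          ))
        }
        NULL
      }
    )
    if (is.null(post)) {
      risk[i] <- NA_real_; flag[i] <- 1L; n_support[i] <- 0L
      referred[i] <- TRUE; rat[[i]] <- character(0)
    } else {
      risk[i] <- sum(post$q * weights)
      flag[i] <- classify(risk[i], tau)
      n_support[i] <- length(post$support)
      rat[[i]] <- rationalize(post, eps_r)
    }
  }
  tibble(
    athlete_id = cohort$athlete_id,
    risk = risk,
    flag = flag,
    n_support = n_support,
    rationalization = rat,
    referred = referred
  )
}

#' Serialize a scoring model to JSON
#'
#' Stores the factor matrices row-major along with state labels, the
#' schema, and the decision parameters, so a saved model can be reloaded
#' and validated elsewhere.
#'
#' @param model A `cs_scoring_model`.
#' @param path File path.
#' @param s,tau,eps_r Decision parameters stored with the model.
#' @return `read_scoring_model()` returns the restored model (with
#'   `$decision` holding `s`, `tau`, `eps_r`).
#' @export
write_scoring_model <- function(model, path, s = 2L, tau = 0.5, eps_r = 0.05) {
  doc <- list(
    type = "cs_scoring_model",
    states = model$states,
    d = nrow(model$U),
    rank = model$rank,
    U = as.vector(t(model$U)),
    V = as.vector(t(model$V)),
    s = as.integer(s), tau = tau, eps_r = eps_r,
    schema = if (!is.null(model$schema)) {
      list(blocks = as.list(model$schema$block_sizes),
           column_names = model$schema$column_names)
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scoring_model
#' @param states A `cs_states` to validate the stored labels against
#'   (optional).
#' @export
read_scoring_model <- function(path, states = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "cs_scoring_model")) {
    cs_abort_data("file is not a serialized scoring model")
  }
  d <- doc$d; r <- doc$rank; nz <- length(doc$states)
  if (length(doc$U) != d * r || length(doc$V) != nz * r) {
    cs_abort_data("stored factor matrices have inconsistent shapes")
  }
  sch <- if (!is.null(doc$schema)) {
    feature_schema(unlist(doc$schema$blocks), doc$schema$column_names)
  }
  st <- states %||% latent_states(doc$states, rep(0, nz))
  if (!identical(st$state, as.character(doc$states))) {
    cs_abort_data("stored state labels do not match the supplied state space")
  }
  m <- scoring_model(
    matrix(doc$U, d, r, byrow = TRUE),
    matrix(doc$V, nz, r, byrow = TRUE),
    st, schema = sch
  )
  m$decision <- list(s = doc$s, tau = doc$tau, eps_r = doc$eps_r)
  m
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted scoring model
#'
#' One row per (feature, state) coefficient of the effective parameter
#' matrix \eqn{\Theta = UV^\top}.
#'
#' @param x A `cs_scoring_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `state`, `estimate`.
#' @method tidy cs_scoring_model
#' @export
tidy.cs_scoring_model <- function(x, ...) {
  Theta <- x$U %*% t(x$V)
  terms <- if (!is.null(x$schema)) x$schema$column_names else
    paste0("x", seq_len(nrow(Theta)))
  tibble(
    term = rep(terms, times = ncol(Theta)),
    state = rep(x$states, each = nrow(Theta)),
    estimate = as.vector(Theta)
  )
}

#' Glance at a fitted scoring model
#' @param x A `cs_scoring_model`.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, rank, final loss, iterations,
#'   convergence flag.
#' @method glance cs_scoring_model
#' @export
glance.cs_scoring_model <- function(x, ...) {
  tibble(
    d = nrow(x$U),
    n_states = nrow(x$V),
    rank = x$rank,
    loss = x$fit$loss %||% NA_real_,
    iterations = x$fit$iterations %||% NA_integer_,
    converged = x$fit$converged %||% NA
  )
}
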