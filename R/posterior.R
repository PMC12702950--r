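#' Sparsemax: Euclidean projection onto the probability simplex
#'
#' Solves \eqn{\arg\max_{q \in \Delta} q^\top v - \tfrac12 \|q\|^2}, i.e.
#' the Euclidean projection of the score vector onto the simplex. Unlike
#' softmax, the solution is exactly sparse: scores below a data-dependent
#' threshold receive zero mass.
#'
#' @param v Numeric score vector.
#' @return A probability vector of the same length, possibly with exact
#'   zeros.
#' @examples
#' sparsemax(c(0.6, 0.4, 0.1))
#' sparsemax(c(2, 0, 0)) # saturates to one-hot when the gap >= 1
#' @export
sparsemax <- function(v) {
  assert_finite(v, "scores")
  ord <- order(v, decreasing = TRUE)
  z <- v[ord]
  k <- seq_along(z)
  css <- cumsum(z)
  support_len <- max(which(1 + k * z > css))
  tau <- (css[support_len] - 1) / support_len
  q <- pmax(v - tau, 0)
  # exact renormalization guards against accumulated rounding
  q / sum(q)
}

# top-s selection with deterministic tie-break toward lower index
top_s_indices <- function(v, s) {
  ord <- order(-v, seq_along(v))
  sort(ord[seq_len(min(s, length(v)))])
}

new_sparse_posterior <- function(q, cap, labels = NULL) {
  if (!is.null(labels)) names(q) <- labels
  structure(
    list(q = q, support = which(q > 0), cap = as.integer(cap)),
    class = "cs_sparse_posterior"
  )
}

#' @export
print.cs_sparse_posterior <- function(x, ...) {
  cat(sprintf("<sparse posterior> cap %d, support %d state(s)\n",
              x$cap, length(x$support)))
  print(round(x$q, 5))
  invisible(x)
}

#' Capped sparsemax posterior over latent states
#'
#' The structured-sparse engine's posterior: the sparsemax projection of
#' the compatibility-masked scores, additionally capped to at most `s`
#' nonzero states. If the unconstrained sparsemax support exceeds `s`, the
#' projection is re-solved on the `s` largest masked-in scores (ties broken
#' toward the lower state index); this restriction is exact for the capped
#' problem because the optimum is always supported on a top-score set.
#' Masked-out states carry exactly zero mass.
#'
#' @param scores Numeric score vector over states (one score per state).
#' @param s Support cap, `1 <= s <= length(scores)`.
#' @param mask Optional 0/1 vector; 0 entries are excluded from the
#'   posterior. Default all-ones.
#' @param labels Optional state labels for the returned vector.
#' @return A `cs_sparse_posterior`: list with elements `q` (probability
#'   vector), `support` (indices with positive mass) and `cap`.
#' @examples
#' sparse_posterior(c(0.6, 0.4, 0.1), s = 3)
#' sparse_posterior(c(0.6, 0.4, 0.1), s = 2)
#' @export
sparse_posterior <- function(scores, s, mask = NULL, labels = names(scores)) {
  nz <- length(scores)
  if (s < 1 || s > nz) cs_abort_config("cap `s` must satisfy 1 <= s <= |Z|")
  if (is.null(mask)) mask <- rep(1L, nz)
  if (length(mask) != nz) cs_abort_data("mask length must match scores")
  alive <- which(mask > 0)
  if (!length(alive)) {
    cs_abort_data("no compatible state", class = "cs_no_compatible_state")
  }
  q <- numeric(nz)
  q_alive <- sparsemax(scores[alive])
  if (sum(q_alive > 0) > s) {
    keep_local <- top_s_indices(scores[alive], s)
    q_alive <- numeric(length(alive))
    q_alive[keep_local] <- sparsemax(scores[alive][keep_local])
  }
  q[alive] <- q_alive
  new_sparse_posterior(q, s, labels)
}

#' Capped softmax posterior from Mahalanobis alignment scores
#'
#' The embedding layer's posterior: a softmax over alignment scores,
#' hard-truncated to the `s` best masked-in states (ties toward the lower
#' state index) and renormalized over that support. Masked-out and
#' off-support states carry exactly zero mass.
#'
#' @param alignment Numeric vector of alignment scores over states.
#' @param s Support cap.
#' @param mask Optional 0/1 compatibility vector.
#' @param labels Optional state labels.
#' @return A `cs_sparse_posterior`.
#' @examples
#' rsee_posterior(c(log(2), 0), s = 2) # (2/3, 1/3)
#' @export
rsee_posterior <- function(alignment, s, mask = NULL, labels = names(alignment)) {
  nz <- length(alignment)
  if (s < 1 || s > nz) cs_abort_config("cap `s` must satisfy 1 <= s <= |Z|")
  if (is.null(mask)) mask <- rep(1L, nz)
  alive <- which(mask > 0)
  if (!length(alive)) {
    cs_abort_data("no compatible state", class = "cs_no_compatible_state")
  }
  keep <- alive[top_s_indices(alignment[alive], s)]
  q <- numeric(nz)
  q[keep] <- softmax_vec(alignment[keep])
  new_sparse_posterior(q, s, labels)
}

#' Plain softmax posterior (sparse-posterior ablation)
#'
#' Used by the `no_sparse_posterior` ablation: a dense softmax over
#' masked-in scores with no support cap.
#' @inheritParams sparse_posterior
#' @return A `cs_sparse_posterior` whose cap equals the number of states.
#' @export
softmax_posterior <- function(scores, mask = NULL, labels = names(scores)) {
  nz <- length(scores)
  if (is.null(mask)) mask <- rep(1L, nz)
  alive <- which(mask > 0)
  if (!length(alive)) {
    cs_abort_data("no compatible state", class = "cs_no_compatible_state")
  }
  q <- numeric(nz)
  q[alive] <- softmax_vec(scores[alive])
  new_sparse_posterior(q, nz, labels)
}

#' Posterior-weighted event risk
#'
#' The expected screening risk \eqn{\hat r(x) = \sum_z q(z \mid x)\,\pi(z)}:
#' the posterior-weighted average of the per-state event priors. Always
#' lies between the smallest and largest prior on the support.
#'
#' @param posterior A `cs_sparse_posterior` (or bare probability vector).
#' @param states A `cs_states` state space.
#' @return A single number in `[0, 1]`.
#' @export
expected_risk <- function(posterior, states) {
  q <- if (inherits(posterior, "cs_sparse_posterior")) posterior$q else posterior
  if (length(q) != n_states(states)) {
    cs_abort_data("posterior length does not match the state space")
  }
  sum(q * states$event_prior)
}

#' Exertion-adjusted risk score
#'
#' \eqn{\hat r(x) = \sum_z q(z \mid x)\,\rho(z)} with \eqn{\rho(z)} the
#' exertion-adjusted risk level of each latent state. Identical in form to
#' [expected_risk()]; the two coincide whenever \eqn{\rho \equiv \pi}.
#'
#' @inheritParams expected_risk
#' @return A single number in `[0, 1]`.
#' @export
exertional_risk <- function(posterior, states) {
  q <- if (inherits(posterior, "cs_sparse_posterior")) posterior$q else posterior
  if (length(q) != n_states(states)) {
    cs_abort_data("posterior length does not match the state space")
  }
  sum(q * states$exertion_risk)
}

#' Binary screening decision
#'
#' Flags an athlete iff the estimated risk strictly exceeds the screening
#' threshold \eqn{\tau}; the threshold is typically tuned toward high
#' sensitivity.
#'
#' @param risk Numeric risk value(s) in `[0, 1]`.
#' @param tau Screening threshold in `[0, 1]`.
#' @return Integer 0/1 vector, 1 where `risk > tau` (strict).
#' @export
classify <- function(risk, tau) {
  if (tau < 0 || tau > 1) cs_abort_config("`tau` must lie in [0, 1]")
  as.integer(risk > tau)
}

#' Rationalization set of a posterior
#'
#' The states carrying non-negligible posterior mass, surfaced so a
#' clinician can trace which diagnostic hypotheses drove a positive
#' screen. Returned in decreasing order of mass.
#'
#' @param posterior A `cs_sparse_posterior` with named `q`, or a named
#'   probability vector.
#' @param eps_r Mass cutoff in `[0, 1)`; states with `q > eps_r` are kept.
#'   `eps_r = 0` returns exactly the support.
#' @return Character vector of state labels, ordered by decreasing mass.
#' @export
rationalize <- function(posterior, eps_r = 0.05) {
  if (eps_r < 0 || eps_r >= 1) cs_abort_config("`eps_r` must lie in [0, 1)")
  q <- if (inherits(posterior, "cs_sparse_posterior")) posterior$q else posterior
  if (is.null(names(q))) names(q) <- as.character(seq_along(q))
  keep <- which(q > eps_r)
  keep <- keep[order(-q[keep], keep)]
  names(q)[keep]
}
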