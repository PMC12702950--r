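cs_activations <- list(
  identity = list(f = function(a) a, grad = function(a, h) rep(1, length(h))),
  tanh = list(f = tanh, grad = function(a, h) 1 - h^2),
  relu = list(
    f = function(a) pmax(a, 0),
    grad = function(a, h) as.numeric(a > 0)
  )
)

#' Exertional embedding model
#'
#' The embedding layer maps a feature vector into a low-dimensional
#' exertional latent space via a single affine map plus an elementwise
#' nonlinearity: \eqn{h = \sigma(Wx + b)}. The default activation is
#' `identity`, under which the Mahalanobis alignment geometry is invariant
#' to affine distortion of the latent space; `tanh` (bounded, appropriate
#' for standardized features) and `relu` are also available.
#'
#' @param W `k x d` projection matrix.
#' @param b Length-`k` offset.
#' @param activation `"identity"` (default), `"tanh"` or `"relu"`.
#' @param schema Optional `cs_schema`.
#' @return A `cs_embedding`.
#' @export
embedding_model <- function(W, b, activation = c("identity", "tanh", "relu"),
                            schema = NULL) {
  activation <- match.arg(activation)
  W <- as.matrix(W)
  if (length(b) != nrow(W)) cs_abort_config("length of b must equal nrow(W)")
  if (nrow(W) > ncol(W)) cs_abort_config("embedding dimension k must not exceed d")
  assert_finite(W, "W"); assert_finite(b, "b")
  structure(
    list(W = W, b = as.numeric(b), activation = activation,
         k = nrow(W), schema = schema),
    class = "cs_embedding"
  )
}

#' @export
print.cs_embedding <- function(x, ...) {
  cat(sprintf("<embedding model> %d -> %d, activation %s\n",
              ncol(x$W), x$k, x$activation))
  invisible(x)
}

#' Embed athlete profiles into the exertional latent space
#'
#' @param data A `cs_cohort`, feature data frame, numeric matrix, or
#'   single numeric vector.
#' @param model A `cs_embedding`.
#' @return An `n x k` numeric matrix of embeddings.
#' @export
embed <- function(data, model) {
  X <- features_as_matrix(data, model$schema)
  if (ncol(X) != ncol(model$W)) {
    cs_abort_data(sprintf(
      "feature dimension %d does not match embedding input dimension %d",
      ncol(X), ncol(model$W)
    ))
  }
  A <- X %*% t(model$W) + matrix(model$b, nrow(X), model$k, byrow = TRUE)
  cs_activations[[model$activation]]$f(A)
}

#' Fit per-state Mahalanobis prototypes
#'
#' Computes each state's prototype as the class mean of its embeddings
#' and a shrunk class covariance
#' \eqn{\Sigma_z = (1-\gamma)\,S_z + \gamma\,\bar\sigma^2_z I}, where
#' \eqn{S_z} is the empirical covariance and \eqn{\bar\sigma^2_z} the mean
#' of its diagonal. Shrinkage keeps small-class covariances invertible; a
#' tiny variance floor covers fully degenerate classes. The benign
#' centroid \eqn{\bar h} is the mean embedding of the designated benign
#' state (athletic remodeling), and `delta` is the fidelity margin around
#' it.
#'
#' @param H `n x k` matrix of embeddings.
#' @param labels Character vector of state labels, one per row of `H`.
#' @param states A `cs_states`.
#' @param benign_state Label of the benign-adaptation state; default picks
#'   the first label containing "remodel", else the first state.
#' @param gamma Shrinkage weight in `[0, 1]` (default 0.1).
#' @param delta Fidelity margin (> 0).
#' @param var_floor Lower bound on the shrinkage target variance.
#' @return A `cs_prototypes`: per-state `mu` and `Sigma`, benign centroid
#'   `h_bar`, `delta`, `gamma`.
#' @export
fit_prototypes <- function(H, labels, states, benign_state = NULL,
                           gamma = 0.1, delta = 2, var_floor = 1e-8) {
  if (gamma < 0 || gamma > 1) cs_abort_config("`gamma` must lie in [0, 1]")
  if (delta <= 0) cs_abort_config("`delta` must be positive")
  H <- as.matrix(H)
  labels <- as.character(labels)
  if (length(labels) != nrow(H)) cs_abort_data("one label per embedding row required")
  benign_state <- benign_state %||% {
    hit <- grep("remodel", states$state)
    if (length(hit)) states$state[[hit[1]]] else states$state[[1]]
  }
  state_index(states, benign_state)
  mu <- list(); Sigma <- list()
  for (z in states$state) {
    rows <- which(labels == z)
    if (length(rows) < 2) {
      cs_abort_data(sprintf("state `%s` has fewer than 2 samples", z))
    }
    Hz <- H[rows, , drop = FALSE]
    mu[[z]] <- colMeans(Hz)
    S <- stats::cov(Hz)
    target <- max(mean(diag(S)), var_floor)
    Sigma[[z]] <- (1 - gamma) * S + gamma * target * diag(ncol(H))
  }
  h_bar <- mu[[benign_state]]
  structure(
    list(mu = mu, Sigma = Sigma, h_bar = h_bar, delta = delta,
         gamma = gamma, benign_state = benign_state, states = states$state,
         k = ncol(H)),
    class = "cs_prototypes"
  )
}

#' @export
print.cs_prototypes <- function(x, ...) {
  cat(sprintf("<state prototypes> %d state(s) in %d-d, benign = %s, delta = %g\n",
              length(x$mu), x$k, x$benign_state, x$delta))
  invisible(x)
}

#' Mahalanobis alignment scores
#'
#' \eqn{\alpha(z) = -(h-\mu_z)^\top \Sigma_z^{-1} (h-\mu_z)}: the negated
#' squared Mahalanobis distance from an embedding to each state
#' prototype. Always nonpositive, and zero exactly at the prototype. With
#' \eqn{\Sigma_z = I} it reduces to the negated squared Euclidean
#' distance.
#'
#' @param H A length-`k` vector or `n x k` matrix of embeddings.
#' @param prototypes A `cs_prototypes`.
#' @return An `n x |Z|` matrix of alignment scores (a 1-row matrix for a
#'   single embedding), states as columns.
#' @export
alignment_scores <- function(H, prototypes) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  nz <- length(prototypes$mu)
  out <- matrix(NA_real_, nrow(H), nz,
                dimnames = list(NULL, prototypes$states))
  for (j in seq_len(nz)) {
    z <- prototypes$states[[j]]
    Rz <- tryCatch(chol(prototypes$Sigma[[z]]), error = function(e) {
      cs_abort_numeric(sprintf(
        "covariance of state `%s` is not positive-definite", z
      ))
    })
    D <- sweep(H, 2, prototypes$mu[[z]])
    # squared Mahalanobis distance via the Cholesky factor
    Wt <- backsolve(Rz, t(D), transpose = TRUE)
    out[, j] <- -colSums(Wt^2)
  }
  out
}

#' Physiological fidelity check
#'
#' An embedding passes iff its Euclidean distance to the benign athletic
#' adaptation centroid is strictly below the margin `delta`; anything at
#' or beyond the margin is flagged for expert review.
#'
#' @param H Embedding vector or matrix.
#' @param prototypes A `cs_prototypes` (carries `h_bar` and `delta`).
#' @return A tibble with columns `distance` and `pass`.
#' @export
fidelity_check <- function(H, prototypes) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1)
  d <- sqrt(rowSums(sweep(H, 2, prototypes$h_bar)^2))
  tibble(distance = d, pass = d < prototypes$delta)
}

#' Hybrid embedding loss
#'
#' The training objective of the embedding layer decomposes into three
#' nonnegative terms: an alignment term \eqn{-\sum_i \log q(z^*_i \mid x_i)}
#' under the capped Mahalanobis-softmax posterior, a fidelity hinge
#' \eqn{\sum_i \max(0, \|h_i - \bar h\| - \delta)^2}, and an orthogonality
#' penalty \eqn{\|WW^\top - I\|_F^2} that promotes diverse embedding axes.
#' The total is \eqn{L_{align} + \lambda_1 L_{fid} + \lambda_2 L_{orth}}.
#'
#' When the cap pushes a sample's label off the posterior support, its
#' alignment contribution uses a floor probability of `1e-12` inside the
#' log; such samples are counted in `off_support`.
#'
#' @param cohort A labeled `cs_cohort` (needs `true_state`).
#' @param model A `cs_embedding`.
#' @param prototypes A `cs_prototypes`.
#' @param states A `cs_states`.
#' @param lambda1,lambda2 Weights of the fidelity and orthogonality terms.
#' @param s Posterior support cap.
#' @return A `cs_loss_report`: `L_align`, `L_fid`, `L_orth`, the weights,
#'   `total` and `off_support`.
#' @export
rsee_loss <- function(cohort, model, prototypes, states,
                      lambda1 = 0.01, lambda2 = 0.1, s = 2L) {
  if (nrow(cohort) == 0) cs_abort_data("empty batch")
  if (!"true_state" %in% names(cohort)) {
    cs_abort_data("the hybrid loss requires `true_state` labels")
  }
  H <- embed(cohort, model)
  A <- alignment_scores(H, prototypes)
  y_idx <- state_index(states, cohort$true_state)
  floor_p <- 1e-12
  l_align <- 0; off_support <- 0L
  for (i in seq_len(nrow(H))) {
    q <- rsee_posterior(A[i, ], s = s)$q
    p <- unname(q[y_idx[i]])
    if (p <= 0) { off_support <- off_support + 1L; p <- floor_p }
    l_align <- l_align - log(p)
  }
  dist <- sqrt(rowSums(sweep(H, 2, prototypes$h_bar)^2))
  l_fid <- sum(pmax(0, dist - prototypes$delta)^2)
  WWt <- model$W %*% t(model$W)
  l_orth <- sum((WWt - diag(model$k))^2)
  structure(
    list(
      L_align = l_align, L_fid = l_fid, L_orth = l_orth,
      lambda1 = lambda1, lambda2 = lambda2,
      total = l_align + lambda1 * l_fid + lambda2 * l_orth,
      off_support = off_support, n = nrow(H)
    ),
    class = "cs_loss_report"
  )
}

#' @export
print.cs_loss_report <- function(x, ...) {
  cat(sprintf(
    "<hybrid loss> align %.4f + %.3g * fid %.4f + %.3g * orth %.4f = %.4f\n",
    x$L_align, x$lambda1, x$L_fid, x$lambda2, x$L_orth, x$total
  ))
  if (x$off_support > 0) {
    cat(sprintf("  off-support labels: %d of %d\n", x$off_support, x$n))
  }
  invisible(x)
}

# gradient of the hybrid loss wrt W and b, prototypes and posterior
# support frozen.  Data-dependent terms are averaged over the batch so the
# learning rate is independent of n; the reported loss keeps the summed form.
rsee_gradients <- function(X, H, A, y_idx, model, prototypes,
                           lambda1, lambda2, s, align_weight) {
  n <- nrow(X); k <- model$k
  Gh <- matrix(0, n, k)
  if (align_weight > 0) {
    inv_list <- lapply(prototypes$states, function(z) solve(prototypes$Sigma[[z]]))
    for (i in seq_len(n)) {
      keep <- top_s_indices(A[i, ], s)
      q <- softmax_vec(A[i, keep])
      if (!(y_idx[i] %in% keep)) next  # floored sample: zero gradient
      coef <- q
      coef[match(y_idx[i], keep)] <- coef[match(y_idx[i], keep)] - 1
      g <- numeric(k)
      for (jj in seq_along(keep)) {
        z <- keep[jj]
        diff <- H[i, ] - prototypes$mu[[prototypes$states[z]]]
        # d alpha_z / dh = -2 Sigma_z^{-1} (h - mu_z)
        g <- g + coef[jj] * (-2 * (inv_list[[z]] %*% diff))
      }
      Gh[i, ] <- Gh[i, ] + align_weight * g
    }
  }
  if (lambda1 > 0) {
    diffb <- sweep(H, 2, prototypes$h_bar)
    dist <- sqrt(rowSums(diffb^2))
    act <- dist > prototypes$delta & dist > 0
    if (any(act)) {
      coefs <- 2 * (dist[act] - prototypes$delta) / dist[act]
      Gh[act, ] <- Gh[act, ] + lambda1 * diffb[act, , drop = FALSE] * coefs
    }
  }
  act_grad <- cs_activations[[model$activation]]$grad
  Apre <- X %*% t(model$W) + matrix(model$b, n, k, byrow = TRUE)
  Ga <- Gh * act_grad(Apre, H)
  gW <- crossprod(Ga, X) / n
  gb <- colSums(Ga) / n
  if (lambda2 > 0) {
    WWt <- model$W %*% t(model$W)
    gW <- gW + lambda2 * 4 * (WWt - diag(k)) %*% model$W
  }
  list(W = gW, b = gb)
}

#' Train the exertional embedding
#'
#' Alternating optimization of the hybrid loss: each epoch refreshes the
#' state prototypes from the current embeddings (class means + shrunk
#' covariances), then takes one full-batch gradient-descent step on `W`
#' and `b` with the prototypes and each sample's posterior support frozen.
#' The data-dependent loss terms are averaged over the batch for the
#' gradient step (so the learning rate does not scale with cohort size)
#' while the recorded trace keeps the summed form of the loss.
#'
#' @param cohort A labeled `cs_cohort`.
#' @param states A `cs_states`.
#' @param k Embedding dimension (`k <= d`).
#' @param s Posterior support cap.
#' @param delta Fidelity margin.
#' @param gamma Covariance shrinkage.
#' @param lambda1,lambda2 Fidelity and orthogonality weights. The
#'   fidelity hinge is primarily a flagging criterion; its default
#'   training weight is small (0.01) because a heavy fidelity penalty
#'   pulls every state into the benign ball and can collapse the
#'   prototype geometry the alignment term is building.
#' @param align_weight Weight on the alignment term (1 by default; 0 turns
#'   training into a pure penalty optimization, e.g. orthogonality-only
#'   with `lambda1 = 0`).
#' @param lr Learning rate of the fixed-step gradient descent.
#' @param epochs Epoch budget.
#' @param tol Stop early when the total loss changes by less than this.
#' @param seed Seed for the random initialization of `W` and `b`.
#' @param activation Activation name.
#' @param benign_state Benign-adaptation state label (see
#'   [fit_prototypes()]).
#' @param clip_norm Cap on the Frobenius norm of each gradient step
#'   (`Inf` to disable); tight class covariances make the Mahalanobis
#'   alignment gradient arbitrarily steep, and clipping keeps the fixed
#'   learning rate stable.
#' @param n_starts Number of seeded random restarts; the fit with the
#'   lowest final (weighted) loss is kept. The alternating scheme can hit
#'   local optima in which two prototypes merge, and restarting from a
#'   few initializations is the standard, still fully deterministic,
#'   defense.
#' @return A `cs_rsee_fit`: `model` (`cs_embedding`), `prototypes`
#'   (`cs_prototypes`), and `trace`, a tibble with per-epoch loss
#'   components of the selected start.
#' @export
train_embedding <- function(cohort, states, k = 4L, s = 2L, delta = 2,
                            gamma = 0.1, lambda1 = 0.01, lambda2 = 0.1,
                            align_weight = 1, lr = 0.05, epochs = 200L,
                            tol = 1e-8, seed = 1L,
                            activation = c("identity", "tanh", "relu"),
                            benign_state = NULL, clip_norm = 10,
                            n_starts = 3L) {
  activation <- match.arg(activation)
  best <- NULL
  best_loss <- Inf
  for (start in seq_len(max(1L, n_starts))) {
    fit <- train_embedding_once(
      cohort, states, k = k, s = s, delta = delta, gamma = gamma,
      lambda1 = lambda1, lambda2 = lambda2, align_weight = align_weight,
      lr = lr, epochs = epochs, tol = tol,
      seed = as.integer(seed) + (start - 1L),
      activation = activation, benign_state = benign_state,
      clip_norm = clip_norm
    )
    last <- fit$trace[nrow(fit$trace), ]
    loss_w <- align_weight * last$L_align + lambda1 * last$L_fid +
      lambda2 * last$L_orth
    if (loss_w < best_loss) {
      best <- fit
      best_loss <- loss_w
    }
  }
  best$config$seed <- as.integer(seed)
  best$config$n_starts <- as.integer(n_starts)
  best
}

train_embedding_once <- function(cohort, states, k, s, delta, gamma,
                                 lambda1, lambda2, align_weight, lr,
                                 epochs, tol, seed, activation,
                                 benign_state, clip_norm) {
  schema <- cohort_schema(cohort)
  X <- cohort_matrix(cohort, schema)
  d <- ncol(X)
  if (k > d) cs_abort_config("embedding dimension k must not exceed d")
  if (!"true_state" %in% names(cohort)) {
    cs_abort_data("training requires `true_state` labels")
  }
  y_idx <- state_index(states, cohort$true_state)
  init <- with_local_seed(seed, {
    W <- matrix(rnorm(k * d), k, d)
    # scale each projection row so initial pre-activations have sd 0.5
    # over the cohort, and center them with the offset: keeps a
    # saturating activation in its responsive range at the start
    Apre <- X %*% t(W)
    sds <- pmax(apply(Apre, 2, stats::sd), 1e-8)
    W <- 0.5 * W / sds
    b <- -colMeans(X %*% t(W)) + rnorm(k, sd = 0.01)
    list(W = W, b = b)
  })
  model <- embedding_model(init$W, init$b, activation, schema = schema)
  trace <- vector("list", epochs)
  prototypes <- NULL
  prev_total <- Inf
  for (ep in seq_len(epochs)) {
    H <- embed(X, model)
    prototypes <- fit_prototypes(H, cohort$true_state, states,
                                 benign_state = benign_state,
                                 gamma = gamma, delta = delta)
    A <- alignment_scores(H, prototypes)
    rep_ <- rsee_loss(cohort, model, prototypes, states,
                      lambda1 = lambda1, lambda2 = lambda2, s = s)
    total_w <- align_weight * rep_$L_align + lambda1 * rep_$L_fid +
      lambda2 * rep_$L_orth
    if (!is.finite(total_w)) {
      cs_abort_numeric(sprintf("loss diverged at epoch %d", ep))
    }
    trace[[ep]] <- tibble(
      epoch = ep, L_align = rep_$L_align, L_fid = rep_$L_fid,
      L_orth = rep_$L_orth, total = rep_$total,
      off_support = rep_$off_support
    )
    if (abs(prev_total - total_w) < tol) {
      trace <- trace[seq_len(ep)]
      break
    }
    prev_total <- total_w
    g <- rsee_gradients(X, H, A, y_idx, model, prototypes,
                        lambda1, lambda2, s, align_weight)
    # norm clipping: Mahalanobis gradients blow up as classes tighten
    # (covariance inverses grow), so cap the update magnitude
    gnorm <- sqrt(sum(g$W^2) + sum(g$b^2))
    if (is.finite(clip_norm) && gnorm > clip_norm) {
      g$W <- g$W * clip_norm / gnorm
      g$b <- g$b * clip_norm / gnorm
    }
    model$W <- model$W - lr * g$W
    model$b <- model$b - lr * g$b
    if (ep == epochs) trace <- trace[seq_len(ep)]
  }
  # final prototypes on the trained embedding
  H <- embed(X, model)
  prototypes <- fit_prototypes(H, cohort$true_state, states,
                               benign_state = benign_state,
                               gamma = gamma, delta = delta)
  structure(
    list(
      model = model, prototypes = prototypes,
      trace = dplyr::bind_rows(trace),
      config = list(k = k, s = s, delta = delta, gamma = gamma,
                    lambda1 = lambda1, lambda2 = lambda2,
                    align_weight = align_weight, lr = lr,
                    epochs = epochs, seed = as.integer(seed),
                    activation = activation)
    ),
    class = "cs_rsee_fit"
  )
}

#' @export
print.cs_rsee_fit <- function(x, ...) {
  n_ep <- nrow(x$trace)
  cat(sprintf("<rsee fit> k = %d, %d epoch(s), final total loss %.4f\n",
              x$model$k, n_ep, x$trace$total[[n_ep]]))
  invisible(x)
}

#' Tidy an embedding fit: the per-epoch loss trace
#' @param x A `cs_rsee_fit`.
#' @param ... Unused.
#' @return The trace tibble in long format: `epoch`, `component`, `value`.
#' @method tidy cs_rsee_fit
#' @export
tidy.cs_rsee_fit <- function(x, ...) {
  tidyr::pivot_longer(
    x$trace[, c("epoch", "L_align", "L_fid", "L_orth", "total")],
    -"epoch", names_to = "component", values_to = "value"
  )
}

#' Glance at an embedding fit
#' @param x A `cs_rsee_fit`.
#' @param ... Unused.
#' @return One-row tibble with final loss components and dimensions.
#' @method glance cs_rsee_fit
#' @export
glance.cs_rsee_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble(
    k = x$model$k, epochs_run = nrow(x$trace),
    L_align = last$L_align, L_fid = last$L_fid, L_orth = last$L_orth,
    total = last$total, off_support = last$off_support
  )
}

#' Perturbation stability of an embedding
#'
#' Draws a perturbed copy of the profile (seeded blockwise Gaussian noise
#' emulating training-induced physiological variability), embeds both,
#' and reports the Euclidean distance between the embeddings together
#' with the strict-inequality verdict against `eps_stab`.
#'
#' @param model A `cs_embedding`.
#' @param profile Named numeric feature vector (or 1-row cohort).
#' @param magnitude Noise scale (>= 0); 0 gives distance 0.
#' @param schema A `cs_schema` (defaults to the model's).
#' @param seed Integer seed for the noise draw.
#' @param eps_stab Stability tolerance (> 0).
#' @param block_scales Optional named per-block noise multipliers.
#' @return A one-row tibble: `distance`, `stable`.
#' @export
stability_check <- function(model, profile, magnitude, schema = model$schema,
                            seed = 1L, eps_stab = 0.1, block_scales = NULL) {
  if (eps_stab <= 0) cs_abort_config("`eps_stab` must be positive")
  x <- if (is.numeric(profile) && is.null(dim(profile))) profile else
    as.numeric(cohort_matrix(profile, schema)[1, ])
  xp <- perturb_features(x, magnitude, schema, seed, block_scales)
  h0 <- embed(matrix(x, nrow = 1), model)
  h1 <- embed(matrix(xp, nrow = 1), model)
  d <- sqrt(sum((h0 - h1)^2))
  tibble(distance = d, stable = d < eps_stab)
}

#' Extract the screening level set in embedding space
#'
#' Evaluates the exertional risk surface
#' \eqn{\hat r(h) = \sum_z q(z \mid h)\,\rho(z)} over a regular grid of a
#' 1- or 2-dimensional embedding space and returns the grid points whose
#' risk is within `tol` of the threshold `tau` -- a discrete approximation
#' of the decision boundary that partitions the manifold into
#' risk-positive and risk-negative regions. The full evaluated grid is
#' attached as the `"grid"` attribute (used by `autoplot()`).
#'
#' @param prototypes A `cs_prototypes` with `k` equal to 1 or 2.
#' @param states A `cs_states`.
#' @param tau Screening threshold.
#' @param lower,upper Numeric bounds of the grid per dimension.
#' @param n_grid Grid resolution per dimension.
#' @param tol Level-set tolerance on `|risk - tau|`.
#' @param s Posterior support cap.
#' @return A `cs_surface` tibble of near-level-set grid points with the
#'   embedding coordinates (`h_1`[, `h_2`]) and `risk`; the attribute
#'   `"grid"` holds every grid point with `risk` and `side`
#'   (`sign(risk - tau)`).
#' @export
screening_surface <- function(prototypes, states, tau, lower, upper,
                              n_grid = 101L, tol = NULL, s = 2L) {
  k <- prototypes$k
  if (!k %in% c(1L, 2L)) {
    cs_abort_config("surface extraction supports k = 1 or 2 only")
  }
  if (any(!is.finite(c(lower, upper)))) cs_abort_config("grid bounds must be finite")
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  axes <- purrr::map2(lower, upper, ~seq(.x, .y, length.out = n_grid))
  grid <- if (k == 1) tibble(h_1 = axes[[1]]) else
    tidyr::expand_grid(h_1 = axes[[1]], h_2 = axes[[2]])
  Hm <- as.matrix(grid)
  A <- alignment_scores(Hm, prototypes)
  risk <- vapply(seq_len(nrow(A)), function(i) {
    exertional_risk(rsee_posterior(A[i, ], s = s), states)
  }, numeric(1))
  if (is.null(tol)) {
    # default: resolvable risk change across one grid cell
    tol <- max(diff(range(risk)) / n_grid * 2, 1e-12)
  }
  grid$risk <- risk
  grid$side <- sign(risk - tau)
  near <- grid[abs(grid$risk - tau) <= tol, , drop = FALSE]
  out <- as_tibble(near)
  attr(out, "grid") <- grid
  attr(out, "tau") <- tau
  class(out) <- c("cs_surface", class(out))
  out
}

#' Serialize an embedding fit (model + prototypes) to JSON
#'
#' @param fit A `cs_rsee_fit` (or a list with `model` and `prototypes`).
#' @param path File path.
#' @return `read_embedding_model()` returns a list with `model` and
#'   `prototypes`.
#' @export
write_embedding_model <- function(fit, path) {
  model <- fit$model; prototypes <- fit$prototypes
  doc <- list(
    type = "cs_embedding_model",
    k = model$k, d = ncol(model$W),
    W = as.vector(t(model$W)), b = model$b,
    activation = model$activation,
    states = prototypes$states,
    mu = purrr::map(prototypes$mu, as.vector),
    Sigma = purrr::map(prototypes$Sigma, ~as.vector(t(.x))),
    h_bar = as.vector(prototypes$h_bar),
    delta = prototypes$delta, gamma = prototypes$gamma,
    benign_state = prototypes$benign_state,
    schema = if (!is.null(model$schema)) {
      list(blocks = as.list(model$schema$block_sizes),
           column_names = model$schema$column_names)
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_embedding_model
#' @export
read_embedding_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "cs_embedding_model")) {
    cs_abort_data("file is not a serialized embedding model")
  }
  k <- doc$k; d <- doc$d
  if (length(doc$W) != k * d || length(doc$b) != k) {
    cs_abort_data("stored projection has inconsistent shapes")
  }
  sch <- if (!is.null(doc$schema)) {
    feature_schema(unlist(doc$schema$blocks), doc$schema$column_names)
  }
  model <- embedding_model(matrix(doc$W, k, d, byrow = TRUE), doc$b,
                           doc$activation, schema = sch)
  mu <- purrr::map(doc$mu, as.numeric)
  Sigma <- purrr::map(doc$Sigma, ~matrix(as.numeric(.x), k, k, byrow = TRUE))
  names(mu) <- doc$states; names(Sigma) <- doc$states
  prototypes <- structure(
    list(mu = mu, Sigma = Sigma, h_bar = as.numeric(doc$h_bar),
         delta = doc$delta, gamma = doc$gamma,
         benign_state = doc$benign_state, states = doc$states, k = k),
    class = "cs_prototypes"
  )
  list(model = model, prototypes = prototypes)
}
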