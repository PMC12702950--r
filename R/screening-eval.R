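#' Confusion counts of screening flags against event labels
#'
#' Exact indicator sums: TP counts flagged athletes with an observed
#' adverse event, FP flagged athletes without one, and so on. Rates
#' (TPR = TP / (TP + FN), FPR = FP / (FP + TN)) are reported as `NA` when
#' the labels are degenerate (all 0 or all 1).
#'
#' @param data A data frame holding the flag and label columns (e.g. the
#'   output of [screen_cohort()] joined to the cohort), or `NULL` when
#'   `flag` and `label` are given as bare vectors.
#' @param flag,label Column names (tidy-eval) when `data` is supplied,
#'   otherwise 0/1 vectors.
#' @return A `cs_confusion` one-row tibble: `tp`, `fp`, `tn`, `fn`,
#'   `tpr`, `fpr`.
#' @examples
#' confusion(flag = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'           label = c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
#' @export
confusion <- function(data = NULL, flag, label) {
  if (!is.null(data)) {
    flag <- dplyr::pull(data, {{ flag }})
    label <- dplyr::pull(data, {{ label }})
  }
  if (length(flag) != length(label)) {
    cs_abort_data("`flag` and `label` must have equal length")
  }
  if (anyNA(flag) || anyNA(label)) cs_abort_data("flags/labels contain NA")
  flag <- as.integer(flag); label <- as.integer(label)
  tp <- sum(flag == 1 & label == 1)
  fp <- sum(flag == 1 & label == 0)
  fn <- sum(flag == 0 & label == 1)
  tn <- sum(flag == 0 & label == 0)
  out <- tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_
  )
  class(out) <- c("cs_confusion", class(out))
  out
}

#' Screening utility
#'
#' \eqn{U(\phi) = \alpha\,TPR(\phi) - \beta\,FPR(\phi)}: the screening
#' objective trading missed cases (sensitivity, weighted by `alpha`)
#' against unjust exclusions (false alarms, weighted by `beta`). Bounded
#' in \eqn{[-\beta, \alpha]}.
#'
#' @param counts A `cs_confusion` row (from [confusion()]).
#' @param alpha,beta Strictly positive trade-off weights.
#' @return A single number.
#' @export
utility <- function(counts, alpha = 1, beta = 1) {
  if (alpha <= 0 || beta <= 0) cs_abort_config("`alpha` and `beta` must be positive")
  if (is.na(counts$tpr) || is.na(counts$fpr)) {
    cs_abort_data("utility undefined: degenerate labels (all 0 or all 1)")
  }
  alpha * counts$tpr - beta * counts$fpr
}

#' Tune the screening threshold by exhaustive utility search
#'
#' Flags are step functions of the threshold, so the utility only changes
#' at observed risk values: the candidate set defaults to the midpoints
#' between consecutive sorted unique risks plus the endpoints 0 and 1,
#' which makes the search exact. Ties in utility resolve toward the
#' smallest threshold, encoding the clinical preference for sensitivity.
#'
#' @param data A data frame holding risk and label columns, or `NULL` for
#'   bare vectors.
#' @param risk,label Column names (tidy-eval) or vectors.
#' @param alpha,beta Utility weights.
#' @param candidates Optional numeric vector of thresholds to evaluate.
#' @return A `cs_tuning` list: `tau` (the maximizer), `utility` (its
#'   utility), and `curve`, a tibble with one row per candidate
#'   (`tau`, `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`, `utility`).
#' @export
tune_threshold <- function(data = NULL, risk, label, alpha = 1, beta = 1,
                           candidates = NULL) {
  if (!is.null(data)) {
    risk <- dplyr::pull(data, {{ risk }})
    label <- dplyr::pull(data, {{ label }})
  }
  label <- as.integer(label)
  if (length(risk) != length(label)) {
    cs_abort_data("`risk` and `label` must have equal length")
  }
  if (!any(label == 1) || !any(label == 0)) {
    cs_abort_data("threshold tuning needs both classes in the labels")
  }
  if (is.null(candidates)) {
    u <- sort(unique(risk))
    mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
    candidates <- sort(unique(c(0, mids, 1)))
  }
  curve <- purrr::map_dfr(candidates, function(tau) {
    cc <- confusion(flag = classify(risk, tau), label = label)
    mutate(cc, tau = tau, utility = alpha * .data$tpr - beta * .data$fpr)
  })
  curve <- select(curve, "tau", "tp", "fp", "tn", "fn", "tpr", "fpr", "utility")
  best <- which(curve$utility >= max(curve$utility) - 1e-12)
  tau_star <- min(curve$tau[best])
  structure(
    list(
      tau = tau_star,
      utility = curve$utility[curve$tau == tau_star][[1]],
      alpha = alpha, beta = beta,
      curve = curve
    ),
    class = "cs_tuning"
  )
}

#' @export
print.cs_tuning <- function(x, ...) {
  cat(sprintf("<threshold tuning> tau* = %.4f, U = %.4f (alpha = %g, beta = %g)\n",
              x$tau, x$utility, x$alpha, x$beta))
  invisible(x)
}

#' Tidy a threshold tuning: the utility curve
#' @param x A `cs_tuning`.
#' @param ... Unused.
#' @return The per-candidate curve tibble.
#' @method tidy cs_tuning
#' @export
tidy.cs_tuning <- function(x, ...) x$curve

#' Glance at a threshold tuning
#' @param x A `cs_tuning`.
#' @param ... Unused.
#' @return One-row tibble with `tau`, `utility`, `alpha`, `beta`.
#' @method glance cs_tuning
#' @export
glance.cs_tuning <- function(x, ...) {
  tibble(tau = x$tau, utility = x$utility, alpha = x$alpha, beta = x$beta)
}

#' Hazard trajectory
#'
#' A sampled time-dependent hazard \eqn{\lambda(t)} on a strictly
#' increasing nonnegative time grid; the cumulative risk is its integral.
#'
#' @param time Strictly increasing nonnegative times.
#' @param hazard Nonnegative finite hazard values at the grid points.
#' @return A `cs_hazard` tibble with columns `time`, `hazard`.
#' @export
hazard_trajectory <- function(time, hazard) {
  if (length(time) != length(hazard) || length(time) < 2) {
    cs_abort_config("need matching time/hazard vectors of length >= 2")
  }
  if (any(diff(time) <= 0) || any(time < 0)) {
    cs_abort_config("time grid must be strictly increasing and nonnegative")
  }
  if (any(!is.finite(hazard)) || any(hazard < 0)) {
    cs_abort_config("hazards must be nonnegative and finite")
  }
  out <- tibble(time = as.numeric(time), hazard = as.numeric(hazard))
  class(out) <- c("cs_hazard", class(out))
  out
}

#' Cumulative temporal risk
#'
#' \eqn{R_t = \int_0^t \lambda(\tau)\,d\tau} by the trapezoid rule on the
#' trajectory's grid, exact for hazards that are piecewise linear between
#' grid points. The hazard at a query time inside a segment is linearly
#' interpolated.
#'
#' @param traj A `cs_hazard` (or data frame with `time` and `hazard`).
#' @param t Query time(s); each must lie within the grid range.
#' @return Nonnegative cumulative risk, one value per `t`.
#' @examples
#' traj <- hazard_trajectory(seq(0, 10), rep(0.02, 11))
#' cumulative_risk(traj, 10) # 0.2
#' @export
cumulative_risk <- function(traj, t) {
  tt <- traj$time; hh <- traj$hazard
  if (any(t < tt[1] - 1e-12) || any(t > tt[length(tt)] + 1e-12)) {
    cs_abort_data("query time outside the hazard grid range")
  }
  # cumulative trapezoid at the grid points
  seg <- diff(tt) * (hh[-1] + hh[-length(hh)]) / 2
  cum <- c(0, cumsum(seg))
  vapply(t, function(ti) {
    j <- findInterval(ti, tt, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(tt) - 1L)
    dt <- ti - tt[j]
    h_ti <- hh[j] + (hh[j + 1] - hh[j]) * dt / (tt[j + 1] - tt[j])
    cum[j] + dt * (hh[j] + h_ti) / 2
  }, numeric(1))
}
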