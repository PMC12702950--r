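#' Synthetic cohort generator configuration
#'
#' The generator draws each athlete's latent state from configured
#' proportions, then draws every feature independently from a Gaussian
#' with that state's per-coordinate mean and scale, and finally draws the
#' adverse-event label Bernoulli with the state's event prior
#' \eqn{\pi(z)}. The `overlap` control pulls the means of the two
#' grey-zone states (athletic remodeling and pathology) toward their
#' common midpoint by the given fraction of their separation, emulating
#' the physiological overlap between benign remodeling and early disease:
#' `overlap = 0` leaves the configured means, `overlap = 1` makes the two
#' states indistinguishable in mean.
#'
#' @param n Cohort size (>= 1).
#' @param schema A `cs_schema`.
#' @param states A `cs_states`.
#' @param state_proportions Probability vector over states (sums to 1).
#' @param state_means `|Z| x d` matrix of per-state feature means (rows in
#'   state order).
#' @param state_scales `|Z| x d` matrix of positive per-state feature
#'   standard deviations, or a single positive number.
#' @param overlap Grey-zone mean shrinkage in `[0, 1]`.
#' @param grey_states Length-2 character vector naming the two grey-zone
#'   states; default picks the labels containing "remodel" and "patho".
#' @param label_noise Probability of replacing an athlete's `true_state`
#'   label with a uniformly random other state (features unchanged).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `cs_generator_config`.
#' @export
generator_config <- function(n, schema, states, state_proportions,
                             state_means, state_scales = 1,
                             overlap = 0, grey_states = NULL,
                             label_noise = 0, seed = 1L) {
  nz <- n_states(states); d <- schema$total_dim
  if (n < 1) cs_abort_config("`n` must be at least 1")
  if (length(state_proportions) != nz ||
      abs(sum(state_proportions) - 1) > 1e-9 || any(state_proportions < 0)) {
    cs_abort_config("`state_proportions` must be a probability vector over states")
  }
  state_means <- as.matrix(state_means)
  if (!all(dim(state_means) == c(nz, d))) {
    cs_abort_config("`state_means` must be a |Z| x d matrix")
  }
  if (length(state_scales) == 1) {
    state_scales <- matrix(state_scales, nz, d)
  }
  state_scales <- as.matrix(state_scales)
  if (!all(dim(state_scales) == c(nz, d)) || any(state_scales <= 0)) {
    cs_abort_config("`state_scales` must be positive and |Z| x d")
  }
  if (overlap < 0) cs_abort_config("`overlap` must be nonnegative")
  overlap <- min(overlap, 1)
  if (is.null(grey_states)) {
    rem <- grep("remodel", states$state, value = TRUE)
    pat <- grep("patho", states$state, value = TRUE)
    grey_states <- c(rem[1], pat[1])
  }
  if (overlap > 0 && anyNA(grey_states)) {
    cs_abort_config("`overlap` > 0 requires two identifiable grey-zone states")
  }
  if (label_noise < 0 || label_noise > 1) {
    cs_abort_config("`label_noise` must lie in [0, 1]")
  }
  structure(
    list(n = as.integer(n), schema = schema, states = states,
         state_proportions = as.numeric(state_proportions),
         state_means = state_means, state_scales = state_scales,
         overlap = overlap, grey_states = grey_states,
         label_noise = label_noise, seed = as.integer(seed)),
    class = "cs_generator_config"
  )
}

# apply the grey-zone mean shrinkage
effective_means <- function(cfg) {
  M <- cfg$state_means
  if (cfg$overlap > 0 && !anyNA(cfg$grey_states)) {
    i <- state_index(cfg$states, cfg$grey_states[[1]])
    j <- state_index(cfg$states, cfg$grey_states[[2]])
    gap <- M[j, ] - M[i, ]
    M[i, ] <- M[i, ] + cfg$overlap / 2 * gap
    M[j, ] <- M[j, ] - cfg$overlap / 2 * gap
  }
  M
}

#' Generate a synthetic athlete cohort
#'
#' Draws a cohort from a [generator_config()]: latent states from the
#' configured proportions, features from per-state diagonal Gaussians
#' (grey-zone means pulled together by `overlap`), and event labels
#' Bernoulli with the per-state event prior. Byte-identical output for
#' identical configs and seeds.
#'
#' @param cfg A `cs_generator_config`.
#' @return A labeled `cs_cohort` with `true_state`, `event_label` and
#'   `athlete_id`.
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "cs_generator_config")) {
    cs_abort_config("`cfg` must be a generator config")
  }
  M <- effective_means(cfg)
  with_local_seed(cfg$seed, {
    z_idx <- sample.int(n_states(cfg$states), cfg$n, replace = TRUE,
                        prob = cfg$state_proportions)
    d <- cfg$schema$total_dim
    X <- matrix(rnorm(cfg$n * d), cfg$n, d)
    X <- X * cfg$state_scales[z_idx, , drop = FALSE] + M[z_idx, , drop = FALSE]
    colnames(X) <- cfg$schema$column_names
    y <- rbinom(cfg$n, 1, cfg$states$event_prior[z_idx])
    lab <- cfg$states$state[z_idx]
    if (cfg$label_noise > 0) {
      flip <- which(stats::runif(cfg$n) < cfg$label_noise)
      if (length(flip)) {
        nz <- n_states(cfg$states)
        lab[flip] <- vapply(z_idx[flip], function(zi) {
          cfg$states$state[sample(setdiff(seq_len(nz), zi), 1)]
        }, character(1))
      }
    }
    out <- as_tibble(X)
    out$event_label <- y
    out$true_state <- lab
    out$athlete_id <- sprintf("ath_%05d", seq_len(cfg$n))
    as_cohort(out, cfg$schema)
  })
}

# blockwise Gaussian perturbation of a feature vector
perturb_features <- function(x, magnitude, schema, seed, block_scales = NULL) {
  if (magnitude < 0) cs_abort_config("`magnitude` must be nonnegative")
  if (magnitude == 0) return(x)
  scales <- rep(1, schema$total_dim)
  if (!is.null(block_scales)) {
    blocks <- schema_blocks_of_columns(schema)
    missing_b <- setdiff(unique(blocks), names(block_scales))
    if (length(missing_b)) {
      cs_abort_config(sprintf(
        "block_scales missing block(s): %s", paste(missing_b, collapse = ", ")
      ))
    }
    scales <- as.numeric(block_scales[blocks])
  }
  with_local_seed(seed, x + rnorm(length(x), sd = magnitude * scales))
}

#' Perturb an athlete profile
#'
#' Adds seeded blockwise Gaussian noise to a profile's features,
#' emulating training-induced physiological variability. Per-block scale
#' multipliers default to 1; the noise standard deviation on a coordinate
#' is `magnitude * block_scale`. Magnitude 0 returns an identical copy,
#' and the same seed always yields the same perturbation.
#'
#' @param profile A named numeric feature vector or 1-row `cs_cohort`.
#' @param magnitude Noise scale (>= 0).
#' @param schema A `cs_schema` (defaults to the cohort's).
#' @param seed Integer seed.
#' @param block_scales Optional named numeric vector of per-block
#'   multipliers (e.g. each block's empirical standard deviation).
#' @return Same shape as `profile` with perturbed features.
#' @export
perturb_profile <- function(profile, magnitude, schema = NULL, seed = 1L,
                            block_scales = NULL) {
  if (is.numeric(profile) && is.null(dim(profile))) {
    if (is.null(schema)) cs_abort_config("a schema is required for a bare vector")
    return(perturb_features(profile, magnitude, schema, seed, block_scales))
  }
  schema <- schema %||% cohort_schema(profile)
  x <- as.numeric(cohort_matrix(profile, schema)[1, ])
  xp <- perturb_features(x, magnitude, schema, seed, block_scales)
  out <- profile
  out[1, schema$column_names] <- as.list(xp)
  out
}

# canonical study conditions shared by the named scenarios
scenario_schema <- function() {
  feature_schema(c(h = 3, f = 3, e = 8, s = 4, m = 2))
}

scenario_states <- function() {
  latent_states(
    c("normal", "remodeling", "borderline", "pathological"),
    event_prior = c(0.01, 0.02, 0.10, 0.30),
    exertion_risk = c(0.05, 0.10, 0.40, 0.90)
  )
}

#' Named synthetic study scenarios
#'
#' Three documented study conditions over the canonical four-state space
#' (normal, remodeling, borderline, pathological; event priors 0.01,
#' 0.02, 0.10, 0.30; exertion risks 0.05, 0.10, 0.40, 0.90) with a
#' 20-feature schema (h=3, f=3, e=8, s=4, m=2) where the ECG and echo
#' blocks are informative:
#'
#' * `separable`: state means laid out on a ladder 3 standard deviations
#'   apart on every informative coordinate -- used for parameter-recovery
#'   checks.
#' * `greyzone`: as `separable` but with the remodeling and pathological
#'   means pulled to within 0.5 standard deviations of each other
#'   (`overlap = 5/6`), emulating the diagnostic grey zone.
#' * `null`: all state means identical -- a negative control under which
#'   no classifier should beat chance.
#'
#' @param name One of `"separable"`, `"greyzone"`, `"null"`.
#' @param n Cohort size (default 2000).
#' @param seed Integer seed.
#' @return A `cs_generator_config`.
#' @export
default_scenario <- function(name = c("separable", "greyzone", "null"),
                             n = 2000L, seed = 1L) {
  name <- match.arg(name)
  schema <- scenario_schema()
  states <- scenario_states()
  d <- schema$total_dim
  informative <- grepl("^(e|s)_", schema$column_names)
  ladder <- c(normal = 0, remodeling = 1, borderline = 2, pathological = 3)
  M <- matrix(0, n_states(states), d)
  for (j in seq_len(n_states(states))) {
    M[j, informative] <- 3 * ladder[[states$state[j]]]
  }
  if (name == "null") M[] <- 0
  overlap <- if (name == "greyzone") 5 / 6 else 0
  if (name == "greyzone") {
    # adjacent ladder so the grey-zone pair starts 3 sd apart; overlap = 5/6
    # then shrinks that gap to 0.5 sd while the other states stay >= 3 sd away
    ladder <- c(normal = 0, borderline = 1, remodeling = 2, pathological = 3)
    for (j in seq_len(n_states(states))) {
      M[j, ] <- 0
      M[j, informative] <- 3 * ladder[[states$state[j]]]
    }
  }
  generator_config(
    n = n, schema = schema, states = states,
    state_proportions = c(0.55, 0.25, 0.12, 0.08),
    state_means = M, state_scales = 1,
    overlap = overlap, label_noise = 0, seed = seed
  )
}
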