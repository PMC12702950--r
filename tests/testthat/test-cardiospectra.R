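test_that("bilinear scoring matches the dense matrix product", {
  st3 <- latent_states(c("a", "b", "c"), c(0.1, 0.2, 0.3))
  # identity factorization: unit input along axis j scores 1 on state j
  m_id <- scoring_model(diag(3), diag(3), st3)
  for (j in 1:3) {
    x <- numeric(3); x[j] <- 1
    expect_equal(unname(score_states(x, m_id)[1, ]),
                 as.numeric(seq_len(3) == j))
  }
  expect_equal(unname(score_states(numeric(3), m_id)[1, ]), rep(0, 3))

  # random low-rank instance equals explicit x' Theta with Theta = U V'
  set.seed(11)
  U <- matrix(rnorm(4 * 2), 4, 2)
  V <- matrix(rnorm(3 * 2), 3, 2)
  m <- scoring_model(U, V, st3)
  X <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(unname(score_states(X, m)),
               unname(X %*% (U %*% t(V))), tolerance = 1e-12)

  expect_error(score_states(numeric(5), m), class = "cs_data_error")
  expect_error(scoring_model(matrix(0, 4, 5), matrix(0, 3, 5), st3),
               class = "cs_config_error")
})

test_that("scoring model fit recovers separable states and beats chance only with real labels", {
  fx <- two_state_cohort(n = 500, sep = 4, seed = 42)
  train <- cohort_slice(fx$cohort, 1:400)
  test <- cohort_slice(fx$cohort, 401:500)
  fit <- fit_scoring_model(train, fx$states, rank = 2, seed = 1)

  # loss trace is monotone non-increasing across accepted steps
  expect_true(all(diff(fit$fit$loss_trace) <= 1e-12))

  scores <- score_states(test, fit)
  map_acc <- mean(fx$states$state[max.col(scores)] == test$true_state)
  expect_gte(map_acc, 0.95)

  # permuted labels -> held-out accuracy near chance (1/2 +- 0.1)
  shuffled <- fx$cohort
  set.seed(5)
  shuffled$true_state <- sample(shuffled$true_state)
  fit_perm <- fit_scoring_model(cohort_slice(shuffled, 1:400), fx$states,
                                rank = 2, seed = 1)
  acc_perm <- mean(
    fx$states$state[max.col(score_states(test, fit_perm))] == test$true_state
  )
  expect_lt(abs(acc_perm - 0.5), 0.1)
})

test_that("full-rank factorized fit reproduces the dense-parameter optimum", {
  fx <- two_state_cohort(n = 300, sep = 4, seed = 7)
  fit_fact <- fit_scoring_model(fx$cohort, fx$states, rank = 2, seed = 3)
  fit_dense <- fit_scoring_model(fx$cohort, fx$states, rank = NULL, seed = 3)
  expect_lt(abs(fit_fact$fit$loss - fit_dense$fit$loss), 1e-6)
})

test_that("fit validates labels and sizes", {
  fx <- two_state_cohort(n = 50, seed = 1)
  unlabeled <- fx$cohort
  unlabeled$true_state <- NULL
  expect_error(fit_scoring_model(unlabeled, fx$states),
               class = "cs_data_error")
})

test_that("single-profile screening composes mask, scores, posterior and decision", {
  sch <- tiny_schema()
  st <- four_states()
  # model scoring pathological strongly from e_1
  U <- matrix(0, 6, 2); U[3, 1] <- 1
  V <- matrix(0, 4, 2); V[4, 1] <- 5; V[3, 1] <- 1
  m <- scoring_model(U, V, st, schema = sch)
  x <- setNames(c(0, 0, 1, 0, 0, 0), sch$column_names)

  dec <- screen_profile(x, m, st, s = 2, tau = 0.25, eps_r = 0.05)
  expect_s3_class(dec, "cs_decision")
  # gap 5 - 1 >= 1 saturates sparsemax at pathological (pi = 0.30)
  expect_equal(dec$risk, 0.30)
  expect_equal(dec$flag, 1L)
  expect_equal(dec$rationalization, "pathological")

  # all states sharing one prior -> risk equals it regardless of the model
  st_flat <- latent_states(st$state, rep(0.2, 4))
  dec_flat <- screen_profile(x, m, st_flat, s = 2, tau = 0.5)
  expect_equal(dec_flat$risk, 0.2)
  expect_equal(dec_flat$flag, 0L)

  # masking out the argmax state reshapes the support accordingly
  rules <- compat_rules(data.frame(
    state = "pathological", column = "e_1", op = ">", value = 2
  ), sch)
  dec_masked <- screen_profile(x, m, st, rules = rules, s = 2, tau = 0.25)
  expect_false("pathological" %in% dec_masked$rationalization)
  scores <- score_states(x, m)[1, ]
  ref <- sparse_posterior(scores, s = 2, mask = c(1, 1, 1, 0),
                          labels = st$state)
  expect_equal(dec_masked$posterior$q, ref$q)
})

test_that("cohort screening handles referral fallback and ablations", {
  sch <- tiny_schema()
  st <- four_states()
  set.seed(21)
  X <- matrix(rnorm(30 * 6), 30, 6)
  colnames(X) <- sch$column_names
  cohort <- as_cohort(as.data.frame(X), sch)
  m <- scoring_model(matrix(rnorm(12), 6, 2), matrix(rnorm(8), 4, 2),
                     st, schema = sch)

  # impossible rule set: every state gated on an impossible predicate
  impossible <- compat_rules(data.frame(
    state = st$state, column = "h_1", op = ">", value = 1e6
  ), sch)
  expect_error(
    screen_cohort(cohort, m, st, rules = impossible),
    class = "cs_data_error"
  )
  ref <- screen_cohort(cohort, m, st, rules = impossible,
                       on_incompatible = "refer")
  expect_true(all(ref$referred))
  expect_true(all(ref$flag == 1L))
  expect_true(all(is.na(ref$risk)))

  # no_compat ignores the rules entirely
  plain <- screen_cohort(cohort, m, st)
  no_compat <- screen_cohort(cohort, m, st, rules = impossible,
                             no_compat = TRUE)
  expect_equal(no_compat$risk, plain$risk)

  # dense-softmax ablation puts every state in the support
  dense <- screen_cohort(cohort, m, st, no_sparse_posterior = TRUE)
  expect_true(all(dense$n_support == 4))
  expect_true(all(plain$n_support <= 2))
})

test_that("scoring models survive JSON serialization with validation", {
  fx <- two_state_cohort(n = 60, seed = 3)
  fit <- fit_scoring_model(fx$cohort, fx$states, rank = 2, seed = 1,
                           max_iter = 200)
  path <- withr::local_tempfile(fileext = ".json")
  write_scoring_model(fit, path, s = 2, tau = 0.4, eps_r = 0.02)
  back <- read_scoring_model(path, states = fx$states)
  expect_equal(back$U, fit$U, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$V, fit$V, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$decision, list(s = 2L, tau = 0.4, eps_r = 0.02))
  # scores from the reloaded model match
  expect_equal(score_states(fx$cohort, back), score_states(fx$cohort, fit),
               tolerance = 1e-12)

  # corrupted file is rejected
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(type = "something_else"), bad, auto_unbox = TRUE)
  expect_error(read_scoring_model(bad), class = "cs_data_error")
})

test_that("tidy and glance summarize a fitted scoring model", {
  fx <- two_state_cohort(n = 80, seed = 2)
  fit <- fit_scoring_model(fx$cohort, fx$states, rank = 1, seed = 1,
                           max_iter = 300)
  td <- tidy(fit)
  expect_equal(nrow(td), 6 * 2)
  expect_named(td, c("term", "state", "estimate"))
  Theta <- fit$U %*% t(fit$V)
  expect_equal(td$estimate[td$state == "benign"], unname(Theta[, 1]))
  gl <- glance(fit)
  expect_equal(gl$rank, 1)
  expect_true(gl$converged %in% c(TRUE, FALSE))
})
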