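make_trials <- function(n_participants = 20, n_pairs = 10, seed = 1,
                        p_correct = 0.6) {
  withr::local_seed(seed)
  g <- expand.grid(
    participant_id = sprintf("p%02d", seq_len(n_participants)),
    pair_id = sprintf("pair%02d", seq_len(n_pairs)),
    language = c("japanese", "polish", "french"),
    stringsAsFactors = FALSE)
  tibble::tibble(
    participant_id = g$participant_id,
    language = g$language,
    pair_id = g$pair_id,
    pos = rep(c("noun", "verb", "adjective"), length.out = nrow(g)),
    correct = stats::rbinom(nrow(g), 1, p_correct),
    known_word_flag = FALSE
  )
}

test_that("known-word filtering removes flagged trials and reports the rate", {
  tr <- make_trials()
  tr$known_word_flag[1:60] <- TRUE
  out <- filter_known_word_trials(tr)
  expect_equal(nrow(out$trials), nrow(tr) - 60)
  expect_false(any(out$trials$known_word_flag))
  expect_equal(out$removed_fraction, 60 / nrow(tr))

  none <- filter_known_word_trials(make_trials())
  expect_equal(none$removed_fraction, 0)

  tr$known_word_flag[5] <- NA
  expect_error(filter_known_word_trials(tr), "data-integrity")
})

test_that("low-WM exclusion uses mean minus k sample SDs", {
  pp <- tibble::tibble(participant_id = paste0("p", 1:5),
                       wm_span = c(10, 16, 17, 18, 20))
  out <- exclude_low_wm(pp, k = 1.5)
  expect_equal(out$threshold, mean(pp$wm_span) - 1.5 * sd(pp$wm_span))
  expect_equal(out$excluded$wm_span, 10)
  expect_equal(nrow(out$participants), 4)

  flat <- tibble::tibble(participant_id = paste0("p", 1:4),
                         wm_span = rep(15, 4))
  expect_warning(out2 <- exclude_low_wm(flat), "zero variance")
  expect_equal(nrow(out2$participants), 4)
})

test_that("standardization follows the sample-sd convention on analysis rows", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(10, 20, 60))
  z <- standardize_predictors(d, c("x", "y"))
  expect_equal(z$x_z, c(-1, 0, 1))
  expect_equal(mean(z$y_z), 0)
  expect_equal(sd(z$y_z), 1)
  # idempotent on already-standardized input
  z2 <- standardize_predictors(z, "x_z")
  expect_equal(z2$x_z_z, z$x_z, tolerance = 1e-12)
  # parameters recorded, from the rows supplied (i.e. post-exclusion)
  params <- attr(z, "standardization")
  expect_equal(params$center[params$covariate == "x"], 2)
  sub <- standardize_predictors(d[1:2, ], "x")
  expect_equal(attr(sub, "standardization")$center[1], 1.5)

  expect_error(standardize_predictors(tibble::tibble(x = c(1, 1, 1)), "x"),
               "degenerate-covariate")
})

test_that("accuracy model sum-codes factors and records its structure", {
  tr <- make_trials(seed = 7)
  fit <- fit_accuracy_model(tr, correct ~ language * pos, nAGQ = 0)
  expect_s3_class(fit, "accuracy_fit")
  expect_equal(fit$fallback, "full")
  expect_true(all(c("participant_id", fit$item) %in% names(fit$data)))
  # sum coding: per-level effects (contrast matrix x coefficients) sum to 0
  co <- fit$coefficients
  lang_coefs <- co$estimate[grepl("^language", co$term) &
                              !grepl(":", co$term)]
  cm <- fit$contrasts$language
  level_effects <- cm %*% lang_coefs
  expect_lt(abs(sum(level_effects)), 1e-8)
  expect_equal(colSums(cm), rep(0, ncol(cm)), ignore_attr = TRUE)

  expect_error(fit_accuracy_model(dplyr::mutate(tr, correct = 1),
                                  correct ~ language),
               "separation")
})

test_that("likelihood-ratio tests drop the term and its higher orders", {
  tr <- make_trials(seed = 8)
  fit <- fit_accuracy_model(tr, correct ~ language * pos, nAGQ = 0)
  lr <- lr_test(fit, "language:pos")
  expect_equal(lr$df, 4)  # (3-1)*(3-1)
  expect_true(lr$p > 0 && lr$p <= 1)
  expect_error(lr_test(fit, "wm"), "specification error")
})

test_that("above-chance tests report Sidak-adjusted per-level estimates", {
  tr <- make_trials(seed = 9, p_correct = 0.7)
  fit <- fit_accuracy_model(tr, correct ~ language, nAGQ = 0)
  ch <- test_above_chance(fit, "language")
  expect_equal(nrow(ch), 3)
  expect_equal(ch$p_adj, sidak_adjust(ch$p, 3), tolerance = 1e-12)
  expect_true(all(ch$prob > 0.5))
  # inverse-logit consistency between scales
  expect_equal(ch$prob, plogis(ch$logit), tolerance = 1e-6)
  expect_error(test_above_chance(fit, "pos"), "specification error")
})

test_that("sidak adjustment is closed-form, monotone and order-preserving", {
  expect_equal(sidak_adjust(0.01, 9), 1 - 0.99^9)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  p <- c(0.001, 0.04, 0.2, 0.7)
  pa <- sidak_adjust(p, 6)
  expect_true(all(pa >= p))
  expect_identical(order(pa), order(p))
})

test_that("pairwise comparisons produce the full odds-ratio family", {
  tr <- make_trials(n_participants = 25, seed = 10)
  fit <- fit_accuracy_model(tr, correct ~ language, nAGQ = 0)
  pw <- pairwise_factor_comparisons(fit, "language")
  expect_equal(nrow(pw), choose(3, 2))
  expect_true(all(pw$ci_low <= pw$odds_ratio & pw$odds_ratio <= pw$ci_high))
  expect_error(
    pairwise_factor_comparisons(fit, "language", adjust = "scheffe"))
  expect_error(pairwise_factor_comparisons(fit, "pos"), "specification")
})

test_that("simple slopes match the interaction structure", {
  withr::local_seed(11)
  n <- 4000
  d <- tibble::tibble(
    participant_id = sample(sprintf("p%02d", 1:40), n, replace = TRUE),
    item_id = sample(sprintf("i%02d", 1:30), n, replace = TRUE),
    reg = rnorm(n), wm = rnorm(n))
  eta <- 0.3 + 0.2 * d$reg + 0.1 * d$wm + 0.1 * d$reg * d$wm
  d$correct <- rbinom(n, 1, plogis(eta))
  fit <- fit_accuracy_model(d, correct ~ reg * wm, nAGQ = 0)
  ss <- simple_slopes(fit, "wm", "reg")
  expect_equal(nrow(ss), 2)
  # slope difference across +/- 1 SD recovers twice the interaction
  delta_hat <- diff(ss$slope)
  beta_int <- fit$coefficients$estimate[fit$coefficients$term == "reg:wm"]
  expect_equal(delta_hat, 2 * beta_int * sd(d$reg), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(ss$odds_ratio, exp(ss$slope))

  fit0 <- fit_accuracy_model(d, correct ~ reg + wm, nAGQ = 0)
  expect_error(simple_slopes(fit0, "wm", "reg"), "specification")

  # zero interaction: identical slopes at both moderator values
  d2 <- d
  d2$correct <- rbinom(n, 1, plogis(0.3 + 0.2 * d2$reg + 0.1 * d2$wm))
  fitz <- fit_accuracy_model(d2, correct ~ reg + wm + reg:wm, nAGQ = 0)
  ssz <- simple_slopes(fitz, "wm", "reg")
  # both conditional slopes estimate the same main effect
  expect_equal(ssz$slope[1], ssz$slope[2],
               tolerance = 10 * ssz$se[1])
})

test_that("the fallback ladder ends in robust logistic regression", {
  # two participants / few items: item variance unidentifiable, but the
  # ladder must still return a usable fit object
  tr <- make_trials(n_participants = 2, n_pairs = 2, seed = 12)
  fit <- fit_accuracy_model(tr, correct ~ language, nAGQ = 0)
  expect_true(fit$fallback %in% c("full", "no_item", "glm_robust"))
  expect_true(all(is.finite(fit$coefficients$se)))
})
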