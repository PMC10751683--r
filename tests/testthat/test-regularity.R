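test_that("regularity hits the normalization extremes on toy lexicons", {
  # same-meaning translations identical, opposite-meaning share no classes
  lex <- iconic_3lang_lexicon()
  reg <- regularity_scores(lex, sca)
  expect_equal(reg$same_mean, rep(0, nrow(reg)))
  expect_equal(reg$opp_mean, rep(1, nrow(reg)))
  expect_equal(reg$value, rep(1, nrow(reg)))

  # every word identical: value is exactly 0
  forms <- list(
    l1 = c(p1_w1 = "KATA", p1_w2 = "KATA"),
    l2 = c(p1_w1 = "KATA", p1_w2 = "KATA"),
    l3 = c(p1_w1 = "KATA", p1_w2 = "KATA")
  )
  lex0 <- toy_lexicon(forms, c(l1 = "slavic", l2 = "romance",
                               l3 = "japonic_sino_tai"))
  reg0 <- regularity_scores(lex0, sca)
  expect_equal(reg0$value, rep(0, nrow(reg0)))
})

test_that("comparison sets respect group exclusion and configuration", {
  cfg <- sim_config(n_participants = 2, seed = 21)
  lex <- generate_lexicon(cfg)
  reg <- regularity_scores(lex, sca, native_language = "english")
  # original configuration: six languages outside the target pair's group
  expect_true(all(reg$n_comparisons == 6))
  expect_equal(nrow(reg), 45 * 9)
  expect_false("english" %in% reg$language)

  # replication rescoring: native excluded, former native included
  rep_reg <- recompute_for_replication(lex, sca,
                                       native_language = "spanish",
                                       include_languages = "english")
  expect_false("spanish" %in% rep_reg$language)
  expect_true("english" %in% rep_reg$language)
  # japonic/slavic targets now compare against 6 of 9 remaining languages:
  # outside-group languages minus spanish plus english
  jp <- rep_reg[rep_reg$language == "japanese", ]
  expect_true(all(jp$n_comparisons == 6))

  expect_error(
    recompute_for_replication(lex, sca, native_language = "spanish",
                              include_languages = c("english", "spanish")),
    "configuration error")
  expect_error(
    regularity_scores(lex, sca,
                      comparison = comparison_spec(
                        include_languages = "x", exclude_languages = "x")),
    "configuration error")
})

test_that("swapping a pair's concepts flips the word scores but not |value|", {
  cfg <- sim_config(n_languages = 6, n_pairs = 6, n_participants = 2,
                    iconicity_rho = 0.4, seed = 33)
  lex <- generate_lexicon(cfg)
  reg <- regularity_scores(lex, sca)

  swapped <- lex
  p <- "pair03"
  idx <- swapped$pair_id == p
  swapped$concept_id[idx] <- ifelse(
    grepl("_w1$", swapped$concept_id[idx]),
    sub("_w1$", "_w2", swapped$concept_id[idx]),
    sub("_w2$", "_w1", swapped$concept_id[idx]))
  reg_sw <- regularity_scores(swapped, sca)
  a <- reg[reg$pair_id == p, ]
  b <- reg_sw[reg_sw$pair_id == p, ]
  expect_equal(abs(a$value), abs(b$value), tolerance = 1e-12)
  # unswapped pairs unchanged
  expect_equal(reg$value[reg$pair_id != p], reg_sw$value[reg_sw$pair_id != p])
})

test_that("the mixed-model meaning test recovers direction and degeneracy", {
  cfg <- sim_config(n_languages = 6, n_pairs = 15, n_participants = 2,
                    iconicity_rho = 0.6, seed = 44)
  lex <- generate_lexicon(cfg)
  rec <- pairwise_distance_table(lex, model = sca)
  fit <- meaning_effect_test(rec, moderators = "pos")
  expect_lt(fit$estimate, 0)   # same-meaning forms are closer
  expect_lt(fit$p, 0.05)
  expect_gt(fit$se, 0)
  expect_equal(nrow(fit$moderators_tested), 1)

  # constant distances: estimate exactly zero
  rec0 <- rec
  rec0$distance <- 0.5
  fit0 <- meaning_effect_test(rec0)
  expect_identical(fit0$estimate, 0)

  expect_error(meaning_effect_test(rec[rec$relation == "same_meaning", ]),
               "degenerate-design")
})

test_that("permutation test is extreme for iconic and flat for constant data", {
  lex <- iconic_3lang_lexicon()
  rec <- pairwise_distance_table(lex, scope = "all", model = sca)
  pt <- permutation_meaning_test(rec, n_perm = 199, seed = 1)
  expect_equal(pt$p, 1 / 200)   # observed is the most extreme possible

  rec0 <- rec
  rec0$distance <- 0.5
  pt0 <- permutation_meaning_test(rec0, n_perm = 199, seed = 1)
  expect_equal(pt0$observed, 0)
  expect_equal(pt0$p, 1)

  expect_error(permutation_meaning_test(rec, n_perm = 50), "configuration")
})

test_that("mixed model and permutation test agree on sign and significance", {
  withr::local_seed(555)
  for (rho in c(0, 0.7)) {
    agree <- replicate(5, {
      seed <- sample.int(10000, 1)
      cfg <- sim_config(n_languages = 6, n_pairs = 15, n_participants = 2,
                        iconicity_rho = rho, seed = seed)
      lex <- generate_lexicon(cfg)
      rec <- pairwise_distance_table(lex, scope = "all", model = sca)
      fit <- meaning_effect_test(rec)
      pt <- permutation_meaning_test(rec, n_perm = 199, seed = seed)
      (fit$p < 0.05) == (pt$p < 0.05)
    })
    expect_gte(mean(agree), 0.8)
  }
})
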