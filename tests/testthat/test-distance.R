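test_that("alignment handles identity and forced-gap cases", {
  d <- diag(sca$similarity)
  al <- align_class_strings("KAT", "KAT", sca)
  expect_equal(al$score, d[["K"]] + d[["A"]] + d[["T"]])
  expect_true(all(!is.na(al$pairs$a_pos)))
  # 3-vs-1: two gaps are forced
  al2 <- align_class_strings("KAT", "K", sca)
  expect_equal(al2$score, sca$similarity["K", "K"] + 2 * sca$gap_penalty)
  # score is recomputable from the per-column contributions
  expect_equal(sum(al2$pairs$contribution), al2$score)
})

test_that("alignment score matches the brute-force oracle", {
  # small hand-checkable case: best of the five global alignments
  expect_equal(align_class_strings("KA", "A", sca)$score,
               brute_force_alignment_oracle("KA", "A", sca))
  expect_equal(brute_force_alignment_oracle("KA", "A", sca),
               sca$similarity["A", "A"] + sca$gap_penalty)

  withr::local_seed(202)
  for (i in 1:50) {
    a <- random_class_string(sample(1:5, 1))
    b <- random_class_string(sample(1:5, 1))
    expect_equal(align_class_strings(a, b, sca)$score,
                 brute_force_alignment_oracle(a, b, sca),
                 info = paste(a, b))
  }
  expect_error(brute_force_alignment_oracle("KAKAKAK", "KA", sca),
               "oracle-scope")
})

test_that("alignment rejects invalid class codes and empty strings", {
  expect_error(align_class_strings("KZT", "KAT", sca), "invalid-class")
  expect_error(align_class_strings("", "KAT", sca), "invalid-input")
})

test_that("distance is zero at identity and one when nothing aligns", {
  expect_equal(phonetic_distance("kat", "kat", sca), 0)
  # distance frozen once from the oracle: S(KAT, TOK) = 3,
  # self-scores 27 each, d = 1 - 6/54 = 8/9
  s <- brute_force_alignment_oracle("KAT", "TOK", sca)
  expect_equal(1 - 2 * s / (27 + 27), 8 / 9)
  expect_equal(phonetic_distance("kat", "dɔg", sca), 8 / 9)
  # one-phone words with non-positive cross similarity clip to 1
  expect_equal(phonetic_distance("k", "m", sca), 1)
})

test_that("distance contract holds on random pairs", {
  withr::local_seed(303)
  for (i in 1:100) {
    a <- random_class_string(sample(1:6, 1))
    b <- random_class_string(sample(1:6, 1))
    dab <- phonetic_distance(list(classes = a), list(classes = b), sca)
    dba <- phonetic_distance(list(classes = b), list(classes = a), sca)
    expect_identical(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dab, 1)
    if (a == b) expect_identical(dab, 0)
  }
})

test_that("appending an unmatched phone perturbs the distance as bounded", {
  # Appending a phone to one of two identical words strictly increases the
  # distance from zero. For non-identical words no monotonicity holds in
  # general (the extra phone can absorb a gap or shift the alignment
  # register to free a better match), but the raw score can move by at most
  # the gap magnitude when the appended class has zero similarity to every
  # class of the other word.
  withr::local_seed(404)
  zero_related <- c("P", "T", "K", "N", "L", "W", "J")
  for (i in 1:40) {
    a <- random_class_string(sample(2:5, 1))
    d_self <- phonetic_distance(list(classes = paste0(a, "G")),
                                list(classes = a), sca)
    expect_gt(d_self, 0)

    b <- random_class_string(sample(1:5, 1))
    bc <- strsplit(b, "")[[1]]
    free <- zero_related[vapply(zero_related, function(cl) {
      all(sca$similarity[cl, bc] == 0)
    }, logical(1))]
    if (!length(free)) next
    s0 <- align_class_strings(a, b, sca)$score
    s1 <- align_class_strings(paste0(a, free[1]), b, sca)$score
    expect_lte(abs(s1 - s0), abs(sca$gap_penalty) + 1e-12)
  }
})

test_that("pairwise table enumerates cross-language pairs with relations", {
  forms <- list(
    l1 = c(p1_w1 = "KATA", p1_w2 = "SILU"),
    l2 = c(p1_w1 = "KETA", p1_w2 = "SALU")
  )
  lex <- toy_lexicon(forms, c(l1 = "slavic", l2 = "romance"))
  rec <- pairwise_distance_table(lex, scope = c("same_meaning",
                                                "opposite_meaning"),
                                 model = sca)
  expect_equal(nrow(rec), 4)
  expect_equal(sum(rec$relation == "same_meaning"), 2)
  expect_equal(sum(rec$relation == "opposite_meaning"), 2)
  # symmetric duplicates absent
  expect_equal(anyDuplicated(
    cbind(pmin(rec$word_a, rec$word_b), pmax(rec$word_a, rec$word_b))), 0)

  # native-translation scope counts: one record per foreign word
  cfg <- sim_config(n_participants = 2, seed = 9)
  lex10 <- generate_lexicon(cfg)
  nat <- pairwise_distance_table(lex10, scope = "native_translation",
                                 model = sca, native_language = "english")
  expect_equal(nrow(nat), 90 * 9)

  expect_equal(nrow(pairwise_distance_table(lex[0, ], model = sca)), 0)
})

test_that("missing native translations are reported by name", {
  forms <- list(
    eng = c(p1_w1 = "KATA", p1_w2 = "SILU"),
    l2 = c(p1_w1 = "KETA", p1_w2 = "SALU", p2_w1 = "NOTO")
  )
  lex <- toy_lexicon(forms, c(eng = "germanic", l2 = "romance"))
  expect_error(
    pairwise_distance_table(lex, scope = "native_translation",
                            model = sca, native_language = "eng"),
    "missing-entry.*p2_w1")
})
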