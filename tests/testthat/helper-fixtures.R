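# Shared fixtures: the shipped sound-class model, random class strings and
# tiny hand-built lexicons.

sca <- load_sound_class_model("sca_default")

# consonant + vowel codes usable for random class strings (no tone/unknown)
segmental_codes <- function(model = sca) {
  setdiff(model$class_alphabet, c("1", model$unknown_code))
}

random_class_string <- function(len, model = sca) {
  paste(sample(segmental_codes(model), len, replace = TRUE), collapse = "")
}

# A full (concept x language) toy lexicon from a named list:
# forms[[language]] = c(concept_id = class_string, ...)
toy_lexicon <- function(forms, groups, pos = "adjective") {
  purrr::map_dfr(names(forms), function(lang) {
    cids <- names(forms[[lang]])
    tibble::tibble(
      pair_id = sub("_w[12]$", "", cids),
      concept_id = cids,
      pair_role = paste0("word", sub("^.*_w", "", cids)),
      pos = pos,
      language = lang,
      language_group = groups[[lang]],
      orthography = tolower(forms[[lang]]),
      ipa = NA_character_,
      classes = unname(forms[[lang]])
    )
  })
}

# Three languages in three groups, four antonym pairs; same-meaning forms
# identical across languages, and the two members of each pair built from
# classes with zero cross-similarity (P, T, K, N, L, W, J are mutually
# unrelated in the shipped table), so within-pair distances are exactly 1.
iconic_3lang_lexicon <- function() {
  one <- c(pair1_w1 = "PPPP", pair1_w2 = "TTTT",
           pair2_w1 = "KKKK", pair2_w2 = "NNNN",
           pair3_w1 = "LLLL", pair3_w2 = "WWWW",
           pair4_w1 = "JJJJ", pair4_w2 = "PTKN")
  forms <- list(l1 = one, l2 = one, l3 = one)
  toy_lexicon(forms, c(l1 = "slavic", l2 = "romance",
                       l3 = "japonic_sino_tai"))
}
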