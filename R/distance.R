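# Normalized phonetic distances between word forms via global alignment of
# sound-class strings. The similarity S between two class strings is the
# maximum global alignment score under the model's class-pair table and
# linear gap penalty; the distance is
#
#   d(a, b) = 1 - 2 S(a,b) / (S(a,a) + S(b,b)),   clipped to [0, 1],
#
# so identical forms are at 0 and fully unalignable forms near 1, matching
# distances that lie in [0, 1] with higher values meaning greater phonetic
# distance.

classes_to_idx <- function(s, model) {
  codes <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(codes, model$class_alphabet)
  if (anyNA(idx)) {
    stop("invalid-class error: code(s) ",
         paste(unique(codes[is.na(idx)]), collapse = ", "),
         " not in the model's class alphabet", call. = FALSE)
  }
  idx
}

#' Globally align two sound-class strings
#'
#' Needleman-Wunsch global alignment under the model's similarity table and
#' linear gap penalty. Traceback ties are broken deterministically:
#' match/mismatch is preferred over a gap in `b`, which is preferred over a
#' gap in `a`; the score is tie-invariant.
#'
#' @param a,b Non-empty sound-class strings over the model's alphabet.
#' @param model A [sound_class_model()].
#' @return An object of class `alignment`: list with `pairs` (tibble of
#'   `a_pos`, `b_pos`, `contribution`; `NA` marks a gap), `score`, `a_len`,
#'   `b_len`.
#' @export
align_class_strings <- function(a, b, model) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("invalid-input error: class strings must be non-empty",
         call. = FALSE)
  }
  ia <- classes_to_idx(a, model)
  ib <- classes_to_idx(b, model)
  res <- .nw_align(ia, ib, model$similarity, model$gap_penalty)
  pr <- res$pairs
  contrib <- vapply(seq_len(nrow(pr)), function(k) {
    if (is.na(pr[k, 1]) || is.na(pr[k, 2])) {
      model$gap_penalty
    } else {
      model$similarity[ia[pr[k, 1]], ib[pr[k, 2]]]
    }
  }, numeric(1))
  structure(
    list(
      pairs = tibble::tibble(a_pos = pr[, 1], b_pos = pr[, 2],
                             contribution = contrib),
      score = res$score,
      a_len = length(ia),
      b_len = length(ib)
    ),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment: score %g over %d columns (%d x %d)>\n",
              x$score, nrow(x$pairs), x$a_len, x$b_len))
  invisible(x)
}

self_score <- function(idx, model) {
  sum(diag(model$similarity)[idx])
}

#' Normalized phonetic distance between two word forms
#'
#' @param word_a,word_b Either plain IPA strings, or rows (lists/one-row
#'   data frames) carrying a `classes` field (sound-class string) or an
#'   `ipa` field.
#' @param model A [sound_class_model()].
#' @param ... Passed to [encode_classes()] when IPA must be encoded.
#' @return Distance in `[0, 1]`; exactly 0 for identical class strings.
#' @export
phonetic_distance <- function(word_a, word_b, model, ...) {
  ca <- word_classes(word_a, model, ...)
  cb <- word_classes(word_b, model, ...)
  if (identical(ca, cb)) return(0)
  ia <- classes_to_idx(ca, model)
  ib <- classes_to_idx(cb, model)
  saa <- self_score(ia, model)
  sbb <- self_score(ib, model)
  if (saa <= 0 || sbb <= 0) {
    stop("numeric-degeneracy error: non-positive self-alignment score",
         call. = FALSE)
  }
  s <- .nw_score(ia, ib, model$similarity, model$gap_penalty)
  min(1, max(0, 1 - 2 * s / (saa + sbb)))
}

word_classes <- function(word, model, ...) {
  if (is.character(word) && length(word) == 1) {
    return(encode_classes(word, model, ...))
  }
  if ("classes" %in% names(word) && !is.na(word$classes[1])) {
    return(word$classes[1])
  }
  if ("ipa" %in% names(word)) {
    return(encode_classes(word$ipa[1], model, ...))
  }
  stop("invalid-input error: word must be an IPA string or carry a ",
       "'classes' or 'ipa' field", call. = FALSE)
}

#' Table of pairwise cross-language phonetic distances
#'
#' Computes one record per unordered cross-language word pair in scope.
#' Relations: `native_translation` (concepts match and exactly one side is
#' the native language), `same_meaning` (concepts match across two non-native
#' languages), `opposite_meaning` (same antonym pair, different concepts),
#' `unrelated` otherwise (returned only under `scope = "all"`).
#'
#' @param lexicon Stimulus tibble with columns `pair_id`, `concept_id`,
#'   `pair_role`, `pos`, `language`, `language_group`, and `classes` or
#'   `ipa`.
#' @param scope Character vector of relations to keep, or `"all"` for every
#'   cross-language pair.
#' @param model A [sound_class_model()].
#' @param native_language Language identifier treated as native for the
#'   `native_translation` relation, or `NULL`.
#' @param ... Passed to [encode_classes()].
#' @return Tibble of distance records: `word_a`, `word_b`, `language_a`,
#'   `language_b`, `concept_a`, `concept_b`, `pair_a`, `pair_b`, `pos_a`,
#'   `relation`, `distance`.
#' @export
pairwise_distance_table <- function(lexicon,
                                    scope = c("same_meaning",
                                              "opposite_meaning"),
                                    model,
                                    native_language = NULL, ...) {
  if (!nrow(lexicon)) {
    return(tibble::tibble(
      word_a = character(), word_b = character(),
      language_a = character(), language_b = character(),
      concept_a = character(), concept_b = character(),
      pair_a = character(), pair_b = character(), pos_a = character(),
      relation = character(), distance = numeric()
    ))
  }
  if (nrow(lexicon) < 2) {
    return(pairwise_distance_table(lexicon[0, ], scope, model))
  }
  lex <- ensure_classes(lexicon, model, ...)
  if (any(!nzchar(lex$classes))) {
    stop("invalid-input error: empty class string in lexicon", call. = FALSE)
  }

  if ("native_translation" %in% scope && !is.null(native_language)) {
    foreign <- lex[lex$language != native_language, ]
    native_concepts <- lex$concept_id[lex$language == native_language]
    miss <- setdiff(unique(foreign$concept_id), native_concepts)
    if (length(miss)) {
      stop("missing-entry error: no ", native_language,
           " translation for concept(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }

  seqs <- lapply(lex$classes, classes_to_idx, model = model)
  D <- .nw_dist_matrix(seqs, model$similarity, model$gap_penalty)

  n <- nrow(lex)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1, from = 2:n)
  keep <- lex$language[ii] != lex$language[jj]
  ii <- ii[keep]; jj <- jj[keep]

  same_concept <- lex$concept_id[ii] == lex$concept_id[jj]
  same_pair <- lex$pair_id[ii] == lex$pair_id[jj]
  has_native <- if (is.null(native_language)) {
    rep(FALSE, length(ii))
  } else {
    xor(lex$language[ii] == native_language,
        lex$language[jj] == native_language)
  }
  relation <- dplyr::case_when(
    same_concept & has_native ~ "native_translation",
    same_concept ~ "same_meaning",
    same_pair ~ "opposite_meaning",
    .default = "unrelated"
  )

  out <- tibble::tibble(
    word_a = paste(lex$language[ii], lex$concept_id[ii], sep = "."),
    word_b = paste(lex$language[jj], lex$concept_id[jj], sep = "."),
    language_a = lex$language[ii],
    language_b = lex$language[jj],
    concept_a = lex$concept_id[ii],
    concept_b = lex$concept_id[jj],
    pair_a = lex$pair_id[ii],
    pair_b = lex$pair_id[jj],
    pos_a = lex$pos[ii],
    relation = relation,
    distance = D[cbind(ii, jj)]
  )
  if (!identical(scope, "all")) {
    out <- out[out$relation %in% scope, , drop = FALSE]
  }
  out
}

# Add a 'classes' column to a lexicon if absent, encoding from IPA.
ensure_classes <- function(lexicon, model, ...) {
  if (!"classes" %in% names(lexicon)) {
    if (!"ipa" %in% names(lexicon) || any(!nzchar(trimws(lexicon$ipa)))) {
      stop("invalid-input error: lexicon needs non-empty 'ipa' or 'classes'",
           call. = FALSE)
    }
    lexicon$classes <- vapply(lexicon$ipa, encode_classes, character(1),
                              model = model, ..., USE.NAMES = FALSE)
  }
  lexicon
}

#' Brute-force alignment score oracle
#'
#' Exhaustively enumerates every global alignment (all monotone paths of
#' match, gap-in-a and gap-in-b moves) by recursion and returns the maximum
#' score. Intended for verification on short strings only.
#'
#' @param a,b Sound-class strings of length at most 6.
#' @param model A [sound_class_model()].
#' @return Maximum global alignment score (numeric scalar).
#' @export
brute_force_alignment_oracle <- function(a, b, model) {
  ia <- classes_to_idx(a, model)
  ib <- classes_to_idx(b, model)
  if (length(ia) > 6 || length(ib) > 6) {
    stop("oracle-scope error: strings longer than 6 classes", call. = FALSE)
  }
  sim <- model$similarity
  gap <- model$gap_penalty
  best <- -Inf
  recurse <- function(i, j, acc) {
    if (i > length(ia) && j > length(ib)) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= length(ia) && j <= length(ib)) {
      recurse(i + 1, j + 1, acc + sim[ia[i], ib[j]])
    }
    if (i <= length(ia)) recurse(i + 1, j, acc + gap)
    if (j <= length(ib)) recurse(i, j + 1, acc + gap)
  }
  recurse(1, 1, 0)
  best
}
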