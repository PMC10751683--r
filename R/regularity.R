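# Form-meaning regularity: does a word's form resemble the forms of its
# same-meaning translations across unrelated languages more than the forms
# of its antonym's translations?
#
# For each target word, same_mean is the mean distance to the translations
# of its own concept in the comparison languages and opp_mean the mean
# distance to the translations of its antonym concept; the pair-level score
# is the mean over the pair's two member words of (opp_mean - same_mean),
# so positive values mean same-meaning forms are closer.

#' Comparison-set specification for regularity scoring
#'
#' @param exclude_own_group Exclude the target word's own language group
#'   from the comparison set (the original-study configuration: comparisons
#'   with the six languages outside the target pair's group).
#' @param include_languages Languages added to the comparison pool (e.g. the
#'   former native language when rescoring for a replication population).
#' @param exclude_languages Languages removed from the comparison pool
#'   (always includes the native language of the scored population).
#' @return A list of class `comparison_spec`.
#' @export
comparison_spec <- function(exclude_own_group = TRUE,
                            include_languages = character(),
                            exclude_languages = character()) {
  overlap <- intersect(include_languages, exclude_languages)
  if (length(overlap)) {
    stop("configuration error: language(s) both included and excluded: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(list(exclude_own_group = exclude_own_group,
                 include_languages = include_languages,
                 exclude_languages = exclude_languages),
            class = "comparison_spec")
}

#' Form-meaning regularity scores per antonym pair and language
#'
#' @param lexicon Stimulus tibble (see [pairwise_distance_table()]).
#' @param model A [sound_class_model()].
#' @param comparison A [comparison_spec()].
#' @param native_language Native language of the scored population; its
#'   words are neither scored nor used in comparisons.
#' @param pair_id Optional filter: score only these antonym pairs.
#' @param ... Passed to [encode_classes()].
#' @return Tibble with one row per (pair_id, language): `pair_id`,
#'   `language`, `language_group`, `pos`, `same_mean`, `opp_mean`, `value`
#'   (= opp_mean - same_mean averaged over the pair's two words) and
#'   `n_comparisons`.
#' @export
regularity_scores <- function(lexicon, model,
                              comparison = comparison_spec(),
                              native_language = NULL,
                              pair_id = NULL, ...) {
  lex <- ensure_classes(lexicon, model, ...)
  pool <- unique(lex$language)
  if (!is.null(native_language)) {
    pool <- setdiff(pool, native_language)
  }
  pool <- setdiff(union(pool, comparison$include_languages),
                  comparison$exclude_languages)
  if (!is.null(native_language) && native_language %in% pool) {
    stop("configuration error: native language '", native_language,
         "' cannot appear in the comparison pool", call. = FALSE)
  }
  missing_pool <- setdiff(pool, unique(lex$language))
  if (length(missing_pool)) {
    stop("missing-entry error: comparison language(s) absent from lexicon: ",
         paste(missing_pool, collapse = ", "), call. = FALSE)
  }

  targets <- lex[lex$language %in% pool, , drop = FALSE]
  if (!is.null(pair_id)) {
    targets <- targets[targets$pair_id %in% pair_id, , drop = FALSE]
  }
  if (!nrow(targets)) {
    stop("configuration error: no target words after exclusions",
         call. = FALSE)
  }

  work <- lex[lex$language %in% pool, , drop = FALSE]
  seqs <- lapply(work$classes, classes_to_idx, model = model)
  D <- .nw_dist_matrix(seqs, model$similarity, model$gap_penalty)
  key <- paste(work$language, work$concept_id, sep = ".")
  loc <- function(language, concept) {
    match(paste(language, concept, sep = "."), key)
  }
  group_of <- stats::setNames(work$language_group, work$language)

  antonym <- antonym_map(work)

  score_word <- function(i) {
    w <- targets[i, ]
    comp <- pool
    if (comparison$exclude_own_group) {
      comp <- comp[group_of[comp] != w$language_group]
    }
    comp <- setdiff(comp, w$language)
    if (!length(comp)) {
      stop("configuration error: empty comparison set for language '",
           w$language, "'", call. = FALSE)
    }
    self <- loc(w$language, w$concept_id)
    same_idx <- loc(comp, w$concept_id)
    opp_idx <- loc(comp, antonym[w$concept_id])
    if (anyNA(same_idx) || anyNA(opp_idx)) {
      stop("missing-entry error: missing translation of pair '", w$pair_id,
           "' in comparison language(s) ",
           paste(comp[is.na(same_idx) | is.na(opp_idx)], collapse = ", "),
           call. = FALSE)
    }
    c(same = mean(D[self, same_idx]),
      opp = mean(D[self, opp_idx]),
      n = length(comp))
  }
  sw <- t(vapply(seq_len(nrow(targets)), score_word, numeric(3)))
  targets$same <- sw[, "same"]
  targets$opp <- sw[, "opp"]
  targets$n_comp <- sw[, "n"]

  out <- dplyr::summarise(
    dplyr::group_by(targets, .data$pair_id, .data$language,
                    .data$language_group, .data$pos),
    same_mean = mean(.data$same),
    opp_mean = mean(.data$opp),
    value = mean(.data$opp - .data$same),
    n_comparisons = .data$n_comp[1],
    .groups = "drop"
  )
  out
}

# concept -> its antonym concept within each pair
antonym_map <- function(lex) {
  cp <- unique(lex[, c("pair_id", "concept_id")])
  out <- character(0)
  for (p in unique(cp$pair_id)) {
    cc <- cp$concept_id[cp$pair_id == p]
    if (length(cc) != 2) {
      stop("invalid-input error: pair '", p, "' does not have exactly two ",
           "concepts", call. = FALSE)
    }
    out[cc[1]] <- cc[2]
    out[cc[2]] <- cc[1]
  }
  out
}

#' Rescore regularity for a replication population
#'
#' Identical arithmetic to [regularity_scores()] with the comparison pool
#' swapped: the replication population's native language is excluded from
#' all comparisons and additional foreign languages (e.g. the original
#' study's native language) are included.
#'
#' @inheritParams regularity_scores
#' @param include_languages Languages to add to the comparison pool.
#' @export
recompute_for_replication <- function(lexicon, model, native_language,
                                      include_languages = character(),
                                      ...) {
  if (native_language %in% include_languages) {
    stop("configuration error: native language '", native_language,
         "' cannot be in the include set", call. = FALSE)
  }
  regularity_scores(
    lexicon, model,
    comparison = comparison_spec(
      exclude_own_group = TRUE,
      include_languages = include_languages,
      exclude_languages = native_language
    ),
    native_language = native_language,
    ...
  )
}

#' Mixed-model test of the same- vs opposite-meaning distance effect
#'
#' Fits a linear mixed model of distance on a same/opposite-meaning
#' indicator with a random intercept for antonym pair (and for language pair
#' when more than five language pairs are present). The meaning effect is
#' the coefficient for `same_meaning` relative to `opposite_meaning`
#' (negative when same-meaning forms are closer), tested with a
#' likelihood-ratio chi-square. Moderation is tested by LR tests of the
#' interaction of meaning with each moderator.
#'
#' @param records Distance records from [pairwise_distance_table()]
#'   containing both `same_meaning` and `opposite_meaning` relations.
#' @param moderators Subset of `c("language_pair", "pos")`.
#' @return Object of class `meaning_effect_fit`: `estimate`, `se`,
#'   `chi_sq`, `df`, `p`, `moderators_tested` (tibble), `model`.
#' @export
meaning_effect_test <- function(records, moderators = NULL) {
  d <- records[records$relation %in% c("same_meaning", "opposite_meaning"), ]
  if (length(unique(d$relation)) < 2) {
    stop("degenerate-design error: records must contain both same- and ",
         "opposite-meaning relations", call. = FALSE)
  }
  d$meaning <- factor(d$relation,
                      levels = c("opposite_meaning", "same_meaning"))
  d$pair <- ifelse(d$pair_a == d$pair_b, d$pair_a,
                   paste(d$pair_a, d$pair_b, sep = "+"))
  d$language_pair <- paste(pmin(d$language_a, d$language_b),
                           pmax(d$language_a, d$language_b), sep = ":")
  d$pos <- d$pos_a

  re <- "(1 | pair)"
  if (length(unique(d$language_pair)) > 5) {
    re <- paste(re, "+ (1 | language_pair)")
  }

  if (stats::sd(d$distance) == 0) {
    # degenerate: constant response; the meaning effect is exactly 0
    return(structure(list(estimate = 0, se = NA_real_, chi_sq = 0,
                          df = 1L, p = 1, moderators_tested = NULL,
                          model = NULL),
                     class = "meaning_effect_fit"))
  }

  fit1 <- lme4::lmer(stats::as.formula(paste("distance ~ meaning +", re)),
                     data = d, REML = FALSE)
  fit0 <- lme4::lmer(stats::as.formula(paste("distance ~ 1 +", re)),
                     data = d, REML = FALSE)
  lr <- stats::anova(fit0, fit1)
  co <- summary(fit1)$coefficients

  mod_tab <- NULL
  if (length(moderators)) {
    mod_tab <- purrr::map_dfr(moderators, function(m) {
      fb <- lme4::lmer(
        stats::as.formula(paste("distance ~ meaning +", m, "+", re)),
        data = d, REML = FALSE)
      fi <- lme4::lmer(
        stats::as.formula(paste("distance ~ meaning *", m, "+", re)),
        data = d, REML = FALSE)
      a <- stats::anova(fb, fi)
      tibble::tibble(moderator = m,
                     chi_sq = a$Chisq[2], df = a$Df[2],
                     p = a[["Pr(>Chisq)"]][2])
    })
  }

  structure(list(
    estimate = unname(co["meaningsame_meaning", "Estimate"]),
    se = unname(co["meaningsame_meaning", "Std. Error"]),
    chi_sq = lr$Chisq[2],
    df = lr$Df[2],
    p = lr[["Pr(>Chisq)"]][2],
    moderators_tested = mod_tab,
    model = fit1
  ), class = "meaning_effect_fit")
}

#' @export
print.meaning_effect_fit <- function(x, ...) {
  cat(sprintf(
    "<meaning effect: estimate %.4g (SE %.3g), chisq(%d) = %.3g, p = %.3g>\n",
    x$estimate, x$se, x$df, x$chi_sq, x$p))
  invisible(x)
}

#' Permutation test of the meaning effect
#'
#' Assumption-light companion to [meaning_effect_test()]: concept labels are
#' permuted within each language (preserving every language's form
#' inventory) and the mean same-meaning minus mean opposite-meaning distance
#' is recomputed for each shuffle. Two-sided
#' `p = (1 + #{|null| >= |observed|}) / (n_perm + 1)`.
#'
#' @param records Full cross-language distance table from
#'   [pairwise_distance_table()] with `scope = "all"` (permuted relabelings
#'   need distances between currently unrelated words).
#' @param n_perm Number of permutations (at least 100).
#' @param seed Optional integer seed (scoped to this call).
#' @return Object of class `permutation_test`: `observed`, `p`, `n_perm`,
#'   `null_mean`, `null_sd`, `null_quantiles`.
#' @export
permutation_meaning_test <- function(records, n_perm = 999, seed = NULL) {
  if (n_perm < 100) {
    stop("configuration error: n_perm must be at least 100", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)

  words <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(word = records$word_a, language = records$language_a,
                   concept = records$concept_a, pair = records$pair_a),
    tibble::tibble(word = records$word_b, language = records$language_b,
                   concept = records$concept_b, pair = records$pair_b)
  ))
  langs <- sort(unique(words$language))
  concepts <- sort(unique(words$concept))
  nc <- length(concepts)
  nl <- length(langs)

  W <- matrix(NA_integer_, nc, nl, dimnames = list(concepts, langs))
  W[cbind(match(words$concept, concepts),
          match(words$language, langs))] <- seq_len(nrow(words))
  if (anyNA(W)) {
    stop("missing-entry error: lexicon behind the records is not a full ",
         "(concept x language) grid", call. = FALSE)
  }

  n <- nrow(words)
  D <- matrix(NA_real_, n, n)
  ia <- match(records$word_a, words$word)
  ib <- match(records$word_b, words$word)
  D[cbind(ia, ib)] <- records$distance
  D[cbind(ib, ia)] <- records$distance

  cp <- unique(words[, c("pair", "concept")])
  pair_rows <- split(match(cp$concept, concepts), cp$pair)
  if (any(lengths(pair_rows) != 2)) {
    stop("invalid-input error: each antonym pair needs exactly two concepts",
         call. = FALSE)
  }
  lp <- utils::combn(nl, 2)

  stat <- function(W) {
    same <- 0; nsame <- 0; opp <- 0; nopp <- 0
    for (k in seq_len(ncol(lp))) {
      i <- lp[1, k]; j <- lp[2, k]
      v <- D[cbind(W[, i], W[, j])]
      same <- same + sum(v); nsame <- nsame + nc
      for (pr in pair_rows) {
        opp <- opp + D[W[pr[1], i], W[pr[2], j]] +
          D[W[pr[2], i], W[pr[1], j]]
        nopp <- nopp + 2
      }
    }
    same / nsame - opp / nopp
  }

  observed <- stat(W)
  null <- vapply(seq_len(n_perm), function(r) {
    Wp <- W
    for (j in seq_len(nl)) Wp[, j] <- W[sample.int(nc), j]
    stat(Wp)
  }, numeric(1))

  if (anyNA(null) || is.na(observed)) {
    stop("missing-entry error: records lack distances needed for permuted ",
         "relabelings; build them with scope = \"all\"", call. = FALSE)
  }

  p <- (1 + sum(abs(null) >= abs(observed) - 1e-12)) / (n_perm + 1)
  structure(list(
    observed = observed, p = p, n_perm = n_perm,
    null_mean = mean(null), null_sd = stats::sd(null),
    null_quantiles = stats::quantile(null, c(0.025, 0.5, 0.975))
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "<permutation test: observed %.4g, p = %.4g (%d shuffles)>\n",
    x$observed, x$p, x$n_perm))
  invisible(x)
}
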