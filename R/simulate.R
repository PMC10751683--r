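# Synthetic lexicons, participants and forced-choice responses.
#
# Lexicon generation works directly on sound-class strings: each concept
# draws a latent class-sequence profile (alternating consonant and vowel
# classes) and each language's form copies the profile position-wise with
# probability iconicity_rho, otherwise drawing a random class of the same
# category. Antonym concepts draw independent profiles, so only same-meaning
# sharing is built in. An IPA realization maps classes to representative
# symbols so the phonology and distance modules are exercised end to end.

STUDY_LANGUAGES <- tibble::tibble(
  language = c("english",
               "japanese", "mandarin", "thai",
               "polish", "russian", "ukrainian",
               "french", "romanian", "spanish"),
  language_group = c("germanic",
                     rep("japonic_sino_tai", 3),
                     rep("slavic", 3),
                     rep("romance", 3))
)

CONS_CLASSES <- c("P", "B", "T", "S", "C", "K", "G", "N", "L", "R", "W", "J")
VOWEL_CLASSES <- c("A", "E", "I", "O", "U")
CLASS_IPA <- c(P = "p", B = "f", T = "t", S = "s", C = "t͡ʃ", K = "k",
               G = "h", N = "n", L = "l", R = "r", W = "w", J = "j",
               A = "a", E = "e", I = "i", O = "o", U = "u")

#' Simulation configuration
#'
#' Defaults mirror the study design: 10 languages (English plus nine
#' foreign languages in three groups), 45 antonym pairs split evenly over
#' three parts of speech, 134 participants each tested on three languages
#' (one per foreign group, 45 trials each, 135 trials total), digit-span
#' scores at mean 16.5 (SD 2.92), and a response model whose intercept is
#' the planning accuracy of 0.65.
#'
#' @param n_languages Number of languages (10 gives the study roster;
#'   other values generate a generic roster cycling over three groups).
#' @param n_pairs Number of antonym pairs, divisible by 3.
#' @param word_length_range Integer bounds on class-string length, within
#'   1..8.
#' @param iconicity_rho Probability in `[0, 1]` that a position copies the
#'   concept's shared latent profile; 0 gives fully arbitrary form-meaning
#'   mapping.
#' @param n_participants Number of simulated participants.
#' @param wm_mean,wm_sd Digit-span distribution (normal, rounded,
#'   truncated at 0).
#' @param beta0,beta_dist,beta_reg,beta_wm,beta_regxwm Logit coefficients
#'   of the response model: intercept, slope on z-scored phonetic distance
#'   to the native language, slope on z-scored regularity, slope on
#'   z-scored working memory, and the regularity-by-memory interaction.
#' @param known_rate Probability a trial is flagged as previously known.
#' @param seed Integer seed; every generator output is deterministic in it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_languages = 10, n_pairs = 45,
                       word_length_range = c(3, 6),
                       iconicity_rho = 0.1,
                       n_participants = 134,
                       wm_mean = 16.5, wm_sd = 2.92,
                       beta0 = stats::qlogis(0.65),
                       beta_dist = -0.5, beta_reg = 0.15,
                       beta_wm = 0.1, beta_regxwm = 0.04,
                       known_rate = 0, seed = 1L) {
  cfg <- list(n_languages = n_languages, n_pairs = n_pairs,
              word_length_range = as.integer(word_length_range),
              iconicity_rho = iconicity_rho,
              n_participants = n_participants,
              wm_mean = wm_mean, wm_sd = wm_sd,
              beta0 = beta0, beta_dist = beta_dist, beta_reg = beta_reg,
              beta_wm = beta_wm, beta_regxwm = beta_regxwm,
              known_rate = known_rate, seed = as.integer(seed))
  if (iconicity_rho < 0 || iconicity_rho > 1) {
    stop("configuration error: iconicity_rho must be in [0, 1]",
         call. = FALSE)
  }
  if (n_pairs %% 3 != 0) {
    stop("configuration error: n_pairs must be divisible by 3",
         call. = FALSE)
  }
  if (length(cfg$word_length_range) != 2 ||
      cfg$word_length_range[1] < 1 || cfg$word_length_range[2] > 8 ||
      cfg$word_length_range[1] > cfg$word_length_range[2]) {
    stop("configuration error: word_length_range must be increasing bounds ",
         "within [1, 8]", call. = FALSE)
  }
  if (wm_sd < 0) {
    stop("configuration error: wm_sd must be non-negative", call. = FALSE)
  }
  if (n_languages < 2) {
    stop("configuration error: need at least two languages", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

sim_languages <- function(config) {
  if (config$n_languages == 10) {
    out <- STUDY_LANGUAGES
    attr(out, "native") <- "english"
    return(out)
  }
  out <- tibble::tibble(
    language = sprintf("lang%02d", seq_len(config$n_languages)),
    language_group = rep(c("japonic_sino_tai", "slavic", "romance"),
                         length.out = config$n_languages)
  )
  attr(out, "native") <- NULL
  out
}

#' Generate a synthetic stimulus lexicon
#'
#' @param config A [sim_config()].
#' @return Tibble of class `fm_lexicon` with the standard stimulus columns
#'   (`pair_id`, `concept_id`, `pair_role`, `pos`, `language`,
#'   `language_group`, `orthography`, `ipa`) plus `classes`; the generating
#'   config, the latent concept profiles and the native language (if any)
#'   are kept in attributes.
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)

  langs <- sim_languages(config)
  pos_levels <- c("noun", "verb", "adjective")
  pairs <- tibble::tibble(
    pair_id = sprintf("pair%02d", seq_len(config$n_pairs)),
    pos = rep(pos_levels, each = config$n_pairs / 3)
  )

  draw_profile <- function(len) {
    vapply(seq_len(len), function(k) {
      if (k %% 2 == 1) sample(CONS_CLASSES, 1) else sample(VOWEL_CLASSES, 1)
    }, character(1))
  }

  profiles <- list()
  rows <- vector("list", config$n_pairs * 2L)
  r <- 0L
  for (p in seq_len(config$n_pairs)) {
    for (w in 1:2) {
      concept <- sprintf("%s_w%d", pairs$pair_id[p], w)
      len <- sample(seq(config$word_length_range[1],
                        config$word_length_range[2]), 1)
      profiles[[concept]] <- draw_profile(len)
      r <- r + 1L
      rows[[r]] <- tibble::tibble(
        pair_id = pairs$pair_id[p], concept_id = concept,
        pair_role = paste0("word", w), pos = pairs$pos[p]
      )
    }
  }
  concepts <- dplyr::bind_rows(rows)

  # A language's form copies the latent profile only through the rho
  # mixture: the word length matches the profile's with probability rho
  # (otherwise drawn independently), and each position copies the profile
  # class with probability rho (otherwise a random class of the same
  # category). At rho = 0 forms are fully independent of the concept, so
  # concept labels are exchangeable within a language; at rho = 1 every
  # language realizes the profile exactly.
  len_range <- seq(config$word_length_range[1], config$word_length_range[2])
  realize <- function(profile) {
    len <- if (stats::runif(1) < config$iconicity_rho) {
      length(profile)
    } else {
      len_range[sample.int(length(len_range), 1)]
    }
    vapply(seq_len(len), function(k) {
      if (k <= length(profile) &&
          stats::runif(1) < config$iconicity_rho) {
        profile[k]
      } else if (k %% 2 == 1) {
        sample(CONS_CLASSES, 1)
      } else {
        sample(VOWEL_CLASSES, 1)
      }
    }, character(1))
  }

  out <- vector("list", nrow(langs))
  for (li in seq_len(nrow(langs))) {
    forms <- vapply(concepts$concept_id, function(cid) {
      paste(realize(profiles[[cid]]), collapse = "")
    }, character(1))
    ipa <- vapply(strsplit(forms, ""), function(cl) {
      paste(CLASS_IPA[cl], collapse = "")
    }, character(1))
    out[[li]] <- dplyr::mutate(
      concepts,
      language = langs$language[li],
      language_group = langs$language_group[li],
      orthography = tolower(forms),
      ipa = ipa,
      classes = unname(forms)
    )
  }
  lex <- dplyr::bind_rows(out)
  attr(lex, "config") <- config
  attr(lex, "profiles") <- profiles
  attr(lex, "native_language") <- attr(langs, "native")
  class(lex) <- c("fm_lexicon", class(lex))
  lex
}

#' Simulate participants
#'
#' Digit spans are drawn from a normal distribution, rounded to integers
#' and truncated at 0. Each participant is assigned one language per
#' foreign language group, counterbalanced by cycling within group.
#'
#' @param config A [sim_config()].
#' @param lexicon Optional lexicon whose language roster to use (defaults
#'   to the roster implied by `config`).
#' @return Tibble: `participant_id`, `native_language`, `wm_span`, and one
#'   `lang<k>` column per assigned language.
#' @export
simulate_participants <- function(config, lexicon = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_participants < 1) {
    stop("configuration error: n_participants must be at least 1",
         call. = FALSE)
  }
  withr::local_seed(config$seed + 1L)

  langs <- if (is.null(lexicon)) {
    sim_languages(config)
  } else {
    out <- dplyr::distinct(tibble::as_tibble(lexicon),
                           .data$language, .data$language_group)
    attr(out, "native") <- attr(lexicon, "native_language")
    out
  }
  native <- attr(langs, "native")
  foreign <- if (is.null(native)) langs else langs[langs$language != native, ]
  groups <- split(foreign$language, foreign$language_group)

  n <- config$n_participants
  assigned <- lapply(groups, function(gl) {
    gl[(seq_len(n) - 1L) %% length(gl) + 1L]
  })
  am <- do.call(cbind, assigned)
  colnames(am) <- paste0("lang_", names(groups))

  wm <- pmax(0L, as.integer(round(stats::rnorm(n, config$wm_mean,
                                               config$wm_sd))))
  out <- tibble::tibble(
    participant_id = sprintf("p%04d", seq_len(n)),
    native_language = if (is.null(native)) NA_character_ else native,
    wm_span = wm
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(am))
  # self-rated proficiency (0-10): native speakers near ceiling, minimal
  # foreign-language exposure, mirroring the eligibility screening
  for (lg in langs$language) {
    out[[paste0("prof_", lg)]] <- if (!is.null(native) && lg == native) {
      sample(8:10, n, replace = TRUE, prob = c(0.05, 0.15, 0.8))
    } else {
      sample(0:1, n, replace = TRUE, prob = c(0.9, 0.1))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate forced-choice antonym-task responses
#'
#' Per trial the probability of a correct response is
#' `plogis(beta0 + beta_dist * z(distance) + beta_reg * z(R) +
#' beta_wm * z(wm) + beta_regxwm * z(R) * z(wm))`, where `distance` is the
#' pair's mean phonetic distance to its native-language translations and
#' `R` its form-meaning regularity score; one Bernoulli draw per trial.
#'
#' @param participants From [simulate_participants()].
#' @param lexicon From [generate_lexicon()]; must contain the native
#'   language when `beta_dist != 0`.
#' @param config The [sim_config()] used to generate both.
#' @param model A [sound_class_model()] (defaults to the shipped model).
#' @return Trial tibble: `participant_id`, `language`, `language_group`,
#'   `pair_id`, `pos`, `correct`, `known_word_flag`, `block_index`, plus
#'   the per-trial predictors `distance_native`, `regularity`, `wm_span`.
#' @export
simulate_responses <- function(participants, lexicon, config,
                               model = load_sound_class_model()) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed + 2L)

  native <- attr(lexicon, "native_language")
  preds <- trial_predictors(lexicon, model, native)

  lang_cols <- grep("^lang_", names(participants), value = TRUE)
  trials <- tidyr::pivot_longer(
    participants[, c("participant_id", "wm_span", lang_cols)],
    cols = dplyr::all_of(lang_cols),
    names_to = "block_group", values_to = "language")
  trials$block_index <- match(trials$block_group, lang_cols)
  trials <- dplyr::inner_join(trials, preds, by = "language",
                              relationship = "many-to-many")

  z <- function(x) if (stats::sd(x) == 0) x * 0 else (x - mean(x)) / stats::sd(x)
  dz <- if (all(is.na(trials$distance_native))) 0 else z(trials$distance_native)
  rz <- z(trials$regularity)
  wz <- z(trials$wm_span)
  eta <- config$beta0 + config$beta_dist * dz + config$beta_reg * rz +
    config$beta_wm * wz + config$beta_regxwm * rz * wz
  trials$correct <- stats::rbinom(nrow(trials), 1, stats::plogis(eta))
  trials$known_word_flag <- stats::runif(nrow(trials)) < config$known_rate

  trials[, c("participant_id", "language", "language_group", "pair_id",
             "pos", "correct", "known_word_flag", "block_index",
             "distance_native", "regularity", "wm_span")]
}

# Pair-level predictors per (pair, language): mean distance of the pair's
# two words to their native translations, and the regularity score.
trial_predictors <- function(lexicon, model, native) {
  reg <- regularity_scores(lexicon, model, native_language = native)
  if (!is.null(native)) {
    nat <- pairwise_distance_table(lexicon, scope = "native_translation",
                                   model = model,
                                   native_language = native)
    nd <- dplyr::summarise(
      dplyr::group_by(nat, pair_id = .data$pair_a,
                      language = ifelse(.data$language_a == native,
                                        .data$language_b,
                                        .data$language_a)),
      distance_native = mean(.data$distance), .groups = "drop")
    out <- dplyr::left_join(reg, nd, by = c("pair_id", "language"))
  } else {
    out <- dplyr::mutate(reg, distance_native = NA_real_)
  }
  dplyr::select(out, "pair_id", "language", "language_group", "pos",
                regularity = "value", "distance_native")
}

#' Parameter-recovery experiment
#'
#' For each replicate: generate a lexicon, compute distances and
#' regularity, simulate participants and responses, and refit the accuracy
#' model `correct ~ distance_z + regularity_z * wm_z` with random
#' intercepts for participant and item. Reports bias, RMSE and 95% CI
#' coverage per generating coefficient.
#'
#' @param config A [sim_config()].
#' @param n_replicates At least 20.
#' @param model A [sound_class_model()].
#' @param nAGQ Passed to [fit_accuracy_model()]; default 0 for speed.
#' @return List of class `recovery_report`: `summary` (tibble per
#'   coefficient: true value, mean estimate, bias, rmse, coverage) and
#'   `estimates` (per-replicate tibble).
#' @export
recovery_experiment <- function(config, n_replicates = 100,
                                model = load_sound_class_model(),
                                nAGQ = 0L) {
  if (n_replicates < 20) {
    stop("configuration error: n_replicates must be at least 20",
         call. = FALSE)
  }
  truth <- c(`(Intercept)` = config$beta0,
             distance_native_z = config$beta_dist,
             regularity_z = config$beta_reg,
             wm_span_z = config$beta_wm,
             `regularity_z:wm_span_z` = config$beta_regxwm)

  est <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * r
    lex <- generate_lexicon(cfg)
    pp <- simulate_participants(cfg, lex)
    tr <- simulate_responses(pp, lex, cfg, model = model)
    tr <- standardize_predictors(
      tr, c("distance_native", "regularity", "wm_span"))
    fit <- fit_accuracy_model(
      tr, correct ~ distance_native_z + regularity_z * wm_span_z,
      nAGQ = nAGQ)
    co <- fit$coefficients
    co$replicate <- r
    co
  })

  est <- est[est$term %in% names(truth), ]
  est$true <- truth[est$term]
  est$covered <- abs(est$estimate - est$true) <= 1.96 * est$se
  summ <- dplyr::summarise(
    dplyr::group_by(est, .data$term),
    true = .data$true[1],
    mean_estimate = mean(.data$estimate),
    bias = mean(.data$estimate - .data$true),
    rmse = sqrt(mean((.data$estimate - .data$true)^2)),
    coverage = mean(.data$covered),
    .groups = "drop")
  structure(list(summary = summ, estimates = est,
                 n_replicates = n_replicates),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report over %d replicates>\n", x$n_replicates))
  print(x$summary)
  invisible(x)
}
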