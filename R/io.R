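# Reading and writing the pipeline's CSV dialects (UTF-8, comma-separated,
# header required, RFC-4180 quoting). A Unicode minus (U+2212) in numeric
# fields is normalized to ASCII hyphen-minus on read, as published tables
# use it.

STIMULUS_COLUMNS <- c("pair_id", "concept_id", "pair_role", "pos",
                      "language", "language_group", "orthography", "ipa")

#' Load a stimulus lexicon table
#'
#' Reads a UTF-8 CSV (byte-order mark tolerated) with columns `pair_id`,
#' `concept_id`, `pair_role`, `pos`, `language`, `language_group`,
#' `orthography`, `ipa` (an optional `classes` column is kept). Validates
#' the stimulus-word invariants: no duplicate (pair_id, language,
#' pair_role), exactly two roles per (pair_id, language), constant part of
#' speech within a pair, and non-empty IPA.
#'
#' @param path Path to the CSV file.
#' @return A validated stimulus tibble.
#' @export
load_stimulus_table <- function(path) {
  if (!file.exists(path)) {
    stop("schema error: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, fileEncoding = "UTF-8-BOM",
                        colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(STIMULUS_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$ipa <- stringi::stri_trans_nfc(df$ipa)

  key <- paste(df$pair_id, df$language, df$pair_role)
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1]
    stop("schema error: duplicate (pair_id, language, pair_role) at row ",
         row, " (", key[row], ")", call. = FALSE)
  }
  empty <- which(!nzchar(trimws(df$ipa)))
  if (length(empty)) {
    stop("schema error: empty IPA at row ", empty[1], call. = FALSE)
  }
  roles <- table(paste(df$pair_id, df$language))
  if (any(roles != 2)) {
    stop("schema error: pair/language cell(s) without exactly two roles: ",
         paste(utils::head(names(roles)[roles != 2], 3), collapse = "; "),
         call. = FALSE)
  }
  pos_per_pair <- tapply(df$pos, df$pair_id,
                         function(x) length(unique(x)))
  if (any(pos_per_pair != 1)) {
    stop("schema error: part of speech varies within pair ",
         names(pos_per_pair)[pos_per_pair != 1][1], call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Load a trial-level behavioral table
#'
#' Columns: `participant_id`, `language`, `language_group`, `pair_id`,
#' `pos`, `correct` (0/1), `known_word_flag` (true/false), `block_index`.
#'
#' @param path Path to the CSV file.
#' @return A trial tibble with typed columns.
#' @export
load_trial_table <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8-BOM",
                        colClasses = "character")
  need <- c("participant_id", "language", "pair_id", "correct",
            "known_word_flag")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$correct <- as.integer(fix_minus(df$correct))
  df$known_word_flag <- tolower(df$known_word_flag) %in%
    c("true", "t", "1", "yes")
  if (!is.null(df$block_index)) {
    df$block_index <- as.integer(fix_minus(df$block_index))
  }
  tibble::as_tibble(df)
}

#' Load a participant table
#'
#' Columns: `participant_id`, `native_language`, `wm_span` plus any
#' `prof_<language>` self-rating columns.
#'
#' @param path Path to the CSV file.
#' @return A participant tibble.
#' @export
load_participant_table <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8-BOM",
                        colClasses = "character")
  need <- c("participant_id", "wm_span")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$wm_span <- as.numeric(fix_minus(df$wm_span))
  num_cols <- grep("^prof_", names(df), value = TRUE)
  for (v in num_cols) df[[v]] <- as.numeric(fix_minus(df[[v]]))
  tibble::as_tibble(df)
}

fix_minus <- function(x) gsub("−", "-", x)

#' Write a table as UTF-8 CSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_output_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write run metadata JSON
#'
#' Records the configuration, seed and sound-class model identity needed to
#' reproduce an output file byte-for-byte.
#'
#' @param path Output path.
#' @param config Named list echoed into the file.
#' @param model Optional [sound_class_model()] whose name/version to record.
#' @export
write_run_metadata <- function(path, config, model = NULL) {
  meta <- list(
    package = "soundmeaning",
    package_version = as.character(utils::packageVersion("soundmeaning")),
    config = config
  )
  if (!is.null(model)) {
    meta$model <- list(name = model$name, version = model$version,
                       gap_penalty = model$gap_penalty,
                       normalization = "1 - 2S/(Saa+Sbb), clipped to [0,1]",
                       tie_rule = "match > gap-in-b > gap-in-a")
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
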