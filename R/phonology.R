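# IPA tokenization and sound-class encoding.
#
# All IPA input is NFC-normalized before tokenization so that precomposed and
# decomposed diacritics tokenize identically. Stress marks are stripped;
# combining diacritics, tie bars and length/modifier letters attach to their
# base symbol; a tie bar additionally pulls the following base symbol into
# the same token (affricates written with tie bars are single tokens).

STRESS_MARKS <- c("ˈ", "ˌ", "'")            # primary, secondary
TIE_BARS <- c("͡", "͜")                     # combining double breve
TONE_LETTERS <- c("˥", "˦", "˧", "˨", "˩")
LENGTH_MARKS <- c("ː", "ˑ")                 # long, half-long

#' Tokenize an IPA transcription into phone tokens
#'
#' Splits an IPA string into grapheme-level phone tokens. Combining
#' diacritics and modifier letters (length marks, aspiration, palatalization,
#' ...) attach to the preceding base symbol; a tie bar joins the two base
#' symbols it connects into one token (affricates). Stress marks and
#' whitespace are stripped. Chao tone letters and ASCII digits become
#' standalone tokens of category `"tone"`.
#'
#' @param ipa IPA transcription (character scalar, non-empty).
#' @return A tibble with columns `symbol` (the grapheme cluster), `category`
#'   (`"consonant"`, `"vowel"`, `"tone"` or `"boundary"`).
#' @examples
#' tokenize_ipa("kat")
#' tokenize_ipa("t͡ʃaː")  # t͡ʃaː -> two tokens
#' @export
tokenize_ipa <- function(ipa) {
  if (!is.character(ipa) || length(ipa) != 1 || is.na(ipa)) {
    stop("invalid-input error: ipa must be a single character string",
         call. = FALSE)
  }
  x <- stringi::stri_trans_nfc(ipa)
  chars <- stringi::stri_sub(x, seq_len(stringi::stri_length(x)), length = 1)
  chars <- chars[!(chars %in% STRESS_MARKS) &
                   !stringi::stri_detect_regex(chars, "^\\s$")]
  if (!length(chars)) {
    stop("invalid-input error: empty or whitespace-only IPA string",
         call. = FALSE)
  }

  is_mark <- stringi::stri_detect_regex(chars, "^\\p{M}$")
  is_tone <- chars %in% TONE_LETTERS |
    stringi::stri_detect_regex(chars, "^[0-9]$")
  is_mod <- stringi::stri_detect_regex(chars, "^\\p{Lm}$") & !is_tone
  is_mod <- is_mod | chars %in% LENGTH_MARKS

  symbols <- character(0)
  tie_open <- FALSE
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (is_mark[k] || is_mod[k]) {
      if (!length(symbols)) {
        stop("invalid-input error: leading combining mark '", ch,
             "' at offset ", k, call. = FALSE)
      }
      symbols[length(symbols)] <- paste0(symbols[length(symbols)], ch)
      if (ch %in% TIE_BARS) tie_open <- TRUE
    } else if (tie_open) {
      symbols[length(symbols)] <- paste0(symbols[length(symbols)], ch)
      tie_open <- FALSE
    } else {
      symbols <- c(symbols, ch)
    }
  }

  base <- vapply(symbols, token_base, character(1), USE.NAMES = FALSE)
  category <- ifelse(
    symbols == "#", "boundary",
    ifelse(stringi::stri_detect_regex(base, "^[0-9˥-˩]"),
           "tone",
           ifelse(stringi::stri_detect_regex(
             base, "^[aeiouyɑɐæäɛəɜœøɘɪɨʏɔɒɤʊɯʉ]"),
             "vowel", "consonant"))
  )
  tibble::tibble(symbol = symbols, category = category)
}

# Strip combining marks and modifier letters from a token symbol, keeping the
# base character(s); a tie-bar affricate reduces to its two base symbols.
# NFD-decomposed first so precomposed nasal vowels (e.g. U+00E3) reduce to
# their plain base.
token_base <- function(symbol) {
  symbol <- stringi::stri_trans_nfd(symbol)
  chars <- stringi::stri_sub(symbol, seq_len(stringi::stri_length(symbol)),
                             length = 1)
  keep <- !stringi::stri_detect_regex(chars, "^\\p{M}$") &
    !(stringi::stri_detect_regex(chars, "^\\p{Lm}$") &
        !(chars %in% TONE_LETTERS))
  paste(chars[keep], collapse = "")
}

#' Encode phone tokens as a sound-class string
#'
#' Maps each non-boundary token to its class code under a sound-class model.
#' The lookup key is the token's base symbol(s), diacritics removed; tie-bar
#' affricates are looked up as the two-symbol sequence first, falling back to
#' the first base symbol.
#'
#' @param tokens Token tibble from [tokenize_ipa()], or an IPA string.
#' @param model A [sound_class_model()].
#' @param policy `"strict"` (error on unmapped symbols, the pipeline
#'   default) or `"lenient"` (emit the model's unknown code with a warning).
#' @param tone `"drop"` (default: lexical tone is excluded from the class
#'   string, as in segmental practice) or `"retain"` (tone tokens encode to
#'   the dedicated tone class).
#' @return A single character string of one-letter class codes.
#' @examples
#' m <- load_sound_class_model()
#' encode_classes("kat", m)  # "KAT"
#' @export
encode_classes <- function(tokens, model, policy = c("strict", "lenient"),
                           tone = c("drop", "retain")) {
  policy <- match.arg(policy)
  tone <- match.arg(tone)
  if (is.character(tokens)) tokens <- tokenize_ipa(tokens)
  if (!nrow(tokens)) stop("invalid-input error: no tokens", call. = FALSE)

  tokens <- tokens[tokens$category != "boundary", , drop = FALSE]
  if (tone == "drop") {
    tokens <- tokens[tokens$category != "tone", , drop = FALSE]
  }
  if (!nrow(tokens)) {
    stop("invalid-input error: no codable tokens after tone/boundary policy",
         call. = FALSE)
  }

  codes <- vapply(seq_len(nrow(tokens)), function(k) {
    sym <- tokens$symbol[k]
    base <- token_base(sym)
    code <- unname(model$mapping[base])
    if (is.na(code) && stringi::stri_length(base) > 1) {
      code <- unname(model$mapping[stringi::stri_sub(base, 1, 1)])
    }
    if (is.na(code)) {
      if (policy == "strict") {
        stop("unknown-symbol error: '", sym, "' (token ", k,
             ") is not in the sound-class mapping", call. = FALSE)
      }
      warning("unmapped symbol '", sym, "' encoded as unknown class '",
              model$unknown_code, "'", call. = FALSE)
      code <- model$unknown_code
    }
    code
  }, character(1))
  paste(codes, collapse = "")
}
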