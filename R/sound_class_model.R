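#' Construct a sound-class model
#'
#' A sound-class model bins IPA phones into coarse phonetic classes (stops,
#' fricatives, vowels, ...) and scores class-pair matches for global
#' alignment. The shipped `"sca_default"` model covers the IPA inventory of
#' the ten study languages; it is an SCA-style table authored for this
#' package, versioned so distances are reproducible.
#'
#' @param name Model identifier.
#' @param mapping Named character vector: IPA base symbol -> class code.
#' @param similarity Square numeric matrix of class-pair match scores with
#'   dimnames equal to the class alphabet (including the unknown code).
#' @param gap_penalty Negative real; linear per-gap alignment penalty.
#' @param unknown_code Single-character code emitted for unmapped symbols
#'   under the lenient policy.
#' @param version Version string recorded in run metadata.
#'
#' @return An object of class `sound_class_model` with fields `name`,
#'   `mapping`, `class_alphabet`, `similarity`, `gap_penalty`,
#'   `unknown_code`, `version`.
#' @export
sound_class_model <- function(name, mapping, similarity, gap_penalty,
                              unknown_code = "?", version = "0") {
  model <- structure(
    list(
      name = name,
      mapping = mapping,
      class_alphabet = colnames(similarity),
      similarity = similarity,
      gap_penalty = gap_penalty,
      unknown_code = unknown_code,
      version = version
    ),
    class = "sound_class_model"
  )
  validate_sound_class_model(model)
  model
}

#' @export
print.sound_class_model <- function(x, ...) {
  cat(sprintf(
    "<sound_class_model '%s' v%s: %d symbols -> %d classes, gap %g>\n",
    x$name, x$version, length(x$mapping),
    length(x$class_alphabet), x$gap_penalty
  ))
  invisible(x)
}

validate_sound_class_model <- function(model) {
  sim <- model$similarity
  if (!is.matrix(sim) || nrow(sim) != ncol(sim) ||
      is.null(rownames(sim)) || !identical(rownames(sim), colnames(sim))) {
    stop("model-validation error: similarity must be square with matching ",
         "row/column class names", call. = FALSE)
  }
  if (!isTRUE(all.equal(sim, t(sim)))) {
    stop("model-validation error: similarity table is not symmetric",
         call. = FALSE)
  }
  off_max <- apply(sim, 1, max)
  if (any(diag(sim) < off_max - 1e-12)) {
    bad <- rownames(sim)[diag(sim) < off_max - 1e-12]
    stop("model-validation error: diagonal is not the row maximum for class ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unmatched <- setdiff(unique(unname(model$mapping)), model$class_alphabet)
  if (length(unmatched)) {
    stop("model-validation error: mapped code(s) not in class alphabet: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  if (!model$unknown_code %in% model$class_alphabet) {
    stop("model-validation error: unknown_code '", model$unknown_code,
         "' not in class alphabet", call. = FALSE)
  }
  if (!is.numeric(model$gap_penalty) || length(model$gap_penalty) != 1 ||
      model$gap_penalty >= 0) {
    stop("model-validation error: gap_penalty must be a single negative number",
         call. = FALSE)
  }
  invisible(model)
}

#' Load a sound-class model by name or from a TSV file
#'
#' Model files are UTF-8 TSV with scalar header lines (`name`, `version`,
#' `gap_penalty`, `unknown_code`), a `[mapping]` section (symbol, class) and
#' a `[similarity]` section (square labelled table). The model is validated
#' on load: the similarity table must be symmetric with row-dominant
#' diagonal, and every mapped code must belong to the class alphabet.
#'
#' @param path_or_name Built-in model name (currently `"sca_default"`) or a
#'   path to a model file.
#' @return A validated [sound_class_model()].
#' @export
load_sound_class_model <- function(path_or_name = "sca_default") {
  path <- path_or_name
  if (!file.exists(path)) {
    path <- system.file("extdata", "models",
                        paste0(path_or_name, ".tsv"),
                        package = "soundmeaning")
    if (!nzchar(path)) {
      stop("no built-in model or readable file named '", path_or_name, "'",
           call. = FALSE)
    }
  }
  lines <- stringi::stri_trans_nfc(readLines(path, encoding = "UTF-8"))
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]

  sec <- cumsum(grepl("^\\[", lines))
  header <- lines[sec == 0]
  fields <- do.call(rbind, strsplit(header, "\t", fixed = TRUE))
  scalars <- stats::setNames(fields[, 2], fields[, 1])

  map_lines <- lines[sec == 1 & !grepl("^\\[", lines)]
  mp <- do.call(rbind, strsplit(map_lines, "\t", fixed = TRUE))
  mapping <- stats::setNames(mp[, 2], mp[, 1])

  sim_lines <- lines[sec == 2 & !grepl("^\\[", lines)]
  cells <- strsplit(sim_lines, "\t", fixed = TRUE)
  alphabet <- cells[[1]][-1]
  sim <- matrix(NA_real_, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  for (row in cells[-1]) {
    sim[row[1], ] <- as.numeric(row[-1])
  }
  if (anyNA(sim)) {
    stop("model-validation error: incomplete similarity table in ", path,
         call. = FALSE)
  }

  sound_class_model(
    name = scalars[["name"]],
    mapping = mapping,
    similarity = sim,
    gap_penalty = as.numeric(scalars[["gap_penalty"]]),
    unknown_code = scalars[["unknown_code"]],
    version = scalars[["version"]]
  )
}
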