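#' Construct a quiz item
#'
#' A quiz item pairs one information payload (a sentence for the text
#' modality, an image reference for the graphic modality) with a
#' four-alternative forced-choice question about that payload. Graphic
#' match-the-image items may leave the question prompt empty.
#'
#' @param item_id Unique identifier within a bank.
#' @param modality `"text"` or `"graphic"`.
#' @param info_payload The presented information: a sentence (text) or an
#'   opaque image reference (graphic). Images are never inspected by the
#'   engine; only the reference string travels through logs and files.
#' @param choices Character vector of exactly four answer choices (answer
#'   strings or image references).
#' @param correct_index Zero-based position of the correct choice (0-3).
#' @param order_rank Fixed presentation position within the bank (1-based).
#'   Presentation order is identical for every participant.
#' @param question_prompt Question text; may be `""` for image-matching items.
#'
#' @return An object of class `quiz_item`.
#' @export
#' @examples
#' quiz_item("q1", "text", "The capital of France is Paris",
#'           choices = c("Paris", "Rome", "Lyon", "Nice"),
#'           correct_index = 0, order_rank = 1,
#'           question_prompt = "What is the capital of France?")
quiz_item <- function(item_id, modality, info_payload, choices, correct_index,
                      order_rank, question_prompt = "") {
  item <- structure(
    list(
      item_id = as.character(item_id),
      modality = modality,
      info_payload = as.character(info_payload),
      question_prompt = as.character(question_prompt),
      choices = as.character(choices),
      correct_index = as.integer(correct_index),
      order_rank = as.integer(order_rank)
    ),
    class = "quiz_item"
  )
  problems <- validate_quiz_item(item)
  if (length(problems)) {
    abort_sr(paste0("invalid quiz item:\n", paste("-", problems, collapse = "\n")),
             "sr_validation_error")
  }
  item
}

# Returns a character vector of violations (empty if valid); word-count
# advisories are emitted as warnings, not violations.
validate_quiz_item <- function(item, warn = TRUE) {
  problems <- character()
  id <- if (is_string(item$item_id)) item$item_id else "<missing id>"
  if (!is_string(item$item_id) || !nzchar(item$item_id)) {
    problems <- c(problems, "item_id must be a non-empty string")
  }
  if (!is_string(item$modality) || !item$modality %in% MODALITIES) {
    problems <- c(problems, sprintf("item '%s': modality must be 'text' or 'graphic'", id))
  }
  if (!is_string(item$info_payload) || !nzchar(item$info_payload)) {
    problems <- c(problems, sprintf("item '%s': info_payload must be a non-empty string", id))
  }
  if (!is.character(item$choices) || length(item$choices) != 4L ||
      anyNA(item$choices)) {
    problems <- c(problems, sprintf(
      "item '%s': must have exactly 4 choices (found %d)", id, length(item$choices)))
  }
  if (!is_count(item$correct_index) || item$correct_index < 0L || item$correct_index > 3L) {
    problems <- c(problems, sprintf("item '%s': correct_index must be in 0..3", id))
  }
  if (!is_count(item$order_rank) || item$order_rank < 1L) {
    problems <- c(problems, sprintf("item '%s': order_rank must be a positive integer", id))
  }
  if (warn && !length(problems) && identical(item$modality, "text")) {
    n_words <- length(strsplit(trimws(item$info_payload), "\\s+")[[1]])
    if (n_words < 5L || n_words > 9L) {
      warning(sprintf(
        "item '%s': text payload has %d words; the protocol's stimuli use 5-9",
        id, n_words), call. = FALSE)
    }
  }
  problems
}

#' Construct an item bank
#'
#' An item bank is an ordered collection of [quiz_item()]s sharing one
#' modality. Items are always iterated in `order_rank` order: the protocol
#' presents the same stimuli in the same fixed order to every participant.
#'
#' @param bank_id Identifier for the bank.
#' @param modality `"text"` or `"graphic"`; all items must match.
#' @param items List of [quiz_item()] objects (at least one).
#'
#' @return An object of class `item_bank`; `items` are sorted by `order_rank`.
#' @export
item_bank <- function(bank_id, modality, items) {
  bank <- structure(
    list(bank_id = as.character(bank_id), modality = modality, items = items),
    class = "item_bank"
  )
  problems <- validate_item_bank(bank)
  if (length(problems)) {
    abort_sr(paste0("invalid item bank:\n", paste("-", problems, collapse = "\n")),
             "sr_validation_error")
  }
  ranks <- vapply(bank$items, function(it) it$order_rank, integer(1))
  bank$items <- bank$items[order(ranks)]
  bank
}

# All violations are collected, never just the first.
validate_item_bank <- function(bank, warn = TRUE) {
  problems <- character()
  if (!is_string(bank$bank_id) || !nzchar(bank$bank_id)) {
    problems <- c(problems, "bank_id must be a non-empty string")
  }
  if (!is_string(bank$modality) || !bank$modality %in% MODALITIES) {
    problems <- c(problems, "bank modality must be 'text' or 'graphic'")
  }
  if (!is.list(bank$items) || length(bank$items) < 1L) {
    return(c(problems, "a bank must hold at least one item"))
  }
  for (it in bank$items) {
    problems <- c(problems, validate_quiz_item(it, warn = warn))
  }
  ids <- vapply(bank$items, function(it) as.character(it$item_id %||% NA), character(1))
  if (anyDuplicated(ids)) {
    problems <- c(problems, sprintf(
      "duplicate item_id: %s", paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  mods <- vapply(bank$items, function(it) as.character(it$modality %||% NA), character(1))
  off <- !is.na(mods) & mods != bank$modality
  if (any(off)) {
    problems <- c(problems, sprintf(
      "items %s do not match the bank modality '%s'",
      paste(ids[off], collapse = ", "), bank$modality))
  }
  ranks <- vapply(bank$items, function(it) as.integer(it$order_rank %||% NA), integer(1))
  if (!anyNA(ranks) && !identical(sort(ranks), seq_along(bank$items))) {
    problems <- c(problems, sprintf(
      "order_rank values must be a permutation of 1..%d (found: %s)",
      length(bank$items), paste(sort(ranks), collapse = ",")))
  }
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ITEM_BANK_SCHEMA_VERSION <- 1L

#' Read an item bank from a JSON file
#'
#' The on-disk format is UTF-8 JSON with a top-level `schema_version`,
#' `bank_id`, `modality`, and an `items` array mirroring the [quiz_item()]
#' fields. Loading validates every invariant and reports all violations at
#' once; a malformed file never yields a partial bank.
#'
#' @param path Path to a bank JSON file.
#' @param expected_modality `"text"`, `"graphic"`, or `"any"` (default); a
#'   mismatch is an error.
#' @return A validated [item_bank()].
#' @export
load_item_bank <- function(path, expected_modality = "any") {
  if (!file.exists(path)) {
    abort_sr(sprintf("item bank file not found: '%s'", path), "sr_io_error")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      abort_sr(sprintf("could not parse '%s' as item-bank JSON: %s", path,
                       conditionMessage(e)), "sr_format_error")
    }
  )
  if (!is.list(raw) || is.null(raw$items)) {
    abort_sr(sprintf("'%s' is not an item-bank file (missing 'items')", path),
             "sr_format_error")
  }
  items <- lapply(raw$items, function(rec) {
    structure(list(
      item_id = as.character(rec$item_id %||% NA),
      modality = as.character(rec$modality %||% NA),
      info_payload = as.character(rec$info_payload %||% NA),
      question_prompt = as.character(rec$question_prompt %||% ""),
      choices = as.character(unlist(rec$choices)),
      correct_index = as.integer(rec$correct_index %||% NA),
      order_rank = as.integer(rec$order_rank %||% NA)
    ), class = "quiz_item")
  })
  bank <- structure(
    list(bank_id = as.character(raw$bank_id %||% NA),
         modality = as.character(raw$modality %||% NA),
         items = items),
    class = "item_bank"
  )
  problems <- validate_item_bank(bank)
  if (length(problems)) {
    abort_sr(paste0(sprintf("invalid item bank in '%s':\n", path),
                    paste("-", problems, collapse = "\n")),
             "sr_validation_error")
  }
  if (!identical(expected_modality, "any") &&
      !identical(bank$modality, expected_modality)) {
    abort_sr(sprintf("bank '%s' has modality '%s', expected '%s'",
                     bank$bank_id, bank$modality, expected_modality),
             "sr_validation_error")
  }
  ranks <- vapply(bank$items, function(it) it$order_rank, integer(1))
  bank$items <- bank$items[order(ranks)]
  bank
}

#' Write an item bank to a JSON file
#'
#' Round trips exactly: `load_item_bank(save_item_bank(bank, path))` equals
#' `bank` field for field.
#'
#' @param bank A valid [item_bank()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_item_bank <- function(bank, path) {
  problems <- validate_item_bank(bank, warn = FALSE)
  if (length(problems)) {
    abort_sr(paste0("refusing to save invalid bank:\n",
                    paste("-", problems, collapse = "\n")),
             "sr_validation_error")
  }
  payload <- list(
    schema_version = ITEM_BANK_SCHEMA_VERSION,
    bank_id = bank$bank_id,
    modality = bank$modality,
    items = lapply(bank$items, function(it) {
      list(item_id = it$item_id, modality = it$modality,
           info_payload = it$info_payload, question_prompt = it$question_prompt,
           choices = it$choices, correct_index = it$correct_index,
           order_rank = it$order_rank)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Built-in demonstration item banks
#'
#' Ten-item demonstration banks in each modality: general-knowledge sentence
#' stimuli (sports, history, geography, movies) for the text task, and
#' shape/flag/traffic-sign image references for the graphic matching task.
#' These are stand-in stimuli in the protocol's stated categories, not a
#' published stimulus set. Deterministic: repeated calls return identical
#' banks.
#'
#' @param modality `"text"` or `"graphic"`.
#' @return A 10-item [item_bank()].
#' @export
#' @examples
#' builtin_bank("text")
builtin_bank <- function(modality) {
  check_modality(modality)
  if (modality == "text") {
    defs <- list(
      list("The marathon race covers just over forty-two kilometers",
           "How many kilometers does a marathon cover?",
           c("Forty-two", "Twenty-six", "Fifty", "Thirty"), 0L),
      list("The Great Wall was built in ancient China",
           "Where was the Great Wall built?",
           c("Japan", "China", "India", "Egypt"), 1L),
      list("The river Nile flows through the country Egypt",
           "Which country does the Nile flow through?",
           c("Kenya", "Morocco", "Egypt", "Sudan"), 2L),
      list("The movie Casablanca was filmed in black and white",
           "How was Casablanca filmed?",
           c("In color", "Animated", "Silent", "Black and white"), 3L),
      list("A football team fields eleven players at once",
           "How many players does a football team field?",
           c("Eleven", "Nine", "Seven", "Fifteen"), 0L),
      list("The pyramids of Giza stand near the city Cairo",
           "Which city is near the pyramids of Giza?",
           c("Luxor", "Cairo", "Alexandria", "Amman"), 1L),
      list("Mount Everest is the highest mountain on Earth",
           "Which mountain is the highest on Earth?",
           c("K2", "Kilimanjaro", "Everest", "Mont Blanc"), 2L),
      list("The Olympic games happen once every four years",
           "How often do the Olympic games happen?",
           c("Every year", "Every two years", "Every five years", "Every four years"), 3L),
      list("The Titanic sank on its very first voyage",
           "On which voyage did the Titanic sink?",
           c("Its first", "Its second", "Its fifth", "Its last"), 0L),
      list("Tennis matches at Wimbledon are played on grass",
           "What surface is used at Wimbledon?",
           c("Clay", "Grass", "Concrete", "Carpet"), 1L)
    )
    items <- lapply(seq_along(defs), function(i) {
      d <- defs[[i]]
      quiz_item(sprintf("text-%02d", i), "text", d[[1]], d[[3]], d[[4]], i, d[[2]])
    })
    return(item_bank("builtin-text", "text", items))
  }
  shapes <- list(
    list("img:shape/red-circle",
         c("img:shape/red-circle", "img:shape/blue-circle",
           "img:shape/red-square", "img:shape/red-triangle"), 0L),
    list("img:shape/blue-square",
         c("img:shape/blue-circle", "img:shape/blue-square",
           "img:shape/green-square", "img:shape/blue-triangle"), 1L),
    list("img:flag/jordan",
         c("img:flag/palestine", "img:flag/sudan", "img:flag/jordan",
           "img:flag/kuwait"), 2L),
    list("img:sign/stop",
         c("img:sign/yield", "img:sign/no-entry", "img:sign/speed-limit",
           "img:sign/stop"), 3L),
    list("img:shape/green-triangle",
         c("img:shape/green-triangle", "img:shape/green-circle",
           "img:shape/yellow-triangle", "img:shape/green-square"), 0L),
    list("img:flag/france",
         c("img:flag/netherlands", "img:flag/france", "img:flag/russia",
           "img:flag/italy"), 1L),
    list("img:sign/yield",
         c("img:sign/stop", "img:sign/roundabout", "img:sign/yield",
           "img:sign/crossing"), 2L),
    list("img:shape/yellow-star",
         c("img:shape/yellow-circle", "img:shape/orange-star",
           "img:shape/yellow-diamond", "img:shape/yellow-star"), 3L),
    list("img:flag/japan",
         c("img:flag/japan", "img:flag/bangladesh", "img:flag/palau",
           "img:flag/south-korea"), 0L),
    list("img:sign/no-entry",
         c("img:sign/stop", "img:sign/no-entry", "img:sign/no-parking",
           "img:sign/one-way"), 1L)
  )
  items <- lapply(seq_along(shapes), function(i) {
    d <- shapes[[i]]
    quiz_item(sprintf("graphic-%02d", i), "graphic", d[[1]], d[[2]], d[[3]], i,
              question_prompt = "")
  })
  item_bank("builtin-graphic", "graphic", items)
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> '%s' (%s modality, %d items)\n",
              x$bank_id, x$modality, length(x$items)))
  for (it in x$items) {
    cat(sprintf("  %2d. [%s] %s\n", it$order_rank, it$item_id,
                substr(it$info_payload, 1, 60)))
  }
  invisible(x)
}

#' @export
print.quiz_item <- function(x, ...) {
  cat(sprintf("<quiz_item> '%s' (%s, rank %d)\n  info: %s\n  choices: %s (correct: %d)\n",
              x$item_id, x$modality, x$order_rank, x$info_payload,
              paste(x$choices, collapse = " | "), x$correct_index))
  invisible(x)
}
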