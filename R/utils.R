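# Internal helpers shared across modules.

MODALITIES <- c("text", "graphic")

#' @keywords internal
abort_sr <- function(msg, class) {
  stop(structure(
    class = c(class, "spacedrecall_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

check_modality <- function(modality) {
  if (!is_string(modality) || !modality %in% MODALITIES) {
    abort_sr(
      sprintf("`modality` must be one of %s", paste(dQuote(MODALITIES, '"'), collapse = ", ")),
      "sr_validation_error"
    )
  }
  modality
}

# A persistent RNG stream bound to an environment, so simulated participants
# carry private reproducible randomness without touching the caller's
# .Random.seed.
rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  env
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  force(expr)
}
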