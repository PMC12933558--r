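# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state so library internals never perturb user-level
#' reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# match.arg with a clearer error for config strings coming from files/CLI
match_choice <- function(value, choices, what) {
  if (!is.character(value) || length(value) != 1L || !value %in% choices) {
    stop(sprintf("%s must be one of: %s", what, paste(choices, collapse = ", ")),
         call. = FALSE)
  }
  value
}

empty_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame", row.names = integer(0),
            names = names(cols))
}
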