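# Small shared helpers.

#' Reverse complement of a DNA string
#'
#' @param x Character vector of A/C/G/T/N strings (case-insensitive).
#' @return Character vector of reverse complements (upper case).
#' @export
revcomp <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty string", call. = FALSE)
}
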