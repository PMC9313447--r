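#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so deterministic helpers do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG stream untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a sub-seed from a master seed
#'
#' A single study seed fans out to per-stage seeds by fixed offsets, so one
#' number reproduces the whole study while stages stay independently
#' re-runnable. Kept below 2^31 (R integer range).
#'
#' @param seed master integer seed.
#' @param offset stage offset (small non-negative integer).
#' @return integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.double(seed) * 7919 + as.double(offset) * 104729) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polynomial rolling hash of a serialized object (hex string)
#'
#' Used to key stage caches and run manifests on the configuration content.
#' @param x any R object (serialized via JSON for stability).
#' @return character scalar, 8 hex digits.
#' @keywords internal
config_hash <- function(x) {
  bytes <- utf8ToInt(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_binary_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) stopf("labels must be coded 0/1")
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  invisible(as.integer(labels))
}
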