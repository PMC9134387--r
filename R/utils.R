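#' @keywords internal
"_PACKAGE"

# Package-local cache for lazily loaded data tables.
.sq_cache <- new.env(parent = emptyenv())

#' Evaluate code with a temporarily fixed RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator, runs `code`, and
#' restores the previous state, so library functions never leak RNG side
#' effects into the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
sq_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a sub-seed from a master seed
#'
#' Expands one master seed into reproducible per-stage seeds by fixed offsets,
#' kept inside the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer stage offset.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 2039 + 7 * as.numeric(offset) + 1) %% 2147483629L
}

#' Structured log line
#'
#' Emits `[stage] message` lines via [message()]. Silenced when
#' `options(snapqsar.verbose = FALSE)`.
#' @param stage short stage tag.
#' @param fmt,... passed to [sprintf()].
#' @keywords internal
sq_log <- function(stage, fmt, ...) {
  if (isFALSE(getOption("snapqsar.verbose", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' MD5 hash of an arbitrary R object
#'
#' Serializes the object (format version 3, no header timestamp issues since
#' xdr serialization of identical objects is byte-stable) and hashes the
#' bytes. Used for content-addressed stage caching.
#' @param x any serializable object.
#' @return hex string.
#' @keywords internal
sq_hash <- function(x) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 3)
  close(con)
  unname(tools::md5sum(f))
}

# Internal: read a packaged extdata CSV once and cache it.
sq_data <- function(name) {
  if (!is.null(.sq_cache[[name]])) return(.sq_cache[[name]])
  path <- system.file("extdata", name, package = "snapqsar")
  if (!nzchar(path)) stop("packaged data file not found: ", name)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  .sq_cache[[name]] <- x
  x
}
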