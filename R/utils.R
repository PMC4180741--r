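# Internal helpers: logging and seeded evaluation.

.logLevels <- c(debug = 1L, info = 2L, warning = 3L, error = 4L)

#' Set the package log level
#' @param level one of "debug", "info", "warning", "error".
#' @return the previous level, invisibly.
#' @export
setLogLevel <- function(level = c("info", "debug", "warning", "error")) {
  level <- match.arg(level)
  old <- getOption("saxspipe.logLevel", "info")
  options(saxspipe.logLevel = level)
  invisible(old)
}

logMsg <- function(level, fmt, ...) {
  current <- getOption("saxspipe.logLevel", "info")
  if (.logLevels[[level]] >= .logLevels[[current]])
    message(sprintf("[saxspipe %s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Condition constructors so callers can distinguish failure modes.
stopUnknownFormat <- function(msg) {
  stop(structure(class = c("saxspipe_unknown_format", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stopIncompleteFile <- function(msg) {
  stop(structure(class = c("saxspipe_incomplete_file", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
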