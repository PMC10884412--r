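## Internal helpers: seeded evaluation, logging, validation.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All exported stochastic entry points funnel through this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; offsets keep stages independent
# while staying inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629L)
}

pk_log_level <- new.env(parent = emptyenv())
pk_log_level$level <- "info"

#' Set the logging level
#'
#' One structured message line is emitted per pipeline stage so that every
#' threshold used in a run is auditable from its log.
#'
#' @param level one of "quiet", "info"
#' @export
set_log_level <- function(level = c("info", "quiet")) {
  pk_log_level$level <- match.arg(level)
  invisible(pk_log_level$level)
}

pk_log <- function(stage, ...) {
  if (identical(pk_log_level$level, "quiet")) return(invisible(NULL))
  kv <- list(...)
  txt <- if (length(kv)) {
    paste(names(kv), vapply(kv, function(x) paste(format(x), collapse = ","),
                            character(1)),
          sep = "=", collapse = " ")
  } else ""
  message(sprintf("[polyrekit] %s %s", stage, txt))
  invisible(NULL)
}

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

stopifnot_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative number", name),
         call. = FALSE)
  }
  invisible(x)
}

stopifnot_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
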