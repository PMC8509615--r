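`%||%` <- function(a, b) if (is.null(a)) b else a

#' Condition helper: classed errors so callers can distinguish failure modes
#' @noRd
stop_snap <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "snapqsar_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression under a temporary RNG seed, restoring global state
#' @noRd
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' md5 of an R object via its canonical JSON dump (stable across sessions)
#' @noRd
hash_object <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), f)
  unname(tools::md5sum(f))
}

snap_log <- function(fmt, ...) {
  if (isTRUE(getOption("snapqsar.quiet", TRUE))) return(invisible())
  message(sprintf("[snapqsar %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
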