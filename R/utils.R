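# internal helpers: logging, seeded evaluation, small validators

#' @keywords internal
pf_log <- function(level, module, msg) {
  if (isTRUE(getOption("prophagr.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s: %s", level, module, msg))
  invisible(NULL)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL means "use the current stream" so composite
# generators stay reproducible from one top-level seed.
#' @keywords internal
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

#' @keywords internal
.assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  }
  invisible(x)
}
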