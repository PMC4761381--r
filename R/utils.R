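# shared condition constructors and small helpers

apms_error <- function(msg, class, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "apms_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

config_error <- function(msg, field = NULL) {
  apms_error(msg, "apms_config_error", field = field)
}

extraction_error <- function(msg, row = NA_integer_, pattern = NULL) {
  apms_error(msg, "apms_extraction_error", row = row, pattern = pattern)
}

insufficiency_error <- function(msg = "fewer than two observed values") {
  apms_error(msg, "apms_insufficiency")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# number of capture groups of a regular expression: unescaped "(" outside a
# character class and not opening a (?...) group
n_capture_groups <- function(pattern) {
  regexpr(pattern, "")  # validates the pattern syntax
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n <- 0L
  i <- 1L
  in_class <- FALSE
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\") {
      i <- i + 2L
      next
    }
    if (in_class) {
      if (ch == "]") in_class <- FALSE
    } else if (ch == "[") {
      in_class <- TRUE
    } else if (ch == "(") {
      if (!(i < length(chars) && chars[i + 1L] == "?")) n <- n + 1L
    }
    i <- i + 1L
  }
  n
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    config_error(sprintf("'%s' must be a single string", what), field = what)
  }
  invisible(x)
}
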