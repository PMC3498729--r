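#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

# Structured abort with a package-scoped condition class, so callers and the
# command-line wrapper can distinguish validation from I/O failures.
pd_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("paradiv_", class), "paradiv_error"), ...)
}

pd_validation_error <- function(message, ...) {
  pd_abort(message, class = "validation_error", ...)
}

pd_io_error <- function(message, ...) {
  pd_abort(message, class = "io_error", ...)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Semicolon-joined domain strings <-> character vectors (annotation tables
# store a set per row).
split_domains <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(d) sort(unique(d[nzchar(d)])))
}

join_domains <- function(x) {
  vapply(x, function(d) paste(sort(unique(d)), collapse = ";"), character(1))
}
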