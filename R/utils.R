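# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("scgpcr_format_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("scgpcr_input_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("scgpcr_config_error", "error")))
}

# numeric parsing that never honours the locale: decimal points only,
# scientific notation accepted
parse_numeric <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop_format("non-numeric entries: ", paste(utils::head(unique(x[bad]), 5L),
                                               collapse = ", "))
  }
  out
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`", name, "` must be a single finite number")
  }
  if (positive && x <= 0) stop_input("`", name, "` must be > 0")
  invisible(x)
}

geomean <- function(x) exp(mean(log(x)))
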