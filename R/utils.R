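# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# validation errors get their own condition class so the CLI can map them to
# exit code 2 (runtime failures map to 3)
qs_stop <- function(..., class = "qs_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

# delimiter by extension: .csv -> comma, anything else -> tab
detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# full-precision numeric formatting so write -> read round-trips bit-exactly;
# NA becomes the empty cell
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
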