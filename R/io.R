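#' Read a CT matrix from a delimited text export
#'
#' Expects the array-export convention: first column assay id, header row of
#' sample ids, one CT value (PCR cycles) per cell. Blank cells and any cell
#' equal to one of `undetected_tokens` are marked undetected. The delimiter is
#' auto-detected from the extension (`.csv` comma, otherwise tab); files are
#' read as UTF-8.
#'
#' @param path path to the delimited file.
#' @param undetected_tokens character values treated as "not detected"
#'   (case-sensitive), in addition to the empty cell.
#' @return A [ct_matrix] at stage `"raw"`.
#' @export
read_ct_table <- function(path, undetected_tokens = c("Undetermined", "NA")) {
  raw <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = NULL,
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) qs_stop("CT table needs an assay id column plus >=1 sample")
  assays <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup <- assays[duplicated(assays)]
  if (length(dup)) qs_stop("duplicate assay id: '", dup[1L], "'")
  dup <- samples[duplicated(samples)]
  if (length(dup)) qs_stop("duplicate sample id: '", dup[1L], "'")

  cells <- as.matrix(raw[, -1L, drop = FALSE])
  undet <- cells == "" | matrix(cells %in% undetected_tokens, nrow = nrow(cells))
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !undet, arr.ind = TRUE)
  if (nrow(bad)) {
    qs_stop(sprintf("cannot parse CT cell '%s' (assay '%s', sample '%s')",
                    cells[bad[1L, 1L], bad[1L, 2L]],
                    assays[bad[1L, 1L]], samples[bad[1L, 2L]]),
            class = "qs_parse_error")
  }
  vals[undet] <- NA_real_
  dimnames(vals) <- list(assays, samples)
  ct_matrix(vals, detected = !undet, stage = "raw")
}

#' Write a CT matrix as delimited text
#'
#' Numerics are written at full precision so a write/read round trip
#' reproduces values bit-exactly. Undetected cells are written as empty cells,
#' so the detection mask survives serialization (a censored-but-recorded CT
#' value is deliberately not written: once masked, its magnitude is
#' uninformative).
#'
#' @param x a [ct_matrix].
#' @param path output path; delimiter from extension.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  m <- masked_ct(x)
  cells <- matrix(fmt_num(m), nrow = nrow(m), dimnames = dimnames(m))
  out <- cbind(assay_id = rownames(m), cells)
  write_delim_checked(out, path)
}

#' Read a sample sheet
#'
#' Required columns: `sample_id` and `cohort` (values `patient` / `control`).
#' Recognized clinical columns: `pain_nrs` (0-10 numerical rating scale),
#' `crps_type` (1 or 2), `duration_years`, `bmi`. Every other column must be a
#' binary indicator (values 0, 1 or blank) and is ingested as a
#' comorbidity/medication flag; anything else is rejected. Controls may leave
#' disease-specific fields blank.
#'
#' @param path path to the delimited file.
#' @return A data frame of class `sample_sheet` with attribute `flag_cols`
#'   naming the binary covariates.
#' @export
read_sample_sheet <- function(path) {
  raw <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = NULL,
                           fileEncoding = "UTF-8")
  as_sample_sheet(raw)
}

# build and validate a sample_sheet from a character (or mixed) data frame
as_sample_sheet <- function(df) {
  need <- c("sample_id", "cohort")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) qs_stop("sample sheet missing column(s): ",
                            paste(miss, collapse = ", "))
  ids <- as.character(df$sample_id)
  dup <- ids[duplicated(ids)]
  if (length(dup)) qs_stop("duplicate sample_id: '", dup[1L], "'")
  cohort <- as.character(df$cohort)
  bad <- setdiff(unique(cohort), c("patient", "control"))
  if (length(bad)) qs_stop("unknown cohort label: '", bad[1L], "'")

  num_col <- function(name, check = NULL) {
    if (!name %in% colnames(df)) return(rep(NA_real_, nrow(df)))
    v <- as.character(df[[name]])
    v[v == ""] <- NA
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out) & !is.na(v))) {
      qs_stop("non-numeric value in column '", name, "'")
    }
    if (!is.null(check)) check(out)
    out
  }
  pain <- num_col("pain_nrs", function(v) {
    if (any(!is.na(v) & (v < 0 | v > 10 | v != round(v)))) {
      qs_stop("pain_nrs must be an integer in [0, 10]")
    }
  })
  crps_type <- num_col("crps_type", function(v) {
    if (any(!is.na(v) & !v %in% c(1, 2))) qs_stop("crps_type must be 1 or 2")
  })
  duration <- num_col("duration_years", function(v) {
    if (any(!is.na(v) & v < 0)) qs_stop("duration_years must be >= 0")
  })
  bmi <- num_col("bmi", function(v) {
    if (any(!is.na(v) & v <= 0)) qs_stop("bmi must be positive")
  })

  known <- c("sample_id", "cohort", "pain_nrs", "crps_type",
             "duration_years", "bmi")
  flag_cols <- setdiff(colnames(df), known)
  flags <- lapply(flag_cols, function(name) {
    v <- as.character(df[[name]])
    v[v == ""] <- NA
    if (!all(is.na(v) | v %in% c("0", "1"))) {
      qs_stop("column '", name, "' is not a recognized clinical field and ",
              "cannot be ingested as a binary flag (values must be 0/1/blank)")
    }
    as.integer(v)
  })
  names(flags) <- flag_cols

  out <- data.frame(sample_id = ids, cohort = cohort, pain_nrs = pain,
                    crps_type = crps_type, duration_years = duration,
                    bmi = bmi, stringsAsFactors = FALSE)
  for (name in flag_cols) out[[name]] <- flags[[name]]
  structure(out, flag_cols = flag_cols,
            class = c("sample_sheet", "data.frame"))
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("<sample_sheet> %d samples (%d patient, %d control), %d flags\n",
              nrow(x), sum(x$cohort == "patient"), sum(x$cohort == "control"),
              length(attr(x, "flag_cols"))))
  invisible(as.data.frame(x))
}

#' Read an analyte (cytokine/chemokine) panel
#'
#' First column `sample_id`, remaining columns one analyte each with
#' concentrations in pg/mL; blanks are missing. Concentrations must be
#' nonnegative when present.
#'
#' @param path path to the delimited file.
#' @return A data frame of class `analyte_panel`.
#' @export
read_analyte_panel <- function(path) {
  raw <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = NULL,
                           fileEncoding = "UTF-8")
  if (!"sample_id" %in% colnames(raw)) qs_stop("analyte panel needs sample_id")
  ids <- as.character(raw$sample_id)
  dup <- ids[duplicated(ids)]
  if (length(dup)) qs_stop("duplicate sample_id: '", dup[1L], "'")
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (name in setdiff(colnames(raw), "sample_id")) {
    v <- as.character(raw[[name]])
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v))) {
      qs_stop("non-numeric concentration in analyte '", name, "'")
    }
    if (any(!is.na(num) & num < 0)) {
      qs_stop("negative concentration in analyte '", name, "'")
    }
    out[[name]] <- num
  }
  structure(out, class = c("analyte_panel", "data.frame"))
}

#' Write a result table (or any data frame) as delimited text
#'
#' Column order is preserved, numerics are written at full precision
#' (`%.17g`), missing values as empty cells; [read_result_table()] recovers an
#' equal data frame.
#'
#' @param table a data frame (differential table, correlation table, sample
#'   sheet, ...).
#' @param path output path; delimiter from extension.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  chr <- as.data.frame(lapply(table, function(col) {
    if (is.numeric(col)) fmt_num(col)
    else {
      v <- as.character(col)
      v[is.na(v)] <- ""
      v
    }
  }), stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  colnames(chr) <- colnames(table)
  if (nrow(table) == 0L) {
    # header-only file for empty tables
    chr <- chr[0L, , drop = FALSE]
  }
  write_delim_checked(as.matrix(chr), path, col_names = colnames(table))
}

#' Read back a table written by [write_result_table()]
#'
#' @param path input path.
#' @return A data frame with numeric/logical/character columns restored.
#' @export
read_result_table <- function(path) {
  raw <- utils::read.table(path, sep = detect_sep(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = NULL,
                           fileEncoding = "UTF-8")
  out <- as.data.frame(lapply(raw, function(v) {
    v[v == ""] <- NA
    utils::type.convert(v, as.is = TRUE)
  }), stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  colnames(out) <- colnames(raw)
  out
}

# shared writer: matrix of character cells (+ optional header), I/O errors
# surface as qs_io_error
write_delim_checked <- function(cells, path, col_names = colnames(cells)) {
  sep <- detect_sep(path)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) qs_stop("cannot write '", path, "': ",
                                              conditionMessage(e),
                                              class = "qs_io_error"))
  on.exit(close(con))
  writeLines(paste(col_names, collapse = sep), con)
  if (!is.null(cells) && nrow(cells)) {
    writeLines(apply(cells, 1L, paste, collapse = sep), con)
  }
  invisible(path)
}
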