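# Readers/writers for the FAERS quarterly ASCII dialect:
# "$"-delimited, one header row, no quoting or escaping.

.faers_fields <- list(
  demo = c("primaryid", "caseid", "caseversion", "age", "age_cod", "sex", "occp_cod"),
  drug = c("primaryid", "drug_seq", "role_cod", "prod_ai", "drugname"),
  reac = c("primaryid", "pt")
)

# drugname is frequently absent from older quarters; everything else is required
.faers_required <- list(
  demo = c("primaryid", "caseid", "caseversion", "age", "age_cod", "sex", "occp_cod"),
  drug = c("primaryid", "drug_seq", "role_cod", "prod_ai"),
  reac = c("primaryid", "pt")
)

.faers_int_fields <- c("caseversion", "drug_seq")
.faers_num_fields <- c("age")

#' Read a text file as UTF-8 with latin-1 fallback
#'
#' Older FAERS quarters contain bytes that are not valid UTF-8; those files
#' are re-read as latin-1 and transcoded.
#' @param path file path.
#' @return character vector of lines.
#' @keywords internal
read_faers_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (any(!validUTF8(lines))) {
    lines <- readLines(path, warn = FALSE, encoding = "latin1")
    lines <- iconv(lines, from = "latin1", to = "UTF-8")
  }
  lines
}

#' Guess the quarter label from a FAERS file name
#'
#' FAERS quarterly files are named like `DEMO20Q3.txt`; the two-digit year and
#' quarter map to a `"2020Q3"` label. Returns `NA` when the name does not
#' follow the convention.
#'
#' @param path file path (only the base name is used).
#' @return a quarter label string (`"YYYYQ[1-4]"`) or `NA_character_`.
#' @export
#' @examples
#' faers_quarter_label("data/DEMO20Q3.txt")
faers_quarter_label <- function(path) {
  base <- tolower(basename(path))
  m <- regmatches(base, regexec("^(demo|drug|reac)(\\d{2})q([1-4])", base))[[1]]
  if (length(m) == 0L) return(NA_character_)
  paste0("20", m[3], "Q", m[4])
}

#' Parse one FAERS quarterly ASCII file
#'
#' Reads a `DEMOyyQq` / `DRUGyyQq` / `REACyyQq` file: `"$"`-delimited with a
#' single header row. Column positions are taken from the header
#' (case-insensitively, surrounding whitespace ignored), never assumed, so
#' files with permuted or extra columns parse identically. Empty fields become
#' `NA`, never sentinel values.
#'
#' Lines that cannot be interpreted (more fields than the header, or an empty
#' `primaryid`) are skipped and counted in the `diagnostics` attribute.
#'
#' @param path path to the file.
#' @param file_kind one of `"demo"`, `"drug"`, `"reac"`. The kind is stated by
#'   the caller, not sniffed from content.
#' @param quarter quarter label (e.g. `"2020Q3"`) attached to demo records;
#'   defaults to a guess from the file name via [faers_quarter_label()].
#' @return a `data.table` with one row per record. Demo tables carry columns
#'   `primaryid, caseid, caseversion, age, age_cod, sex, occp_cod, quarter`;
#'   drug tables `primaryid, drug_seq, role_cod, prod_ai, drugname`; reac
#'   tables `primaryid, pt`. Attributes: `kind` (the file kind) and
#'   `diagnostics` (list with `n_lines` and `n_skipped`).
#' @export
parse_faers_file <- function(path, file_kind = c("demo", "drug", "reac"),
                             quarter = faers_quarter_label(path)) {
  file_kind <- match.arg(file_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- read_faers_lines(path)
  if (length(lines) == 0L) stop("empty file (no header row): ", path)

  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  fields <- .faers_fields[[file_kind]]
  missing_cols <- setdiff(.faers_required[[file_kind]], header)
  if (length(missing_cols) > 0L) {
    stop(sprintf("FAERS %s file %s is missing required column(s): %s",
                 file_kind, path, paste(missing_cols, collapse = ", ")))
  }

  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  n_lines <- length(body)

  parts <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(parts)
  readable <- nf <= length(header)
  parts <- parts[readable]

  # strsplit drops a trailing empty field; pad every line to header width
  cols <- lapply(seq_along(header), function(j) {
    vapply(parts, function(p) if (j <= length(p)) p[[j]] else "", character(1))
  })
  names(cols) <- header

  dt <- data.table::as.data.table(cols[!duplicated(names(cols))])
  present <- intersect(fields, names(dt))
  dt <- dt[, present, with = FALSE]
  for (f in setdiff(fields, present)) dt[, (f) := ""]
  data.table::setcolorder(dt, fields)

  for (f in fields) {
    v <- trimws(dt[[f]])
    v[v == ""] <- NA_character_
    if (f %in% .faers_int_fields) {
      dt[, (f) := suppressWarnings(as.integer(v))]
    } else if (f %in% .faers_num_fields) {
      dt[, (f) := suppressWarnings(as.numeric(v))]
    } else {
      dt[, (f) := v]
    }
  }

  bad_id <- is.na(dt$primaryid)
  dt <- dt[!bad_id]
  n_skipped <- sum(!readable) + sum(bad_id)

  if (file_kind == "demo") dt[, quarter := quarter]

  data.table::setattr(dt, "kind", file_kind)
  data.table::setattr(dt, "diagnostics",
                      list(n_lines = n_lines, n_skipped = n_skipped))
  dt[]
}

#' Write records in the FAERS quarterly ASCII dialect
#'
#' Inverse of [parse_faers_file()]: emits a `"$"`-delimited header naming the
#' canonical columns for the record kind, then one line per record with `NA`
#' serialized as the empty field. Round-trips: parsing the written file
#' reproduces the records field-for-field.
#'
#' @param records a `data.table`/`data.frame` of one record kind (as returned
#'   by [parse_faers_file()] or built by the synthetic generator).
#' @param path output file path.
#' @param file_kind one of `"demo"`, `"drug"`, `"reac"`; defaults to the
#'   records' `kind` attribute.
#' @return `path`, invisibly.
#' @export
write_faers_file <- function(records, path,
                             file_kind = attr(records, "kind")) {
  if (is.null(file_kind)) {
    stop("file_kind is not given and the records carry no 'kind' attribute")
  }
  file_kind <- match.arg(file_kind, c("demo", "drug", "reac"))
  fields <- .faers_fields[[file_kind]]
  records <- data.table::as.data.table(records)
  missing_f <- setdiff(fields, names(records))
  if (length(missing_f) > 0L) {
    stop("records lack field(s): ", paste(missing_f, collapse = ", "))
  }

  ser <- vapply(fields, function(f) {
    v <- records[[f]]
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  }, character(nrow(records)))
  body <- if (nrow(records) == 0L) character(0)
          else if (nrow(records) == 1L) paste(ser, collapse = "$")
          else apply(ser, 1L, paste, collapse = "$")

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(fields, collapse = "$"), body), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}
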