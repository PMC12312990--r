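# Cleaning rules applied to raw FAERS records before any statistics:
# professional-reporter filter, latest-version deduplication, primary-suspect
# ingredient extraction, and missing-essential exclusion, with full
# accounting of every dropped row.

#' Occupation codes counted as health care professionals
#' @keywords internal
.professional_codes <- c("HP", "MD", "OT", "PH")

#' Keep only reports filed by health care professionals
#'
#' Retains demo records whose reporter occupation code is one of HP (health
#' professional), MD (physician), OT (other health professional) or PH
#' (pharmacist), matched case-insensitively. Consumer reports (CN), empty and
#' unrecognized codes are dropped and counted.
#'
#' @param records demo record table from [parse_faers_file()].
#' @return the retained records, with attribute `dropped_nonprofessional`
#'   (count of rows removed).
#' @export
filter_professional <- function(records) {
  records <- data.table::as.data.table(records)
  code <- toupper(trimws(records$occp_cod))
  keep <- !is.na(code) & code %in% .professional_codes
  out <- records[keep]
  data.table::setattr(out, "kind", "demo")
  data.table::setattr(out, "dropped_nonprofessional", sum(!keep))
  out[]
}

#' Keep only the latest version of each case
#'
#' FAERS cases are resubmitted with corrections under the same `caseid` with
#' an incremented `caseversion`; only the latest version should be analyzed.
#' For each `caseid` exactly the record with maximal `caseversion` survives
#' (a missing version is treated as 0 so any explicit version supersedes it);
#' ties are broken by the maximal `primaryid`, compared as strings after
#' left-zero-padding to equal length.
#'
#' @param records demo record table.
#' @return one record per `caseid`, with attribute `dropped_duplicate`.
#' @export
deduplicate_cases <- function(records) {
  records <- data.table::as.data.table(records)
  n_in <- nrow(records)
  if (n_in == 0L) {
    out <- records
  } else {
    dt <- data.table::copy(records)
    v <- dt$caseversion
    dt[, .version_key := data.table::fifelse(is.na(v), 0L, v)]
    wid <- max(nchar(dt$primaryid), 1L)
    dt[, .id_key := gsub(" ", "0", formatC(primaryid, width = wid))]
    data.table::setorder(dt, caseid, -.version_key, -.id_key)
    out <- dt[, utils::head(.SD, 1L), by = caseid]
    data.table::setcolorder(out, names(records))
    out[, c(".version_key", ".id_key") := NULL]
  }
  data.table::setattr(out, "kind", "demo")
  data.table::setattr(out, "dropped_duplicate", n_in - nrow(out))
  out[]
}

#' Convert reported ages to years
#'
#' FAERS ages carry a unit code: DEC (decades), YR (years), MON (months),
#' WK (weeks), DY (days), HR (hours). A missing code is read as years.
#' Results are rounded to 4 decimals. Ages above 120 years are treated as
#' data-entry errors and returned as missing, as are negative values and
#' unrecognized unit codes.
#'
#' @param age numeric vector of reported age values.
#' @param age_cod character vector of unit codes (recycled if length 1).
#' @return numeric vector of ages in years (`NA` where invalid), with
#'   attributes `n_unrecognized_unit` and `n_out_of_range`.
#' @export
#' @examples
#' normalize_age(c(30, 24, 1), c("YR", "MON", "DEC"))
normalize_age <- function(age, age_cod = NULL) {
  n <- length(age)
  if (is.null(age_cod)) age_cod <- rep("", n)
  if (length(age_cod) == 1L && n > 1L) age_cod <- rep(age_cod, n)
  stopifnot(length(age_cod) == n)

  code <- toupper(trimws(age_cod))
  code[is.na(code) | code == ""] <- "YR"
  per_year <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                DY = 1 / 365.25, HR = 1 / 8766)
  mult <- per_year[code]
  unrecognized <- !is.na(age) & is.na(mult)

  years <- round(as.numeric(age) * as.numeric(mult), 4)
  out_of_range <- !is.na(years) & (years > 120 | years < 0)
  years[out_of_range] <- NA_real_

  structure(years,
            n_unrecognized_unit = sum(unrecognized),
            n_out_of_range = sum(out_of_range))
}

#' Normalize an active-ingredient string
#'
#' Uppercases, trims, collapses internal whitespace, and normalizes the
#' combination-product separator `"\"` to `"/"` (so e.g. Paxlovid appears
#' uniformly as `"NIRMATRELVIR/RITONAVIR"` and is targeted verbatim as a
#' single token; components are never expanded).
#'
#' @param x character vector of ingredient strings.
#' @return normalized character vector (`NA` preserved).
#' @export
normalize_ingredient <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub("\\", "/", x, fixed = TRUE)
  gsub("[[:space:]]+", " ", x)
}

#' Extract primary-suspect ingredients per report
#'
#' Only drug rows whose role code is PS (primary suspect) contribute; their
#' `prod_ai` strings are normalized with [normalize_ingredient()]. Rows whose
#' ingredient is empty after normalization are dropped and counted.
#'
#' @param records drug record table from [parse_faers_file()].
#' @return a `data.table` with columns `primaryid`, `ingredient` — the long
#'   form of the report-to-ingredient-set map, one row per distinct
#'   (report, ingredient) pair. Attribute `dropped_empty_ingredient` counts
#'   PS rows removed for lacking an ingredient.
#' @export
extract_primary_suspect <- function(records) {
  records <- data.table::as.data.table(records)
  role <- toupper(trimws(records$role_cod))
  ps <- records[!is.na(role) & role == "PS"]
  ing <- normalize_ingredient(ps$prod_ai)
  empty <- is.na(ing) | ing == ""
  out <- unique(data.table::data.table(primaryid = ps$primaryid[!empty],
                                       ingredient = ing[!empty]))
  data.table::setattr(out, "dropped_empty_ingredient", sum(empty))
  out[]
}

#' Construct a clean case table from components
#' @keywords internal
new_clean_case_table <- function(cases, provenance = list()) {
  dt <- data.table::as.data.table(cases)
  stopifnot(all(c("caseid", "primaryid", "sex", "age_years", "reporter",
                  "ps_ingredients", "pts") %in% names(dt)))
  data.table::setattr(dt, "provenance", provenance)
  data.table::setattr(dt, "class",
                      c("clean_case_table", class(data.table::data.table())))
  dt[]
}

#' Assemble the analysis-ready case table
#'
#' Inner-joins demo, drug and reac records on `primaryid` and applies the
#' missing-essential rule: a case must have at least one primary-suspect
#' ingredient and at least one reaction term, otherwise it is excluded and
#' counted. Sex codes are mapped F→female, M→male, everything else (including
#' UNK) → unknown; unknown-sex and unknown-age cases stay in the table and are
#' only excluded from the respective subgroup analyses. PT strings are
#' trimmed; matching thereafter is exact and case-preserving.
#'
#' @param demo demo records, already professional-filtered and deduplicated
#'   (one row per case).
#' @param drug drug records (any rows; only PS rows contribute).
#' @param reac reac records.
#' @param single_ps_only if `TRUE` (default), cases with more than one
#'   distinct primary-suspect ingredient are excluded (reports where a single
#'   drug was implicated), and counted in `dropped_multi_ps`.
#' @return a `clean_case_table`: a `data.table` with columns `caseid`,
#'   `primaryid`, `sex`, `age_years`, `reporter`, and list columns
#'   `ps_ingredients` and `pts` (each a sorted character vector per case).
#'   The `provenance` attribute carries quarter labels and per-stage
#'   exclusion counts.
#' @export
build_case_table <- function(demo, drug, reac, single_ps_only = TRUE) {
  demo <- data.table::as.data.table(demo)
  reac <- data.table::as.data.table(reac)

  ps_map <- extract_primary_suspect(drug)
  ing_sets <- ps_map[, .(ps_ingredients = list(sort(unique(ingredient)))),
                     by = primaryid]

  pt <- trimws(reac$pt)
  ok_pt <- !is.na(pt) & pt != ""
  pt_sets <- data.table::data.table(primaryid = reac$primaryid[ok_pt],
                                    pt = pt[ok_pt])
  pt_sets <- pt_sets[, .(pts = list(sort(unique(pt)))), by = primaryid]

  cases <- data.table::data.table(
    caseid = demo$caseid,
    primaryid = demo$primaryid,
    sex = data.table::fcase(
      toupper(trimws(demo$sex)) == "F", "female",
      toupper(trimws(demo$sex)) == "M", "male",
      default = "unknown"),
    age_years = as.numeric(normalize_age(demo$age, demo$age_cod)),
    reporter = toupper(trimws(demo$occp_cod))
  )
  cases <- ing_sets[cases, on = "primaryid"]
  cases <- pt_sets[cases, on = "primaryid"]

  no_ing <- vapply(cases$ps_ingredients, is.null, logical(1))
  no_pt <- vapply(cases$pts, is.null, logical(1))
  essential <- !no_ing & !no_pt
  dropped_missing <- sum(!essential)
  cases <- cases[essential]

  dropped_multi <- 0L
  if (isTRUE(single_ps_only) && nrow(cases) > 0L) {
    multi <- lengths(cases$ps_ingredients) > 1L
    dropped_multi <- sum(multi)
    cases <- cases[!multi]
  }

  data.table::setcolorder(cases, c("caseid", "primaryid", "sex", "age_years",
                                   "reporter", "ps_ingredients", "pts"))
  prov <- list(
    quarters = sort(unique(stats::na.omit(demo$quarter))),
    n_raw_demo = attr(demo, "n_raw_demo") %||% nrow(demo),
    dropped_nonprofessional = attr(demo, "dropped_nonprofessional") %||% 0L,
    dropped_duplicate = attr(demo, "dropped_duplicate") %||% 0L,
    dropped_missing_essential = dropped_missing,
    dropped_multi_ps = dropped_multi,
    dropped_empty_ingredient_rows =
      attr(ps_map, "dropped_empty_ingredient") %||% 0L,
    n_cases = nrow(cases),
    single_ps_only = isTRUE(single_ps_only)
  )
  new_clean_case_table(cases, prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full preprocessing flow on raw record tables
#'
#' Applies, in order: the health-professional reporter filter (optional),
#' latest-version deduplication, and case-table assembly with the
#' missing-essential rule. Exclusion counts for every stage are accumulated
#' into the result's `provenance` attribute, which satisfies the conservation
#' identity: raw demo rows = retained cases + dropped(non-professional) +
#' dropped(duplicate version) + dropped(missing essentials)
#' (+ dropped(multiple primary suspects) when `single_ps_only`).
#'
#' @param demo,drug,reac raw record tables from [parse_faers_file()]
#'   (multiple quarters may be row-bound beforehand).
#' @param professional_only apply the reporter-occupation filter (default
#'   `TRUE`, the standard analysis population).
#' @param single_ps_only see [build_case_table()].
#' @return a `clean_case_table`; see [build_case_table()].
#' @export
preprocess_faers <- function(demo, drug, reac, professional_only = TRUE,
                             single_ps_only = TRUE) {
  demo <- data.table::as.data.table(demo)
  n_raw <- nrow(demo)
  if (isTRUE(professional_only)) demo <- filter_professional(demo)
  dropped_prof <- attr(demo, "dropped_nonprofessional") %||% 0L
  demo <- deduplicate_cases(demo)
  data.table::setattr(demo, "n_raw_demo", n_raw)
  data.table::setattr(demo, "dropped_nonprofessional", dropped_prof)
  build_case_table(demo, drug, reac, single_ps_only = single_ps_only)
}

#' Provenance of a clean case table
#'
#' @param x a `clean_case_table`.
#' @return the provenance list: quarter labels and per-stage exclusion counts.
#' @export
provenance <- function(x) attr(x, "provenance")

#' Serialize a clean case table to a tab-separated file
#'
#' The ingredient and PT sets are written as `"|"`-joined sorted lists, so the
#' file is a plain rectangular TSV readable by any tool.
#'
#' @param x a `clean_case_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_case_table <- function(x, path) {
  flat <- data.table::data.table(
    caseid = x$caseid,
    primaryid = x$primaryid,
    sex = x$sex,
    age_years = x$age_years,
    reporter = x$reporter,
    ps_ingredients = vapply(x$ps_ingredients, paste, character(1),
                            collapse = "|"),
    pts = vapply(x$pts, paste, character(1), collapse = "|")
  )
  data.table::fwrite(flat, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read a clean case table written by [write_case_table()]
#'
#' @param path path to the TSV file.
#' @return a `clean_case_table` (provenance is not stored in the file and is
#'   returned empty).
#' @export
read_case_table <- function(path) {
  flat <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("caseid", "primaryid", "sex", "reporter",
                  "ps_ingredients", "pts")),
    na.strings = "")
  cases <- data.table::data.table(
    caseid = flat$caseid,
    primaryid = flat$primaryid,
    sex = flat$sex,
    age_years = as.numeric(flat$age_years),
    reporter = flat$reporter,
    ps_ingredients = strsplit(flat$ps_ingredients, "|", fixed = TRUE),
    pts = strsplit(flat$pts, "|", fixed = TRUE)
  )
  new_clean_case_table(cases, list())
}
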