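# Reporting odds ratio disproportionality statistics on 2x2 contingency
# tables of spontaneous reports, with Wald confidence intervals and a z test
# for subgroup heterogeneity of log RORs.

#' Build a 2x2 report contingency table
#'
#' @param a reports exposed to the drug group with the event.
#' @param b reports exposed to the drug group without the event.
#' @param c reports with the event but not exposed.
#' @param d reports with neither.
#' @return a `contingency_table` object (named list with `a`, `b`, `c`, `d`,
#'   `cohort_size`).
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d),
                 cohort_size = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Count the drug-by-event contingency table over a cohort
#'
#' A case is "exposed" iff its primary-suspect ingredient set intersects
#' `drug_group`; it "has the event" iff `pt` is among its reaction terms
#' (exact string match after trimming). The four cells partition the cohort,
#' so `a + b + c + d` equals the cohort size. A PT reported by no case yields
#' a valid table with `a = c = 0`.
#'
#' @param cases a `clean_case_table`.
#' @param drug_group character vector of ingredient names (normalized with
#'   [normalize_ingredient()] before matching), or a [drug_group()] object.
#' @param pt a single reaction preferred term.
#' @param cohort_filter optional predicate: a function taking the case table
#'   and returning a logical vector selecting the cohort (e.g. one sex
#'   stratum). `NULL` means the whole table.
#' @return a `contingency_table`.
#' @export
count_contingency <- function(cases, drug_group, pt, cohort_filter = NULL) {
  if (inherits(drug_group, "drug_group")) drug_group <- drug_group$ingredients
  if (length(drug_group) == 0L) stop("drug_group must be non-empty")
  dg <- normalize_ingredient(drug_group)
  pt <- trimws(pt)
  stopifnot(length(pt) == 1L)

  cohort <- cases
  if (!is.null(cohort_filter)) {
    keep <- cohort_filter(cases)
    stopifnot(is.logical(keep), length(keep) == nrow(cases))
    cohort <- cases[which(keep)]
  }
  if (nrow(cohort) == 0L) return(contingency_table(0L, 0L, 0L, 0L))

  exposed <- vapply(cohort$ps_ingredients, function(s) any(s %in% dg),
                    logical(1))
  has_event <- vapply(cohort$pts, function(s) pt %in% s, logical(1))
  contingency_table(sum(exposed & has_event),
                    sum(exposed & !has_event),
                    sum(!exposed & has_event),
                    sum(!exposed & !has_event))
}

#' Vectorized ROR with Wald CI over cell vectors
#'
#' Workhorse behind [ror()] and the bulk analysis modes. Applies the
#' Haldane-Anscombe continuity correction (add 0.5 to all four cells) to rows
#' with at least one zero cell; rows with no exposed (`a + b = 0`) or no
#' comparator (`c + d = 0`) reports are returned as non-estimable (`NA`).
#'
#' @param a,b,c,d numeric vectors of cell counts (recycled to equal length).
#' @return a `data.table` with columns `a, b, c, d, ror, ln_ror, se_ln,
#'   ci_low, ci_high, corrected, significant, estimable`.
#' @keywords internal
ror_stats <- function(a, b, c, d) {
  dt <- data.table::data.table(a = as.numeric(a), b = as.numeric(b),
                               c = as.numeric(c), d = as.numeric(d))
  estimable <- (dt$a + dt$b) > 0 & (dt$c + dt$d) > 0
  corrected <- estimable & (dt$a == 0 | dt$b == 0 | dt$c == 0 | dt$d == 0)
  k <- data.table::fifelse(corrected, 0.5, 0)
  aa <- dt$a + k; bb <- dt$b + k; cc <- dt$c + k; dd <- dt$d + k

  ln_ror <- log(aa) - log(bb) - log(cc) + log(dd)
  se_ln <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  ci_low <- exp(ln_ror - 1.96 * se_ln)
  ci_high <- exp(ln_ror + 1.96 * se_ln)

  dt[, ror := data.table::fifelse(estimable, exp(ln_ror), NA_real_)]
  dt[, ln_ror := data.table::fifelse(estimable, ln_ror, NA_real_)]
  dt[, se_ln := data.table::fifelse(estimable, se_ln, NA_real_)]
  dt[, ci_low := data.table::fifelse(estimable, ci_low, NA_real_)]
  dt[, ci_high := data.table::fifelse(estimable, ci_high, NA_real_)]
  dt[, corrected := corrected]
  # forest criterion: lower bound of the log2 CI > 0 <=> ci_low > 1
  dt[, significant := !is.na(ci_low) & ci_low > 1]
  dt[, estimable := estimable]
  dt[]
}

#' Reporting odds ratio with 95% Wald confidence interval
#'
#' For a 2x2 table of report counts, the ROR is `(a/b) / (c/d)`: the odds of
#' the event among reports of the drug over the same odds among comparator
#' reports. The standard error of the log ROR is
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and the 95% CI is
#' `exp(ln ROR +/- 1.96 * SE)`. If any raw cell is zero, 0.5 is added to all
#' four cells first (Haldane-Anscombe correction) and the result is marked
#' `corrected`. The signal flag `significant` is `TRUE` when the CI lower
#' bound exceeds 1 — equivalently, when the lower bound of the
#' log2-transformed CI is greater than zero, the forest-plot criterion.
#'
#' @param table a `contingency_table`, or a numeric vector of the four cells
#'   `(a, b, c, d)`.
#' @return a `ror_result` object: named list with `ror`, `ln_ror`, `se_ln`,
#'   `ci_low`, `ci_high`, `corrected`, `significant`, and the (uncorrected)
#'   cells.
#' @export
#' @examples
#' ror(contingency_table(20, 80, 100, 900))
ror <- function(table) {
  if (inherits(table, "contingency_table")) {
    cells <- c(table$a, table$b, table$c, table$d)
  } else if (is.numeric(table) && length(table) == 4L) {
    cells <- as.numeric(table)
  } else {
    stop("table must be a contingency_table or a numeric vector (a, b, c, d)")
  }
  if (cells[1] + cells[2] == 0) {
    stop("undefined estimate: no exposed reports (a + b = 0)")
  }
  if (cells[3] + cells[4] == 0) {
    stop("undefined estimate: no comparator reports (c + d = 0)")
  }
  s <- ror_stats(cells[1], cells[2], cells[3], cells[4])
  structure(list(ror = s$ror, ln_ror = s$ln_ror, se_ln = s$se_ln,
                 ci_low = s$ci_low, ci_high = s$ci_high,
                 corrected = s$corrected, significant = s$significant,
                 a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "ror_result")
}

#' @export
print.ror_result <- function(x, ...) {
  cat(sprintf("ROR %.4g (95%% CI %.4g-%.4g)%s%s\n",
              x$ror, x$ci_low, x$ci_high,
              if (x$corrected) ", continuity-corrected" else "",
              if (x$significant) ", signal" else ""))
  invisible(x)
}

#' Compare RORs between two subgroups with a z test
#'
#' Tests heterogeneity of the log RORs of two independent strata:
#' `z = (ln ROR1 - ln ROR2) / sqrt(SE1^2 + SE2^2)`, with two-sided
#' `p = 2 * (1 - Phi(|z|))` from the standard-normal CDF. The difference is
#' `flagged` when the fold ratio `max(ROR1, ROR2) / min(ROR1, ROR2)` is at
#' least 1.5 **and** p < .05.
#'
#' @param r1,r2 `ror_result` objects for the two strata.
#' @param labels character vector of two stratum names.
#' @return a `subgroup_comparison` object: named list with `label_1`,
#'   `label_2`, `r1`, `r2`, `fold`, `z`, `p`, `flagged`.
#' @export
compare_subgroups <- function(r1, r2, labels = c("group1", "group2")) {
  stopifnot(inherits(r1, "ror_result"), inherits(r2, "ror_result"),
            length(labels) == 2L)
  z <- (r1$ln_ror - r2$ln_ror) / sqrt(r1$se_ln^2 + r2$se_ln^2)
  # p = 2 * (1 - Phi(|z|)), via the complementary tail (= erfc(|z|/sqrt(2)))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  fold <- max(r1$ror, r2$ror) / min(r1$ror, r2$ror)
  structure(list(label_1 = labels[[1]], label_2 = labels[[2]],
                 r1 = r1, r2 = r2, fold = fold, z = z, p = p,
                 flagged = fold >= 1.5 && p < 0.05),
            class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat(sprintf(
    "%s ROR %.4g vs %s ROR %.4g: fold %.3g, z = %.3g, p = %.3g%s\n",
    x$label_1, x$r1$ror, x$label_2, x$r2$ror, x$fold, x$z,
    signif(x$p, 3), if (x$flagged) " *" else ""))
  invisible(x)
}

#' Reconstruct a point estimate from Wald CI bounds
#'
#' A Wald interval on the odds-ratio scale is geometrically symmetric about
#' the estimate: `exp((ln L + ln U) / 2)` recovers the ROR from its CI
#' bounds. Useful for validating published (ROR, CI) triples.
#'
#' @param ror reported point estimate (unused in the computation; returned
#'   alongside for convenience when not `NULL`).
#' @param ci_low,ci_high positive CI bounds with `ci_low <= ci_high`.
#' @return the reconstructed point estimate.
#' @export
#' @examples
#' ci_consistency_check(47.26, 45.22, 49.40)
ci_consistency_check <- function(ror = NULL, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_high <= 0)) {
    stop("CI bounds must be positive")
  }
  if (any(ci_low > ci_high)) stop("ci_low must not exceed ci_high")
  exp((log(ci_low) + log(ci_high)) / 2)
}
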