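# The two analysis modes over a clean case table: the top-k reaction profile
# of one drug group (frequency table + ROR forest vs all other drugs), and
# drug-vs-drug comparison of selected reactions with optional sex or age
# subgrouping.

#' Define a drug group
#'
#' A drug group is a named set of active ingredients; a case is exposed to the
#' group when its primary-suspect ingredient set intersects the group's.
#' Ingredients are normalized with [normalize_ingredient()], so
#' `"hydroxychloroquine"` and `"HYDROXYCHLOROQUINE"` are the same token, and
#' combination products are matched verbatim (e.g.
#' `"NIRMATRELVIR/RITONAVIR"`).
#'
#' @param name user-facing label for the group.
#' @param ingredients character vector of ingredient names; must be non-empty
#'   unless `is_other_drugs`.
#' @param is_other_drugs if `TRUE` the group is the complement comparator:
#'   every case not exposed to the target group.
#' @return a `drug_group` object.
#' @export
drug_group <- function(name, ingredients = character(0),
                       is_other_drugs = FALSE) {
  if (!is_other_drugs && length(ingredients) == 0L) {
    stop("a drug group needs at least one ingredient (or is_other_drugs)")
  }
  structure(list(name = name,
                 ingredients = normalize_ingredient(ingredients),
                 is_other_drugs = isTRUE(is_other_drugs)),
            class = "drug_group")
}

#' The "all other drugs" comparator group
#'
#' @param name label, default `"OTHER DRUGS"`.
#' @return a `drug_group` with `is_other_drugs = TRUE`.
#' @export
other_drugs <- function(name = "OTHER DRUGS") {
  drug_group(name, character(0), is_other_drugs = TRUE)
}

#' Subgroup specification for drug-vs-drug comparisons
#'
#' @param mode `"none"`, `"sex"` or `"age"`.
#' @param age_split age cutoff in years for `mode = "age"`; the two strata
#'   are `age > age_split` and `age <= age_split` (the boundary age belongs
#'   to the younger stratum). Default 50.
#' @return a `subgroup_spec` object.
#' @export
subgroup_spec <- function(mode = c("none", "sex", "age"), age_split = 50) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(age_split), length(age_split) == 1L, age_split > 0)
  structure(list(mode = mode, age_split = age_split), class = "subgroup_spec")
}

.exposure_mask <- function(cases, group) {
  stopifnot(inherits(group, "drug_group"))
  if (group$is_other_drugs) {
    stop("exposure to the OTHER DRUGS comparator is defined relative to a ",
         "target group; pass it as the control of reaction_comparison()")
  }
  dg <- group$ingredients
  vapply(cases$ps_ingredients, function(s) any(s %in% dg), logical(1))
}

# counts of cases reporting each PT within a logical case subset
.pt_case_counts <- function(cases, mask) {
  pts <- unlist(cases$pts[mask], use.names = FALSE)
  if (length(pts) == 0L) {
    return(data.table::data.table(pt = character(0), n = integer(0)))
  }
  dt <- data.table::data.table(pt = pts)[, .(n = .N), by = pt]
  # descending count, ties alphabetical
  data.table::setorderv(dt, c("n", "pt"), order = c(-1L, 1L))
  dt[]
}

#' Rank the most frequently reported reactions of a drug group
#'
#' Counts, for each reaction preferred term, the number of exposed cases
#' reporting it (a case contributes at most once per PT), and returns the top
#' `k` ranked by count descending, ties broken alphabetically by PT.
#'
#' @param cases a `clean_case_table`.
#' @param group a [drug_group()].
#' @param k number of reactions to return (default 15); if fewer distinct PTs
#'   exist, all are returned.
#' @return a `data.table` with columns `pt`, `n`.
#' @export
top_reactions <- function(cases, group, k = 15L) {
  stopifnot(k >= 1L)
  mask <- .exposure_mask(cases, group)
  if (!any(mask)) {
    stop("empty cohort: no case is exposed to drug group '", group$name, "'")
  }
  counts <- .pt_case_counts(cases, mask)
  utils::head(counts, min(k, nrow(counts)))
}

# per-PT contingency cells of an exposed-vs-comparator split, vectorized
.pt_contingency <- function(cases, exposed_mask, comparator_mask, pts) {
  n_exp <- sum(exposed_mask)
  n_cmp <- sum(comparator_mask)
  exp_counts <- .pt_case_counts(cases, exposed_mask)
  cmp_counts <- .pt_case_counts(cases, comparator_mask)
  a <- exp_counts$n[match(pts, exp_counts$pt)]
  c_ <- cmp_counts$n[match(pts, cmp_counts$pt)]
  a[is.na(a)] <- 0L
  c_[is.na(c_)] <- 0L
  data.table::data.table(pt = pts, a = a, b = n_exp - a, c = c_,
                         d = n_cmp - c_)
}

.ror_rows <- function(cells) {
  s <- ror_stats(cells$a, cells$b, cells$c, cells$d)
  out <- cbind(cells[, .(pt)], s)
  out[, note := data.table::fifelse(
    estimable & (a + c) > 0, "",
    data.table::fifelse(!estimable, "not estimable: empty stratum or cohort",
                        "not estimable: PT reported by no case in cohort"))]
  # a PT reported by no case carries no information; mark it not estimable
  out[(a + c) == 0, `:=`(ror = NA_real_, ln_ror = NA_real_, se_ln = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_,
                         corrected = FALSE, significant = FALSE,
                         estimable = FALSE)]
  out[]
}

#' Most potential reactions of a drug group
#'
#' The first analysis mode: ranks the drug group's reactions by reported-case
#' count, then computes, for each of the top `k`, the ROR of the group against
#' all other drugs (comparator = every unexposed case in the table). The
#' report also carries the complete reaction frequency table of the group.
#'
#' @inheritParams top_reactions
#' @return a `faers_report` with `mode = "most_potential_reactions"`,
#'   `results` (per-PT cells and ROR statistics), `freq` (full frequency
#'   table), and `cohort` sizes.
#' @export
most_potential_reactions <- function(cases, group, k = 15L) {
  mask <- .exposure_mask(cases, group)
  if (!any(mask)) {
    stop("empty cohort: no case is exposed to drug group '", group$name, "'")
  }
  freq <- .pt_case_counts(cases, mask)
  top <- utils::head(freq, min(k, nrow(freq)))
  cells <- .pt_contingency(cases, mask, !mask, top$pt)
  results <- .ror_rows(cells)
  results[, stratum := "overall"]
  structure(list(mode = "most_potential_reactions",
                 target = group$name,
                 control = "OTHER DRUGS",
                 results = results,
                 comparisons = NULL,
                 freq = freq,
                 cohort = list(n_exposed = sum(mask),
                               n_comparator = sum(!mask)),
                 excluded = list(),
                 k = k),
            class = "faers_report")
}

.stratum_masks <- function(cases, sub) {
  if (sub$mode == "sex") {
    list(labels = c("female", "male"),
         masks = list(cases$sex == "female", cases$sex == "male"),
         excluded = sum(cases$sex == "unknown"),
         excluded_what = "unknown sex")
  } else {
    age <- cases$age_years
    list(labels = c(sprintf("age>%g", sub$age_split),
                    sprintf("age<=%g", sub$age_split)),
         masks = list(!is.na(age) & age > sub$age_split,
                      !is.na(age) & age <= sub$age_split),
         excluded = sum(is.na(age)),
         excluded_what = "unknown age")
  }
}

#' Compare selected reactions between two drug groups
#'
#' The second analysis mode. The cohort is restricted to cases exposed to the
#' target or the control group (when the control is the OTHER DRUGS
#' comparator, that is every case); cases exposed to both explicit groups are
#' excluded and counted. Per requested PT:
#' \itemize{
#'   \item `mode "none"` — one ROR of target vs control;
#'   \item `mode "sex"` — RORs within the female and male strata plus a
#'     [compare_subgroups()] z test; unknown-sex cases are excluded and
#'     counted;
#'   \item `mode "age"` — strata are `age > age_split` vs `age <= age_split`
#'     (boundary in the younger stratum); unknown-age cases excluded and
#'     counted.
#' }
#' In subgroup modes the whole cohort is restricted to each stratum, so the
#' comparator cells are stratum-specific too, making the two strata
#' independent as the z test assumes. A stratum with no exposed case, or a PT
#' reported by no case, yields a not-estimable row; the remaining PTs are
#' still computed.
#'
#' @param cases a `clean_case_table`.
#' @param target a [drug_group()].
#' @param control a [drug_group()], default [other_drugs()].
#' @param pts character vector of reaction preferred terms (non-empty).
#' @param sub a [subgroup_spec()], default no subgrouping.
#' @return a `faers_report` with `results` (one row per PT x stratum) and, in
#'   subgroup modes, `comparisons` (one row per PT with fold, z, p, flagged).
#' @export
reaction_comparison <- function(cases, target, control = other_drugs(),
                                pts, sub = subgroup_spec("none")) {
  stopifnot(inherits(target, "drug_group"), inherits(control, "drug_group"),
            inherits(sub, "subgroup_spec"))
  if (length(pts) == 0L) stop("pts must be non-empty")
  pts <- trimws(pts)

  t_mask <- .exposure_mask(cases, target)
  excluded <- list()
  if (control$is_other_drugs) {
    c_mask <- !t_mask
    cohort <- cases
  } else {
    c_mask <- .exposure_mask(cases, control)
    dual <- t_mask & c_mask
    excluded$dual_exposure <- sum(dual)
    keep <- (t_mask | c_mask) & !dual
    cohort <- cases[which(keep)]
    t_mask <- t_mask[keep]
    c_mask <- c_mask[keep]
  }

  if (sub$mode == "none") {
    cells <- .pt_contingency(cohort, t_mask, c_mask, pts)
    results <- .ror_rows(cells)
    results[, stratum := "overall"]
    comparisons <- NULL
    cohort_sizes <- list(n_target = sum(t_mask), n_control = sum(c_mask))
  } else {
    st <- .stratum_masks(cohort, sub)
    excluded[[st$excluded_what]] <- st$excluded
    res_list <- vector("list", 2L)
    for (i in 1:2) {
      m <- st$masks[[i]]
      cells <- .pt_contingency(cohort[which(m)], t_mask[m], c_mask[m], pts)
      r <- .ror_rows(cells)
      r[, stratum := st$labels[[i]]]
      res_list[[i]] <- r
    }
    results <- data.table::rbindlist(res_list)
    r1 <- res_list[[1]]; r2 <- res_list[[2]]
    both <- r1$estimable & r2$estimable
    z <- (r1$ln_ror - r2$ln_ror) / sqrt(r1$se_ln^2 + r2$se_ln^2)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    fold <- pmax(r1$ror, r2$ror) / pmin(r1$ror, r2$ror)
    comparisons <- data.table::data.table(
      pt = r1$pt,
      label_1 = st$labels[[1]], label_2 = st$labels[[2]],
      ror_1 = r1$ror, ror_2 = r2$ror,
      fold = data.table::fifelse(both, fold, NA_real_),
      z = data.table::fifelse(both, z, NA_real_),
      p = data.table::fifelse(both, p, NA_real_),
      flagged = both & !is.na(fold) & fold >= 1.5 & !is.na(p) & p < 0.05,
      estimable = both,
      note = data.table::fifelse(both, "",
                                 "not estimable in at least one stratum"))
    cohort_sizes <- list(
      n_target = sum(t_mask), n_control = sum(c_mask),
      per_stratum = stats::setNames(
        lapply(st$masks, function(m) list(n_target = sum(t_mask & m),
                                          n_control = sum(c_mask & m))),
        st$labels))
  }

  structure(list(mode = paste0("reaction_comparison_", sub$mode),
                 target = target$name,
                 control = control$name,
                 results = results,
                 comparisons = comparisons,
                 freq = .pt_case_counts(cohort, t_mask),
                 cohort = cohort_sizes,
                 excluded = excluded,
                 k = NA_integer_),
            class = "faers_report")
}

#' @export
print.faers_report <- function(x, ...) {
  cat(sprintf("FAERS disproportionality report [%s]\n", x$mode))
  cat(sprintf("  target: %s, control: %s\n", x$target, x$control))
  cat(sprintf("  cohort: %s\n",
              paste(names(unlist(x$cohort[c("n_exposed", "n_comparator",
                                            "n_target", "n_control")])),
                    unlist(x$cohort[c("n_exposed", "n_comparator",
                                      "n_target", "n_control")]),
                    sep = "=", collapse = ", ")))
  print(x$results)
  if (!is.null(x$comparisons)) {
    cat("subgroup comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}

#' Write the four report artifacts of an analysis run
#'
#' Mirrors the downloadable outputs of an interactive run: the reaction pie
#' chart and ROR forest plot (each as PNG and PDF), the full reaction
#' frequency table, and the raw forest-plot data table (tab-separated).
#'
#' @param report a `faers_report`.
#' @param out_dir output directory (created if needed).
#' @param basename file name stem, default the report mode.
#' @return named character vector of the written paths, invisibly.
#' @export
write_report <- function(report, out_dir, basename = report$mode) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()

  freq_path <- file.path(out_dir, paste0(basename, "_frequency.tsv"))
  data.table::fwrite(report$freq, freq_path, sep = "\t")
  paths["frequency"] <- freq_path

  raw <- data.table::copy(report$results)
  raw[, `:=`(drug_group = report$target, control = report$control)]
  data.table::setcolorder(raw, c("drug_group", "control", "pt", "stratum"))
  raw_path <- file.path(out_dir, paste0(basename, "_forest_data.tsv"))
  data.table::fwrite(raw, raw_path, sep = "\t")
  paths["forest_data"] <- raw_path

  if (!is.null(report$comparisons)) {
    cmp_path <- file.path(out_dir, paste0(basename, "_comparisons.tsv"))
    data.table::fwrite(report$comparisons, cmp_path, sep = "\t")
    paths["comparisons"] <- cmp_path
  }

  if (nrow(report$freq) > 0L) {
    top <- utils::head(report$freq,
                       min(report$k, nrow(report$freq), na.rm = TRUE))
    for (ext in c("png", "pdf")) {
      p <- file.path(out_dir, paste0(basename, "_pie.", ext))
      render_pie(top, p)
      paths[paste0("pie_", ext)] <- p
    }
  }

  rows <- forest_rows(report)
  if (nrow(rows) > 0L) {
    for (ext in c("png", "pdf")) {
      p <- file.path(out_dir, paste0(basename, "_forest.", ext))
      render_forest(rows, p)
      paths[paste0("forest_", ext)] <- p
    }
  }
  invisible(paths)
}
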