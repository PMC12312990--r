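# Synthetic FAERS quarter generator with known ground truth: each case draws
# one primary-suspect ingredient and a set of reaction PTs whose probabilities
# are odds-adjusted so that injected (ingredient, PT) signals hit a target
# population ROR against the all-other-drugs comparator.

#' Invert the ROR definition to an exposed-case event probability
#'
#' Given a background event probability `p` among comparator cases, returns
#' the probability `p'` for exposed cases such that the odds ratio
#' `odds(p') / odds(p)` equals `target_ror`:
#' `p' = (ror * o) / (1 + ror * o)` with `o = p / (1 - p)`.
#'
#' @param background_p background event probability, strictly inside (0, 1).
#' @param target_ror target reporting odds ratio (> 0).
#' @return the exposed-case event probability (vectorized).
#' @export
#' @examples
#' odds_adjust(0.1, 9)  # 0.5
odds_adjust <- function(background_p, target_ror) {
  if (any(background_p <= 0 | background_p >= 1)) {
    stop("background_p must lie strictly inside (0, 1)")
  }
  if (any(target_ror <= 0)) stop("target_ror must be positive")
  o <- background_p / (1 - background_p)
  (target_ror * o) / (1 + target_ror * o)
}

#' Define an injectable drug-event signal
#'
#' @param ingredient normalized active-ingredient name of the exposed group.
#' @param pt reaction preferred term.
#' @param ror target population ROR against all other drugs.
#' @param ror_female,ror_male optional sex-specific target RORs (override
#'   `ror` for cases of that sex; `NA` = no override).
#' @param ror_older,ror_younger optional age-specific target RORs (override
#'   `ror` for cases above / at-or-below the generator's `age_split`).
#' @return a one-row `data.frame` suitable for the `signals` field of
#'   [synth_config()].
#' @export
make_signal <- function(ingredient, pt, ror, ror_female = NA_real_,
                        ror_male = NA_real_, ror_older = NA_real_,
                        ror_younger = NA_real_) {
  data.frame(ingredient = normalize_ingredient(ingredient), pt = pt,
             ror = ror, ror_female = ror_female, ror_male = ror_male,
             ror_older = ror_older, ror_younger = ror_younger,
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic FAERS generator
#'
#' Defaults emulate a plausible spontaneous-reporting cohort: a majority of
#' reports from health care professionals with a consumer fraction to
#' exercise the reporter filter, a catch-all background reaction term so that
#' (as in real spontaneous reports) nearly every case lists at least one
#' reaction, a 55/42/3 female/male/unknown sex mix, ages
#' drawn from N(55, 18^2) truncated to \[0, 100\] and encoded in a mixture of
#' FAERS age units (mostly years, with decades and infant units represented),
#' a 5% superseded-version rate, and modest per-field missingness.
#'
#' @param n_cases number of distinct cases.
#' @param ingredients named numeric vector: exposure probability of each
#'   active ingredient (one primary suspect drawn per case; normalized to
#'   sum to 1).
#' @param pts named numeric vector: background (comparator) report
#'   probability of each reaction PT, strictly inside (0, 1).
#' @param signals `data.frame` of injected associations, rows from
#'   [make_signal()]; `NULL` for a null cohort.
#' @param sex_mix named probabilities for `female`, `male`, `unknown`.
#' @param age list with `mean`, `sd`, `min`, `max` (years) and `unit_mix`, a
#'   named probability vector over the age-unit codes DEC/YR/MON/WK/DY/HR.
#' @param occupation_mix named probabilities over reporter occupation codes
#'   (`missing` = empty field); includes non-professional codes.
#' @param duplicate_version_rate probability a case also gets a superseded
#'   earlier version (same caseid, lower caseversion, perturbed primaryid,
#'   one degraded demographic field).
#' @param missing named per-field missingness probabilities: `age`, `sex`,
#'   `prod_ai`, `pt` (the last applies per reaction row).
#' @param age_split years; boundary used by age-specific signal overrides
#'   (boundary age counts as younger).
#' @param quarter FAERS quarter label for the emitted files, e.g. `"2023Q1"`.
#' @param concomitant_rate probability a case's report also lists one
#'   concomitant (role C) drug row, which the primary-suspect extraction
#'   must ignore.
#' @param seed integer seed; same config and seed give byte-identical files.
#' @return a `synth_config` object.
#' @export
synth_config <- function(n_cases = 10000L,
                         ingredients = c(DRUG_A = 0.06, DRUG_B = 0.06,
                                         DRUG_C = 0.08, DRUG_D = 0.10,
                                         DRUG_E = 0.70),
                         pts = c(PT_HEADACHE = 0.08, PT_NAUSEA = 0.06,
                                 PT_DYSGEUSIA = 0.04, PT_RASH = 0.03,
                                 PT_RETINOPATHY = 0.02, PT_DIARRHOEA = 0.05,
                                 PT_FATIGUE = 0.05, PT_DIZZINESS = 0.04,
                                 PT_OTHER_REACTION = 0.90),
                         signals = NULL,
                         sex_mix = c(female = 0.55, male = 0.42,
                                     unknown = 0.03),
                         age = list(mean = 55, sd = 18, min = 0, max = 100,
                                    unit_mix = c(YR = 0.85, DEC = 0.05,
                                                 MON = 0.04, WK = 0.02,
                                                 DY = 0.03, HR = 0.01)),
                         occupation_mix = c(MD = 0.40, PH = 0.15, OT = 0.12,
                                            HP = 0.08, CN = 0.20,
                                            missing = 0.05),
                         duplicate_version_rate = 0.05,
                         missing = c(age = 0.08, sex = 0.03,
                                     prod_ai = 0.01, pt = 0.01),
                         age_split = 50,
                         quarter = "2023Q1",
                         concomitant_rate = 0.3,
                         seed = 1L) {
  stopifnot(n_cases >= 0,
            all(ingredients > 0), length(ingredients) >= 1L,
            all(pts > 0 & pts < 1), length(pts) >= 1L,
            all(sex_mix >= 0), abs(sum(sex_mix) - 1) < 1e-8,
            all(occupation_mix >= 0),
            duplicate_version_rate >= 0, duplicate_version_rate <= 1,
            all(missing >= 0 & missing <= 1),
            grepl("^\\d{4}Q[1-4]$", quarter))
  if (!is.null(signals)) {
    signals <- data.table::as.data.table(signals)
    stopifnot(all(c("ingredient", "pt", "ror") %in% names(signals)),
              all(signals$ror > 0, na.rm = TRUE),
              all(signals$ingredient %in% normalize_ingredient(
                names(ingredients))),
              all(signals$pt %in% names(pts)))
    for (col in c("ror_female", "ror_male", "ror_older", "ror_younger")) {
      if (!col %in% names(signals)) signals[, (col) := NA_real_]
    }
  }
  structure(list(n_cases = as.integer(n_cases),
                 ingredients = ingredients / sum(ingredients),
                 pts = pts, signals = signals, sex_mix = sex_mix,
                 age = age, occupation_mix = occupation_mix,
                 duplicate_version_rate = duplicate_version_rate,
                 missing = missing, age_split = age_split,
                 quarter = quarter, concomitant_rate = concomitant_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.years_to_unit <- function(years, unit) {
  per_year <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                DY = 1 / 365.25, HR = 1 / 8766)
  round(years / per_year[unit], 2)
}

#' Generate a synthetic cohort in memory
#'
#' Draws every case's true fields, applies missingness and superseded
#' versions, and returns the three raw record tables plus the ground-truth
#' manifest. [generate_quarter()] writes the same objects to disk.
#'
#' Per case: one primary-suspect ingredient is drawn from the exposure
#' distribution, then each PT independently with its background probability,
#' odds-adjusted via [odds_adjust()] when an injected signal matches the
#' case's ingredient (sex-/age-specific overrides applied from the case's
#' true demographics). Superseded versions duplicate the final record under
#' the same caseid with a lower caseversion, a perturbed primaryid, and one
#' degraded demographic field (age or sex), so deduplication correctness is
#' observable.
#'
#' @param config a [synth_config()].
#' @return list with elements `demo`, `drug`, `reac` (raw record
#'   `data.table`s in the [parse_faers_file()] layout) and `manifest`, a
#'   `data.table` with one row per case: true and observable fields plus the
#'   derived flags `professional`, `essentials_ok` and `survives` that
#'   predict exactly which cases pass the preprocessing filters.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_cases
  pt_names <- names(config$pts)
  J <- length(pt_names)

  # caseid block derived from the quarter so ids never collide when several
  # generated quarters are pooled (as FAERS caseids never do)
  yy <- as.integer(substr(config$quarter, 1, 4)) - 2000L
  qq <- as.integer(substr(config$quarter, 6, 6))
  caseid <- as.character((4L * yy + qq) * 1e7 + seq_len(n))
  ingredient <- if (n > 0) {
    sample(normalize_ingredient(names(config$ingredients)), n,
           replace = TRUE, prob = config$ingredients)
  } else character(0)
  sex_true <- sample(names(config$sex_mix), n, replace = TRUE,
                     prob = config$sex_mix)
  age_true <- pmin(pmax(stats::rnorm(n, config$age$mean, config$age$sd),
                        config$age$min), config$age$max)
  age_unit <- sample(names(config$age$unit_mix), n, replace = TRUE,
                     prob = config$age$unit_mix)
  age_value <- .years_to_unit(age_true, age_unit)
  # the observable truth: what the emitted value decodes back to
  age_obs <- normalize_age(age_value, age_unit)
  occ_names <- names(config$occupation_mix)
  occp <- sample(occ_names, n, replace = TRUE, prob = config$occupation_mix)
  occp[occp == "missing"] <- NA_character_

  # per-case event probabilities, odds-adjusted for injected signals
  P <- matrix(rep(config$pts, each = max(n, 1L)), nrow = max(n, 1L), ncol = J,
              dimnames = list(NULL, pt_names))
  if (n > 0 && !is.null(config$signals)) {
    older <- age_obs > config$age_split
    for (i in seq_len(nrow(config$signals))) {
      sg <- config$signals[i]
      hit <- ingredient == sg$ingredient
      if (!any(hit)) next
      eff <- rep(sg$ror, n)
      if (!is.na(sg$ror_female)) eff[sex_true == "female"] <- sg$ror_female
      if (!is.na(sg$ror_male)) eff[sex_true == "male"] <- sg$ror_male
      if (!is.na(sg$ror_older)) eff[!is.na(older) & older] <- sg$ror_older
      if (!is.na(sg$ror_younger)) eff[!is.na(older) & !older] <- sg$ror_younger
      j <- match(sg$pt, pt_names)
      P[hit, j] <- odds_adjust(config$pts[[j]], eff[hit])
    }
  }
  events <- if (n > 0) matrix(stats::runif(n * J), n, J) < P else
    matrix(logical(0), 0, J)

  # missingness draws
  miss_age <- stats::runif(n) < config$missing[["age"]]
  miss_sex <- stats::runif(n) < config$missing[["sex"]]
  miss_ai <- stats::runif(n) < config$missing[["prod_ai"]]

  # superseded versions
  dup <- stats::runif(n) < config$duplicate_version_rate
  degrade_age <- stats::runif(n) < 0.5  # which field the old version loses
  version <- data.table::fifelse(dup, 2L, 1L)
  primaryid <- paste0(caseid, version)

  sex_code <- c(female = "F", male = "M", unknown = "UNK")[sex_true]
  sex_emit <- data.table::fifelse(miss_sex, NA_character_, sex_code)
  age_emit <- data.table::fifelse(miss_age, NA_real_, age_value)
  age_cod_emit <- data.table::fifelse(miss_age, NA_character_, age_unit)

  demo <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, caseversion = version,
    age = age_emit, age_cod = age_cod_emit, sex = sex_emit,
    occp_cod = occp, quarter = config$quarter)

  if (any(dup)) {
    old <- demo[dup]
    old[, caseversion := 1L]
    old[, primaryid := paste0(caseid, caseversion)]
    deg_age <- degrade_age[dup]
    old[deg_age, `:=`(age = NA_real_, age_cod = NA_character_)]
    old[!deg_age, sex := NA_character_]
    demo <- rbind(demo, old)
    data.table::setorder(demo, caseid, caseversion)
  }

  prod_ai_emit <- data.table::fifelse(miss_ai, NA_character_, ingredient)

  # per-(case, PT) missingness for reaction rows, and the "|"-joined PT
  # strings for the manifest, built by concatenating the PT columns in
  # alphabetical order (so the joined strings come out sorted)
  miss_mat <- if (n > 0) {
    matrix(stats::runif(n * J), n, J) < config$missing[["pt"]]
  } else matrix(logical(0), 0, J)
  events_obs <- events & !miss_mat
  pts_true <- rep("", n)
  pts_obs <- rep("", n)
  for (j in order(pt_names)) {
    nm <- pt_names[j]
    e <- events[, j]
    pts_true[e] <- data.table::fifelse(pts_true[e] == "", nm,
                                       paste0(pts_true[e], "|", nm))
    o <- events_obs[, j]
    pts_obs[o] <- data.table::fifelse(pts_obs[o] == "", nm,
                                      paste0(pts_obs[o], "|", nm))
  }

  # reaction rows per case (each version of a case repeats drug/reac rows)
  ev_idx <- which(events, arr.ind = TRUE)
  reac_case <- data.table::data.table(
    case_row = if (length(ev_idx)) ev_idx[, 1L] else integer(0),
    pt = pt_names[if (length(ev_idx)) ev_idx[, 2L] else integer(0)],
    pt_emit = if (length(ev_idx)) {
      data.table::fifelse(miss_mat[ev_idx], NA_character_,
                          pt_names[ev_idx[, 2L]])
    } else character(0))
  data.table::setorder(reac_case, case_row, pt)

  conc <- stats::runif(n) < config$concomitant_rate
  conc_ing <- if (n > 0) sample(normalize_ingredient(
    names(config$ingredients)), n, replace = TRUE) else character(0)

  old_pid <- if (any(dup)) paste0(caseid[dup], 1L) else character(0)
  versions <- data.table::data.table(
    case_row = c(seq_len(n), which(dup)),
    primaryid = c(primaryid, old_pid))
  data.table::setorder(versions, case_row, primaryid)

  ps_rows <- data.table::data.table(
    case_row = versions$case_row, primaryid = versions$primaryid,
    drug_seq = 1L, role_cod = "PS",
    prod_ai = prod_ai_emit[versions$case_row],
    drugname = prod_ai_emit[versions$case_row])
  with_conc <- versions[conc[versions$case_row]]
  conc_rows <- data.table::data.table(
    case_row = with_conc$case_row, primaryid = with_conc$primaryid,
    drug_seq = 2L, role_cod = "C",
    prod_ai = conc_ing[with_conc$case_row],
    drugname = conc_ing[with_conc$case_row])
  drug <- rbind(ps_rows, conc_rows)
  data.table::setorder(drug, case_row, primaryid, drug_seq)
  drug[, case_row := NULL]

  reac <- versions[reac_case, on = "case_row", allow.cartesian = TRUE][
    !is.na(primaryid), .(primaryid, pt = pt_emit)]
  data.table::setorder(reac, primaryid, pt, na.last = TRUE)

  data.table::setattr(demo, "kind", "demo")
  data.table::setattr(drug, "kind", "drug")
  data.table::setattr(reac, "kind", "reac")

  professional <- !is.na(occp) & occp %in% .professional_codes
  essentials_ok <- !miss_ai & pts_obs != ""
  manifest <- data.table::data.table(
    caseid = caseid, primaryid = primaryid, caseversion = version,
    has_duplicate = dup, occp_cod = occp,
    sex_true = sex_true,
    sex_obs = data.table::fifelse(miss_sex, "unknown", sex_true),
    age_true_years = age_true,
    age_obs_years = data.table::fifelse(miss_age, NA_real_,
                                        as.numeric(age_obs)),
    ingredient = ingredient, prod_ai_missing = miss_ai,
    pts_true = pts_true, pts_obs = pts_obs,
    professional = professional, essentials_ok = essentials_ok,
    survives = professional & essentials_ok)

  list(demo = demo[], drug = drug[], reac = reac[], manifest = manifest)
}

#' Generate a synthetic FAERS quarter on disk
#'
#' Writes the DEMO/DRUG/REAC file trio in the FAERS ASCII dialect (named
#' `DEMOyyQq.txt` etc. after the config's quarter), the ground-truth manifest
#' (`manifest.tsv`), and the config (`config.yaml`) into `out_dir`. Output is
#' byte-identical for identical config and seed.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `paths` (named: demo, drug, reac, manifest,
#'   config) and the `manifest` table.
#' @export
generate_quarter <- function(config, out_dir) {
  cohort <- generate_cohort(config)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  yy <- substr(config$quarter, 3, 4)
  qq <- substr(config$quarter, 5, 6)
  stem <- paste0(yy, qq)
  paths <- c(demo = file.path(out_dir, paste0("DEMO", stem, ".txt")),
             drug = file.path(out_dir, paste0("DRUG", stem, ".txt")),
             reac = file.path(out_dir, paste0("REAC", stem, ".txt")),
             manifest = file.path(out_dir, "manifest.tsv"),
             config = file.path(out_dir, "config.yaml"))
  write_faers_file(cohort$demo, paths[["demo"]], "demo")
  write_faers_file(cohort$drug, paths[["drug"]], "drug")
  write_faers_file(cohort$reac, paths[["reac"]], "reac")
  data.table::fwrite(cohort$manifest, paths[["manifest"]], sep = "\t",
                     na = "", quote = FALSE)
  write_synth_config(config, paths[["config"]])
  invisible(list(paths = paths, manifest = cohort$manifest))
}

#' Write a generator config as YAML
#' @param config a [synth_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synth_config <- function(config, path) {
  x <- unclass(config)
  # named atomic vectors must become maps, or yaml drops the names
  for (f in c("ingredients", "pts", "sex_mix", "occupation_mix", "missing")) {
    x[[f]] <- as.list(x[[f]])
  }
  x$age$unit_mix <- as.list(x$age$unit_mix)
  if (!is.null(x$signals)) {
    s <- as.data.frame(x$signals)
    x$signals <- lapply(seq_len(nrow(s)), function(i) as.list(s[i, ]))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a generator config written by [write_synth_config()]
#' @param path path to the YAML file.
#' @return a [synth_config()].
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  for (f in c("ingredients", "pts", "sex_mix", "occupation_mix", "missing")) {
    x[[f]] <- unlist(x[[f]])
  }
  x$age$unit_mix <- unlist(x$age$unit_mix)
  if (!is.null(x$signals)) {
    x$signals <- data.table::rbindlist(
      lapply(x$signals, function(row) {
        row[vapply(row, is.null, logical(1))] <- NA_real_
        row
      }), fill = TRUE)
  }
  do.call(synth_config, x)
}
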