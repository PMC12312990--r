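test_that("only the four professional occupation codes are retained", {
  demo <- raw_demo(as.character(1:6), as.character(1:6),
                   occp_cod = c("MD", "CN", NA, "ph", "LW", "OT"))
  kept <- filter_professional(demo)
  expect_equal(kept$primaryid, c("1", "4", "6"))  # case-insensitive match
  expect_equal(attr(kept, "dropped_nonprofessional"), 3L)
  expect_equal(nrow(filter_professional(demo[0])), 0L)
})

test_that("professional filter count matches an exhaustive count", {
  set.seed(401)
  occ <- sample(c("MD", "PH", "OT", "HP", "CN"), 1000, replace = TRUE)
  demo <- raw_demo(as.character(1:1000), as.character(1:1000),
                   occp_cod = occ)
  kept <- filter_professional(demo)
  expect_equal(nrow(kept), sum(occ != "CN"))
  expect_equal(attr(kept, "dropped_nonprofessional"), sum(occ == "CN"))
})

test_that("deduplication keeps the maximal case version", {
  demo <- raw_demo(c("1001", "1002"), c("100", "100"), caseversion = c(1, 2))
  out <- deduplicate_cases(demo)
  expect_equal(out$primaryid, "1002")
  expect_equal(attr(out, "dropped_duplicate"), 1L)

  one <- deduplicate_cases(raw_demo("1", "1"))
  expect_equal(nrow(one), 1L)

  # version tie broken by zero-padded primaryid ("99" pads below "100")
  tie <- raw_demo(c("99", "100"), c("7", "7"), caseversion = c(2, 2))
  expect_equal(deduplicate_cases(tie)$primaryid, "100")

  # missing version is superseded by any explicit version
  mv <- raw_demo(c("5000", "4999"), c("8", "8"), caseversion = c(NA, 1))
  expect_equal(deduplicate_cases(mv)$primaryid, "4999")
})

test_that("deduplication matches a brute-force scan on random versions", {
  set.seed(402)
  rows <- do.call(rbind, lapply(1:50, function(cid) {
    k <- sample(1:4, 1)
    vers <- sample(1:9, k)
    raw_demo(primaryid = as.character(sample(1e5, k)),
             caseid = as.character(cid), caseversion = vers)
  }))
  data.table::setattr(rows, "kind", "demo")
  out <- deduplicate_cases(rows)
  expect_equal(nrow(out), 50L)
  # oracle: per caseid, scan all rows for the max (version, padded id)
  wid <- max(nchar(rows$primaryid))
  for (cid in unique(rows$caseid)) {
    sub <- rows[rows$caseid == cid]
    key <- paste0(sprintf("%09d", sub$caseversion),
                  gsub(" ", "0", formatC(sub$primaryid, width = wid)))
    expect_equal(out[out$caseid == cid]$primaryid,
                 sub$primaryid[order(key, decreasing = TRUE)[1]])
  }
})

test_that("ages convert to years by unit code with bounds checking", {
  expect_equal(normalize_age(30, "YR"), 30, ignore_attr = TRUE)
  expect_equal(normalize_age(24, "MON"), 2, ignore_attr = TRUE)
  expect_equal(normalize_age(1, "DEC"), 10, ignore_attr = TRUE)
  expect_equal(normalize_age(730.5, "DY"), 2, ignore_attr = TRUE)
  expect_equal(normalize_age(52.1775, "WK"), 1, ignore_attr = TRUE)
  expect_equal(normalize_age(8766, "HR"), 1, ignore_attr = TRUE)
  expect_equal(normalize_age(45, NA), 45, ignore_attr = TRUE)  # default YR

  out <- normalize_age(c(30, 5, 121, -1), c("YR", "CENTURY", "YR", "YR"))
  expect_equal(as.numeric(out), c(30, NA, NA, NA))
  expect_equal(attr(out, "n_unrecognized_unit"), 1L)
  expect_equal(attr(out, "n_out_of_range"), 2L)
})

test_that("primary-suspect extraction normalizes ingredients and roles", {
  drug <- raw_drug(c("1", "1", "2", "3", "4"),
                   role_cod = c("PS", "C", "SS", "ps", "PS"),
                   prod_ai = c(" hydroxychloroquine   sulfate ", "IGNORED",
                               "ONLY SECONDARY", "NIRMATRELVIR\\RITONAVIR",
                               ""))
  map <- extract_primary_suspect(drug)
  expect_equal(map$ingredient[map$primaryid == "1"],
               "HYDROXYCHLOROQUINE SULFATE")
  expect_false("2" %in% map$primaryid)  # SS-only report contributes nothing
  expect_equal(map$ingredient[map$primaryid == "3"],
               "NIRMATRELVIR/RITONAVIR")
  expect_equal(attr(map, "dropped_empty_ingredient"), 1L)

  two <- extract_primary_suspect(
    raw_drug(c("9", "9"), role_cod = "PS", prod_ai = c("A", "B")))
  expect_equal(sort(two$ingredient), c("A", "B"))
})

test_that("the six-case fixture assembles to the hand-built table", {
  cases <- six_case_table()
  expect_s3_class(cases, "clean_case_table")
  expect_equal(nrow(cases), 6L)
  expect_equal(cases[cases$caseid == "3"]$pts[[1]], c("X", "Y"))
  expect_equal(cases[cases$caseid == "4"]$ps_ingredients[[1]], "B")
  expect_equal(cases$sex, rep(c("female", "male"), 3))
  expect_equal(cases$age_years, c(30, 60, 45, 70, 25, 50))
})

test_that("cases without reactions or suspects are excluded and counted", {
  f <- six_case_raw()
  extra <- raw_demo(c("900", "901"), c("90", "91"), sex = "F")
  demo <- rbind(f$demo, extra)
  drug <- rbind(f$drug, raw_drug("900", prod_ai = "A"))  # 900: no reac rows
  # 901: reac but no PS drug row
  reac <- rbind(f$reac, raw_reac("901", "X"))
  cases <- preprocess_faers(demo, drug, reac)
  expect_equal(nrow(cases), 6L)
  expect_equal(provenance(cases)$dropped_missing_essential, 2L)
})

test_that("multi-suspect cases obey the single_ps_only switch", {
  f <- six_case_raw()
  drug <- rbind(f$drug, raw_drug("101", prod_ai = "Z", drug_seq = 2L))
  with_filter <- preprocess_faers(f$demo, drug, f$reac)
  expect_equal(nrow(with_filter), 5L)
  expect_equal(provenance(with_filter)$dropped_multi_ps, 1L)
  without <- preprocess_faers(f$demo, drug, f$reac, single_ps_only = FALSE)
  expect_equal(nrow(without), 6L)
  expect_equal(without[without$caseid == "1"]$ps_ingredients[[1]],
               c("A", "Z"))
})

test_that("every raw demo row lands in exactly one provenance bucket", {
  cfg <- synth_config(n_cases = 2000, seed = 31)
  co <- generate_cohort(cfg)
  cases <- preprocess_faers(co$demo, co$drug, co$reac)
  p <- provenance(cases)
  expect_equal(p$n_raw_demo, nrow(co$demo))
  expect_equal(p$n_cases + p$dropped_nonprofessional + p$dropped_duplicate +
                 p$dropped_missing_essential + p$dropped_multi_ps,
               p$n_raw_demo)
})

test_that("preprocessing an already-clean cohort changes nothing", {
  cases <- six_case_table()
  # re-emit the clean table as raw records and run the full flow again
  demo <- raw_demo(cases$primaryid, cases$caseid,
                   age = cases$age_years, age_cod = "YR",
                   sex = data.table::fcase(cases$sex == "female", "F",
                                           cases$sex == "male", "M",
                                           default = NA_character_),
                   occp_cod = cases$reporter)
  drug <- raw_drug(rep(cases$primaryid, lengths(cases$ps_ingredients)),
                   prod_ai = unlist(cases$ps_ingredients))
  reac <- raw_reac(rep(cases$primaryid, lengths(cases$pts)),
                   pt = unlist(cases$pts))
  again <- preprocess_faers(demo, drug, reac)
  expect_equal(as.data.frame(again), as.data.frame(cases),
               ignore_attr = TRUE)
  p <- provenance(again)
  expect_equal(p$dropped_nonprofessional + p$dropped_duplicate +
                 p$dropped_missing_essential + p$dropped_multi_ps, 0L)
})

test_that("the clean case table is invariant to input record order", {
  f <- six_case_raw()
  set.seed(403)
  shuffled <- preprocess_faers(f$demo[sample(.N)], f$drug[sample(.N)],
                               f$reac[sample(.N)])
  orig <- six_case_table()
  data.table::setkey(shuffled, caseid)
  data.table::setkey(orig, caseid)
  expect_equal(as.data.frame(shuffled), as.data.frame(orig),
               ignore_attr = TRUE)
})

test_that("clean case tables round-trip through the TSV serialization", {
  cases <- six_case_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_case_table(cases, f)
  back <- read_case_table(f)
  expect_equal(as.data.frame(back), as.data.frame(cases),
               ignore_attr = TRUE)
})
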