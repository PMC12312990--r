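test_that("top reactions rank by case count with alphabetical ties", {
  cases <- skewed_cohort()
  top2 <- top_reactions(cases, drug_group("A", "A"), k = 2)
  expect_equal(top2$pt, c("X", "Y"))
  expect_equal(top2$n, c(3L, 2L))

  # k beyond the vocabulary returns everything
  all_pts <- top_reactions(cases, drug_group("A", "A"), k = 99)
  expect_equal(all_pts$pt, c("X", "Y", "Z"))

  # ties broken alphabetically: in the six-case fixture X and Y tie at 2
  tied <- top_reactions(six_case_table(), drug_group("A", "A"))
  expect_equal(tied$pt, c("X", "Y"))
  expect_equal(tied$n, c(2L, 2L))

  expect_error(top_reactions(cases, drug_group("zzz", "ZZZ")),
               "empty cohort")
})

test_that("most_potential_reactions reproduces the six-case tables", {
  cases <- six_case_table()
  rep_a <- most_potential_reactions(cases, drug_group("A", "A"))
  res <- rep_a$results
  expect_equal(res$pt, c("X", "Y"))
  expect_equal(unlist(res[res$pt == "X", .(a, b, c, d)]), c(2, 1, 1, 2),
               ignore_attr = TRUE)
  expect_equal(unlist(res[res$pt == "Y", .(a, b, c, d)]), c(2, 1, 2, 1),
               ignore_attr = TRUE)
  expect_equal(res$ror, c((2 / 1) / (1 / 2), (2 / 1) / (2 / 1)))
  # frequency table covers all PTs of the exposed cases
  expect_equal(sum(rep_a$freq$n), 4L)

  # degenerate comparator: every case exposed, all rows not estimable
  rep_all <- most_potential_reactions(cases, drug_group("all", c("A", "B")))
  expect_true(all(!rep_all$results$estimable))
  expect_true(all(grepl("not estimable", rep_all$results$note)))
})

test_that("an injected signal surfaces as a significant top reaction", {
  cfg <- synth_config(n_cases = 20000,
                      signals = make_signal("DRUG_A", "PT_RETINOPATHY", 5),
                      seed = 405)
  co <- generate_cohort(cfg)
  cases <- preprocess_faers(co$demo, co$drug, co$reac)
  rep_a <- most_potential_reactions(cases, drug_group("A", "DRUG_A"))
  row <- rep_a$results[pt == "PT_RETINOPATHY"]
  expect_equal(nrow(row), 1L)
  expect_true(row$significant)
  # and no other PT carries an injected signal
  expect_false(any(rep_a$results[pt != "PT_RETINOPATHY"]$significant))
})

test_that("reaction comparison against OTHER DRUGS matches the fixture", {
  cases <- six_case_table()
  rc <- reaction_comparison(cases, drug_group("A", "A"), pts = "X")
  expect_equal(unlist(rc$results[, .(a, b, c, d)]), c(2, 1, 1, 2),
               ignore_attr = TRUE)
  expect_equal(rc$results$ror, 4)

  # requested-but-unreported PTs come back as not-estimable rows
  rc2 <- reaction_comparison(cases, drug_group("A", "A"),
                             pts = c("X", "NOT A TERM"))
  expect_equal(nrow(rc2$results), 2L)
  expect_false(rc2$results[pt == "NOT A TERM"]$estimable)
  expect_true(rc2$results[pt == "X"]$estimable)
})

test_that("explicit control groups restrict the cohort and stay reciprocal", {
  cases <- six_case_table()
  fwd <- reaction_comparison(cases, drug_group("A", "A"),
                             drug_group("B", "B"), pts = c("X", "Y"))
  rev <- reaction_comparison(cases, drug_group("B", "B"),
                             drug_group("A", "A"), pts = c("X", "Y"))
  expect_equal(fwd$results$ror * rev$results$ror, c(1, 1))
  expect_equal(fwd$excluded$dual_exposure, 0L)

  # a case exposed to both groups is excluded and counted
  f <- six_case_raw()
  drug <- rbind(f$drug, raw_drug("101", prod_ai = "B", drug_seq = 2L))
  both <- preprocess_faers(f$demo, drug, f$reac, single_ps_only = FALSE)
  rc <- reaction_comparison(both, drug_group("A", "A"),
                            drug_group("B", "B"), pts = "X")
  expect_equal(rc$excluded$dual_exposure, 1L)
  expect_equal(rc$cohort$n_target + rc$cohort$n_control, 5L)
})

test_that("the age boundary case lands in the younger stratum", {
  cases <- six_case_table()  # case 6 is aged exactly 50
  rc <- reaction_comparison(cases, drug_group("A", "A"), pts = "X",
                            sub = subgroup_spec("age", age_split = 50))
  young <- rc$results[stratum == "age<=50"]
  old <- rc$results[stratum == "age>50"]
  # younger stratum: cases 1, 3, 5, 6 -> (a, b, c, d) = (2, 0, 0, 2)
  expect_equal(unlist(young[, .(a, b, c, d)]), c(2, 0, 0, 2),
               ignore_attr = TRUE)
  # older stratum: case 2 (A, no X) and case 4 (B, has X)
  expect_equal(unlist(old[, .(a, b, c, d)]), c(0, 1, 1, 0),
               ignore_attr = TRUE)
})

test_that("sex-specific injected RORs are detected by the subgroup z test", {
  cfg <- synth_config(
    n_cases = 40000,
    signals = make_signal("DRUG_A", "PT_RETINOPATHY", ror = 1,
                          ror_female = 5, ror_male = 1),
    seed = 406)
  co <- generate_cohort(cfg)
  cases <- preprocess_faers(co$demo, co$drug, co$reac)
  rc <- reaction_comparison(cases, drug_group("A", "DRUG_A"),
                            pts = "PT_RETINOPATHY",
                            sub = subgroup_spec("sex"))
  cmp <- rc$comparisons
  expect_true(cmp$flagged)
  expect_gt(cmp$ror_1, cmp$ror_2)  # female stratum is listed first
  expect_lt(cmp$p, 0.05)
  expect_gte(cmp$fold, 1.5)
})

test_that("stratum cells sum to the unknown-excluded overall cells", {
  cfg <- synth_config(n_cases = 5000, seed = 407)
  co <- generate_cohort(cfg)
  cases <- preprocess_faers(co$demo, co$drug, co$reac)
  for (mode in c("sex", "age")) {
    rc <- reaction_comparison(cases, drug_group("A", "DRUG_A"),
                              pts = "PT_HEADACHE", sub = subgroup_spec(mode))
    known <- if (mode == "sex") function(x) x$sex != "unknown"
             else function(x) !is.na(x$age_years)
    overall <- count_contingency(cases, "DRUG_A", "PT_HEADACHE",
                                 cohort_filter = known)
    sums <- rc$results[, lapply(.SD, sum), .SDcols = c("a", "b", "c", "d")]
    expect_equal(unlist(sums),
                 c(a = overall$a, b = overall$b, c = overall$c,
                   d = overall$d))
  }
})

test_that("a stratum without exposed cases is reported not-estimable", {
  ids <- as.character(301:304)
  cases <- preprocess_faers(
    raw_demo(ids, caseid = ids, sex = c("F", "F", "F", "M")),
    raw_drug(ids, prod_ai = c("A", "A", "B", "B")),
    raw_reac(rep(ids, each = 1), pt = c("X", "Y", "X", "X")))
  rc <- reaction_comparison(cases, drug_group("A", "A"), pts = "X",
                            sub = subgroup_spec("sex"))
  expect_false(rc$comparisons$estimable)
  expect_match(rc$comparisons$note, "not estimable")
  # the female stratum itself is still computed
  expect_true(rc$results[stratum == "female"]$estimable)
})

test_that("the two analysis modes agree on shared PTs", {
  cases <- six_case_table()
  mp <- most_potential_reactions(cases, drug_group("A", "A"))
  rc <- reaction_comparison(cases, drug_group("A", "A"),
                            pts = mp$results$pt)
  expect_equal(rc$results$ror, mp$results$ror)
  expect_equal(rc$results$ci_low, mp$results$ci_low)
  expect_equal(rc$results$ci_high, mp$results$ci_high)
})
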