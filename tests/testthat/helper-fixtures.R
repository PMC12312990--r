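# Fixtures built in code: a hand-checkable six-case cohort and small raw
# record tables in the parse_faers_file() layout.

raw_demo <- function(primaryid, caseid, caseversion = 1L, age = NA_real_,
                     age_cod = NA_character_, sex = NA_character_,
                     occp_cod = "MD", quarter = "2020Q3") {
  dt <- data.table::data.table(
    primaryid = as.character(primaryid), caseid = as.character(caseid),
    caseversion = as.integer(caseversion), age = as.numeric(age),
    age_cod = age_cod, sex = sex, occp_cod = occp_cod, quarter = quarter)
  data.table::setattr(dt, "kind", "demo")
  dt
}

raw_drug <- function(primaryid, role_cod = "PS", prod_ai = "DRUG_A",
                     drug_seq = 1L, drugname = prod_ai) {
  dt <- data.table::data.table(
    primaryid = as.character(primaryid), drug_seq = as.integer(drug_seq),
    role_cod = role_cod, prod_ai = prod_ai, drugname = drugname)
  data.table::setattr(dt, "kind", "drug")
  dt
}

raw_reac <- function(primaryid, pt) {
  dt <- data.table::data.table(primaryid = as.character(primaryid), pt = pt)
  data.table::setattr(dt, "kind", "reac")
  dt
}

# six cases: 1 A/{X}, 2 A/{Y}, 3 A/{X,Y}, 4 B/{X}, 5 B/{Y}, 6 B/{Y}
# drug group {A} vs pt X gives the 2x2 table (a, b, c, d) = (2, 1, 1, 2)
six_case_raw <- function() {
  ids <- as.character(101:106)
  list(
    demo = raw_demo(ids, caseid = as.character(1:6),
                    age = c(30, 60, 45, 70, 25, 50),
                    age_cod = "YR",
                    sex = c("F", "M", "F", "M", "F", "M")),
    drug = raw_drug(ids, prod_ai = c("A", "A", "A", "B", "B", "B")),
    reac = raw_reac(rep(ids, times = c(1, 1, 2, 1, 1, 1)),
                    pt = c("X", "Y", "X", "Y", "X", "Y", "Y"))
  )
}

six_case_table <- function() {
  f <- six_case_raw()
  preprocess_faers(f$demo, f$drug, f$reac)
}

# a 3-case drug-A cohort whose reaction counts are X:3, Y:2, Z:1, plus one
# unexposed case so comparisons stay estimable
skewed_cohort <- function() {
  ids <- as.character(201:204)
  preprocess_faers(
    raw_demo(ids, caseid = as.character(1:4), sex = c("F", "M", "F", "M")),
    raw_drug(ids, prod_ai = c("A", "A", "A", "B")),
    raw_reac(rep(ids, times = c(3, 2, 1, 1)),
             pt = c("X", "Y", "Z", "X", "Y", "X", "W")))
}

# random raw record tables for round-trip property tests
random_records <- function(kind, n, seed = 1) {
  set.seed(seed)
  maybe <- function(x, p = 0.2) {
    x[stats::runif(length(x)) < p] <- NA
    x
  }
  id <- as.character(sample(1e6:2e6, n))
  switch(kind,
    demo = raw_demo(id, caseid = as.character(sample(1e5:2e5, n)),
                    caseversion = sample(1:4, n, replace = TRUE),
                    age = maybe(round(stats::runif(n, 0, 90), 2)),
                    age_cod = maybe(sample(c("YR", "DEC", "MON", "WK", "DY",
                                             "HR"), n, replace = TRUE)),
                    sex = maybe(sample(c("F", "M", "UNK"), n, replace = TRUE)),
                    occp_cod = maybe(sample(c("MD", "PH", "OT", "HP", "CN"),
                                            n, replace = TRUE))),
    drug = raw_drug(id, role_cod = sample(c("PS", "SS", "C", "I"), n, TRUE),
                    prod_ai = maybe(sample(c("DRUG A", "DRUG B",
                                             "NIRMATRELVIR/RITONAVIR"),
                                           n, replace = TRUE)),
                    drug_seq = sample(1:5, n, replace = TRUE)),
    reac = raw_reac(id, pt = maybe(sample(c("Dysgeusia", "Headache",
                                            "Retinopathy", "QT prolonged"),
                                          n, replace = TRUE))))
}
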