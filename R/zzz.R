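#' @importFrom data.table data.table as.data.table := .N .SD fifelse fcase
#' @importFrom stats pnorm rnorm runif setNames na.omit
#' @importFrom utils head
NULL

# make data.table's [ NSE work inside this namespace
.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", ".version_key", ".id_key", "primaryid", "caseid", "caseversion",
  "quarter", "ingredient", "pt", "pts", "ps_ingredients", "age", "age_cod",
  "sex", "occp_cod", "drug_seq", "role_cod", "prod_ai", "drugname",
  "ror", "ln_ror", "se_ln", "ci_low", "ci_high", "corrected", "significant",
  "estimable", "note", "stratum", "n", "case_row", "pt_emit", "label",
  "signal", "log2_ror", "log2_ci_low", "log2_ci_high", "lab", "s",
  "V1"
))
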