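# Simulation drivers for the calibration / recovery properties.

# two independent strata with a common true ROR; returns the fraction of
# compare_subgroups p-values below alpha. Cell counts are drawn at the
# binomial level (n exposed ~ Bin(n, p_exp); events ~ Bin per arm), the same
# generative model as per-case Bernoulli draws. Stratum sizes are large so
# the Wald z test's nominal level is meaningful.
null_zrejection_rate <- function(n_reps = 10000, n_per_stratum = 20000,
                                 p_exposure = 0.3, p_event = 0.08,
                                 common_ror = 2, alpha = 0.05, seed = 1) {
  set.seed(seed)
  p_exp_event <- odds_adjust(p_event, common_ror)
  draw <- function() {
    ne <- stats::rbinom(n_reps, n_per_stratum, p_exposure)
    a <- stats::rbinom(n_reps, ne, p_exp_event)
    c_ <- stats::rbinom(n_reps, n_per_stratum - ne, p_event)
    list(a = a, b = ne - a, c = c_, d = n_per_stratum - ne - c_)
  }
  s1 <- draw()
  s2 <- draw()
  p <- vapply(seq_len(n_reps), function(i) {
    r1 <- ror(c(s1$a[i], s1$b[i], s1$c[i], s1$d[i]))
    r2 <- ror(c(s2$a[i], s2$b[i], s2$c[i], s2$d[i]))
    compare_subgroups(r1, r2)$p
  }, numeric(1))
  mean(p < alpha)
}

# generator config used for CI-coverage runs: one signal drug against a
# background drug, a signal PT plus a catch-all reaction, no duplicate
# versions or missingness so every generated case is analyzable
coverage_config <- function(true_ror, n_cases, seed) {
  synth_config(
    n_cases = n_cases,
    ingredients = c(DRUG_A = 0.3, DRUG_OTHER = 0.7),
    pts = c(PT_SIGNAL = 0.05, PT_OTHER_REACTION = 0.9),
    signals = make_signal("DRUG_A", "PT_SIGNAL", true_ror),
    occupation_mix = c(MD = 1),
    sex_mix = c(female = 0.5, male = 0.5, unknown = 0),
    duplicate_version_rate = 0,
    missing = c(age = 0, sex = 0, prod_ai = 0, pt = 0),
    concomitant_rate = 0,
    seed = seed)
}

# 2x2 cells for (DRUG_A, PT_SIGNAL) straight from a cohort manifest; the
# equivalence of this counting with the preprocess + count_contingency path
# is asserted once in test-synth.R, which licenses the shortcut in the
# 200-replicate coverage loops
manifest_cells <- function(manifest, ingredient = "DRUG_A",
                           pt = "PT_SIGNAL") {
  m <- manifest[manifest$survives, ]
  exposed <- m$ingredient == ingredient
  event <- grepl(pt, m$pts_obs, fixed = TRUE)
  contingency_table(sum(exposed & event), sum(exposed & !event),
                    sum(!exposed & event), sum(!exposed & !event))
}

# fraction of replicates whose 95% CI covers the injected ROR
ci_coverage <- function(true_ror, n_reps = 200, n_cases = 50000,
                        seed0 = 1000) {
  hits <- vapply(seq_len(n_reps), function(i) {
    cohort <- generate_cohort(coverage_config(true_ror, n_cases, seed0 + i))
    r <- ror(manifest_cells(cohort$manifest))
    r$ci_low <= true_ror && true_ror <= r$ci_high
  }, logical(1))
  mean(hits)
}
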