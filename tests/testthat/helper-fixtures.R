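# shared fixtures built in code

# brute-force maximally selected log-rank scan: independent oracle for
# maxstat_cutoff, computing each candidate's statistic via survival::survdiff
oracle_maxstat <- function(density, time, event, min_group_fraction = 0.10) {
  n <- length(density)
  cand <- sort(unique(density))
  n_high <- vapply(cand, function(c) sum(density >= c), integer(1))
  adm <- pmin(n_high, n - n_high) >= min_group_fraction * n
  cand <- cand[adm]
  stat <- vapply(cand, function(c) {
    survival::survdiff(
      survival::Surv(time, as.logical(event)) ~ factor(density >= c))$chisq
  }, numeric(1))
  best <- which.max(stat)
  list(cutoff = cand[best], statistic = stat[best])
}

# small cohort with a hand-set missingness pattern: patient P2 lost the IM
# core, P3 lost the DM core
tiny_cohort <- function() {
  ids <- c("P1", "P2", "P3")
  dens <- expand.grid(patient_id = ids, marker = markers(),
                      region = regions(), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(404)
  dens$density <- round(rlnorm(nrow(dens), 5, 1), 2)
  dens$metastatic_site <- ifelse(dens$region == "DM", "liver", NA_character_)
  dens$missing <- (dens$patient_id == "P2" & dens$region == "IM") |
                  (dens$patient_id == "P3" & dens$region == "DM")
  dens$density[dens$missing] <- NA_real_
  clin <- data.frame(
    patient_id = ids, age_years = c(55, 70, 63),
    sex = c("male", "female", "male"),
    pT = c("T1_3", "T4", "T1_3"), pN = c("N0", "N1_2", "N1_2"),
    metastasis_timing = c("synchronous", "metachronous", "synchronous"),
    differentiation = c("WD_MD", "WD_MD", "PD_UD"),
    lymphatic_invasion = c(TRUE, FALSE, TRUE),
    perineural_invasion = c(FALSE, FALSE, TRUE),
    venous_invasion = c(FALSE, TRUE, FALSE),
    kras = c("wild", "mutant", "wild"),
    pik3ca = c("wild", "wild", "mutant"),
    braf = c("wild", "wild", "wild"),
    stringsAsFactors = FALSE)
  surv <- data.frame(patient_id = ids, time_months = c(12.5, 40.1, 88),
                     event = c(TRUE, TRUE, FALSE))
  cohort(clin, surv, dens)
}

# uniform cutoff table (same threshold everywhere) for scoring tests
flat_cutoffs <- function(cutoff = 100) {
  g <- expand.grid(marker = markers(), region = regions(),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tab <- data.frame(marker = g$marker, region = g$region, cutoff = cutoff,
                    statistic = NA_real_, method = "median",
                    n_candidates = NA_integer_, n_low = NA_integer_,
                    n_high = NA_integer_, n = NA_integer_)
  class(tab) <- c("cutoff_table", "data.frame")
  tab
}

# simulated binary-covariate survival data with known hazard ratio:
# exponential baseline, uniform censoring tuned to ~20%
simulate_binary_cox <- function(n, true_hr, seed, censor = TRUE) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n) / (0.03 * true_hr^x)
  c_time <- if (censor) runif(n, 0, 165) else Inf
  data.frame(x = x,
             time_months = pmin(t_event, c_time),
             event = t_event <= c_time)
}
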