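#' Default log-normal density parameters
#'
#' Densities of tumor-infiltrating immune cells are strongly right-skewed,
#' so each (marker, region) marginal is modelled log-normal. Parameters are
#' solved from the reference median and IQR of [crc_density_reference()]:
#' `meanlog = log(median)` and
#' `sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75))`,
#' which reproduces the reference median exactly and the IQR approximately
#' (exactly when the reference quartiles are log-symmetric about the median).
#'
#' @param reference data.frame with `marker`, `region`, `median`, `q1`, `q3`
#'   (default [crc_density_reference()]).
#' @return data.frame `marker`, `region`, `meanlog`, `sdlog`.
#' @export
default_density_params <- function(reference = crc_density_reference()) {
  z75 <- stats::qnorm(0.75)
  data.frame(marker = reference$marker, region = reference$region,
             meanlog = log(reference$median),
             sdlog = (log(reference$q3) - log(reference$q1)) / (2 * z75))
}

default_organ_mix <- function() {
  c(liver = 0.58, lung = 0.15, peritoneum = 0.10,
    non_regional_lymph_node = 0.09, ovary = 0.04, other = 0.04)
}

# per-organ multipliers on DM density medians: lymphocytes densest in
# non-regional lymph nodes, FOXP3 relatively high in lung, everything
# lowest in the ovary. Normalized downstream so the mixture-weighted
# geometric mean is 1 and marginal DM medians stay on their anchors.
default_organ_multipliers <- function() {
  sites <- metastatic_sites()
  m <- matrix(1, nrow = length(markers()), ncol = length(sites),
              dimnames = list(markers(), sites))
  m[c("CD3", "CD4", "CD8"), "non_regional_lymph_node"] <- 2.2
  m["FOXP3", "lung"] <- 1.6
  m[, "ovary"] <- 0.45
  m
}

default_component_log_hr <- function() {
  data.frame(
    marker = c("CD3", "CD3", "CD3", "CD8", "CD8", "CD8", "CD163", "CD163"),
    region = c("CT", "IM", "DM", "CT", "IM", "DM", "CT", "IM"),
    polarity = c(1L, 1L, 1L, 1L, 1L, 1L, -1L, -1L),
    log_hr = c(rep(log(1.45), 6), 0, 0),
    stringsAsFactors = FALSE)
}

default_covariate_model <- function() {
  list(
    prevalence = c(male = 0.54, pT4 = 0.39, pN1_2 = 0.81, synchronous = 0.66,
                   pd_ud = 0.15, lymphatic = 0.66, perineural = 0.52,
                   venous = 0.30, kras = 0.54, pik3ca = 0.13, braf = 0.036),
    age_mean = 60, age_sd = 11,
    log_hr = c(age65 = log(1.7), pT4 = log(1.3), pN1_2 = log(1.6),
               synchronous = log(2.0), lymphatic = log(1.5),
               perineural = log(1.3))
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defines every stochastic ingredient of a simulated advanced colorectal
#' cancer cohort: log-normal density marginals per (marker, region) with a
#' Gaussian-copula correlation across regions of the same marker; a
#' categorical metastatic-organ mix with per-organ density multipliers;
#' proportional-hazards survival with a Weibull baseline whose linear
#' predictor sums per-component log hazard ratios over the patient's true
#' high/low states (true state = density above the configured marginal
#' median, so cutpoint recovery is a genuine inference problem); clinical
#' covariates with configurable prevalence and optional hazard effects;
#' administrative censoring plus uniform dropout; and missing-core masking
#' at the region level.
#'
#' Default rates mask `round(3/196 * n)` primary cores and `round(5/196 * n)`
#' distant-metastasis cores in disjoint patients, so at the default
#' `n_patients = 196` exactly 193 patients are evaluable for primary-tumor
#' scores and 188 for metastasis-inclusive scores.
#'
#' @param n_patients cohort size (default 196).
#' @param seed integer RNG seed.
#' @param density_params data.frame from [default_density_params()].
#' @param region_correlation within-marker across-region copula correlation
#'   in [-1, 1] (default 0.3).
#' @param organ_mix named probability vector over [metastatic_sites()].
#' @param organ_multipliers marker x site multiplier matrix.
#' @param missing_core_rates named vector `c(primary =, dm =)` of masking
#'   rates in [0, 1].
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (months; defaults 1.1 and 60).
#' @param component_log_hr data.frame `marker`, `region`, `polarity`,
#'   `log_hr`: the hazard contribution of a patient in the unfavorable state
#'   of that component (low lymphocytes / high macrophages).
#' @param admin_censor_months administrative censoring horizon (default
#'   104.6).
#' @param dropout_rate probability of uniform early dropout (default 0.2).
#' @param covariate_model list with `prevalence`, `age_mean`, `age_sd`,
#'   `log_hr` (see `default_covariate_model()`).
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 196L, seed = 1L,
                          density_params = default_density_params(),
                          region_correlation = 0.3,
                          organ_mix = default_organ_mix(),
                          organ_multipliers = default_organ_multipliers(),
                          missing_core_rates = c(primary = 3 / 196,
                                                 dm = 5 / 196),
                          baseline_shape = 1.1, baseline_scale = 60,
                          component_log_hr = default_component_log_hr(),
                          admin_censor_months = 104.6, dropout_rate = 0.2,
                          covariate_model = default_covariate_model()) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              density_params = density_params,
              region_correlation = region_correlation,
              organ_mix = organ_mix, organ_multipliers = organ_multipliers,
              missing_core_rates = missing_core_rates,
              baseline_shape = baseline_shape,
              baseline_scale = baseline_scale,
              component_log_hr = component_log_hr,
              admin_censor_months = admin_censor_months,
              dropout_rate = dropout_rate,
              covariate_model = covariate_model)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 0)
    stopf("n_patients must be a non-negative integer")
  if (abs(cfg$region_correlation) > 1)
    stopf("region_correlation must lie in [-1, 1]")
  if (any(cfg$missing_core_rates < 0) || any(cfg$missing_core_rates > 1))
    stopf("missing_core_rates must lie in [0, 1]")
  if (cfg$baseline_scale <= 0 || cfg$baseline_shape <= 0)
    stopf("Weibull baseline parameters must be positive")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate > 1)
    stopf("dropout_rate must lie in [0, 1]")
  if (abs(sum(cfg$organ_mix) - 1) > 1e-8)
    stopf("organ_mix must sum to 1")
  stop_if_bad_enum(names(cfg$organ_mix), metastatic_sites(), "metastatic_site")
  need <- setdiff(c("marker", "region", "meanlog", "sdlog"),
                  names(cfg$density_params))
  if (length(need)) stopf("density_params lacks column(s): %s",
                          paste(need, collapse = ", "))
  invisible(cfg)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort (densities, clinical covariates, survival) from a
#' [cohort_config()]. Fully reproducible: the same config (including its
#' `seed`) gives a bit-identical cohort, and the caller's RNG state is left
#' untouched.
#'
#' @param config a `cohort_config`.
#' @return a [cohort()] object.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 42))
#' coh
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  if (n == 0) {
    empty_clin <- empty_clinical()
    return(cohort(empty_clin,
                  data.frame(patient_id = character(), time_months = numeric(),
                             event = logical()),
                  data.frame(patient_id = character(), marker = character(),
                             region = character(),
                             metastatic_site = character(),
                             density = numeric(), missing = logical())))
  }

  # --- densities: per-marker Gaussian copula across the three regions
  rho <- cfg$region_correlation
  sigma <- matrix(rho, 3, 3); diag(sigma) <- 1
  L <- chol(sigma)
  pars <- cfg$density_params
  dens <- list()
  true_high <- list()   # generative high/low state vs the marginal median
  for (m in markers()) {
    z <- matrix(stats::rnorm(n * 3), n, 3) %*% L
    for (k in 1:3) {
      r <- regions()[k]
      p <- pars[pars$marker == m & pars$region == r, ]
      if (!nrow(p)) stopf("density_params lacks %s/%s", m, r)
      d <- exp(p$meanlog + p$sdlog * z[, k])
      dens[[paste(m, r, sep = ".")]] <- d
      true_high[[paste(m, r, sep = ".")]] <- d > exp(p$meanlog)
    }
  }

  # --- metastatic organ and DM multipliers (geometric-mean normalized)
  site <- sample(names(cfg$organ_mix), n, replace = TRUE,
                 prob = cfg$organ_mix)
  for (m in markers()) {
    mult <- cfg$organ_multipliers[m, names(cfg$organ_mix)]
    mult <- mult / exp(sum(cfg$organ_mix * log(mult)))
    key <- paste(m, "DM", sep = ".")
    dens[[key]] <- dens[[key]] * unname(mult[site])
    p <- pars[pars$marker == m & pars$region == "DM", ]
    true_high[[key]] <- dens[[key]] > exp(p$meanlog)
  }

  # --- clinical covariates
  cm <- cfg$covariate_model
  pv <- cm$prevalence
  rb <- function(p) stats::runif(n) < p
  age <- pmax(20, stats::rnorm(n, cm$age_mean, cm$age_sd))
  clin <- data.frame(
    patient_id = ids,
    age_years = round(age, 1),
    sex = ifelse(rb(pv["male"]), "male", "female"),
    pT = ifelse(rb(pv["pT4"]), "T4", "T1_3"),
    pN = ifelse(rb(pv["pN1_2"]), "N1_2", "N0"),
    metastasis_timing = ifelse(rb(pv["synchronous"]),
                               "synchronous", "metachronous"),
    differentiation = ifelse(rb(pv["pd_ud"]), "PD_UD", "WD_MD"),
    lymphatic_invasion = rb(pv["lymphatic"]),
    perineural_invasion = rb(pv["perineural"]),
    venous_invasion = rb(pv["venous"]),
    kras = ifelse(rb(pv["kras"]), "mutant", "wild"),
    pik3ca = ifelse(rb(pv["pik3ca"]), "mutant", "wild"),
    braf = ifelse(rb(pv["braf"]), "mutant", "wild"),
    stringsAsFactors = FALSE)

  # --- proportional-hazards survival, Weibull baseline
  lp <- numeric(n)
  ch <- cfg$component_log_hr
  for (i in seq_len(nrow(ch))) {
    key <- paste(ch$marker[i], ch$region[i], sep = ".")
    high <- true_high[[key]]
    unfavorable <- if (ch$polarity[i] > 0) !high else high
    # centered so the baseline stays the median-patient hazard
    lp <- lp + ch$log_hr[i] * (as.numeric(unfavorable) - 0.5)
  }
  chr <- cm$log_hr
  cov_ind <- cbind(age65 = age >= 65, pT4 = clin$pT == "T4",
                   pN1_2 = clin$pN == "N1_2",
                   synchronous = clin$metastasis_timing == "synchronous",
                   lymphatic = clin$lymphatic_invasion,
                   perineural = clin$perineural_invasion)
  prev_center <- c(age65 = mean(stats::pnorm((cm$age_mean - 65) / cm$age_sd,
                                             lower.tail = FALSE)),
                   pT4 = unname(pv["pT4"]), pN1_2 = unname(pv["pN1_2"]),
                   synchronous = unname(pv["synchronous"]),
                   lymphatic = unname(pv["lymphatic"]),
                   perineural = unname(pv["perineural"]))
  for (nm in names(chr))
    lp <- lp + chr[[nm]] * (as.numeric(cov_ind[, nm]) - prev_center[[nm]])

  t_event <- cfg$baseline_scale *
    (stats::rexp(n) / exp(lp))^(1 / cfg$baseline_shape)
  dropout <- ifelse(stats::runif(n) < cfg$dropout_rate,
                    stats::runif(n, 0, cfg$admin_censor_months), Inf)
  c_time <- pmin(cfg$admin_censor_months, dropout)
  surv <- data.frame(patient_id = ids,
                     time_months = pmax(0.1, round(pmin(t_event, c_time), 1)),
                     event = t_event <= c_time)

  # --- assemble density table and mask lost cores (region-level)
  densities <- expand.grid(patient_id = ids, marker = markers(),
                           region = regions(), stringsAsFactors = FALSE,
                           KEEP.OUT.ATTRS = FALSE)
  densities$metastatic_site <- ifelse(densities$region == "DM",
                                      site[match(densities$patient_id, ids)],
                                      NA_character_)
  # expand.grid varies patient fastest, then marker, then region, so the
  # density column is the marker.region vectors stacked in that order
  densities$density <- unlist(lapply(regions(), function(r)
    lapply(markers(), function(m) dens[[paste(m, r, sep = ".")]])),
    use.names = FALSE)
  densities$missing <- FALSE

  n_primary <- round(cfg$missing_core_rates[["primary"]] * n)
  n_dm <- round(cfg$missing_core_rates[["dm"]] * n)
  lost <- if (n_primary + n_dm > 0)
    sample(ids, min(n, n_primary + n_dm)) else character()
  lost_primary <- utils::head(lost, n_primary)
  lost_dm <- utils::tail(lost, length(lost) - n_primary)
  for (p in lost_primary) {
    reg <- sample(c("CT", "IM"), 1)
    hit <- densities$patient_id == p & densities$region == reg
    densities$missing[hit] <- TRUE
  }
  densities$missing[densities$patient_id %in% lost_dm &
                    densities$region == "DM"] <- TRUE
  densities$density[densities$missing] <- NA_real_

  cohort(clin, surv, densities)
}

empty_clinical <- function() {
  data.frame(patient_id = character(), age_years = numeric(),
             sex = character(), pT = character(), pN = character(),
             metastasis_timing = character(), differentiation = character(),
             lymphatic_invasion = logical(), perineural_invasion = logical(),
             venous_invasion = logical(), kras = character(),
             pik3ca = character(), braf = character(),
             stringsAsFactors = FALSE)
}

#' Simulated sample with a known prognostic density threshold
#'
#' Test harness for cutpoint recovery: densities are drawn from a bimodal
#' mixture straddling `true_threshold` (equal-weight normals centered at
#' 0.5x and 1.5x the threshold), and the event hazard is multiplied by
#' `exp(effect_log_hr)` for densities above the threshold. Exponential
#' baseline with median 35 months; administrative censoring at 105 months.
#'
#' @param n sample size (>= 20).
#' @param true_threshold the generative density threshold (default 200).
#' @param effect_log_hr log hazard ratio of the high-density group (e.g.
#'   `log(4)` for a strong adverse effect, `log(0.25)` protective, 0 null).
#' @param seed integer RNG seed.
#' @return data.frame `density`, `time_months`, `event`.
#' @export
generate_known_cutpoint_sample <- function(n, true_threshold = 200,
                                           effect_log_hr = log(4), seed = 1) {
  if (n < 20) stopf("need n >= 20")
  with_seed(seed, {
    grp <- stats::runif(n) < 0.5
    density <- pmax(1, ifelse(grp,
                              stats::rnorm(n, 1.5 * true_threshold,
                                           0.3 * true_threshold),
                              stats::rnorm(n, 0.5 * true_threshold,
                                           0.15 * true_threshold)))
    rate0 <- log(2) / 35
    haz <- rate0 * exp(effect_log_hr * (density > true_threshold))
    t_event <- stats::rexp(n) / haz
    admin <- 105
    data.frame(density = density,
               time_months = pmax(0.1, round(pmin(t_event, admin), 2)),
               event = t_event <= admin)
  })
}
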