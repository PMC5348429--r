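#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the curve as a plain
#' data.frame plus the median survival (earliest time at which the estimated
#' survival drops to 0.5 or below; NA when never reached, e.g. with no
#' events).
#'
#' @param time follow-up times (months), all positive.
#' @param event logical/0-1 event indicator.
#' @return object of class `km_curve`: list with `curve` (data.frame `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`), `median_survival`, `n`,
#'   `n_events`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stopf("km_estimate: empty input")
  stopifnot(length(time) == length(event), all(time > 0))
  fit <- survival::survfit(survival::Surv(time, as.logical(event)) ~ 1,
                           conf.type = "none")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  hit <- which(curve$surv <= 0.5 & curve$n_event > 0)
  med <- if (length(hit)) curve$time[hit[1]] else NA_real_
  structure(list(curve = curve, median_survival = med,
                 n = length(time), n_events = sum(as.logical(event))),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n=%d, events=%d, median survival %s months\n",
              x$n, x$n_events,
              if (is.na(x$median_survival)) "not reached"
              else format(x$median_survival)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a `km_curve`.
#' @param t times at which to read off the step function.
#' @return survival probabilities (1 before the first event time).
#' @export
km_survival_at <- function(km, t) {
  sf <- stats::stepfun(km$curve$time, c(1, km$curve$surv), right = FALSE)
  sf(t)
}

#' Log-rank test across two or more groups
#'
#' Standard observed-minus-expected / hypergeometric-variance test via
#' [survival::survdiff()] (rho = 0).
#'
#' @param time,event follow-up and event indicator.
#' @param group group labels (k >= 2 non-empty groups).
#' @return list with `chi_square`, `df` (k - 1), `p_value`, `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stopf("log-rank requires at least two groups")
  if (any(table(group) == 0)) stopf("log-rank: empty group")
  if (!any(as.logical(event))) stopf("log-rank requires at least one event")
  sd <- survival::survdiff(
    survival::Surv(time, as.logical(event)) ~ group)
  df <- nlevels(group) - 1L
  list(chi_square = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = as.vector(sd$n))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()] with the Efron tie
#' correction (month-resolution follow-up makes ties ubiquitous). Hazard
#' ratios are exponentiated coefficients with Wald 95% confidence intervals
#' on the log scale.
#'
#' @param data data.frame holding the covariates plus `time_months` and
#'   `event`.
#' @param terms character vector of covariate column names to enter.
#' @param ties tie-handling method (default `"efron"`).
#' @return object of class `cox_fit`: list with `terms` (data.frame `term`,
#'   `hr`, `ci_lo`, `ci_hi`, `p`), `n`, `n_events`, `converged`,
#'   `score_test` (score chi-square at coefficient zero), `fit` (the coxph
#'   object).
#' @export
cox_fit <- function(data, terms, ties = "efron") {
  stopifnot(is.data.frame(data), length(terms) >= 1)
  miss <- setdiff(c(terms, "time_months", "event"), names(data))
  if (length(miss)) stopf("cox_fit: column(s) not in data: %s",
                          paste(miss, collapse = ", "))
  use <- stats::complete.cases(data[c(terms, "time_months", "event")])
  data <- data[use, , drop = FALSE]
  if (!sum(as.logical(data$event))) stopf("cox_fit requires at least one event")
  for (tm in terms) {
    v <- data[[tm]]
    if (length(unique(v[!is.na(v)])) < 2)
      stopf("constant covariate: %s", tm)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, as.logical(event)) ~",
    paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties)
  s <- summary(fit)
  tt <- data.frame(term = rownames(s$coefficients),
                   hr = unname(s$coefficients[, "exp(coef)"]),
                   ci_lo = unname(s$conf.int[, "lower .95"]),
                   ci_hi = unname(s$conf.int[, "upper .95"]),
                   p = unname(s$coefficients[, "Pr(>|z|)"]),
                   stringsAsFactors = FALSE)
  converged <- !any(is.na(stats::coef(fit))) &&
    fit$iter < survival::coxph.control()$iter.max
  structure(list(terms = tt, n = fit$n, n_events = fit$nevent,
                 converged = converged, score_test = unname(fit$score),
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n=%d, events=%d%s\n", x$n, x$n_events,
              if (x$converged) "" else " (NOT converged)"))
  df <- x$terms
  df$hr <- sprintf("%.3f", df$hr)
  df$ci <- sprintf("%.3f-%.3f", x$terms$ci_lo, x$terms$ci_hi)
  df$p <- format_p(x$terms$p)
  print(df[c("term", "hr", "ci", "p")], row.names = FALSE)
  invisible(x)
}

# printed convention: very small p-values shown as "<0.001"; raw values kept
format_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

# analysis frame with reference levels matching the reported contrasts:
# pT (T4 vs T1-3), pN (N1-2 vs N0), metastasis (synchronous vs metachronous),
# differentiation (PD/UD vs WD/MD), invasions (present vs absent),
# scores (low vs high: high survival class is the reference)
prognostic_frame <- function(x, scores, age_term = c("binary65", "continuous")) {
  age_term <- match.arg(age_term)
  df <- merge(x$clinical, x$survival, by = "patient_id")
  df$age65 <- factor(ifelse(df$age_years >= 65, "ge65", "lt65"),
                     levels = c("lt65", "ge65"))
  df$age <- if (age_term == "binary65") df$age65 else df$age_years
  df$pT <- factor(df$pT, levels = c("T1_3", "T4"))
  df$pN <- factor(df$pN, levels = c("N0", "N1_2"))
  df$metastasis_timing <- factor(df$metastasis_timing,
                                 levels = c("metachronous", "synchronous"))
  df$differentiation <- factor(df$differentiation, levels = c("WD_MD", "PD_UD"))
  for (v in c("lymphatic_invasion", "perineural_invasion", "venous_invasion"))
    df[[v]] <- factor(ifelse(df[[v]], "present", "absent"),
                      levels = c("absent", "present"))
  for (mod in unique(scores$model)) {
    sc <- scores[scores$model == mod & scores$evaluable, ]
    df[[mod]] <- factor(sc$klass[match(df$patient_id, sc$patient_id)],
                        levels = c("high", "low"))
  }
  df
}

#' Univariate and multivariate prognostic tables
#'
#' Reproduces the structure of the standard reporting tables: a univariate
#' Cox hazard ratio per clinicopathologic factor and per immunoscore model
#' (low vs high, high as reference), and one multivariate fit per score
#' model combining that model with age, pT and pN stage, metastasis timing,
#' and lymphatic and perineural invasion. When `subgroup_by` names a mutation
#' column, every fit is run separately within the wild and mutant strata.
#'
#' @param x a `crc_cohort`.
#' @param scores output of [classify_cohort()].
#' @param age_term `"binary65"` (dichotomized at 65 years, default) or
#'   `"continuous"`.
#' @param subgroup_by optional: `"kras"`, `"pik3ca"` or `"braf"`.
#' @return list of class `prognostic_report` with data.frames `univariate`
#'   and `multivariate` (columns `term`, `hr`, `ci_lo`, `ci_hi`, `p`, `n`,
#'   `n_events`, `model_id`, and `subgroup` when stratified).
#' @export
prognostic_report <- function(x, scores, age_term = "binary65",
                              subgroup_by = NULL) {
  stopifnot(inherits(x, "crc_cohort"))
  df <- prognostic_frame(x, scores, age_term)
  if (!sum(as.logical(df$event))) stopf("prognostic_report: no events")
  model_names <- intersect(c("IS", "IS_M", "IS_MA"), unique(scores$model))
  clin_terms <- c("age", "pT", "pN", "metastasis_timing", "differentiation",
                  "lymphatic_invasion", "perineural_invasion",
                  "venous_invasion")
  mv_adj <- c("age", "pT", "pN", "metastasis_timing",
              "lymphatic_invasion", "perineural_invasion")

  run_one <- function(dat, subgroup = NA_character_) {
    uni <- lapply(c(clin_terms, model_names), function(tm) {
      f <- tryCatch(cox_fit(dat, tm), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      cbind(f$terms, n = f$n, n_events = f$n_events,
            model_id = "univariate", subgroup = subgroup)
    })
    mv <- lapply(model_names, function(mod) {
      f <- tryCatch(cox_fit(dat, c(mod, mv_adj)), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      cbind(f$terms, n = f$n, n_events = f$n_events,
            model_id = paste0("multivariate_", mod), subgroup = subgroup)
    })
    list(uni = do.call(rbind, uni), mv = do.call(rbind, mv))
  }

  if (is.null(subgroup_by)) {
    res <- run_one(df)
  } else {
    stopifnot(subgroup_by %in% c("kras", "pik3ca", "braf"))
    parts <- lapply(c("wild", "mutant"), function(lv) {
      run_one(df[df[[subgroup_by]] == lv, , drop = FALSE],
              subgroup = paste0(subgroup_by, ":", lv))
    })
    res <- list(uni = do.call(rbind, lapply(parts, `[[`, "uni")),
                mv = do.call(rbind, lapply(parts, `[[`, "mv")))
  }
  structure(list(univariate = res$uni, multivariate = res$mv),
            class = "prognostic_report")
}

#' Kaplan-Meier curves per score model class
#'
#' One curve per (model, low/high class), in long CSV-ready form.
#'
#' @param x a `crc_cohort`.
#' @param scores output of [classify_cohort()].
#' @return data.frame `group`, `time`, `survival`, `at_risk`, `n_censored`,
#'   with a log-rank p-value per model in attribute `"logrank"`.
#' @export
km_curves_table <- function(x, scores) {
  df <- merge(scores[scores$evaluable, ], x$survival, by = "patient_id")
  out <- list(); lr <- list()
  for (mod in unique(df$model)) {
    sub <- df[df$model == mod, ]
    lr[[mod]] <- logrank_test(sub$time_months, sub$event, sub$klass)$p_value
    for (kl in c("low", "high")) {
      g <- sub[sub$klass == kl, ]
      if (!nrow(g)) next
      km <- km_estimate(g$time_months, g$event)
      out[[paste(mod, kl)]] <- data.frame(
        group = paste(mod, kl, sep = "_"), time = km$curve$time,
        survival = km$curve$surv, at_risk = km$curve$n_risk,
        n_censored = km$curve$n_censor)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "logrank") <- lr
  res
}
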