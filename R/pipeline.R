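#' Pipeline run configuration
#'
#' Exactly one input source is allowed: either `densities`/`clinical` file
#' paths, or a `simulate` [cohort_config()]. The configuration is validated
#' up front so misconfigurations (e.g. requesting the metastasis-inclusive
#' model on data without DM densities) fail before any computation.
#'
#' @param densities,clinical input CSV paths (together), or NULL.
#' @param simulate a `cohort_config`, or NULL.
#' @param cutoff_method `"maxstat"` (default) or `"median"`.
#' @param min_group_fraction passed to [maxstat_cutoff()].
#' @param models score models to compute (non-empty subset of
#'   `c("IS", "IS_M", "IS_MA")`).
#' @param age_term `"binary65"` or `"continuous"`.
#' @param subgroup_by optional mutation column for stratified Cox fits.
#' @param out_dir output directory.
#' @param seed integer seed for any stochastic stage (overrides the simulate
#'   config's seed so one flag controls the whole run).
#' @return list of class `run_config`.
#' @export
run_config <- function(densities = NULL, clinical = NULL, simulate = NULL,
                       cutoff_method = c("maxstat", "median"),
                       min_group_fraction = 0.10,
                       models = c("IS", "IS_M", "IS_MA"),
                       age_term = "binary65", subgroup_by = NULL,
                       out_dir = "immunoscore_out", seed = 1L) {
  cutoff_method <- match.arg(cutoff_method)
  from_files <- !is.null(densities) || !is.null(clinical)
  if (from_files && is.null(simulate)) {
    if (is.null(densities) || is.null(clinical))
      stopf("file input needs both densities and clinical paths")
  } else if (!from_files && !is.null(simulate)) {
    stopifnot(inherits(simulate, "cohort_config"))
  } else {
    stopf("exactly one input source: (densities, clinical) or simulate")
  }
  if (!length(models)) stopf("models must be non-empty")
  models <- vapply(models, function(m) score_model(m)$name, character(1))
  structure(list(densities = densities, clinical = clinical,
                 simulate = simulate, cutoff_method = cutoff_method,
                 min_group_fraction = min_group_fraction,
                 models = unname(models), age_term = age_term,
                 subgroup_by = subgroup_by, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full immunoscore pipeline
#'
#' Stages: read or simulate the cohort; dichotomize each (marker, region)
#' density; flag and score patients under the requested models;
#' Kaplan-Meier curves and log-rank tests per model; univariate and
#' multivariate Cox tables; regional heterogeneity and by-organ summaries;
#' clinicopathologic cross-tabulations. Results are written to
#' `config$out_dir` (cutoffs.json, scores.csv, km_curves.csv,
#' cox_univariate.csv, cox_multivariate.csv, heterogeneity.csv, by_organ.csv,
#' crosstab.csv, manifest.json). A rerun with identical config and inputs is
#' bit-identical. Any stage error aborts with the stage name; files already
#' written by the failed run are removed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the cohort and every result table plus
#'   `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  coh <- stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- config$seed
      generate_cohort(sim)
    } else {
      read_cohort(config$densities, config$clinical)
    }
  })

  # configuration errors before computation
  need <- unique(do.call(rbind, lapply(config$models, function(m)
    score_model(m)$components[c("marker", "region")])))
  have_regions <- unique(coh$densities$region[!coh$densities$missing])
  lack <- setdiff(unique(need$region), have_regions)
  if (length(lack))
    stopf("configuration error: model(s) need region(s) %s absent from input",
          paste(lack, collapse = ", "))

  cutoffs <- stage("cutoffs",
                   build_cutoff_table(coh, method = config$cutoff_method,
                                      min_group_fraction =
                                        config$min_group_fraction))
  scores <- stage("scores", classify_cohort(coh, cutoffs, config$models))
  km <- stage("km_curves", km_curves_table(coh, scores))
  prog <- stage("cox", prognostic_report(coh, scores,
                                         age_term = config$age_term,
                                         subgroup_by = config$subgroup_by))
  het <- stage("heterogeneity", region_heterogeneity(coh))
  organ <- stage("by_organ", {
    tabs <- lapply(markers(), function(m)
      tryCatch(by_organ_summary(coh, m), error = function(e) NULL))
    do.call(rbind, tabs)
  })
  xtab <- stage("crosstab", crosstab_report(scores, coh$clinical))

  # hash the analysis-relevant configuration: the destination directory does
  # not affect the results, so two runs into different folders hash alike
  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  cfg_for_hash$simulate <- unclass(cfg_for_hash$simulate)
  meta <- list(seed = config$seed,
               config_hash = object_hash(unclass(cfg_for_hash)),
               n_patients = nrow(coh$clinical),
               n_events = sum(as.logical(coh$survival$event)))
  bundle <- list(cutoffs = cutoffs, scores = scores, km_curves = km,
                 cox_univariate = prog$univariate,
                 cox_multivariate = prog$multivariate,
                 heterogeneity = het, by_organ = organ, crosstab = xtab,
                 meta = meta)
  # write atomically: stage into a temp dir, then move into out_dir, so a
  # failed run leaves no partial outputs behind
  files <- stage("write", {
    tmp <- tempfile("immunoscore_bundle_")
    on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
    staged <- write_results(bundle, tmp)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    dest <- file.path(config$out_dir, basename(staged))
    ok <- file.copy(staged, dest, overwrite = TRUE)
    if (!all(ok)) stopf("could not write to %s", config$out_dir)
    dest
  })
  invisible(c(list(cohort = coh), bundle, list(files = files)))
}

#' Association of score class with clinicopathologic factors
#'
#' For each model, cross-tabulates the low/high class against every
#' categorical covariate with counts and column percentages, testing
#' independence by Pearson chi-square, or Fisher's exact test when any
#' expected cell count falls below 5. Age is compared between classes by a
#' two-sample t-test. Mutation status `"unknown"` is excluded from its
#' table.
#'
#' @param scores output of [classify_cohort()].
#' @param clinical the cohort's clinical table.
#' @return data.frame `model`, `covariate`, `level`, `n_low`, `pct_low`,
#'   `n_high`, `pct_high`, `test`, `p` (test and p repeated across a
#'   covariate's levels).
#' @export
crosstab_report <- function(scores, clinical) {
  covs <- c("sex", "pT", "pN", "metastasis_timing", "differentiation",
            "lymphatic_invasion", "perineural_invasion", "venous_invasion",
            "kras", "pik3ca", "braf")
  out <- list()
  for (mod in unique(scores$model)) {
    sc <- scores[scores$model == mod & scores$evaluable, ]
    df <- merge(sc, clinical, by = "patient_id")
    if (!nrow(df)) stopf("crosstab_report: no overlap between scores and clinical")
    df$klass <- factor(df$klass, levels = c("low", "high"))
    for (cv in covs) {
      v <- df[[cv]]
      keep <- if (cv %in% c("kras", "pik3ca", "braf")) v != "unknown"
              else rep(TRUE, length(v))
      tab <- table(factor(as.character(v[keep])), df$klass[keep])
      if (nrow(tab) < 2 || any(colSums(tab) == 0)) next
      exp_ok <- tryCatch({
        e <- suppressWarnings(stats::chisq.test(tab)$expected)
        all(e >= 5)
      }, error = function(err) FALSE)
      ht <- if (exp_ok) suppressWarnings(stats::chisq.test(tab))
            else stats::fisher.test(tab)
      test <- if (exp_ok) "chi_square" else "fisher_exact"
      pct <- sweep(tab, 2, colSums(tab), "/") * 100
      for (lv in rownames(tab)) {
        out[[paste(mod, cv, lv)]] <- data.frame(
          model = mod, covariate = cv, level = lv,
          n_low = tab[lv, "low"], pct_low = round_half_up(pct[lv, "low"], 1),
          n_high = tab[lv, "high"], pct_high = round_half_up(pct[lv, "high"], 1),
          test = test, p = ht$p.value)
      }
    }
    age_ok <- length(unique(df$klass)) == 2 &&
      all(tapply(df$age_years, df$klass, function(v) length(unique(v))) > 1)
    if (age_ok) {
      tt <- stats::t.test(age_years ~ klass, data = df)
      out[[paste(mod, "age")]] <- data.frame(
        model = mod, covariate = "age_years", level = "mean",
        n_low = sum(df$klass == "low"),
        pct_low = round_half_up(mean(df$age_years[df$klass == "low"]), 1),
        n_high = sum(df$klass == "high"),
        pct_high = round_half_up(mean(df$age_years[df$klass == "high"]), 1),
        test = "t_test", p = tt$p.value)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
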