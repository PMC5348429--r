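#' Assemble and validate a patient cohort
#'
#' A cohort bundles three tables keyed by `patient_id`:
#' \describe{
#'   \item{clinical}{one row per patient: demographics, pathology stage,
#'     invasion flags and mutation status (see [read_cohort()] for columns).}
#'   \item{survival}{one row per patient: `time_months` (> 0) and `event`
#'     (TRUE = death from colorectal cancer; FALSE = censored, covering loss
#'     to follow-up and death from other causes).}
#'   \item{densities}{one row per (patient, marker, region) cell:
#'     `density` in the marker's unit, `metastatic_site` for DM rows, and
#'     `missing` (TRUE when the tissue core was lost). Missingness is tracked
#'     at the (patient, marker, region) level; a lost core voids all markers
#'     of that region.}
#' }
#'
#' @param clinical data.frame of clinical covariates (one row per patient).
#' @param survival data.frame with `patient_id`, `time_months`, `event`.
#' @param densities data.frame with `patient_id`, `marker`, `region`,
#'   `metastatic_site`, `density`, `missing`.
#' @return object of class `crc_cohort`.
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
cohort <- function(clinical, survival, densities) {
  clinical <- as.data.frame(clinical)
  survival <- as.data.frame(survival)
  densities <- as.data.frame(densities)
  if (!"missing" %in% names(densities)) densities$missing <- is.na(densities$density)
  if (!"metastatic_site" %in% names(densities)) densities$metastatic_site <- NA_character_
  validate_cohort(clinical, survival, densities)
  structure(list(clinical = clinical, survival = survival,
                 densities = densities),
            class = "crc_cohort")
}

validate_cohort <- function(clinical, survival, densities) {
  need_clin <- c("patient_id", "age_years", "sex", "pT", "pN",
                 "metastasis_timing", "differentiation", "lymphatic_invasion",
                 "perineural_invasion", "venous_invasion",
                 "kras", "pik3ca", "braf")
  miss <- setdiff(need_clin, names(clinical))
  if (length(miss)) stopf("clinical table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  miss <- setdiff(c("patient_id", "time_months", "event"), names(survival))
  if (length(miss)) stopf("survival table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  miss <- setdiff(c("patient_id", "marker", "region", "density", "missing"),
                  names(densities))
  if (length(miss)) stopf("density table lacks column(s): %s",
                          paste(miss, collapse = ", "))

  if (anyDuplicated(clinical$patient_id))
    stopf("duplicate patient_id in clinical table")
  if (!setequal(clinical$patient_id, survival$patient_id))
    stopf("clinical and survival tables must cover identical patient_id sets")
  orphan <- setdiff(densities$patient_id, clinical$patient_id)
  if (length(orphan)) stopf("density rows for unknown patient(s): %s",
                            paste(utils::head(orphan, 5), collapse = ", "))

  stop_if_bad_enum(densities$marker, markers(), "marker")
  stop_if_bad_enum(densities$region, regions(), "region")
  site <- densities$metastatic_site
  site_given <- !is.na(site) & nzchar(as.character(site))
  stop_if_bad_enum(site[site_given], metastatic_sites(), "metastatic_site")
  if (any(site_given & densities$region != "DM"))
    stopf("metastatic_site may only be set on DM rows")

  key <- paste(densities$patient_id, densities$marker, densities$region)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stopf("duplicate (patient, marker, region): %s", dup)
  }
  obs <- !densities$missing
  if (any(obs & is.na(densities$density)))
    stopf("non-missing density rows must carry a value")
  if (any(obs & densities$density < 0)) {
    bad <- which(obs & densities$density < 0)[1]
    stopf("negative density for %s %s/%s", densities$patient_id[bad],
          densities$marker[bad], densities$region[bad])
  }

  if (any(is.na(survival$time_months)) || any(survival$time_months <= 0))
    stopf("time_months must be positive for every patient")
  if (!all(survival$event %in% c(TRUE, FALSE, 0L, 1L)))
    stopf("event must be logical (or 0/1)")

  stop_if_bad_enum(clinical$sex, c("male", "female"), "sex")
  stop_if_bad_enum(clinical$pT, c("T1_3", "T4"), "pT")
  stop_if_bad_enum(clinical$pN, c("N0", "N1_2"), "pN")
  stop_if_bad_enum(clinical$metastasis_timing,
                   c("synchronous", "metachronous"), "metastasis_timing")
  stop_if_bad_enum(clinical$differentiation, c("WD_MD", "PD_UD"),
                   "differentiation")
  for (v in c("kras", "pik3ca", "braf"))
    stop_if_bad_enum(clinical[[v]], c("wild", "mutant", "unknown"), v)
  for (v in c("lymphatic_invasion", "perineural_invasion", "venous_invasion"))
    if (!all(clinical[[v]] %in% c(TRUE, FALSE)))
      stopf("%s must be logical", v)
  if (any(is.na(clinical$age_years)) || any(clinical$age_years <= 0))
    stopf("age_years must be positive")
  invisible(TRUE)
}

#' @export
print.crc_cohort <- function(x, ...) {
  n <- nrow(x$clinical)
  nev <- sum(as.logical(x$survival$event))
  nmiss <- sum(x$densities$missing)
  cat(sprintf("<crc_cohort> %d patients, %d events, %d density cells (%d missing cores)\n",
              n, nev, nrow(x$densities), nmiss))
  invisible(x)
}

#' Read a cohort from density and clinical CSV files
#'
#' `densities.csv` holds one row per measured (patient, marker, region) cell
#' with columns `patient_id, marker, region, metastatic_site, density`; a
#' blank density cell marks a lost core. `clinical.csv` holds one row per
#' patient with the clinical covariates plus `time_months` and `event`.
#' The reader completes the (patient x marker x region) grid over every
#' region present in the file: a (patient, region) with no rows at all is a
#' lost core, so all markers of that region become `missing = TRUE` records.
#'
#' @param density_path path to densities.csv.
#' @param clinical_path path to clinical.csv.
#' @return a [cohort()] object.
#' @export
read_cohort <- function(density_path, clinical_path) {
  dens <- utils::read.csv(density_path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  clin <- utils::read.csv(clinical_path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  need <- c("patient_id", "marker", "region", "metastatic_site", "density")
  miss <- setdiff(need, names(dens))
  if (length(miss)) stopf("densities file lacks column(s): %s",
                          paste(miss, collapse = ", "))
  # enum tokens must be checked before grid completion: the completion merge
  # would silently drop rows keyed by an unknown marker or region
  stop_if_bad_enum(dens$marker, markers(), "marker")
  stop_if_bad_enum(dens$region, regions(), "region")
  dens$density <- suppressWarnings(as.numeric(dens$density))
  dens$metastatic_site <- trimws(as.character(dens$metastatic_site))
  dens$metastatic_site[!nzchar(dens$metastatic_site)] <- NA_character_
  dens$missing <- is.na(dens$density)

  # complete the TMA grid: unrecorded region rows are lost cores
  dens <- complete_density_grid(dens, unique(clin$patient_id))

  surv <- clin[, c("patient_id", "time_months", "event")]
  surv$event <- as.logical(surv$event)
  clin <- clin[, setdiff(names(clin), c("time_months", "event"))]
  for (v in c("lymphatic_invasion", "perineural_invasion", "venous_invasion"))
    if (v %in% names(clin)) clin[[v]] <- as.logical(clin[[v]])
  cohort(clin, surv, dens)
}

complete_density_grid <- function(dens, patients) {
  reg <- intersect(regions(), unique(dens$region))
  grid <- expand.grid(patient_id = patients, marker = markers(),
                      region = reg, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- merge(grid, dens, by = c("patient_id", "marker", "region"),
               all.x = TRUE, sort = FALSE)
  absent <- is.na(out$missing)
  out$missing[absent] <- TRUE
  # a DM row synthesized for a lost core inherits the patient's site, if known
  if (any(absent & out$region == "DM")) {
    site_map <- unique(dens[dens$region == "DM" & !is.na(dens$metastatic_site),
                            c("patient_id", "metastatic_site")])
    idx <- match(out$patient_id, site_map$patient_id)
    fill <- absent & out$region == "DM"
    out$metastatic_site[fill] <- site_map$metastatic_site[idx[fill]]
  }
  out <- out[order(out$patient_id, match(out$marker, markers()),
                   match(out$region, regions())), ]
  rownames(out) <- NULL
  out
}

#' Write a cohort back to CSV files
#'
#' Inverse of [read_cohort()]: re-reading the written files reproduces the
#' cohort (missing cores round-trip as blank density cells).
#'
#' @param x a `crc_cohort`.
#' @param density_path,clinical_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(x, density_path, clinical_path) {
  stopifnot(inherits(x, "crc_cohort"))
  dens <- x$densities[, c("patient_id", "marker", "region",
                          "metastatic_site", "density")]
  dens$density[x$densities$missing] <- NA
  utils::write.csv(dens, density_path, row.names = FALSE, na = "")
  clin <- merge(x$clinical, x$survival, by = "patient_id", sort = TRUE)
  utils::write.csv(clin, clinical_path, row.names = FALSE, na = "")
  invisible(c(density_path, clinical_path))
}

#' Patients evaluable for a set of score components
#'
#' A composite score is computed only for patients with a non-missing
#' density for every component; a single lost core drops the patient from
#' that model (but not from models that avoid the lost region).
#'
#' @param x a `crc_cohort`.
#' @param components data.frame with columns `marker` and `region`.
#' @return character vector of evaluable patient ids.
#' @export
evaluable_patients <- function(x, components) {
  stopifnot(inherits(x, "crc_cohort"))
  components <- as.data.frame(components)
  if (!nrow(components)) stopf("components must be non-empty")
  stop_if_bad_enum(components$marker, markers(), "marker")
  stop_if_bad_enum(components$region, regions(), "region")
  d <- x$densities
  ok <- unique(x$clinical$patient_id)
  for (i in seq_len(nrow(components))) {
    have <- d$patient_id[d$marker == components$marker[i] &
                         d$region == components$region[i] & !d$missing]
    ok <- intersect(ok, have)
  }
  sort(ok)
}

#' Write a result bundle to an output directory
#'
#' Emits the standard pipeline outputs — `cutoffs.json`, `scores.csv`,
#' `km_curves.csv`, `cox_univariate.csv`, `cox_multivariate.csv`,
#' `heterogeneity.csv`, `crosstab.csv` — for whichever elements the bundle
#' carries, plus a `manifest.json` recording package version, seed, config
#' hash and per-file row counts. Numbers round-trip to 12 significant digits.
#'
#' @param bundle named list; recognized names are `cutoffs` (a
#'   [build_cutoff_table()] result), data.frames `scores`, `km_curves`,
#'   `cox_univariate`, `cox_multivariate`, `heterogeneity`, `crosstab`, and
#'   `meta` (a list merged into the manifest).
#' @param out_dir output directory, created if needed.
#' @return invisibly, character vector of files written.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stopf("out_dir not writable: %s", out_dir)
  written <- character()
  rows <- list()

  if (!is.null(bundle$cutoffs)) {
    path <- file.path(out_dir, "cutoffs.json")
    jsonlite::write_json(cutoff_table_json(bundle$cutoffs), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, path)
    rows$cutoffs.json <- nrow(bundle$cutoffs)
  }
  for (nm in c("scores", "km_curves", "cox_univariate", "cox_multivariate",
               "heterogeneity", "crosstab", "by_organ")) {
    if (is.null(bundle[[nm]])) next
    path <- file.path(out_dir, paste0(nm, ".csv"))
    df <- as.data.frame(bundle[[nm]])
    num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], signif, digits = 12)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    written <- c(written, path)
    rows[[paste0(nm, ".csv")]] <- nrow(df)
  }
  # no timestamp: reruns with identical inputs must be byte-identical
  manifest <- c(list(package = "immunoscore",
                     version = as.character(utils::packageVersion("immunoscore")),
                     rows = rows),
                bundle$meta %||% list())
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(written, mpath))
}
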