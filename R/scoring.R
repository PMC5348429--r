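#' Composite immunoscore model definitions
#'
#' Three composite models built from binary high/low density flags:
#' \describe{
#'   \item{IS}{CD3 and CD8 in tumor center (CT) and invasive margin (IM);
#'     score 0-4, low 0-2, high 3-4.}
#'   \item{IS_M}{immunoscore-metastatic: IS plus CD3 and CD8 in the distant
#'     metastasis (DM); score 0-6, low 0-3, high 4-6.}
#'   \item{IS_MA}{immunoscore-macrophage: IS plus CD163 in CT and IM with
#'     inverted polarity — macrophages carry the opposite prognostic
#'     direction to lymphocytes, so a LOW CD163 density scores 1; score 0-6,
#'     low 0-3, high 4-6.}
#' }
#' Each component is a (marker, region, polarity) triple; polarity +1 scores
#' the high flag, -1 its complement.
#'
#' @return `score_models()`: named list of model specs; `score_model(name)`:
#'   a single spec — a list with `name`, `label`, `components` (data.frame
#'   `marker`, `region`, `polarity`), `max_score`, `low_max` (largest score
#'   still classified low).
#' @examples
#' score_model("IS_MA")$components
#' @export
score_models <- function() {
  is_comp <- data.frame(marker = c("CD3", "CD3", "CD8", "CD8"),
                        region = c("CT", "IM", "CT", "IM"),
                        polarity = 1L, stringsAsFactors = FALSE)
  list(
    IS = list(name = "IS", label = "IS", components = is_comp,
              max_score = 4L, low_max = 2L),
    IS_M = list(name = "IS_M", label = "IS-M",
                components = rbind(is_comp,
                                   data.frame(marker = c("CD3", "CD8"),
                                              region = "DM", polarity = 1L)),
                max_score = 6L, low_max = 3L),
    IS_MA = list(name = "IS_MA", label = "IS-ma",
                 components = rbind(is_comp,
                                    data.frame(marker = "CD163",
                                               region = c("CT", "IM"),
                                               polarity = -1L)),
                 max_score = 6L, low_max = 3L)
  )
}

#' @rdname score_models
#' @param name one of `"IS"`, `"IS_M"`, `"IS_MA"` (labels `"IS-M"`/`"IS-ma"`
#'   accepted).
#' @export
score_model <- function(name) {
  key <- toupper(gsub("-", "_", name))
  key <- c(IS = "IS", IS_M = "IS_M", IS_MA = "IS_MA")[key]
  if (is.na(key)) stopf("unknown score model: %s", name)
  score_models()[[key]]
}

#' Binary high/low density flag
#'
#' @param density observed density (marker unit).
#' @param cutoff dichotomization threshold.
#' @return 1 if `density >= cutoff` (a value exactly at the cutoff is high),
#'   else 0. Vectorized.
#' @export
flag_density <- function(density, cutoff) {
  stopifnot(is.finite(density), is.finite(cutoff), all(density >= 0))
  as.integer(density >= cutoff)
}

#' Component score under a polarity
#'
#' Lymphocyte components (+1) score the high flag directly; macrophage
#' components (-1) score its complement, so low macrophage density scores 1.
#'
#' @param flag binary flag from [flag_density()].
#' @param polarity +1 or -1.
#' @return 0 or 1. Vectorized.
#' @export
component_score <- function(flag, polarity) {
  stopifnot(all(flag %in% c(0L, 1L)), all(polarity %in% c(-1L, 1L)))
  ifelse(polarity > 0, flag, 1L - flag)
}

#' Composite score for one patient
#'
#' @param flags named binary vector keyed `"MARKER.REGION"` (e.g. `"CD3.CT"`);
#'   an `NA` or absent component marks a lost core.
#' @param model a spec from [score_model()].
#' @return list with `score`, `klass` (`"low"`/`"high"`) and `evaluable`;
#'   when any component flag is unavailable the patient is not evaluable for
#'   this model and `score`/`klass` are NA. Not-evaluable is a value, not an
#'   error: a patient can hold an IS but no IS-M.
#' @export
compute_score <- function(flags, model) {
  comp <- model$components
  keys <- paste(comp$marker, comp$region, sep = ".")
  f <- flags[keys]
  if (any(is.na(f))) {
    return(list(score = NA_integer_, klass = NA_character_, evaluable = FALSE))
  }
  sc <- sum(component_score(as.integer(f), comp$polarity))
  list(score = as.integer(sc),
       klass = if (sc <= model$low_max) "low" else "high",
       evaluable = TRUE)
}

#' Score every patient of a cohort under one or more models
#'
#' Flags each component density against its cutoff and sums component scores
#' per model. Patients with any lost component core are reported as not
#' evaluable for that model only.
#'
#' @param x a `crc_cohort`.
#' @param cutoffs a `cutoff_table` covering every component of every
#'   requested model (missing keys are a configuration error).
#' @param models character vector of model names (default all three).
#' @return data.frame with `patient_id`, `model`, `score`, `klass`,
#'   `evaluable`, one row per patient per model.
#' @export
classify_cohort <- function(x, cutoffs, models = c("IS", "IS_M", "IS_MA")) {
  stopifnot(inherits(x, "crc_cohort"))
  specs <- lapply(models, score_model)
  need <- unique(do.call(rbind, lapply(specs, function(s)
    s$components[c("marker", "region")])))
  for (i in seq_len(nrow(need))) {
    if (is.na(cutoff_for(cutoffs, need$marker[i], need$region[i])))
      stopf("no cutoff for required component %s/%s",
            need$marker[i], need$region[i])
  }
  pts <- x$clinical$patient_id
  if (!length(pts)) {
    return(data.frame(patient_id = character(), model = character(),
                      score = integer(), klass = character(),
                      evaluable = logical()))
  }
  d <- x$densities
  d$key <- paste(d$marker, d$region, sep = ".")
  cutmap <- stats::setNames(cutoffs$cutoff,
                            paste(cutoffs$marker, cutoffs$region, sep = "."))
  allkeys <- unique(paste(need$marker, need$region, sep = "."))
  # patient x component flag matrix; NA marks a lost core
  flags <- matrix(NA_integer_, nrow = length(pts), ncol = length(allkeys),
                  dimnames = list(pts, allkeys))
  d2 <- d[d$key %in% allkeys & !d$missing, ]
  if (nrow(d2)) {
    flags[cbind(match(d2$patient_id, pts), match(d2$key, allkeys))] <-
      flag_density(d2$density, cutmap[d2$key])
  }
  out <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    keys <- paste(spec$components$marker, spec$components$region, sep = ".")
    fm <- flags[, keys, drop = FALSE]
    neg <- spec$components$polarity < 0
    fm[, neg] <- 1L - fm[, neg]
    score <- as.integer(rowSums(fm))
    evaluable <- !is.na(score)
    klass <- ifelse(evaluable,
                    ifelse(score <= spec$low_max, "low", "high"),
                    NA_character_)
    out[[k]] <- data.frame(patient_id = pts, model = spec$name, score = score,
                           klass = klass, evaluable = evaluable)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score distribution and low/high classification summary
#'
#' Tabulates integer scores over a model's full range and reports the low and
#' high class sizes with percentages rounded half-up to one decimal — the
#' convention of the printed cohort tables.
#'
#' @param score integer vector of composite scores (NAs dropped).
#' @param model spec from [score_model()], or a model name.
#' @return list with `model`, `n`, `categories` (data.frame `score`, `n`,
#'   `pct`), `n_low`, `n_high`, `pct_low`, `pct_high`.
#' @examples
#' # a 193-patient score distribution: 96 low (49.7%), 97 high
#' score_distribution(rep(0:4, c(11, 38, 47, 83, 14)), "IS")
#' @export
score_distribution <- function(score, model) {
  if (is.character(model)) model <- score_model(model)
  score <- score[!is.na(score)]
  if (length(score) && (min(score) < 0 || max(score) > model$max_score))
    stopf("score outside the %s range 0-%d", model$name, model$max_score)
  n <- length(score)
  cats <- data.frame(score = 0:model$max_score)
  cats$n <- vapply(cats$score, function(s) sum(score == s), integer(1))
  cats$pct <- if (n) round_half_up(100 * cats$n / n, 1) else NA_real_
  n_low <- sum(score <= model$low_max)
  list(model = model$name, n = n, categories = cats,
       n_low = n_low, n_high = n - n_low,
       pct_low = if (n) round_half_up(100 * n_low / n, 1) else NA_real_,
       pct_high = if (n) round_half_up(100 * (n - n_low) / n, 1) else NA_real_)
}
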