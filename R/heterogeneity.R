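#' Median and interquartile range of a density sample
#'
#' Quartiles use linear interpolation between order statistics (the type-7
#' convention of [stats::quantile()]).
#'
#' @param values numeric vector.
#' @return list with `n`, `median`, `q1`, `q3`.
#' @export
summarize_density <- function(values) {
  if (!length(values)) stopf("summarize_density: empty input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3])
}

#' Within-patient comparison of a marker's density between two regions
#'
#' Restricted to patients with a non-missing core in both regions; tests the
#' paired differences with a paired t-test (default, matching how regional
#' heterogeneity is conventionally reported) or the Wilcoxon signed-rank
#' test.
#'
#' @param x a `crc_cohort`.
#' @param marker one marker name.
#' @param region_pair two region names, e.g. `c("CT", "IM")`.
#' @param test `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @return data.frame row: `marker`, `comparison`, `test`, `n_pairs`,
#'   `statistic`, `p`.
#' @export
paired_region_test <- function(x, marker, region_pair = c("CT", "IM"),
                               test = c("paired_t", "wilcoxon_signed_rank")) {
  stopifnot(inherits(x, "crc_cohort"), length(region_pair) == 2)
  test <- match.arg(test)
  stop_if_bad_enum(marker, markers(), "marker")
  stop_if_bad_enum(region_pair, regions(), "region")
  d <- x$densities[!x$densities$missing & x$densities$marker == marker, ]
  a <- d[d$region == region_pair[1], c("patient_id", "density")]
  b <- d[d$region == region_pair[2], c("patient_id", "density")]
  pair <- merge(a, b, by = "patient_id", suffixes = c("_a", "_b"))
  if (nrow(pair) < 2) stopf("fewer than 2 complete pairs for %s %s vs %s",
                            marker, region_pair[1], region_pair[2])
  if (all(pair$density_a == pair$density_b)) {
    # identical measurements: no evidence of heterogeneity by convention
    return(data.frame(marker = marker,
                      comparison = paste(region_pair, collapse = "_vs_"),
                      test = test, n_pairs = nrow(pair),
                      statistic = 0, p = 1))
  }
  if (test == "paired_t") {
    ht <- stats::t.test(pair$density_a, pair$density_b, paired = TRUE)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(pair$density_a, pair$density_b, paired = TRUE,
                         exact = FALSE, correct = TRUE))
  }
  data.frame(marker = marker,
             comparison = paste(region_pair, collapse = "_vs_"),
             test = test, n_pairs = nrow(pair),
             statistic = unname(ht$statistic), p = ht$p.value)
}

#' Regional heterogeneity table over all markers and region pairs
#'
#' @param x a `crc_cohort`.
#' @param test passed to [paired_region_test()].
#' @return data.frame, one row per marker x region pair (CT_vs_IM, CT_vs_DM,
#'   IM_vs_DM). No multiplicity correction is applied across the grid.
#' @export
region_heterogeneity <- function(x, test = "paired_t") {
  pairs <- list(c("CT", "IM"), c("CT", "DM"), c("IM", "DM"))
  out <- list()
  for (m in markers()) for (rp in pairs) {
    row <- tryCatch(paired_region_test(x, m, rp, test),
                    error = function(e) NULL)
    if (!is.null(row)) out[[paste(m, rp[1], rp[2])]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Density summaries of the distant metastasis by organ
#'
#' One summary per metastatic site; sites with fewer than `min_n` patients
#' are retained but flagged and should be excluded from between-organ
#' comparisons.
#'
#' @param x a `crc_cohort`.
#' @param marker one marker name.
#' @param min_n minimum patients per site (default 3).
#' @return data.frame `marker`, `site`, `n`, `median`, `q1`, `q3`, `flagged`.
#' @export
by_organ_summary <- function(x, marker, min_n = 3) {
  stopifnot(inherits(x, "crc_cohort"))
  stop_if_bad_enum(marker, markers(), "marker")
  d <- x$densities[!x$densities$missing & x$densities$marker == marker &
                   x$densities$region == "DM", ]
  if (any(is.na(d$metastatic_site)))
    stopf("DM density records must carry a metastatic_site")
  out <- lapply(split(d, d$metastatic_site), function(g) {
    s <- summarize_density(g$density)
    data.frame(marker = marker, site = g$metastatic_site[1], n = s$n,
               median = s$median, q1 = s$q1, q3 = s$q3, flagged = s$n < min_n)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$site), ]
}

#' Concordance of duplicated tissue cores
#'
#' Pearson correlation between paired density measurements of the same
#' region sampled twice, as used to check that single-core sampling is
#' representative despite spatial heterogeneity.
#'
#' @param value_a,value_b paired density measurements (>= 3 pairs).
#' @return list with `r`, `p_value`, `n`.
#' @export
core_concordance <- function(value_a, value_b) {
  stopifnot(length(value_a) == length(value_b))
  if (length(value_a) < 3) stopf("core_concordance: need at least 3 pairs")
  if (stats::sd(value_a) == 0 || stats::sd(value_b) == 0)
    stopf("core_concordance: constant measurements")
  ct <- stats::cor.test(value_a, value_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(value_a))
}
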