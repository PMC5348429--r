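#' Two-sample log-rank chi-square from first principles
#'
#' Computes the classical log-rank statistic for a binary group split by
#' summing, over distinct event times, the hypergeometric observed-minus-
#' expected event counts and variances in group 1:
#' \deqn{\chi^2 = \left(\sum_j d_{1j} - d_j n_{1j}/n_j\right)^2 /
#'   \sum_j d_j \frac{n_{1j}}{n_j}\left(1-\frac{n_{1j}}{n_j}\right)
#'   \frac{n_j - d_j}{n_j - 1}}
#' where \eqn{n_j, n_{1j}} are at-risk counts and \eqn{d_j, d_{1j}} event
#' counts at the j-th distinct event time. This routine powers the maximal
#' chi-square cutpoint scan and is exposed for cross-checks against
#' model-based tests (the score test of a Cox fit at coefficient zero equals
#' this statistic on tie-free data).
#'
#' @param time follow-up times (months).
#' @param event logical/0-1 event indicator.
#' @param group logical/0-1 group membership.
#' @return list with `chi_square`, `observed` (events in group 1), `expected`,
#'   `variance`, `df` (1) and `p_value`.
#' @export
logrank_chisq2 <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  event <- as.logical(event)
  g <- as.logical(group)
  if (!any(event)) stopf("log-rank requires at least one event")
  if (all(g) || !any(g)) stopf("log-rank requires two non-empty groups")
  pre <- logrank_riskset(time, event)
  s <- logrank_scan_stat(pre, g)
  chi <- if (s$V > 0) (s$O - s$E)^2 / s$V else 0
  list(chi_square = chi, observed = s$O, expected = s$E, variance = s$V,
       df = 1L, p_value = stats::pchisq(chi, 1L, lower.tail = FALSE))
}

# Precompute the risk-set geometry shared by every candidate split:
# observations sorted by time, distinct-time index, total events and
# at-risk counts per distinct time.
logrank_riskset <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  tt <- time[ord]
  ev <- as.numeric(event[ord])
  tidx <- cumsum(!duplicated(tt))          # distinct-time id per observation
  J <- tidx[n]
  cnt <- rowsum(rep(1, n), tidx)[, 1]      # observations per distinct time
  d <- rowsum(ev, tidx)[, 1]               # events per distinct time
  n_at_risk <- n - c(0, cumsum(cnt))[seq_len(J)]
  keep <- d > 0
  list(ord = ord, ev = ev, tidx = tidx, J = J, d = d,
       n_at_risk = n_at_risk, keep = keep)
}

# O, E, V for group g (logical, original order) given precomputed risk sets
logrank_scan_stat <- function(pre, g) {
  gs <- as.numeric(g[pre$ord])
  agg <- rowsum(cbind(gs, gs * pre$ev), pre$tidx)
  n1 <- sum(gs) - c(0, cumsum(agg[, 1]))[seq_len(pre$J)]  # at risk in group 1
  d1 <- agg[, 2]
  k <- pre$keep
  d <- pre$d[k]; nj <- pre$n_at_risk[k]; n1 <- n1[k]; d1 <- d1[k]
  O <- sum(d1)
  E <- sum(d * n1 / nj)
  vok <- nj > 1
  V <- sum((d * (n1 / nj) * (1 - n1 / nj) * (nj - d) / (nj - 1))[vok])
  list(O = O, E = E, V = V)
}

#' Survival-driven dichotomization by the maximal chi-square method
#'
#' Scans every distinct observed density as a candidate threshold, splits
#' patients into low (`density < c`) and high (`density >= c`) groups, and
#' computes the two-sample log-rank chi-square for each admissible split
#' (both groups at least `min_group_fraction` of the sample). The cutoff
#' maximizing the statistic is returned; ties go to the smallest cutoff.
#'
#' Maximally selected statistics are anti-conservative: the maximal
#' chi-square is not chi-square distributed under the null. No multiplicity
#' correction is applied here; [maxstat_permutation_p()] provides a
#' permutation p-value when one is needed.
#'
#' @param density non-negative densities, one per patient.
#' @param time follow-up times in months.
#' @param event logical event indicator (TRUE = death from disease).
#' @param min_group_fraction minimum fraction of patients in each arm for a
#'   split to be admissible (default 0.10); must lie in (0, 0.5).
#' @return object of class `maxstat_cutpoint`: list with `cutoff`,
#'   `statistic` (maximal log-rank chi-square), `method = "maxstat"`,
#'   `n_candidates` (admissible splits scanned), `n_low`, `n_high`, `n`.
#' @examples
#' d <- generate_known_cutpoint_sample(200, true_threshold = 200,
#'                                     effect_log_hr = log(4), seed = 7)
#' maxstat_cutoff(d$density, d$time_months, d$event)
#' @export
maxstat_cutoff <- function(density, time, event, min_group_fraction = 0.10) {
  stopifnot(length(density) == length(time), length(time) == length(event))
  n <- length(density)
  if (n < 10) stopf("maxstat requires at least 10 observations (got %d)", n)
  event <- as.logical(event)
  if (!any(event)) stopf("maxstat requires at least one event")
  if (min_group_fraction <= 0 || min_group_fraction >= 0.5)
    stopf("min_group_fraction must lie in (0, 0.5)")
  cand <- sort(unique(density))
  if (length(cand) < 2)
    stopf("degenerate input: all densities equal (%g)", density[1])

  min_arm <- min_group_fraction * n
  # n_high for candidate c = #{density >= c}; admissible if both arms large
  n_high <- n - findInterval(cand, sort(density), left.open = TRUE)
  admissible <- pmin(n_high, n - n_high) >= min_arm
  cand <- cand[admissible]
  n_high <- n_high[admissible]
  if (!length(cand))
    stopf("degenerate input: no admissible split at min_group_fraction %.2f",
          min_group_fraction)

  pre <- logrank_riskset(time, event)
  stat <- vapply(cand, function(cc) {
    s <- logrank_scan_stat(pre, density >= cc)
    if (s$V > 0) (s$O - s$E)^2 / s$V else 0
  }, numeric(1))
  best <- which.max(stat)   # ties: first (= smallest candidate) wins
  structure(list(cutoff = cand[best], statistic = stat[best],
                 method = "maxstat", n_candidates = length(cand),
                 n_low = n - n_high[best], n_high = n_high[best], n = n),
            class = "maxstat_cutpoint")
}

#' @export
print.maxstat_cutpoint <- function(x, ...) {
  cat(sprintf("maxstat cutpoint: %.4g (chi-square %.3f over %d admissible splits; %d low / %d high)\n",
              x$cutoff, x$statistic, x$n_candidates, x$n_low, x$n_high))
  invisible(x)
}

#' Permutation p-value for a maximal chi-square cutpoint
#'
#' Recomputes the maximal statistic under `n_perm` random permutations of the
#' (time, event) pairs against the densities and reports the proportion of
#' permutations reaching or exceeding the observed maximum. This respects the
#' selection effect of scanning many candidate thresholds.
#'
#' @inheritParams maxstat_cutoff
#' @param n_perm number of permutations (default 200).
#' @return list with `p_value`, `statistic`, `n_perm`.
#' @export
maxstat_permutation_p <- function(density, time, event,
                                  min_group_fraction = 0.10, n_perm = 200) {
  obs <- maxstat_cutoff(density, time, event, min_group_fraction)$statistic
  n <- length(density)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    st <- tryCatch(
      maxstat_cutoff(density, time[idx], event[idx],
                     min_group_fraction)$statistic,
      error = function(e) NA_real_)
    if (!is.na(st) && st >= obs) exceed <- exceed + 1L
  }
  list(p_value = (exceed + 1) / (n_perm + 1), statistic = obs, n_perm = n_perm)
}

#' Median cutoff
#'
#' Sample median used as the alternative dichotomization threshold; for even
#' n the mean of the two central order statistics.
#'
#' @param x numeric vector of densities.
#' @return the median.
#' @export
median_cutoff <- function(x) {
  if (!length(x)) stopf("median_cutoff: empty input")
  stats::median(x)
}

#' Dichotomization thresholds for every (marker, region) cell
#'
#' Applies [maxstat_cutoff()] or [median_cutoff()] to each marker x region
#' density vector, using only patients with a non-missing core for that cell.
#' Cells with fewer than `min_n` evaluable observations are skipped with a
#' warning; degenerate cells (all densities equal, or no admissible split)
#' abort with the offending key in the message.
#'
#' @param x a `crc_cohort`.
#' @param method `"maxstat"` (default) or `"median"`.
#' @param min_group_fraction passed to [maxstat_cutoff()].
#' @param min_n minimum evaluable observations per cell (default 10).
#' @return `cutoff_table`: data.frame with one row per (marker, region) —
#'   columns `marker`, `region`, `cutoff`, `statistic`, `method`,
#'   `n_candidates`, `n_low`, `n_high`, `n`.
#' @export
build_cutoff_table <- function(x, method = c("maxstat", "median"),
                               min_group_fraction = 0.10, min_n = 10) {
  stopifnot(inherits(x, "crc_cohort"))
  method <- match.arg(method)
  d <- x$densities[!x$densities$missing, ]
  surv <- x$survival
  out <- list()
  for (m in markers()) for (r in intersect(regions(), unique(x$densities$region))) {
    cell <- d[d$marker == m & d$region == r, ]
    if (nrow(cell) < min_n) {
      warnf("skipping %s/%s: only %d evaluable observations", m, r, nrow(cell))
      next
    }
    i <- match(cell$patient_id, surv$patient_id)
    row <- if (method == "maxstat") {
      res <- tryCatch(
        maxstat_cutoff(cell$density, surv$time_months[i],
                       as.logical(surv$event[i]), min_group_fraction),
        error = function(e) stopf("%s/%s: %s", m, r, conditionMessage(e)))
      data.frame(marker = m, region = r, cutoff = res$cutoff,
                 statistic = res$statistic, method = "maxstat",
                 n_candidates = res$n_candidates, n_low = res$n_low,
                 n_high = res$n_high, n = res$n)
    } else {
      cut <- median_cutoff(cell$density)
      nh <- sum(cell$density >= cut)
      data.frame(marker = m, region = r, cutoff = cut, statistic = NA_real_,
                 method = "median", n_candidates = NA_integer_,
                 n_low = nrow(cell) - nh, n_high = nh, n = nrow(cell))
    }
    out[[paste(m, r, sep = ".")]] <- row
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("cutoff_table", "data.frame")
  tab
}

#' Look up a threshold in a cutoff table
#'
#' @param tab a `cutoff_table`.
#' @param marker,region the cell key.
#' @return the cutoff, or NA if the key is absent.
#' @export
cutoff_for <- function(tab, marker, region) {
  i <- which(tab$marker == marker & tab$region == region)
  if (!length(i)) return(NA_real_)
  tab$cutoff[i[1]]
}

# JSON shape for cutoffs.json: keyed "MARKER.REGION"
cutoff_table_json <- function(tab) {
  out <- list()
  for (i in seq_len(nrow(tab))) {
    out[[paste(tab$marker[i], tab$region[i], sep = ".")]] <- list(
      cutoff = tab$cutoff[i],
      statistic = if (is.na(tab$statistic[i])) NULL else tab$statistic[i],
      method = tab$method[i], n_low = tab$n_low[i], n_high = tab$n_high[i])
  }
  out
}
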