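test_that("density flags use the at-or-above-cutoff rule", {
  # CD3 tumor-center: a median-level patient clears the survival cutoff
  expect_equal(flag_density(297.79, 158.52), 1L)
  # CD3 distant metastasis: median density falls below its cutoff
  expect_equal(flag_density(76.27, 272.23), 0L)
  # a value exactly at the cutoff is high
  expect_equal(flag_density(158.52, 158.52), 1L)
  expect_equal(flag_density(c(0, 99.999, 100), 100), c(0L, 0L, 1L))
})

test_that("component polarity inverts macrophage scores", {
  expect_equal(component_score(1L, 1L), 1L)
  expect_equal(component_score(0L, 1L), 0L)
  expect_equal(component_score(1L, -1L), 0L)  # dense macrophages score 0
  expect_equal(component_score(0L, -1L), 1L)
})

test_that("model specs define the documented components and bands", {
  sm <- score_models()
  expect_equal(nrow(sm$IS$components), 4L)
  expect_equal(sm$IS$max_score, 4L)
  expect_equal(sm$IS$low_max, 2L)
  expect_equal(nrow(sm$IS_M$components), 6L)
  expect_true(all(sm$IS_M$components$region[5:6] == "DM"))
  expect_equal(nrow(sm$IS_MA$components), 6L)
  expect_equal(sm$IS_MA$components$polarity[5:6], c(-1L, -1L))
  expect_equal(sm$IS_MA$low_max, 3L)
  # bands partition the range: every score classifiable
  for (m in sm) {
    kl <- ifelse(0:m$max_score <= m$low_max, "low", "high")
    expect_true(all(kl %in% c("low", "high")))
  }
  expect_equal(score_model("IS-ma")$name, "IS_MA")
  expect_error(score_model("IS_X"), "unknown score model")
})

test_that("composite scores sum polarized component flags", {
  # CD3/CD8 high in CT and IM, CD163 high in CT (scores 0), low in IM
  # (scores 1): 4 + 0 + 1
  flags <- c(CD3.CT = 1, CD3.IM = 1, CD8.CT = 1, CD8.IM = 1,
             CD163.CT = 1, CD163.IM = 0)
  r <- compute_score(flags, score_model("IS_MA"))
  expect_equal(r$score, 5L)
  expect_equal(r$klass, "high")

  r <- compute_score(c(CD3.CT = 1, CD3.IM = 1, CD8.CT = 0, CD8.IM = 0),
                     score_model("IS"))
  expect_equal(r$score, 2L)
  expect_equal(r$klass, "low")

  # a lost DM core voids IS-M but not IS
  flags6 <- c(CD3.CT = 1, CD3.IM = 1, CD8.CT = 1, CD8.IM = 1,
              CD3.DM = 1, CD8.DM = NA)
  expect_false(compute_score(flags6, score_model("IS_M"))$evaluable)
  expect_true(compute_score(flags6, score_model("IS"))$evaluable)
})

test_that("cohort classification respects missingness per model", {
  coh <- tiny_cohort()
  tab <- flat_cutoffs(cutoff = 100)
  sc <- classify_cohort(coh, tab)
  expect_equal(nrow(sc), 9L)  # 3 patients x 3 models
  # P2 lost IM: nothing evaluable; P3 lost DM: only IS_M drops
  expect_false(any(sc$evaluable[sc$patient_id == "P2"]))
  p3 <- sc[sc$patient_id == "P3", ]
  expect_true(p3$evaluable[p3$model == "IS"])
  expect_false(p3$evaluable[p3$model == "IS_M"])
  expect_true(p3$evaluable[p3$model == "IS_MA"])
  # scores stay in range and bands classify every evaluable patient
  ok <- sc$evaluable
  expect_true(all(sc$score[ok] >= 0))
  expect_true(all(sc$klass[ok] %in% c("low", "high")))

  expect_error(classify_cohort(coh, tab[tab$region != "DM", ],
                               models = "IS_M"), "no cutoff")
  empty <- generate_cohort(cohort_config(0, seed = 1))
  expect_equal(nrow(classify_cohort(empty, tab)), 0L)
})

test_that("scores are monotone in favorable component flags", {
  set.seed(55)
  for (m in score_models()) {
    keys <- paste(m$components$marker, m$components$region, sep = ".")
    for (i in 1:20) {
      f <- setNames(sample(0:1, length(keys), replace = TRUE), keys)
      base <- compute_score(f, m)$score
      j <- sample(length(keys), 1)
      pol <- m$components$polarity[j]
      f2 <- f
      f2[j] <- if (pol > 0) 1 else 0   # move component j favorably
      expect_gte(compute_score(f2, m)$score, base)
    }
  }
})

test_that("scores depend only on the cutoff comparison, not magnitudes", {
  coh <- generate_cohort(cohort_config(50, seed = 23))
  cuts <- build_cutoff_table(coh, method = "median")
  sc1 <- classify_cohort(coh, cuts)
  # stretch every density away from its cutoff without crossing it
  d <- coh$densities
  cutmap <- setNames(cuts$cutoff, paste(cuts$marker, cuts$region))
  cu <- cutmap[paste(d$marker, d$region)]
  d$density <- ifelse(d$missing, d$density,
                      pmax(0, cu + (d$density - cu) * 3.7))
  sc2 <- classify_cohort(cohort(coh$clinical, coh$survival, d), cuts)
  expect_equal(sc2$score, sc1$score)
  expect_equal(sc2$klass, sc1$klass)
})

test_that("IS-M decomposes as IS plus the two DM component scores", {
  coh <- generate_cohort(cohort_config(120, seed = 31))
  cuts <- build_cutoff_table(coh, method = "median")
  sc <- classify_cohort(coh, cuts)
  w <- reshape(sc[, c("patient_id", "model", "score")],
               idvar = "patient_id", timevar = "model", direction = "wide")
  d <- coh$densities
  both <- w[!is.na(w$score.IS) & !is.na(w$score.IS_M), ]
  for (p in both$patient_id) {
    dm <- d[d$patient_id == p & d$region == "DM" &
            d$marker %in% c("CD3", "CD8") & !d$missing, ]
    dm_cuts <- vapply(dm$marker, function(m) cutoff_for(cuts, m, "DM"),
                      numeric(1))
    dmscore <- sum(flag_density(dm$density, dm_cuts))
    expect_equal(both$score.IS_M[both$patient_id == p],
                 both$score.IS[both$patient_id == p] + dmscore)
  }
})

test_that("distribution summaries round percentages half-up to one decimal", {
  d <- score_distribution(rep(0:4, c(11, 38, 47, 83, 14)), "IS")
  expect_equal(d$n, 193L)
  expect_equal(d$n_low, 96L)
  expect_equal(d$pct_low, 49.7)
  expect_equal(d$categories$pct, c(5.7, 19.7, 24.4, 43.0, 7.3))
  expect_error(score_distribution(c(1, 5), "IS"), "range")
  expect_equal(round_half_up(c(0.05, 0.15, -0.05), 1), c(0.1, 0.2, -0.1))
})
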