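test_that("write/read round-trips a cohort, including lost cores", {
  coh <- generate_cohort(cohort_config(n_patients = 40, seed = 7))
  dp <- tempfile(fileext = ".csv"); cp <- tempfile(fileext = ".csv")
  write_cohort(coh, dp, cp)
  back <- read_cohort(dp, cp)

  sort_dens <- function(d) {
    d <- d[order(d$patient_id, d$marker, d$region),
           c("patient_id", "marker", "region", "metastatic_site",
             "density", "missing")]
    rownames(d) <- NULL
    d
  }
  expect_equal(sort_dens(back$densities), sort_dens(coh$densities))

  ord <- function(d) { d <- d[order(d$patient_id), ]; rownames(d) <- NULL; d }
  expect_equal(ord(back$survival), ord(coh$survival))
  expect_equal(ord(back$clinical)[names(coh$clinical)], ord(coh$clinical))
})

test_that("blank density cells and absent region rows become lost cores", {
  dp <- tempfile(fileext = ".csv"); cp <- tempfile(fileext = ".csv")
  coh <- tiny_cohort()
  write_cohort(coh, dp, cp)
  back <- read_cohort(dp, cp)
  d <- back$densities
  # P2 lost the whole IM core: every marker of that region is missing
  expect_true(all(d$missing[d$patient_id == "P2" & d$region == "IM"]))
  expect_true(all(is.na(d$density[d$patient_id == "P2" & d$region == "IM"])))
  expect_false(any(d$missing[d$patient_id == "P1"]))

  # drop P3's DM rows entirely from the file: the reader must synthesize
  # missing records for all six markers of that region
  raw <- read.csv(dp, stringsAsFactors = FALSE)
  raw <- raw[!(raw$patient_id == "P3" & raw$region == "DM"), ]
  write.csv(raw, dp, row.names = FALSE, na = "")
  back2 <- read_cohort(dp, cp)
  d2 <- back2$densities
  expect_equal(sum(d2$patient_id == "P3" & d2$region == "DM"), 6L)
  expect_true(all(d2$missing[d2$patient_id == "P3" & d2$region == "DM"]))
})

test_that("malformed inputs are rejected with row-identifying messages", {
  dp <- tempfile(fileext = ".csv"); cp <- tempfile(fileext = ".csv")
  write_cohort(tiny_cohort(), dp, cp)

  raw <- read.csv(dp, stringsAsFactors = FALSE)
  bad <- raw; bad$density[bad$patient_id == "P1" & bad$marker == "CD3" &
                          bad$region == "CT"] <- -5
  f <- tempfile(fileext = ".csv"); write.csv(bad, f, row.names = FALSE, na = "")
  expect_error(read_cohort(f, cp), "negative density.*P1.*CD3")

  bad <- rbind(raw, raw[1, ])
  write.csv(bad, f, row.names = FALSE, na = "")
  expect_error(read_cohort(f, cp), "duplicate")

  bad <- raw; bad$marker[1] <- "CD99"
  write.csv(bad, f, row.names = FALSE, na = "")
  expect_error(read_cohort(f, cp), "invalid marker")

  bad <- raw[, setdiff(names(raw), "region")]
  write.csv(bad, f, row.names = FALSE, na = "")
  expect_error(read_cohort(f, cp), "lacks column")
})

test_that("marker families determine units and are closed enums", {
  expect_equal(unname(marker_family(c("CD3", "CD163"))),
               c("lymphocyte", "macrophage"))
  expect_equal(unname(marker_unit(c("CD8", "CD68"))),
               c("cells_per_mm2", "pixels_per_mm2"))
  expect_error(marker_family("CD45RO"), "invalid marker")
})

test_that("evaluable patient sets mirror the lost-core structure", {
  coh <- tiny_cohort()
  is_comp <- score_model("IS")$components
  ism_comp <- score_model("IS_M")$components
  # P2 lost IM (an IS component region), P3 lost only DM
  expect_equal(evaluable_patients(coh, is_comp), c("P1", "P3"))
  expect_equal(evaluable_patients(coh, ism_comp), "P1")
  expect_error(evaluable_patients(coh, is_comp[0, ]), "non-empty")

  # no missing data: every patient evaluable
  full <- generate_cohort(cohort_config(25, seed = 3,
                                        missing_core_rates = c(primary = 0,
                                                               dm = 0)))
  expect_equal(length(evaluable_patients(full, ism_comp)), 25L)
})

test_that("evaluable_patients is antitone in the component list", {
  coh <- generate_cohort(cohort_config(60, seed = 11,
                                       missing_core_rates = c(primary = 0.1,
                                                              dm = 0.1)))
  all_comp <- expand.grid(marker = markers(), region = regions(),
                          stringsAsFactors = FALSE)
  set.seed(20)
  for (i in 1:10) {
    k <- sample(1:(nrow(all_comp) - 1), 1)
    idx <- sample(nrow(all_comp), k + 1)
    smaller <- evaluable_patients(coh, all_comp[idx[1:k], ])
    larger <- evaluable_patients(coh, all_comp[idx, ])
    expect_true(all(larger %in% smaller))
  }
})

test_that("cohort validation enforces key and enum invariants", {
  coh <- tiny_cohort()
  clin2 <- coh$clinical; clin2$patient_id[3] <- "P9"
  expect_error(cohort(clin2, coh$survival, coh$densities), "identical patient_id")
  surv2 <- coh$survival; surv2$time_months[1] <- 0
  expect_error(cohort(coh$clinical, surv2, coh$densities), "positive")
  dens2 <- coh$densities
  dens2$metastatic_site[dens2$region == "CT"][1] <- "liver"
  expect_error(cohort(coh$clinical, coh$survival, dens2), "DM rows")
})

test_that("result bundles round-trip through the output directory", {
  out <- tempfile("bundle_")
  coh <- generate_cohort(cohort_config(30, seed = 2))
  cuts <- build_cutoff_table(coh, method = "median")
  scores <- classify_cohort(coh, cuts)
  files <- write_results(list(cutoffs = cuts, scores = scores,
                              meta = list(seed = 2)), out)
  expect_true(all(file.exists(files)))
  back <- read.csv(file.path(out, "scores.csv"), stringsAsFactors = FALSE)
  expect_equal(back$score, scores$score)
  js <- jsonlite::read_json(file.path(out, "cutoffs.json"))
  expect_equal(length(js), nrow(cuts))
  expect_equal(js[["CD3.CT"]]$cutoff, cutoff_for(cuts, "CD3", "CT"),
               tolerance = 1e-12)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 2L)

  # empty bundle still leaves a manifest
  out2 <- tempfile("bundle_")
  files2 <- write_results(list(), out2)
  expect_equal(basename(files2), "manifest.json")
})
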