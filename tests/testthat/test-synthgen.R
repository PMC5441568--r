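# Synthetic cohort generator: atlas invariants, time-course spectra
# (periodogram oracle), cohort structure and truth bookkeeping, disk
# round-trip.

test_that("atlas blobs are dispersed, unit-peak and deterministic", {
  a <- make_atlas(c(16, 16, 8), k = 20, seed = 1)
  expect_equal(nrow(a$maps), 20L)
  expect_true(all(a$maps >= 0))
  expect_equal(unname(apply(a$maps, 1, max)), rep(1, 20))
  R <- cor(t(a$maps))
  expect_lt(max(abs(R[upper.tri(R)])), 0.3)
  expect_identical(a, make_atlas(c(16, 16, 8), k = 20, seed = 1))
  expect_false(identical(a$centers, make_atlas(c(16, 16, 8), k = 20, seed = 2)$centers))
  expect_identical(a$labels[a$anchors], c("DMN", "MTL"))
  expect_length(a$affected, 6L)
})

test_that("atlas rejects invalid configurations", {
  expect_error(make_atlas(c(4, 4, 1), k = 20, seed = 1), "too small")
  expect_error(make_atlas(c(16, 16, 8), k = 1), "k")
  expect_error(make_atlas(c(16, 16), k = 5), "grid_shape")
})

test_that("time courses are normalized, orthogonal and band-limited", {
  tc <- simulate_time_courses(20, 240, 2, seed = 7)
  expect_equal(dim(tc), c(20L, 240L))
  expect_lt(max(abs(rowMeans(tc))), 1e-10)
  expect_lt(max(abs(apply(tc, 1, var) - 1)), 1e-10)
  cc <- cor(t(tc))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.2)
  bf <- apply(tc, 1, band_fraction, tr = 2)     # periodogram oracle
  expect_true(all(bf >= 0.8))
  expect_identical(tc, simulate_time_courses(20, 240, 2, seed = 7))
  expect_error(simulate_time_courses(2, 10, 2), "n_volumes")
})

test_that("cohort structure matches the study design", {
  # Defaults state the emulated design exactly.
  cfg <- cohort_config()
  expect_equal(cfg$n_patients, 34L)
  expect_equal(cfg$n_controls, 34L)
  expect_equal(cfg$n_followup_ect, 13L)
  expect_equal(cfg$n_followup_med, 16L)
  expect_equal(cfg$n_volumes, 240L)
  expect_equal(cfg$tr_seconds, 2)
  expect_equal(cfg$k_components, 20L)
  expect_error(cohort_config(delta = -1), "delta")
  expect_error(cohort_config(n_patients = 5, n_followup_ect = 4, n_followup_med = 3),
               "follow-ups")

  # Scan/record counts at the default design (reduced volumes/grid to keep
  # the fixture light; counts do not depend on either).
  a <- make_atlas(c(12, 12, 8), k = 10, seed = 5, n_affected = 6)
  cfg <- cohort_config(n_volumes = 40, k_components = 10, seed = 9)
  co <- simulate_cohort(a, cfg)
  expect_length(co$scans, 68L + 29L)
  expect_equal(sum(co$records$session == "baseline"), 68L)
  expect_equal(sum(co$records$session == "followup"), 29L)
  fu <- co$records[co$records$session == "followup", ]
  expect_equal(sum(fu$arm == "ECT"), 13L)
  expect_equal(sum(fu$arm == "MED"), 16L)
  # every follow-up has a matching baseline
  expect_true(all(paste(fu$subject_id, "baseline", sep = "_") %in% names(co$scans)))
  # baseline PANSS near the printed mean
  base_p <- co$records[co$records$session == "baseline" & co$records$group == "patient", ]
  expect_gt(mean(base_p$panss_total), 75)
  expect_lt(mean(base_p$panss_total), 86)
  expect_equal(base_p$panss_total, base_p$panss_pos + base_p$panss_neg + base_p$panss_gen)
  expect_error(simulate_cohort(a, cohort_config(k_components = 10, affected = c(1, 99))),
               "affected")
})

test_that("truth records every planted quantity", {
  co <- small_cohort()
  k <- co$config$k_components
  expect_equal(nrow(co$truth$loadings), k * length(co$scans))
  expect_true(all(co$truth$affected %in% seq_len(k)))
  expect_true(all(co$truth$signs[co$truth$affected] %in% c(-1L, 1L)))
  rho <- co$truth$rho
  fu_ids <- unique(co$records$subject_id[co$records$session == "followup"])
  expect_true(all(!is.na(rho$rho[rho$subject_id %in% fu_ids])))
  expect_true(all(rho$rho >= 0 & rho$rho <= 1, na.rm = TRUE))
  # patient baseline loadings deviate from 1 by about sign*delta on affected comps
  ld <- co$truth$loadings
  pat_base <- ld[ld$session == "baseline" & grepl("^PAT", ld$subject_id) &
                   ld$component %in% co$truth$affected, ]
  for (cc in co$truth$affected) {
    dev <- mean(pat_base$loading[pat_base$component == cc]) - 1
    expect_equal(sign(dev), co$truth$signs[cc])
  }
  # follow-up loadings moved toward 1 on affected components
  some_fu <- co$records$subject_id[co$records$session == "followup"][1]
  lb <- ld[ld$subject_id == some_fu & ld$session == "baseline", "loading"]
  lf <- ld[ld$subject_id == some_fu & ld$session == "followup", "loading"]
  aff <- co$truth$affected
  expect_lt(mean(abs(lf[aff] - 1)), mean(abs(lb[aff] - 1)) + 0.05)
  # true subject maps are reconstructible
  tm <- true_subject_maps(co, some_fu)
  expect_equal(dim(tm), dim(co$atlas$maps))
  expect_error(true_subject_maps(co, "NOPE"), "unknown subject")
})

test_that("delta = 0 leaves patient and control scan distributions identical", {
  a <- make_atlas(c(10, 10, 4), k = 4, seed = 4, n_affected = 2)
  cfg <- cohort_config(n_patients = 6, n_controls = 6, n_followup_ect = 1,
                       n_followup_med = 1, n_volumes = 40, k_components = 4,
                       delta = 0, seed = 8)
  co <- simulate_cohort(a, cfg)
  ld <- co$truth$loadings
  base <- ld[ld$session == "baseline", ]
  pat <- base$loading[grepl("^PAT", base$subject_id)]
  ctl <- base$loading[grepl("^CTL", base$subject_id)]
  # same generative law: both N(1, 0.1); compare moments loosely
  expect_lt(abs(mean(pat) - mean(ctl)), 0.08)
  expect_gt(stats::t.test(pat, ctl)$p.value, 0.01)
})

test_that("cohorts are deterministic given the seed", {
  a <- make_atlas(c(10, 10, 4), k = 4, seed = 4, n_affected = 2)
  cfg <- cohort_config(n_patients = 4, n_controls = 4, n_followup_ect = 1,
                       n_followup_med = 1, n_volumes = 40, k_components = 4, seed = 12)
  co1 <- simulate_cohort(a, cfg)
  co2 <- simulate_cohort(a, cfg)
  expect_identical(co1$records, co2$records)
  expect_identical(co1$scans[[3]]$data, co2$scans[[3]]$data)
  expect_identical(co1$truth$loadings, co2$truth$loadings)
})

test_that("write_cohort round-trips through the readers", {
  co <- small_cohort()
  dir <- tempfile("cohort_")
  mf <- write_cohort(co, dir)
  n_scans <- length(co$scans)
  expect_equal(mf$n_scans, n_scans)
  expect_equal(nrow(mf$files), 2L * n_scans + 3L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  loaded <- read_cohort(dir)
  expect_equal(nrow(loaded$records), nrow(co$records))
  key <- names(co$scans)[5]
  expect_lt(max(abs(loaded$scans[[key]]$data - co$scans[[key]]$data)), 1e-6)
  expect_equal(loaded$nuisance[[key]]$wm, unname(co$nuisance[[key]]$wm),
               tolerance = 1e-10)
  empty <- co; empty$scans <- list()
  expect_error(write_cohort(empty, tempfile()), "empty cohort")
})
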