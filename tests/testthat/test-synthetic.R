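test_that("cell generation respects class contracts and determinism", {
  c1 <- generate_cell("control", seed = 42)
  c2 <- generate_cell("control", seed = 42)
  expect_identical(c1$matrix, c2$matrix)          # determinism
  expect_identical(c1$record, c2$record)
  expect_null(c1$log$dots)                        # controls carry no dots
  expect_equal(c1$log$patch_px, 0L)               # and no patch
  expect_error(generate_cell("reticulocyte"), "unknown cell class")

  s1 <- generate_cell("sickled", seed = 7)
  expect_gt(s1$log$patch_px, 0L)                  # sickled cells have a patch
  # elongated footprint: ROI wider than tall by the axis ratio
  expect_gt(roi_width(s1$roi) / roi_height(s1$roi), 2.5)
})

test_that("the ROI lies strictly inside the cell footprint", {
  # with the plasma pushed far above any possible cytoplasm value, a ROI
  # pixel at background level would mean the rectangle left the cell
  p <- flim_default_params(background_lifetime_ps = 1500)
  for (cls in c("control", "nonsickled", "sickled")) {
    g <- generate_cell(cls, p, seed = 11)
    roi <- extract_roi(g$matrix, g$roi)
    expect_lt(max(roi), 900)
    expect_false(anyNA(roi))
  }
})

test_that("dot placement follows the configured count range", {
  p <- flim_default_params()
  counts <- vapply(1:300, function(s) {
    g <- generate_cell("nonsickled", p, seed = s)
    if (is.null(g$log$dots)) 0L else nrow(g$log$dots)
  }, integer(1))
  expect_setequal(sort(unique(counts)), 0:3)
  expect_true(all(counts >= 0 & counts <= 3))
  # fixed range is honored exactly
  p2 <- flim_default_params(dot_count_range = c(2L, 2L))
  g <- generate_cell("nonsickled", p2, seed = 5)
  expect_equal(nrow(g$log$dots), 2L)
})

test_that("class moments are recovered and ordered across the cohort", {
  p <- flim_default_params()
  n <- 80
  stats <- lapply(c("control", "nonsickled", "sickled"), function(cls) {
    ms <- vapply(seq_len(n), function(s) {
      g <- generate_cell(cls, p, seed = 1000 + s)
      roi <- extract_roi(g$matrix, g$roi)
      c(mean(roi), sd(roi))
    }, numeric(2))
    list(mean = mean(ms[1, ]), se_mean = sd(ms[1, ]) / sqrt(n),
         sd = mean(ms[2, ]), se_sd = sd(ms[2, ]) / sqrt(n))
  })
  names(stats) <- c("control", "nonsickled", "sickled")
  for (cls in names(stats)) {
    expect_lt(abs(stats[[cls]]$mean - p$class_means_ps[[cls]]),
              3 * stats[[cls]]$se_mean)
    expect_lt(abs(stats[[cls]]$sd - p$class_sds_ps[[cls]]),
              3 * stats[[cls]]$se_sd)
  }
  expect_lt(stats$control$mean, stats$nonsickled$mean)
  expect_lt(stats$nonsickled$mean, stats$sickled$mean)
})

test_that("raising the dot offset raises the upper lifetime tail", {
  # dots must cover > 5% of the ROI for p95 to sit inside the dot mass;
  # the per-cell moment calibration otherwise reallocates the tail into
  # noise (three dots of radius 3 cover ~8% of the default ROI)
  p_lo <- flim_default_params(dot_count_range = c(3L, 3L), dot_radius_px = 3,
                              dot_lifetime_offset_ps = 60)
  p_hi <- flim_default_params(dot_count_range = c(3L, 3L), dot_radius_px = 3,
                              dot_lifetime_offset_ps = 150)
  d <- vapply(1:40, function(s) {
    g_lo <- generate_cell("nonsickled", p_lo, seed = s)
    g_hi <- generate_cell("nonsickled", p_hi, seed = s)
    percentile(as.vector(extract_roi(g_hi$matrix, g_hi$roi)), 0.95) -
      percentile(as.vector(extract_roi(g_lo$matrix, g_lo$roi)), 0.95)
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("cohorts have the requested layout and reproduce bit-identically", {
  p <- flim_default_params()
  co <- generate_cohort(c(control = 3L, scd = 4L),
                        c(control = 4L, nonsickled = 3L, sickled = 2L),
                        p, seed = 9)
  tb <- table(co$manifest$subtype)
  expect_equal(unname(tb[c("control", "nonsickled", "sickled")]),
               c(3L * 4L, 4L * 3L, 4L * 2L), ignore_attr = TRUE)
  expect_equal(length(unique(co$manifest$patient_id)), 7L)
  # patient ids nested within groups
  expect_true(all(grepl("^C", co$manifest$patient_id[co$manifest$group == "control"])))
  expect_true(all(grepl("^P", co$manifest$patient_id[co$manifest$group == "SCD"])))
  co2 <- generate_cohort(c(control = 3L, scd = 4L),
                         c(control = 4L, nonsickled = 3L, sickled = 2L),
                         p, seed = 9)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$cells[[5]]$matrix, co2$cells[[5]]$matrix)
  expect_error(generate_cohort(c(control = 0L, scd = 2L),
                               c(control = 1L, nonsickled = 1L, sickled = 0L),
                               p, seed = 1),
               "at least one patient")
})

test_that("written cohorts parse round-trip through the manifest", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(c(control = 2L, scd = 2L),
                        c(control = 2L, nonsickled = 2L, sickled = 1L),
                        flim_default_params(), seed = 3, out_dir = dir)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), nrow(co$manifest))
  for (i in seq_len(nrow(man))) {
    m <- read_lifetime_matrix(file.path(dir, man$path[i]))
    expect_identical(m, co$cells[[man$cell_id[i]]]$matrix)
    roi <- extract_roi(m, manifest_roi(man[i, ]))
    expect_false(anyNA(roi))
  }
})

test_that("generator parameter invariants are enforced", {
  expect_error(flim_default_params(background_lifetime_ps = 100),
               "must exceed")
  expect_error(flim_default_params(dot_count_range = c(3L, 1L)),
               "nondecreasing")
  expect_error(flim_default_params(patch_area_fraction = c(0.5, 0.4)),
               "increasing pair")
  expect_error(flim_default_params(class_sds_ps = c(control = -1,
                                                    nonsickled = 1,
                                                    sickled = 1)),
               "strictly positive")
  expect_s3_class(flim_default_params(), "flim_gen_params")
})
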