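test_that("tsv lifetime matrices round-trip bit-exactly", {
  set.seed(11)
  m <- matrix(runif(12, 100, 400), 3, 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lifetime_matrix(m, f)
  expect_identical(read_lifetime_matrix(f), m)

  m1 <- matrix(175.5, 1, 1)
  write_lifetime_matrix(m1, f)
  expect_identical(read_lifetime_matrix(f), m1)

  # NaN-masked pixels survive the round trip
  m[2, 2] <- NaN
  write_lifetime_matrix(m, f)
  expect_identical(read_lifetime_matrix(f), m)
})

test_that("tiff matrices round-trip within float32 precision", {
  set.seed(12)
  m <- matrix(runif(30, 100, 400), 5, 6)
  f <- withr::local_tempfile(fileext = ".tif")
  write_lifetime_matrix(m, f)
  r <- read_lifetime_matrix(f)
  expect_equal(dim(r), dim(m))
  expect_lt(max(abs(r - m) / m), 1e-6)
  # lifetimes beyond the TIFF nanosecond range are refused, not clipped
  expect_error(write_lifetime_matrix(matrix(1500, 2, 2), f), "1000 ps")
})

test_that("malformed matrix files are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2\t3", "4\t5"), f)
  expect_error(read_lifetime_matrix(f), "ragged")
  writeLines(c("1\t2", "3\tx"), f)
  expect_error(read_lifetime_matrix(f), "non-numeric")
  expect_error(read_lifetime_matrix("no/such/file.tsv"), "no such file")
  expect_error(write_lifetime_matrix(matrix(-1, 2, 2), f), "nonnegative")
})

test_that("extract_roi follows the 0-based half-open convention", {
  m <- matrix(1:16, 4, 4)
  storage.mode(m) <- "double"
  expect_identical(extract_roi(m, roi_rect(0, 0, 4, 4)), m)
  expect_identical(extract_roi(m, roi_rect(1, 1, 3, 3)), m[2:3, 2:3])
  one <- extract_roi(m, roi_rect(2, 1, 3, 2))
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one[1, 1], m[2, 3])
  expect_error(extract_roi(m, roi_rect(1, 1, 5, 3)), "bounds")
  expect_error(roi_rect(2, 0, 2, 3), "x1 > x0")
})

test_that("ROI extraction agrees with manual slicing for downstream stats", {
  set.seed(13)
  m <- matrix(runif(400, 100, 300), 20, 20)
  r <- roi_rect(3, 5, 15, 18)
  s1 <- histogram_stats(extract_roi(m, r))
  s2 <- histogram_stats(m[6:18, 4:15])
  expect_equal(unclass(s1), unclass(s2))
})

test_that("manifests round-trip and validate their schema", {
  rec <- data.frame(
    cell_id = c("a", "b", "c"), patient_id = c("P1", "P1", "P2"),
    group = c("SCD", "SCD", "control"),
    subtype = c("nonsickled", "sickled", "control"),
    shape_class = c("round", "sickled", "round"),
    roi_x0 = 1L, roi_y0 = 2L, roi_x1 = 10L, roi_y1 = 12L,
    path = c("a.tsv", "b.tsv", "c.tsv"),
    extra_note = c("x", "y", "z"),           # unknown column preserved
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(rec, f)
  back <- read_manifest(f)
  expect_equal(back, rec)

  write_manifest(rec, f)
  txt <- readLines(f)
  writeLines(txt[1], f)                       # header-only manifest
  expect_equal(nrow(read_manifest(f)), 0L)

  expect_error(write_manifest(rec[setdiff(names(rec), "roi_x0")], f),
               "roi_x0")
  utils::write.table(rec[setdiff(names(rec), "patient_id")], f,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest(f), "patient_id")
})
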