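test_that("trial construction validates inputs and converts units", {
  arr <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  tr <- trial(arr, c("A", "B", "C"), rate = 250)
  expect_s3_class(tr, "trial")
  expect_equal(dim(tr$data), c(2L, 3L, 3L))

  arr_m <- array(0.25, c(1, 1, 3))
  tr_m <- trial(arr_m, "A", rate = 100, units = "m")
  expect_equal(unname(tr_m$data[1, 1, 1]), 250)

  expect_error(trial(arr, c("A", "B"), rate = 250), "marker names")
  expect_error(trial(arr, c("A", "A", "B"), rate = 250), "duplicate")
  expect_error(trial(arr, c("A", "B", "C"), rate = -1), "rate")
  expect_error(trial(arr, c("A", "B", "C"), rate = 250, label = "pirouette"),
               "unknown trial label")
})

test_that("write/read round-trips coordinates to 1e-9 mm and restores gaps", {
  set.seed(1)
  arr <- array(rnorm(20 * 4 * 3, sd = 500), c(20, 4, 3))
  arr[3, 2, ] <- NA  # a flagged gap
  tr <- trial(arr, c("CAL", "SUS", "HDL", "NAV"), rate = 250, label = "saute")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial(tr, path)
  tr2 <- read_trial(path)
  expect_equal(tr2$markers, tr$markers)
  expect_equal(tr2$rate, 250)
  expect_equal(tr2$label, "saute")
  expect_lt(max(abs(tr2$data - tr$data)), 1e-9)
  expect_identical(tr2$gaps, tr$gaps)
})

test_that("a hand-written TSV fixture parses with the declared header keys", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rate_hz\t250", "units\tmm", "up_axis\tz", "label\tnatural",
    "side\tright",
    "frame\ttime\tA_X\tA_Y\tA_Z\tB_X\tB_Y\tB_Z\tC_X\tC_Y\tC_Z",
    paste(c(0, 0, 1:9), collapse = "\t"),
    paste(c(1, 0.004, 10:18), collapse = "\t")), path)
  tr <- read_trial(path)
  expect_equal(dim(tr$data), c(2L, 3L, 3L))
  expect_equal(tr$markers, c("A", "B", "C"))
  expect_equal(unname(tr$data[2, 1, 2]), 11)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("units\tmm", "frame\ttime\tA_X\tA_Y\tA_Z", "0\t0\t1\t2\t3"), bad)
  expect_error(read_trial(bad), "missing header field")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rate_hz\t250", "units\tmm", "up_axis\tz",
               "frame\ttime\tA_X\tA_Y\tA_Z\tA_X\tA_Y\tA_Z",
               "0\t0\t1\t2\t3\t4\t5\t6"), dup)
  expect_error(read_trial(dup), "duplicate marker")
  expect_error(read_trial("no-such-file.tsv"), "not found")
  expect_error(read_trial(path, format = "c3d"), "not supported")
})

test_that("a generated saute trial survives the on-disk round trip", {
  cfg <- quick_config(seed = 3, noise_sd = 0.5)
  gt <- generate_trial(cfg, "saute")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial(gt$trial, path)
  expect_gt(file.size(path), 0)
  tr2 <- read_trial(path)
  expect_equal(tr2$rate, 250)
  expect_lt(max(abs(tr2$data - gt$trial$data)), 1e-9)
})

test_that("trial validation reports missing markers and gap fractions", {
  schema <- default_marker_schema()
  cfg <- quick_config(seed = 4)
  tr <- generate_trial(cfg, "natural")$trial
  rep_full <- validate_trial(tr, schema, calibration = TRUE)
  expect_true(rep_full$pass)
  expect_length(rep_full$missing, 0)

  drop_hal <- tr
  keep <- tr$markers != "HAL"
  drop_hal$markers <- tr$markers[keep]
  drop_hal$data <- tr$data[, keep, , drop = FALSE]
  drop_hal$gaps <- tr$gaps[, keep, drop = FALSE]
  rep_miss <- validate_trial(drop_hal, schema)
  expect_false(rep_miss$pass)
  expect_equal(rep_miss$missing, "HAL")

  # 2% gaps on CAL with a 5% threshold: pass, with a warning note
  gappy <- tr
  idx <- match("CAL", tr$markers)
  gappy$gaps[1:ceiling(0.02 * n_frames(tr)), idx] <- TRUE
  rep_gap <- validate_trial(gappy, schema, gap_threshold = 0.05)
  expect_true(rep_gap$pass)
  expect_match(paste(rep_gap$warnings, collapse = " "), "CAL")

  # validation is monotone: removing a marker never un-reports another
  rep2 <- validate_trial(drop_hal, schema)
  keep2 <- drop_hal$markers != "NAV"
  drop_two <- drop_hal
  drop_two$markers <- drop_hal$markers[keep2]
  drop_two$data <- drop_hal$data[, keep2, , drop = FALSE]
  drop_two$gaps <- drop_hal$gaps[, keep2, drop = FALSE]
  rep3 <- validate_trial(drop_two, schema)
  expect_true(all(rep2$missing %in% rep3$missing))
})

test_that("the schema owns each virtual marker exactly once", {
  schema <- default_marker_schema()
  expect_true(all(c("CAL", "SUS", "HDL") %in%
                    schema$segments$hindfoot$anatomical))
  expect_true(all(c("MTB1", "MT1", "MTS1", "MTS2") %in%
                    schema$segments$first_metatarsal$anatomical))
  expect_true("MT5" %in% schema$segments$forefoot$anatomical)
  expect_true("HAL" %in% schema$segments$hallux$anatomical)
  expect_true("NAV" %in% schema$segments$midfoot$anatomical)
  expect_false(anyDuplicated(names(schema$virtual_markers)) > 0)
  expect_true(all(schema$virtual_markers %in% names(schema$segments)))
})
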