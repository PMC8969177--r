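small_plate <- function(plate_type = 48, duration_s = 0.5, seed = 3,
                        included = c("A1", "B2")) {
  sc <- plate_scenario(plate_type = plate_type, duration_s = duration_s,
                       included_wells = included,
                       model = train_model("tonic_poisson", tonic_rate_hz = 20))
  generate_plate(sc, seed = seed)$plate
}

test_that("HDF5 write/read round trip preserves traces and metadata", {
  plate <- small_plate()
  f <- withr::local_tempfile(fileext = ".h5")
  write_plate(plate, f)
  back <- read_plate(f)
  expect_identical(back$metadata$plate_type, 48L)
  expect_equal(back$metadata$duration_s, plate$metadata$duration_s)
  expect_equal(back$metadata$sampling_frequency_hz, 12500)
  expect_identical(sort(back$metadata$excluded_wells),
                   sort(plate$metadata$excluded_wells))
  expect_identical(names(back$wells), sort(names(plate$wells)))
  # traces agree within 32-bit storage precision
  for (w in names(plate$wells)) {
    expect_equal(back$wells[[w]][["11"]], plate$wells[[w]][["11"]],
                 tolerance = 1e-6)
  }
  # a second trip is bit-identical (values already representable)
  f2 <- withr::local_tempfile(fileext = ".h5")
  write_plate(back, f2)
  expect_identical(read_plate(f2)$wells, back$wells)
})

test_that("well groups hold one dataset per electrode (64 / 16 by geometry)", {
  f <- withr::local_tempfile(fileext = ".h5")
  write_plate(small_plate(48, included = "A1"), f)
  ls <- rhdf5::h5ls(f)
  expect_equal(sum(ls$group == "/Data/A1"), 16L)
  sc12 <- plate_scenario(plate_type = 12, duration_s = 0.2,
                         included_wells = "A3",
                         model = train_model("tonic_poisson", tonic_rate_hz = 5))
  f12 <- withr::local_tempfile(fileext = ".h5")
  write_plate(generate_plate(sc12, seed = 1)$plate, f12)
  ls12 <- rhdf5::h5ls(f12)
  expect_equal(sum(ls12$group == "/Data/A3"), 64L)
})

test_that("fully excluded plate writes an empty /Data and lists all wells", {
  md <- recording_metadata(duration_s = 1, plate_type = 12L,
                           excluded_wells = well_labels(12))
  plate <- mea_plate(list(), md)
  f <- withr::local_tempfile(fileext = ".h5")
  write_plate(plate, f)
  ls <- rhdf5::h5ls(f)
  expect_equal(sum(ls$group == "/Data"), 0L)
  back <- read_plate(f)
  expect_setequal(back$metadata$excluded_wells, well_labels(12))
})

test_that("excluded-well and inactive-electrode lookups raise errors", {
  plate <- small_plate(included = "A1")
  expect_error(plate_trace(plate, "A2", "11"), "excluded")
  md <- plate$metadata
  md$inactive_channels <- data.frame(well = "A1", electrode = "12")
  plate2 <- plate
  plate2$metadata <- md
  plate2$wells$A1[["12"]] <- NULL
  expect_error(plate_trace(plate2, "A1", "12"), "inactive")
  expect_silent(validate_plate(plate2))
  # invariant violation names the offending electrode
  plate_bad <- plate
  plate_bad$wells$A1[["11"]] <- plate_bad$wells$A1[["11"]][-1]
  expect_error(write_plate(plate_bad, withr::local_tempfile()), "A1 electrode 11")
})

test_that("a file missing a metadata attribute is rejected by name", {
  plate <- small_plate(included = "A1")
  f <- withr::local_tempfile(fileext = ".h5")
  write_plate(plate, f)
  fid <- rhdf5::H5Fopen(f)
  gid <- rhdf5::H5Gopen(fid, "DataInfo")
  rhdf5::H5Adelete(gid, "DurationInSec")
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  expect_error(read_plate(f), "DurationInSec")
})

test_that("spike CSV round trips rows, order and 6-decimal precision", {
  st <- spike_table(well = c("B1", "A1", "A1"), electrode = c("11", "12", "11"),
                    time_s = c(1.5, 0.25, 0.000123))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spike_csv(st, f)
  back <- read_spike_csv(f)
  expect_equal(nrow(back), 3L)
  expect_identical(back$well, c("A1", "A1", "B1"))
  expect_true(0.000123 %in% back$time_s)
  # empty table -> header-only file
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_spike_csv(spike_table(), f0)
  expect_identical(readLines(f0), "well,electrode,time_s")
  expect_equal(nrow(read_spike_csv(f0)), 0L)
})

test_that("noisy-electrode and experiment-log readers validate and dedupe", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,electrode", "A1,11", "A1,11", "B2,21"), f)
  ne <- read_noisy_electrodes(f, plate_type = 48)
  expect_equal(nrow(ne), 2L)
  writeLines(c("well,electrode", "Z9,11"), f)
  expect_error(read_noisy_electrodes(f, plate_type = 48), "Z9")
  writeLines("well,electrode", f)
  expect_equal(nrow(read_noisy_electrodes(f)), 0L)
  fe <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,treatment", "A1,Baseline", "A2,TTX"), fe)
  log <- read_explog(fe, plate_type = 48)
  expect_identical(log$treatment, c("Baseline", "TTX"))
})

test_that("feature tables use canonical names, omit empty wells, round trip", {
  vals <- matrix(c(1.5, NA, 2.5, NA), nrow = 2,
                 dimnames = list(c("A1", "A2"), c("DIV21", "DIV24")))
  d <- withr::local_tempdir()
  path <- write_feature_table(vals, "bursts_per_min", "hPSC_20517_MEA1", d)
  expect_true(file.exists(file.path(d, "hPSC_20517_MEA1_bursts_per_min.csv")))
  back <- read_feature_table(path)
  expect_identical(rownames(back), "A1")  # A2 has no value at any DIV
  expect_equal(back["A1", ], c(DIV21 = 1.5, DIV24 = 2.5))
  expect_error(write_feature_table(vals, "not_a_feature", "x", d),
               "meanfiringrate_by_active_electrodes")
})
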