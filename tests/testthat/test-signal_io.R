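test_that("plain-text signals round-trip losslessly", {
  path <- withr::local_tempfile(fileext = ".txt")
  set.seed(101)
  vals <- round(rnorm(2000, sd = 40), 6)
  write_signal_text(eeg_channel(vals, fs = 200), path)
  ch <- read_signal_text(path, fs = 200, label = "Cz")
  expect_s3_class(ch, "eeg_channel")
  expect_length(ch, 2000)
  expect_equal(ch$samples, vals)
  expect_equal(ch$fs, 200)

  tiny <- withr::local_tempfile()
  writeLines(c("0.0", "1.0", "-1.0"), tiny)
  expect_equal(read_signal_text(tiny, fs = 200)$samples, c(0, 1, -1))
})

test_that("text reader rejects empty and non-numeric files", {
  empty <- withr::local_tempfile()
  file.create(empty)
  expect_error(read_signal_text(empty), "no numeric data")

  bad <- withr::local_tempfile()
  writeLines(c("1.0", "oops", "2.0"), bad)
  expect_error(read_signal_text(bad), "non-numeric")

  expect_error(read_signal_text(file.path(tempdir(), "nope.txt")), "not found")
})

test_that("EDF files written by the fixture round-trip", {
  path <- withr::local_tempfile(fileext = ".edf")
  set.seed(7)
  vals <- as.numeric(sample(-500:500, 2000, replace = TRUE))
  write_edf(eeg_channel(vals, fs = 200, label = "Cz"), path)
  ch <- read_edf(path, "Cz")
  expect_equal(ch$fs, 200)
  expect_length(ch, 2000)
  expect_equal(ch$samples, vals)  # integer microvolts survive quantization
  expect_equal(ch$label, "Cz")
  # index-based selection agrees with label-based
  expect_equal(read_edf(path, 1L)$samples, vals)
})

test_that("EDF errors are raised distinctly", {
  expect_error(read_edf(file.path(tempdir(), "absent.edf")), "not found")

  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(eeg_channel(as.numeric(1:400), fs = 200, label = "Cz"), path)
  expect_error(read_edf(path, "Fp1"), "unknown channel 'Fp1'")
  expect_error(read_edf(path, 4L), "unknown channel index")

  corrupt <- withr::local_tempfile(fileext = ".edf")
  writeLines("this is not an EDF header, just prose padding out some bytes",
             corrupt)
  expect_error(read_edf(corrupt), "corrupt EDF header")
})

test_that("multi-channel EDF keeps channels separate", {
  path <- withr::local_tempfile(fileext = ".edf")
  a <- eeg_channel(rep(c(-10, 10), 100), fs = 100, label = "Fp1")
  b <- eeg_channel(rep(c(5, -5), 100), fs = 100, label = "Cz")
  write_edf(list(a, b), path)
  expect_equal(read_edf(path, "Fp1")$samples, a$samples)
  expect_equal(read_edf(path, "Cz")$samples, b$samples)
})

test_that("annotation CSV parses, sorts and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("begin,end,label", "100,115,spike"), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$begin, 100L)
  expect_equal(ann$end, 115L)

  # out-of-order rows come back sorted by begin
  writeLines(c("begin,end,label", "500,515,spike", "100,115,spike",
               "300,315,spike"), path)
  expect_equal(read_annotations(path)$begin, c(100L, 300L, 500L))

  # round-trip of 56 synthetic events is exact
  set.seed(42)
  begins <- sort(sample.int(50000, 56))
  ann <- annotation_set(begins, begins + 15L)
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$begin, ann$begin)
  expect_equal(back$end, ann$end)
})

test_that("degenerate annotation intervals are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("begin,end,label", "115,100,spike"), path)
  expect_error(read_annotations(path), "begin < end")
  expect_error(annotation_set(10, 10), "begin < end")
})

test_that("detection CSV round-trips through write/read", {
  path <- withr::local_tempfile(fileext = ".csv")
  ev <- data.frame(begin = c(10L, 200L), end = c(170L, 360L),
                   score = c(0.91, -0.85), confirmed = c(TRUE, FALSE))
  write_detections(ev, path)
  back <- read_detections(path)
  expect_equal(back$begin, ev$begin)
  expect_equal(back$end, ev$end)
  expect_equal(back$score, ev$score)
  expect_equal(back$confirmed, ev$confirmed)
})
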