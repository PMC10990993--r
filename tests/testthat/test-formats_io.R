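test_that("image runs round-trip through NIfTI with header metadata", {
  set.seed(11)
  run <- image_run(array(runif(10 * 16 * 16), c(10, 16, 16)),
                   fps = 8, pixel_mm = c(2.5, 2.5), run_id = "rt")
  f <- withr::local_tempfile(fileext = ".nii")
  write_run(run, f)
  back <- read_run(f)
  expect_identical(dim(back$intensities), c(10L, 16L, 16L))
  expect_equal(back$intensities, run$intensities)
  expect_equal(back$pixel_mm, c(2.5, 2.5))
  expect_equal(back$fps, 8)
  expect_identical(back$run_id, "rt")
})

test_that("NIfTI pixel size is taken from the header when no sidecar exists", {
  arr <- array(runif(4 * 8 * 8), c(8, 8, 4))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(2.5, 2.5, 1)
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  expect_warning(back <- read_run(f), "fps")
  expect_equal(back$pixel_mm, c(2.5, 2.5))
})

test_that("frame axis is first in memory, last on disk, never reordered", {
  # distinct value per (frame,row,col) so any axis swap is caught
  arr <- array(seq_len(3 * 4 * 5), c(3, 4, 5))
  run <- image_run(arr, fps = 5)
  f <- withr::local_tempfile(fileext = ".nii")
  write_run(run, f)
  expect_equal(read_run(f)$intensities, arr)
})

test_that("TIFF runs round-trip at the 32-bit storage precision", {
  set.seed(3)
  run <- image_run(array(runif(5 * 12 * 12), c(5, 12, 12)), fps = 10)
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_run(run, f1)
  r1 <- read_run(f1)           # quantized to the 32-bit sample grid once
  expect_equal(r1$intensities, run$intensities, tolerance = 1e-9)
  write_run(r1, f2)
  r2 <- read_run(f2)
  # libtiff re-quantization wobbles by at most one least-significant step
  expect_lt(max(abs(r2$intensities - r1$intensities)), 2^-31)
  expect_identical(dim(r2$intensities), dim(run$intensities))
})

test_that("TIFF writer refuses out-of-range intensities", {
  run <- image_run(array(2, c(2, 4, 4)))
  expect_error(write_run(run, withr::local_tempfile(fileext = ".tif")),
               "\\[0, 1\\]")
})

test_that("raw dumps round-trip via their sidecar", {
  set.seed(5)
  run <- image_run(array(runif(4 * 6 * 7) * 10, c(4, 6, 7)), fps = 12,
                   pixel_mm = c(2, 3), run_id = "raw1")
  f <- withr::local_tempfile(fileext = ".bin")
  write_run(run, f)
  back <- read_run(f)
  expect_identical(back$intensities, run$intensities)
  expect_equal(back$pixel_mm, c(2, 3))
  expect_identical(back$run_id, "raw1")
})

test_that("unreadable and 2-D inputs produce informative format errors", {
  f <- withr::local_tempfile(fileext = ".nii")
  writeLines("not a nifti", f)
  suppressWarnings(expect_error(read_run(f), "NIfTI"))
  expect_error(read_run(file.path(tempdir(), "absent.nii")), "not found")
  img <- RNifti::asNifti(matrix(runif(16), 4, 4))
  f2 <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f2)
  expect_error(read_run(f2), "2-D")
})

test_that("CSV logfiles parse, validate, and order segments", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset,offset,label", "30,35,da", "10,20,ba"), f)
  log <- read_logfile(f)
  expect_equal(nrow(log), 2L)
  expect_equal(log$onset, c(10L, 30L))
  expect_equal(log$label, c("ba", "da"))

  writeLines(c("onset,offset,label"), f)
  expect_equal(nrow(read_logfile(f)), 0L)

  writeLines(c("onset,offset,label", "5,3,x"), f)
  expect_error(read_logfile(f), "row\\(s\\) 1")
  writeLines(c("onset,offset,label", "1.5,3,x"), f)
  expect_error(read_logfile(f), "non-integer")
  writeLines(c("onset,offset,label", "90,99,x"), f)
  expect_error(read_logfile(f, n_frames = 50), "outside")
})

test_that("TextGrid intervals convert to frames by floor/ceil at fps", {
  tg <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
          "xmin = 0", "xmax = 3", "tiers? <exists>", "size = 1",
          "item []:", "    item [1]:",
          '        class = "IntervalTier"', '        name = "phones"',
          "        xmin = 0", "        xmax = 3", "        intervals: size = 3",
          "        intervals [1]:", "            xmin = 0",
          "            xmax = 1.0", '            text = ""',
          "        intervals [2]:", "            xmin = 1.0",
          "            xmax = 2.0", '            text = "ba"',
          "        intervals [3]:", "            xmin = 2.0",
          "            xmax = 3.0", '            text = ""')
  f <- withr::local_tempfile(fileext = ".TextGrid")
  writeLines(tg, f)
  log <- read_logfile(f, fps = 8, n_frames = 30)
  expect_equal(nrow(log), 1L)
  # floor(1.0 * 8) + 1 = 9, ceiling(2.0 * 8) = 16
  expect_equal(log$onset, 9L)
  expect_equal(log$offset, 16L)
  expect_equal(log$label, "ba")
  expect_error(read_logfile(f), "fps")
})

test_that("mask series round-trip losslessly and reject non-binary files", {
  set.seed(7)
  roi <- region_of_interest(matrix(TRUE, 8, 9))
  ms <- tract_mask_series(array(runif(5 * 8 * 9) < 0.3, c(5, 8, 9)), roi,
                          threshold_used = 0.4)
  f <- withr::local_tempfile(fileext = ".nii")
  write_mask_series(ms, f)
  back <- read_mask_series(f)
  expect_identical(back$masks, ms$masks)
  expect_equal(back$threshold_used, 0.4)
  expect_identical(back$roi_used$mask, roi$mask)

  empty <- tract_mask_series(array(FALSE, c(3, 8, 9)), roi)
  write_mask_series(empty, f)
  expect_identical(read_mask_series(f)$masks, empty$masks)

  bad <- withr::local_tempfile(fileext = ".nii")
  img <- RNifti::asNifti(array(c(0, 1, 2, 1), c(2, 2, 1)))
  RNifti::writeNifti(img, bad)
  expect_error(read_mask_series(bad), "non-binary")
})

test_that("outline CSVs have one row per site and round-trip to 1e-6", {
  o <- tract_outline(cbind(c(1, 5, 5, 1), c(1, 1, 5, 5)), frame = 3L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_outlines(list(o), f, run_id = "r1")
  raw <- utils::read.csv(f)
  expect_equal(nrow(raw), 4L)
  expect_equal(names(raw), c("run_id", "frame", "site_index", "y", "z"))

  set.seed(9)
  many <- lapply(1:3, function(k)
    tract_outline(matrix(runif(16, 1, 20), 8, 2), frame = k))
  write_outlines(many, f)
  back <- read_outlines(f)
  expect_equal(length(back), 3L)
  for (k in 1:3)
    expect_equal(back[[k]]$points, many[[k]]$points, tolerance = 2e-6)

  expect_error(write_outlines(list(), f), "no outlines")
})
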