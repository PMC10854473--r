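test_that("NIfTI round-trip preserves voxel data and slicing works", {
  set.seed(11)
  arr <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8))
  vol <- volume3d(arr, spacing = c(1, 1, 2), subject_id = "rt")
  fp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, fp)
  back <- read_volume(fp)
  expect_equal(as.numeric(back$voxels), as.numeric(arr), tolerance = 1e-6)
  expect_equal(dim(back$voxels), c(8L, 8L, 8L))
  expect_equal(back$spacing, c(1, 1, 2), tolerance = 1e-6)
})

test_that("read_volume rejects genuinely 4D images and missing files", {
  fp <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 3))), fp)
  expect_error(read_volume(fp), "3D")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "no such file")
})

test_that("axial slice extraction matches direct array indexing", {
  ph <- make_phantom(phantom_spec(shape = c(32L, 32L, 24L), seed = 4))
  slices <- extract_axial_slices(ph$volume)
  expect_equal(n_slices(slices), 24L)
  expect_equal(slices$meta$slice_index, 0:23)
  for (k in c(1L, 12L, 24L))
    expect_identical(slices$images[[k]], ph$volume$voxels[, , k])
  # degenerate depth-1 volume via direct construction
  v1 <- volume3d(array(1:9, c(3, 3, 1)))
  s1 <- extract_axial_slices(v1)
  expect_equal(n_slices(s1), 1L)
  expect_equal(s1$meta$slice_index, 0L)
  # 189-deep volume yields 189 slices
  v189 <- volume3d(array(0, c(4, 4, 189)))
  expect_equal(n_slices(extract_axial_slices(v189)), 189L)
})

test_that("slice image export writes one file and manifest row per slice", {
  sl <- toy_slices(n_subjects = 3L, n_slices = 10L, labels = c("x", "y", "x"))
  out <- withr::local_tempdir()
  n <- write_slice_images(sl, out)
  expect_equal(n, 30L)
  man <- utils::read.csv(file.path(out, "manifest.csv"))
  expect_equal(nrow(man), 30L)
  expect_named(man, c("subject_id", "slice_index", "label", "stratum",
                      "path"))
  expect_equal(sum(file.exists(file.path(out, man$path))), 30L)
})

test_that("PNG round-trip is pixel-identical after the 8-bit rescale", {
  sl <- toy_slices(n_subjects = 1L, n_slices = 4L, seed = 7)
  out <- withr::local_tempdir()
  write_slice_images(sl, out)
  back <- read_slice_dataset(file.path(out, "manifest.csv"))
  expect_equal(n_slices(back), 4L)
  ref <- cdtl:::rescale_8bit(sl)
  for (i in 1:4)
    expect_equal(unname(back$images[[i]]), ref[[i]],
                 ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("JPEG export warns about lossiness and round-trips approximately", {
  sl <- toy_slices(n_subjects = 1L, n_slices = 2L, dim = c(16L, 16L),
                   seed = 5)
  out <- withr::local_tempdir()
  expect_warning(write_slice_images(sl, out, format = "jpeg"), "lossy")
  back <- read_slice_dataset(file.path(out, "manifest.csv"))
  ref <- cdtl:::rescale_8bit(sl)
  mad <- mean(abs(unname(back$images[[1]]) - ref[[1]]))
  expect_lt(mad, 10)  # on the 0..255 scale
})

test_that("manifest round-trip preserves metadata; duplicates rejected", {
  sl <- toy_slices(n_subjects = 2L, n_slices = 3L, labels = c("ad", NA))
  sl$meta$stratum <- rep(c("F", "M"), each = 3)
  out <- withr::local_tempdir()
  write_slice_images(sl, out)
  back <- read_slice_dataset(file.path(out, "manifest.csv"))
  expect_equal(back$meta$subject_id, sl$meta$subject_id)
  expect_equal(back$meta$slice_index, sl$meta$slice_index)
  expect_equal(back$meta$label, sl$meta$label)
  expect_equal(back$meta$stratum, sl$meta$stratum)
  # unlabeled rows were accepted as NA labels
  expect_true(all(is.na(back$meta$label[4:6])))
  # duplicate a manifest row -> validation error naming the row
  man <- utils::read.csv(file.path(out, "manifest.csv"),
                         colClasses = "character")
  man2 <- rbind(man, man[1, ])
  fp2 <- file.path(out, "dup.csv")
  utils::write.csv(man2, fp2, row.names = FALSE)
  expect_error(read_slice_dataset(fp2), "duplicate")
  # missing image file -> I/O error naming the row
  man3 <- man
  man3$path[2] <- "missing.png"
  fp3 <- file.path(out, "missing.csv")
  utils::write.csv(man3, fp3, row.names = FALSE)
  expect_error(read_slice_dataset(fp3), "row 2")
})

test_that("slice sets reject duplicate (subject, slice) keys", {
  img <- list(matrix(0, 2, 2), matrix(1, 2, 2))
  expect_error(
    slice_set(img, data.frame(subject_id = c("a", "a"),
                              slice_index = c(0L, 0L))),
    "duplicate")
})
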