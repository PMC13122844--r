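test_that("volume_grid validates its invariants", {
  g <- volume_grid(c(4, 5, 6), c(1.5, 1.5, 1.5))
  expect_equal(g$shape, c(4L, 5L, 6L))
  expect_equal(sqrt(colSums(g$affine[1:3, 1:3]^2)), g$voxel_size_mm)
  expect_error(volume_grid(c(0, 4, 4)), class = "funcphen_bad_grid")
  expect_error(volume_grid(c(4, 4, 4), c(1, 1, -1)),
               class = "funcphen_bad_grid")
  expect_error(volume_grid(c(4, 4, 4), affine = matrix(0, 4, 4)),
               class = "funcphen_bad_grid")
  # affine column norms must agree with the stated voxel size
  bad <- diag(c(2, 1.5, 1.5, 1))
  expect_error(volume_grid(c(4, 4, 4), c(1.5, 1.5, 1.5), bad),
               class = "funcphen_bad_grid")
})

test_that("NIfTI volumes round-trip bit-exactly for float64", {
  grid <- tiny_grid()
  set.seed(7)
  vol <- array(rnorm(4 * 4 * 4 * 10), dim = c(4, 4, 4, 10))
  path <- withr::local_tempfile(fileext = ".nii")
  write_nifti(vol, path, grid, tr_s = 2)
  back <- read_nifti(path)
  expect_identical(back$data, vol)
  expect_equal(back$tr_s, 2)
  expect_equal(back$grid$shape, grid$shape)
  expect_equal(back$grid$affine, grid$affine)

  # integer dtype round trip
  ivol <- array(sample.int(1000L, 64), dim = c(4, 4, 4))
  write_nifti(ivol, path, grid, datatype = 4L)
  expect_equal(as.integer(read_nifti(path)$data), as.integer(ivol))
})

test_that("read_bold honours masks and raises distinct errors", {
  grid <- tiny_grid()
  set.seed(8)
  vol <- array(rnorm(640), dim = c(4, 4, 4, 10))
  path <- withr::local_tempfile(fileext = ".nii")
  write_nifti(vol, path, grid, tr_s = 2)

  mask <- roi_mask("m5", matrix(c(0,0,0, 1,0,0, 2,1,0, 3,3,3, 1,2,3),
                                ncol = 3, byrow = TRUE), grid)
  s <- read_bold(path, mask = mask)
  expect_equal(dim(s$data), c(10L, 5L))
  expect_equal(s$voxel_index, mask$voxel_index)
  # values align with the voxel coordinates
  expect_equal(s$data[, 1], vol[1, 1, 1, ])

  expect_error(read_bold("no/such/file.nii"),
               class = "funcphen_file_not_found")
  write_nifti(vol[, , , 1], path, grid)
  expect_error(read_bold(path), class = "funcphen_not_4d")
  big_grid <- volume_grid(c(8, 8, 8))
  big_mask <- roi_mask("big", matrix(c(7, 7, 7), 1), big_grid)
  write_nifti(vol, path, grid, tr_s = 2)
  expect_error(read_bold(path, mask = big_mask),
               class = "funcphen_mask_out_of_bounds")
})

test_that("a written synthetic cohort member reads back in generator order", {
  cfg <- cohort_config(n_patients = 1, n_controls = 1, n_reps = 1, seed = 5)
  ch <- generate_cohort(cfg)
  s <- ch$bold[[1]]
  path <- withr::local_tempfile(fileext = ".nii")
  write_bold(s, path)
  back <- read_bold(path, tr_s = s$tr_s)
  expect_equal(back$voxel_index, s$voxel_index)
  expect_equal(back$data, s$data, tolerance = 1e-12)
})

test_that("NIfTI writer agrees with nibabel", {
  grid <- volume_grid(c(3, 4, 5), c(1.5, 1.5, 1.5))
  set.seed(11)
  vol <- array(rnorm(3 * 4 * 5 * 6), dim = c(3, 4, 5, 6))
  path <- withr::local_tempfile(fileext = ".nii")
  csvp <- withr::local_tempfile(fileext = ".csv")
  write_nifti(vol, path, grid, tr_s = 2)
  code <- sprintf(paste0(
    "import nibabel, numpy; img = nibabel.load('%s'); ",
    "d = numpy.asarray(img.dataobj); ",
    "numpy.savetxt('%s', d.reshape(-1, order='F')); ",
    "print(d.shape, img.header.get_zooms())"), path, csvp)
  out <- suppressWarnings(system2("python", c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  expect_equal(scan(csvp, quiet = TRUE), as.numeric(vol), tolerance = 1e-12)
})

test_that("mask serialization round-trips with its JSON sidecar", {
  grid <- tiny_grid()
  m <- roi_mask("LH", matrix(c(0,0,0, 3,2,1, 1,1,1), ncol = 3,
                             byrow = TRUE), grid)
  path <- withr::local_tempfile(fileext = ".nii")
  write_mask(m, path)
  back <- read_mask(path)
  expect_equal(back$label, "LH")
  expect_equal(back$voxel_index, m$voxel_index)
})

test_that("the packaged clinical table reproduces the study cohort", {
  path <- system.file("extdata", "clinical_table1.csv", package = "funcphen")
  rec <- read_clinical_table(path)
  expect_equal(nrow(rec), 14L)
  expect_equal(sum(rec$onset_type == "UL"), 8L)
  expect_equal(max(rec$pumns), 22L)
  expect_equal(mean(rec$age_years), 56.07, tolerance = 1e-3)
  expect_equal(sqrt(mean((rec$age_years - mean(rec$age_years))^2)), 15.62,
               tolerance = 1e-3)
  expect_true(all(rec$kings_stage %in% 1:3))
  # onset -> first-affected mapping
  expect_equal(rec$first_affected_rois[[1]], c("LH", "RH"))   # P1, UL
  expect_equal(rec$first_affected_rois[[2]], c("LF", "RF"))   # P2, LL
  expect_equal(rec$first_affected_rois[[5]], "TONGUE")        # P5, B
})

test_that("clinical table parsing flags bad rows and empty input", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- "patient_id,age_years,sex,onset_type,alsfrs_total,kings_stage,pumns"
  writeLines(c(hdr, "P1,50,F,XX,44,1,1"), path)
  expect_error(read_clinical_table(path), class = "funcphen_bad_onset")
  writeLines(c(hdr, "P1,50,F,UL,99,1,1"), path)
  expect_error(read_clinical_table(path),
               class = "funcphen_score_out_of_range")
  writeLines(c(hdr, "P1,50,F,UL,44,1,1", "P2,60,M,LL,40,7,2"), path)
  err <- tryCatch(read_clinical_table(path), error = identity)
  expect_match(conditionMessage(err), "P2")
  writeLines(hdr, path)
  expect_warning(empty <- read_clinical_table(path),
                 class = "funcphen_empty_clinical")
  expect_equal(nrow(empty), 0L)
})

test_that("scalar map types enforce their invariants", {
  idx <- matrix(c(0,0,0, 1,0,0), ncol = 3, byrow = TRUE)
  expect_error(ec_map(c(-0.5, 0.5), idx, "bad"), class = "funcphen_bad_map")
  expect_error(ec_map(c(0.9, 0.9), idx, "bad"), class = "funcphen_bad_map")
  ok <- ec_map(c(1, 1) / sqrt(2), idx, "ok")
  expect_s3_class(ok, "ec_map")
  expect_error(scalar_map(c(1, NaN), idx, "bad"), class = "funcphen_bad_map")
})
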