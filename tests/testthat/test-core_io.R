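# study data model, NIfTI round-trips, marker schema and table persistence

test_that("tumor_study enforces its invariants", {
  s <- toy_study()
  expect_s3_class(s, "tumor_study")
  expect_identical(s$phase_times, c(0, 35, 50, 180))

  mask <- digital_ball(6, 20)
  phases <- s$phases
  expect_error(tumor_study("x", phases, array(FALSE, dim(mask))), "empty mask")
  bad <- phases
  bad$arterial <- array(0, c(10, 10, 10))
  expect_error(tumor_study("x", bad, mask), "grid mismatch")
  expect_error(tumor_study("x", phases, mask, phase_times = c(0, 50, 35, 180)),
               "bad phase times")
  two <- array(FALSE, c(8, 8, 8))
  two[c(2, 6), 2, 2] <- TRUE  # two separated voxels
  expect_error(tumor_study("x", lapply(phases, function(p) p[1:8, 1:8, 1:8]), two),
               "connected")
})

test_that("NIfTI volumes round-trip, including through nibabel", {
  set.seed(4)
  a <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(a, f, spacing = c(0.7, 0.8, 1.2))
  r <- read_nifti(f)
  expect_identical(r$data, a)
  expect_equal(r$spacing, c(0.7, 0.8, 1.2), tolerance = 1e-6)

  # independent reader: nibabel agrees on shape, content and spacing
  out <- system2("python", c("-c", shQuote(paste0(
    "import nibabel; img = nibabel.load('", f, "'); d = img.get_fdata(); ",
    "print(d.shape[0], d.shape[1], d.shape[2], abs(d).sum(), ",
    "*img.header.get_zooms())"))), stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(vals[1:3], c(4, 5, 6))
  expect_equal(vals[4], sum(abs(a)), tolerance = 1e-10)
  expect_equal(vals[5:7], c(0.7, 0.8, 1.2), tolerance = 1e-6)

  # and a nibabel-written file is read back correctly
  f2 <- tempfile(fileext = ".nii")
  system2("python", c("-c", shQuote(paste0(
    "import nibabel, numpy; numpy.random.seed(1); ",
    "d = numpy.random.rand(3,4,5); ",
    "img = nibabel.Nifti1Image(d, numpy.diag([1.5,2.0,2.5,1.0])); ",
    "nibabel.save(img, '", f2, "'); print(d.sum())"))), stdout = TRUE) -> py_sum
  r2 <- read_nifti(f2)
  expect_equal(dim(r2$data), c(3L, 4L, 5L))
  expect_equal(sum(r2$data), as.numeric(py_sum), tolerance = 1e-9)
  expect_equal(r2$spacing, c(1.5, 2.0, 2.5), tolerance = 1e-6)
})

test_that("load_study reads phases and mask from NIfTI", {
  s <- toy_study(seed = 9)
  dir <- tempfile()
  dir.create(dir)
  paths <- setNames(file.path(dir, paste0(names(s$phases), ".nii.gz")),
                    names(s$phases))
  for (ph in names(s$phases)) write_nifti(s$phases[[ph]], paths[ph], s$spacing)
  maskp <- file.path(dir, "mask.nii.gz")
  write_nifti(s$mask, maskp, s$spacing)

  s2 <- load_study(paths, maskp)
  expect_identical(s2$phases, s$phases)
  expect_identical(s2$mask, s$mask)
  expect_identical(s2$phase_times, c(0, 35, 50, 180))
  expect_identical(s2$study_id, "mask")

  # degenerate inputs
  write_nifti(array(FALSE, dim(s$mask)), file.path(dir, "empty.nii.gz"))
  expect_error(load_study(paths, file.path(dir, "empty.nii.gz")), "empty mask")
  write_nifti(s$phases$pre[1:10, 1:10, 1:10], file.path(dir, "small.nii.gz"))
  badp <- paths
  badp["arterial"] <- file.path(dir, "small.nii.gz")
  expect_error(load_study(badp, maskp), "grid mismatch")
  expect_error(load_study(paths, maskp, phase_times = c(0, 35, 35, 180)),
               "bad phase times")
})

test_that("the default marker schema has the published census", {
  sc <- marker_schema()
  expect_equal(nrow(sc), 249L)
  expect_false(anyDuplicated(sc$name) > 0)
  expect_equal(as.vector(table(sc$group)[c("morphological", "first_order",
                                           "glcm", "glrlm", "functional")]),
               c(70L, 104L, 24L, 48L, 3L))
})

test_that("extract_all_markers is deterministic and schema-stable", {
  s <- small_phantom("LR2", seed = 21)
  cfg <- tiny_cfg()
  mv1 <- suppressWarnings(extract_all_markers(s, cfg))
  mv2 <- suppressWarnings(extract_all_markers(s, cfg))
  expect_identical(mv1$values, mv2$values)  # bit-identical
  expect_identical(names(mv1$values), marker_schema(cfg$morph$L_max)$name)
  expect_true(all(is.finite(mv1$values)))

  # degenerate mask: morphology error, tagged with the module name
  one <- array(FALSE, c(8, 8, 8))
  one[4, 4, 4] <- TRUE
  s1 <- tumor_study("one", lapply(s$phases, function(p) p[1:8, 1:8, 1:8]), one)
  expect_error(extract_all_markers(s1, cfg), "morphology: .*mesh degenerate")
})

test_that("marker tables round-trip losslessly as CSV", {
  cfg <- tiny_cfg()
  recs <- lapply(c(3, 4, 5), function(sd)
    suppressWarnings(extract_all_markers(small_phantom("LR3", sd), cfg)))
  f <- tempfile(fileext = ".csv")
  write_marker_table(recs, f)
  tab <- read_marker_table(f)
  expect_equal(dim(tab$X), c(3L, length(recs[[1]]$values)))
  expect_identical(colnames(tab$X), names(recs[[1]]$values))
  for (i in 1:3) expect_identical(unname(tab$X[i, ]), unname(recs[[i]]$values))
  expect_identical(tab$grade, rep("LR3", 3))

  bad <- recs
  bad[[2]]$values <- bad[[2]]$values[-1]
  expect_error(write_marker_table(bad, f), "inconsistent marker schema")
})

test_that("the cad command-line interface extracts and simulates", {
  dir <- tempfile()
  dir.create(dir)
  cad_main(c("simulate", "--out", dir, "--n-per-grade", "1", "--grid", "24",
             "--seed", "5", "--log-level", "quiet"))
  lab <- read.csv(file.path(dir, "labels.csv"))
  expect_equal(nrow(lab), 5L)
  id <- lab$study_id[1]
  out <- file.path(dir, "m.csv")
  cfgf <- tempfile(fileext = ".json")
  writeLines('{"morph": {"L_max": 10, "ar": {"max_iters": 50}}}', cfgf)
  suppressWarnings(cad_main(c("extract",
    "--pre", file.path(dir, paste0(id, "_pre.nii.gz")),
    "--arterial", file.path(dir, paste0(id, "_arterial.nii.gz")),
    "--venous", file.path(dir, paste0(id, "_venous.nii.gz")),
    "--delayed", file.path(dir, paste0(id, "_delayed.nii.gz")),
    "--mask", file.path(dir, paste0(id, "_mask.nii.gz")),
    "--config", cfgf, "--out", out, "--log-level", "quiet")))
  tab <- read_marker_table(out)
  expect_equal(ncol(tab$X), 10L + 176L + 3L)
})
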