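write_pair_files <- function(dir, cond, id, nuc, pol,
                             suf = c("_dapi", "_pol")) {
  dir.create(file.path(dir, cond), recursive = TRUE, showWarnings = FALSE)
  write_raster(nuc, file.path(dir, cond, paste0(id, suf[1], ".tif")))
  write_raster(pol, file.path(dir, cond, paste0(id, suf[2], ".tif")))
}

test_that("rasters round-trip bit-identically through TIFF", {
  set.seed(1)
  for (depth in c(8L, 16L)) {
    x <- matrix(sample.int(2^depth, 200, replace = TRUE) - 1, 20, 10)
    f <- tempfile(fileext = ".tif")
    write_raster(x, f, bit_depth = depth)
    y <- read_raster(f)
    expect_equal(unname(as.matrix(y)), x, ignore_attr = TRUE)
  }
  expect_error(read_raster(tempfile(fileext = ".bmp")), "unsupported")
})

test_that("dataset discovery pairs channels per condition deterministically", {
  root <- tempfile()
  img <- matrix(1:100, 10, 10)
  for (cond in c("treated", "control"))
    for (id in c("f3", "f1", "f2"))
      write_pair_files(root, cond, id, img, img + 1)

  ds <- discover_dataset(root)
  expect_length(ds, 6L)
  expect_identical(vapply(ds, `[[`, "", "condition"),
                   rep(c("control", "treated"), each = 3))
  expect_identical(vapply(ds, `[[`, "", "field_id"),
                   rep(c("f1", "f2", "f3"), 2))
  expect_identical(vapply(discover_dataset(root), `[[`, "", "field_id"),
                   vapply(ds, `[[`, "", "field_id"))

  # an orphan nuclear file is named in the error
  write_raster(img, file.path(root, "treated", "f9_dapi.tif"))
  expect_error(discover_dataset(root), "f9_dapi")

  # dimension mismatch within a pair
  root2 <- tempfile()
  write_pair_files(root2, "c1", "f1", img, matrix(1, 5, 5))
  expect_error(discover_dataset(root2), "dimensions")
})

test_that("overlays annotate retained and excluded acini differently", {
  sim <- simulate_field(quick_sim(61))
  an <- analyze_field(sim$pair, quick_run_config())
  f <- tempfile(fileext = ".png")
  rgb <- write_annotated_overlay(an$pair, an$seg, an$table, f)
  expect_true(file.exists(f))
  green <- rgb[, , 2] == 1 & rgb[, , 1] == 0
  expect_identical(sum(an$table$excluded_reason == "none") > 0, any(green))

  # every retained acinus contributes a contour and a stamped number
  yellow <- rgb[, , 1] == 1 & rgb[, , 2] == 1 & rgb[, , 3] == 0
  expect_true(sum(yellow) >= 15 * sum(an$table$excluded_reason == "none"))

  # excluded acini get the distinct style and no number near them
  an2 <- analyze_field(sim$pair, quick_run_config(wavr_cutoff = 1e6))
  rgb2 <- write_annotated_overlay(an2$pair, an2$seg, an2$table, NULL)
  red <- rgb2[, , 1] == 1 & rgb2[, , 2] < 0.5
  expect_gt(sum(red), 0)
  expect_identical(sum(rgb2[, , 1] == 1 & rgb2[, , 2] == 1 & rgb2[, , 3] == 0), 0L)

  # a field with no acini renders the polarity image untouched
  blank <- field_pair("c", "f", matrix(5, 64, 64), matrix(3, 64, 64))
  anb <- analyze_field(blank, quick_run_config())
  rgb0 <- write_annotated_overlay(blank, anb$seg, anb$table, NULL)
  expect_equal(rgb0, array(blank$polarity / 3, c(64, 64, 3)))
})

test_that("blind manifest randomizes order and withholds conditions", {
  root <- tempfile()
  for (cond in c("alpha", "beta")) {
    cfg <- quick_sim(if (cond == "alpha") 71 else 72)
    sim <- simulate_field(cfg, condition = cond, field_id = "f1")
    write_pair_files(root, cond, "f1", sim$pair$nuclear, sim$pair$polarity)
  }
  an <- analyze_dataset(discover_dataset(root), quick_run_config())

  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  m1 <- write_blind_manifest(an, seed = 1, out_dir = d1)
  m2 <- write_blind_manifest(an, seed = 1, out_dir = d2)
  m3 <- write_blind_manifest(an, seed = 2, out_dir = d3)

  k1 <- read.csv(m1$key); k2 <- read.csv(m2$key); k3 <- read.csv(m3$key)
  expect_identical(k1$acinus_id, k2$acinus_id)       # same seed, same order
  expect_false(identical(k1$acinus_id, k3$acinus_id))  # new seed, new order
  expect_identical(sort(paste(k1$condition, k1$field_id, k1$acinus_id)),
                   sort(paste(k3$condition, k3$field_id, k3$acinus_id)))

  man <- read.csv(m1$manifest)
  expect_false(any(grepl("alpha|beta", unlist(man))))
  expect_true(all(file.exists(file.path(d1, man$nuclear_file))))

  empty <- an
  empty$table$excluded_reason <- "blur"
  expect_error(write_blind_manifest(empty, 1, tempfile()), "no retained")
})
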