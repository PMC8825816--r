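test_that("noise-free phantom renders the exact band pattern", {
  spec <- dme_phantom_spec(cystic = FALSE, noise_sigma = 0)
  scan <- generate_phantom(spec)
  img <- unclass(scan$image)
  expect_true(all(img[1:19, ] == 30))
  expect_true(all(img[20:28, ] == 180))
  expect_true(all(img[29:70, ] == 120))
  expect_true(all(img[71:80, ] == 200))
  expect_true(all(img[81:90, ] == 140))
  expect_equal(img[100, 1], 30)  # roll-off reaches background
  expect_true(all(diff(img[91:100, 5]) < 0))
  expect_equal(scan$truth_label, "non-cystic")
  expect_false(any(scan$cyst_mask))
  expect_identical(classify_scan(scan$image)$label, "non-cystic")
})

test_that("phantom generation is deterministic per seed and varies across seeds", {
  s1 <- generate_phantom(dme_phantom_spec(seed = 7))
  s2 <- generate_phantom(dme_phantom_spec(seed = 7))
  s3 <- generate_phantom(dme_phantom_spec(seed = 8))
  expect_identical(unclass(s1$image), unclass(s2$image))
  expect_false(identical(unclass(s1$image), unclass(s3$image)))
  # generation does not disturb the caller's RNG stream
  set.seed(99); a <- runif(3)
  set.seed(99); invisible(generate_phantom(dme_phantom_spec(seed = 7)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("cyst mask equals the brute-force point-in-ellipse scan", {
  spec <- dme_phantom_spec(seed = 7)
  scan <- generate_phantom(spec)
  cy <- spec$cysts[[1]]
  ref <- matrix(FALSE, spec$m, spec$n)
  for (i in seq_len(spec$m)) for (j in seq_len(spec$n)) {
    ref[i, j] <- ((i - cy$center_row) / cy$semi_row)^2 +
      ((j - cy$center_col) / cy$semi_col)^2 <= 1
  }
  expect_identical(scan$cyst_mask, ref)
  expect_equal(scan$truth_label, "cystic")
  expect_true(all(unclass(generate_phantom(
    dme_phantom_spec(noise_sigma = 0)))$image[scan$cyst_mask] == 35))
})

test_that("shadow rendering attenuates only below from_row within the band", {
  spec <- dme_phantom_spec(cystic = FALSE, shadow = TRUE, noise_sigma = 0)
  scan <- generate_phantom(spec)
  img <- unclass(scan$image)
  expect_equal(scan$true_shadow_columns, 60:70)
  expect_true(all(img[29:70, 60:70] == 24))   # attenuated mid tissue
  expect_true(all(img[71:80, 60:70] == 40))   # attenuated outer band
  expect_true(all(img[20:28, 60:70] == 180))  # above from_row untouched
  expect_true(all(img[29:70, c(59, 71)] == 120))
})

test_that("batch generation books the requested label mix reproducibly", {
  expect_length(generate_batch(0, 0, 0), 0)
  b <- generate_batch(5, 3, 4, seed = 41)
  expect_length(b, 12)
  labels <- vapply(b, `[[`, character(1), "truth_label")
  expect_equal(sum(labels == "cystic"), 5)
  expect_equal(sum(labels == "non-cystic"), 7)
  n_shadow <- sum(vapply(b, function(s) length(s$true_shadow_columns) > 0,
                         logical(1)))
  expect_equal(n_shadow, 4)
  b2 <- generate_batch(5, 3, 4, seed = 41)
  expect_identical(lapply(b, function(s) unclass(s$image)),
                   lapply(b2, function(s) unclass(s$image)))
  # truth bookkeeping consistent with content
  for (s in b) {
    expect_identical(s$truth_label,
                     if (any(s$cyst_mask)) "cystic" else "non-cystic")
  }
})

test_that("spec validation rejects bad layers, bright cysts and bad shadows", {
  layers <- list(list(top = 1, bottom = 50, intensity = 30),
                 list(top = 51, bottom = 100, intensity = 120))
  expect_error(phantom_spec(100, 100, layers[1]), "cover")
  gap <- list(list(top = 1, bottom = 40, intensity = 30),
              list(top = 45, bottom = 100, intensity = 120))
  expect_error(phantom_spec(100, 100, gap), "cover|overlap")
  expect_error(phantom_spec(100, 100, layers,
                            cysts = list(list(center_row = 70, center_col = 50,
                                              semi_row = 5, semi_col = 5,
                                              intensity = 200))),
               "darker")
  expect_error(phantom_spec(100, 100, layers,
                            shadows = list(list(col_start = 10, col_end = 20,
                                                attenuation = 1.5,
                                                from_row = 10))),
               "attenuation")
})

test_that("phantom files round-trip through the writers", {
  dir <- withr::local_tempdir()
  scans <- generate_batch(1, 1, 0, seed = 43)
  mpath <- write_batch(scans, dir)
  manifest <- read_truth_csv(mpath)
  expect_equal(nrow(manifest), 2)
  expect_setequal(manifest$label, c("cystic", "non-cystic"))
  img <- read_oct_image(file.path(dir, manifest$path[1]))
  expect_equal(dim(img), c(100, 256))
  truth <- jsonlite::read_json(file.path(dir, "phantom_001.truth.json"))
  expect_equal(truth$label, scans[[1]]$truth_label)
  # labels survive quantization: classification of the reloaded image agrees
  expect_equal(classify_scan(img)$label, scans[[1]]$truth_label)
})
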