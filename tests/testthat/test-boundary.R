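# A bright band over a dark band: the canonical light-to-dark transition.
step_image <- function(m = 20, n = 20, step_row = 10, hi = 200, lo = 50,
                       noise = 0.5, seed = 1) {
  x <- matrix(lo, m, n)
  x[1:step_row, ] <- hi
  set.seed(seed)
  pmin(pmax(x + matrix(rnorm(m * n, sd = noise), m, n), 0), 255)
}

test_that("a bright-over-dark step yields one seed per interior column", {
  x <- step_image()
  dm <- diff_maps(x)
  seeds <- find_vertical_seeds(dm, thv = 20)
  expect_setequal(unique(seeds[, "col"]), 2:19)
  # dv peaks on the rows straddling the step, at the same rows in all columns
  expect_true(all(seeds[, "row"] %in% 10:11))
  expect_equal(nrow(seeds), 18)

  # flipped contrast (dark over bright): dv < 0, no seeds
  dmf <- diff_maps(x[20:1, ])
  expect_equal(nrow(find_vertical_seeds(dmf, thv = 20)), 0)

  # constant image: V, L, R all empty
  dmc <- diff_maps(matrix(77, 15, 15))
  expect_equal(nrow(find_vertical_seeds(dmc, 10)), 0)
  sets <- find_diagonal_sets(dmc, 10)
  expect_false(any(sets$L) || any(sets$R))
})

test_that("V, L and R shrink as thv increases", {
  set.seed(31)
  x <- random_image(30, 30)
  dm <- diff_maps(x)
  for (pair in list(c(5, 20), c(20, 60))) {
    lo <- pair[1]; hi <- pair[2]
    s_lo <- find_vertical_seeds(dm, lo); s_hi <- find_vertical_seeds(dm, hi)
    expect_true(all(paste(s_hi[, 1], s_hi[, 2]) %in%
                      paste(s_lo[, 1], s_lo[, 2])))
    d_lo <- find_diagonal_sets(dm, lo); d_hi <- find_diagonal_sets(dm, hi)
    expect_true(all(which(d_hi$L) %in% which(d_lo$L)))
    expect_true(all(which(d_hi$R) %in% which(d_lo$R)))
  }
})

test_that("a dark disk populates L on its upper-left arc and R on its upper-right arc", {
  m <- 40; n <- 40
  x <- matrix(200, m, n)
  ii <- matrix(1:m, m, n); jj <- matrix(1:n, m, n, byrow = TRUE)
  inside <- (ii - 20)^2 + (jj - 20)^2 <= 12^2
  x[inside] <- 40
  dm <- diff_maps(x)
  sets <- find_diagonal_sets(dm, thv = 30)
  Lpix <- which(sets$L, arr.ind = TRUE)
  Rpix <- which(sets$R, arr.ind = TRUE)
  expect_gt(nrow(Lpix), 0)
  expect_gt(nrow(Rpix), 0)
  # L: transitions along the down-right diagonal -> upper-left arc
  expect_true(all(Lpix[, 1] + Lpix[, 2] < 40 + 2))
  # R: transitions along the down-left diagonal -> upper-right arc
  expect_true(all(Rpix[, 2] - Rpix[, 1] > -2))
  # membership agrees with brute-force evaluation of the three conditions
  nl <- naive_local_max(dm$dl, c(-1, -1), c(1, 1)) &
    !is.na(dm$dl) & dm$dl > 0 & dm$dl > 30
  nl[is.na(nl)] <- FALSE
  expect_identical(sets$L, nl)

  # horizontal mirror swaps the arcs
  dmm <- diff_maps(x[, n:1])
  setsm <- find_diagonal_sets(dmm, thv = 30)
  expect_identical(setsm$L, sets$R[, n:1])
  expect_identical(setsm$R, sets$L[, n:1])
})

test_that("detect_candidates matches the brute-force triple-loop reimplementation", {
  set.seed(33)
  for (rep in 1:6) {
    x <- random_image(30, 30)
    # low thv so random images actually produce seeds and members
    p <- detection_params(thv = 3, s = 5, t = 4, num = 2)
    got <- detect_candidates(oct_image(x), p)
    ref <- naive_candidates(x, thv = 3, s = 5, t = 4, num = 2)
    got_key <- paste(got$seed_row, got$seed_col, got$side, got$member_count)
    ref_key <- paste(ref$seed_row, ref$seed_col, ref$side, ref$member_count)
    expect_setequal(got_key, ref_key)
  }
})

test_that("candidate set shrinks as num increases and candidates satisfy all invariants", {
  scan <- generate_phantom(dme_phantom_spec(seed = 7))
  den <- denoise_median(scan$image)
  p10 <- detection_params(num = 10)
  p12 <- detection_params(num = 12)
  c10 <- detect_candidates(den, p10)
  c12 <- detect_candidates(den, p12)
  expect_gt(nrow(c10), 0)
  k10 <- paste(c10$seed_row, c10$seed_col, c10$side)
  k12 <- paste(c12$seed_row, c12$seed_col, c12$side)
  expect_true(all(k12 %in% k10))
  expect_valid_candidates(c10, den, p10)

  # every accepted patch certifies at least num + 1 member pixels
  expect_true(all(c10$member_count >= 11))
})

test_that("candidate seeds localize the top boundary of a phantom cyst", {
  scan <- generate_phantom(dme_phantom_spec(seed = 7))
  den <- denoise_median(scan$image)
  cands <- detect_candidates(den, detection_params())
  expect_gt(nrow(cands), 0)
  # true top of the cyst ellipse: row 40 at column 128
  top_rows <- apply(cands, 1, function(r) {
    j <- as.integer(r[["seed_col"]])
    rows <- which(scan$cyst_mask[, j])
    if (length(rows)) min(rows) else NA_integer_
  })
  expect_true(any(abs(cands$seed_row - top_rows) <= 3, na.rm = TRUE))

  # the same phantom without a cyst yields no candidates at all
  clean <- generate_phantom(dme_phantom_spec(cystic = FALSE, seed = 7))
  expect_equal(nrow(detect_candidates(denoise_median(clean$image),
                                      detection_params())), 0)
})

test_that("detection_params rejects invalid values", {
  expect_error(detection_params(thv = -1), "thv")
  expect_error(detection_params(s = 0), "`s`")
  expect_error(detection_params(num = -1), "`num`")
  expect_error(detection_params(s = 2, t = 2, num = 4), "s \\* t")
  expect_error(detection_params(thv_rel = 1.2), "thv_rel")
})
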