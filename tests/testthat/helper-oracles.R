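# Brute-force reference implementations used as independent oracles.
# Deliberately written as plain double/triple loops with no shared code
# with the package internals.

naive_mean_map <- function(x, a = 1, b = 1) {
  m <- nrow(x); n <- ncol(x)
  A <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      if (i - a >= 1 && i + a <= m && j - b >= 1 && j + b <= n) {
        s <- 0
        for (p in (i - a):(i + a)) for (q in (j - b):(j + b)) s <- s + x[p, q]
        A[i, j] <- s / ((2 * a + 1) * (2 * b + 1))
      }
    }
  }
  A
}

naive_diff <- function(A, o1, o2) {
  # out[i,j] = A[i + o1[1], j + o1[2]] - A[i + o2[1], j + o2[2]]
  m <- nrow(A); n <- ncol(A)
  D <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    i1 <- i + o1[1]; j1 <- j + o1[2]; i2 <- i + o2[1]; j2 <- j + o2[2]
    if (i1 >= 1 && i1 <= m && j1 >= 1 && j1 <= n &&
        i2 >= 1 && i2 <= m && j2 >= 1 && j2 <= n) {
      D[i, j] <- A[i1, j1] - A[i2, j2]
    }
  }
  D
}

naive_diff_maps <- function(x, a = 1, b = 1) {
  A <- naive_mean_map(x, a, b)
  list(A = A,
       dv = naive_diff(A, c(-1, 0), c(1, 0)),
       dl = naive_diff(A, c(-1, -1), c(1, 1)),
       dr = naive_diff(A, c(-1, 1), c(1, -1)),
       df = naive_diff(A, c(2, 0), c(-2, 0)))
}

naive_local_max <- function(map, d1, d2, strict = TRUE) {
  m <- nrow(map); n <- ncol(map)
  out <- matrix(FALSE, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    i1 <- i + d1[1]; j1 <- j + d1[2]; i2 <- i + d2[1]; j2 <- j + d2[2]
    if (i1 < 1 || i1 > m || j1 < 1 || j1 > n ||
        i2 < 1 || i2 > m || j2 < 1 || j2 > n) next
    v <- map[i, j]; v1 <- map[i1, j1]; v2 <- map[i2, j2]
    if (is.na(v) || is.na(v1) || is.na(v2)) next
    out[i, j] <- if (strict) v > v1 && v > v2 else v >= v1 && v >= v2
  }
  out
}

# Straight-line reimplementation of the boundary pixel determination
# algorithm (no vectorization, no shared helpers).
naive_candidates <- function(x, thv, s = 11, t = 11, num = 10, a = 1, b = 1) {
  dm <- naive_diff_maps(x, a, b)
  m <- nrow(x); n <- ncol(x)
  V <- naive_local_max(dm$dv, c(-1, 0), c(1, 0))
  L <- naive_local_max(dm$dl, c(-1, -1), c(1, 1))
  R <- naive_local_max(dm$dr, c(-1, 1), c(1, -1))
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (V[i, j] && (is.na(dm$dv[i, j]) || dm$dv[i, j] <= 0 ||
                    abs(dm$dv[i, j]) <= thv)) V[i, j] <- FALSE
    if (L[i, j] && (is.na(dm$dl[i, j]) || dm$dl[i, j] <= 0 ||
                    dm$dl[i, j] <= thv)) L[i, j] <- FALSE
    if (R[i, j] && (is.na(dm$dr[i, j]) || dm$dr[i, j] <= 0 ||
                    dm$dr[i, j] <= thv)) R[i, j] <- FALSE
  }
  out <- NULL
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (!V[i, j]) next
    rr <- max(1, i - floor(s / 2)):min(m, i + ceiling(s / 2) - 1)
    for (side in c("left", "right")) {
      cc <- if (side == "left") (j - t):(j - 1) else (j + 1):(j + t)
      cc <- cc[cc >= 1 & cc <= n]
      if (length(cc) == 0) next
      cnt <- 0
      for (p in rr) for (q in cc) {
        if (side == "left" && L[p, q]) cnt <- cnt + 1
        if (side == "right" && R[p, q]) cnt <- cnt + 1
      }
      if (cnt > num) {
        out <- rbind(out, data.frame(seed_row = i, seed_col = j, side = side,
                                     member_count = cnt,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(seed_row = integer(), seed_col = integer(),
                      side = character(), member_count = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

# Brute-force scan of the per-column transition conditions.
naive_column_transition <- function(x, col, alpha, a = 1, b = 1) {
  dm <- naive_diff_maps(x, a, b)
  m <- nrow(x)
  Av <- dm$A[, col]
  vals <- sort(Av[!is.na(Av)], decreasing = TRUE)
  k <- max(1, floor(alpha * m))
  m_th <- vals[min(k, length(vals))]
  q <- NA_integer_
  for (i in seq_len(m)) {
    dfv <- dm$df[i, col]
    if (is.na(dfv) || dfv >= 0) next
    up <- if (i > 1) abs(dm$df[i - 1, col]) else NA
    dn <- if (i < m) abs(dm$df[i + 1, col]) else NA
    if (is.na(up) || is.na(dn)) next
    if (!(abs(dfv) >= up && abs(dfv) >= dn)) next
    if (i - 2 < 1 || is.na(dm$A[i - 2, col]) || dm$A[i - 2, col] < m_th) next
    q <- i  # loop ascends, so the last hit is the bottom-most
  }
  list(q_row = q, m_th = m_th)
}

# Structural audit of every cyst_candidates invariant.
expect_valid_candidates <- function(cands, img, params, diff = NULL,
                                    thv = NULL) {
  m <- nrow(img); n <- ncol(img)
  mems <- attr(cands, "members")
  expect_equal(length(mems), nrow(cands))
  if (is.null(thv)) thv <- attr(cands, "thv")
  if (is.null(diff)) diff <- diff_maps(img, params$a, params$b)
  sets <- find_diagonal_sets(diff, thv)
  seeds <- find_vertical_seeds(diff, thv)
  seed_key <- paste(seeds[, 1], seeds[, 2])
  for (r in seq_len(nrow(cands))) {
    expect_gt(cands$member_count[r], params$num)
    expect_equal(nrow(mems[[r]]), cands$member_count[r])
    expect_true(paste(cands$seed_row[r], cands$seed_col[r]) %in% seed_key)
    expect_true(cands$row_min[r] >= 1 && cands$row_max[r] <= m)
    expect_true(cands$col_min[r] >= 1 && cands$col_max[r] <= n)
    mask <- if (cands$side[r] == "left") sets$L else sets$R
    for (k in seq_len(nrow(mems[[r]]))) {
      p <- mems[[r]][k, 1]; q <- mems[[r]][k, 2]
      expect_true(p >= cands$row_min[r] && p <= cands$row_max[r])
      expect_true(q >= cands$col_min[r] && q <= cands$col_max[r])
      expect_true(mask[p, q])
    }
  }
}

random_image <- function(m, n) {
  matrix(runif(m * n, 0, 255), m, n)
}
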