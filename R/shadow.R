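# Vessel-shadow column detection: per-column tracking of the bottom-most
# significant dark-to-light (bottom-up) transition into a bright region.

#' Shadow-detection parameters
#'
#' @param alpha brightness-quantile fraction in `(0, 1)`. Per column, the
#'   brightness cutoff `m_th` is the minimum of the `floor(alpha * m)`
#'   largest neighborhood-mean values; smaller `alpha` demands a brighter
#'   region above the transition and so flags more columns as shadow.
#'   Default 0.08.
#' @param jump_thr minimum change of the transition row between consecutive
#'   columns that signals a shadow boundary, in pixels. `NULL` (default)
#'   resolves to `max(10, ceiling(0.05 * m))` for an image with `m` rows:
#'   a vessel shadow displaces the transition from the bright outer band to
#'   a much higher structure, so the two-scale default adapts to image
#'   height.
#' @param a,b averaging-window half-widths (defaults 1 and 1).
#' @return A `shadow_params` object (list).
#' @export
shadow_params <- function(alpha = 0.08, jump_thr = NULL, a = 1L, b = 1L) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(jump_thr) && (!is.numeric(jump_thr) || jump_thr < 1)) {
    stop("`jump_thr` must be >= 1", call. = FALSE)
  }
  if (a < 1L || b < 1L) stop("`a` and `b` must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, jump_thr = jump_thr,
                 a = as.integer(a), b = as.integer(b)),
            class = "shadow_params")
}

#' @export
print.shadow_params <- function(x, ...) {
  jt <- if (is.null(x$jump_thr)) "max(10, 0.05 m)" else format(x$jump_thr)
  cat(sprintf("<shadow_params> alpha = %.3f, jump_thr = %s, a = %d, b = %d\n",
              x$alpha, jt, x$a, x$b))
  invisible(x)
}

resolve_jump_thr <- function(params, m) {
  if (!is.null(params$jump_thr)) return(params$jump_thr)
  max(10, ceiling(0.05 * m))
}

#' Per-column dark-to-light transition point
#'
#' For one column, finds the transition row `Q_j`: the bottom-most (largest
#' row index) pixel at which `|df|` is a local maximum along the column
#' (non-strict, so ideal two-row step plateaus still qualify), `df < 0`
#' (brighter above, darker below — a dark-to-light transition when the
#' column is read bottom-up), and the region two rows above is bright
#' enough: `A[i - 2, j] >= m_th`, where `m_th` is the minimum of the
#' `floor(alpha * m)` largest defined values of `A` in the column.
#'
#' In a column free of vessel shadow this transition sits at the lower edge
#' of the bright outer band (the retinal pigment epithelium); under a shadow
#' the outer band is attenuated below the cutoff and the transition jumps to
#' a much higher structure, or disappears.
#'
#' @param diff an [diff_maps()] result.
#' @param col 1-based column index within the defined interior.
#' @param alpha brightness-quantile fraction, see [shadow_params()].
#' @return A list with `q_row` (integer row index, or `NA` if no pixel
#'   qualifies) and `m_th` (the brightness cutoff used; `NA` if the column
#'   has no defined values, with a warning).
#' @export
column_transition <- function(diff, col, alpha = 0.08) {
  stopifnot(inherits(diff, "oct_diff_maps"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (col < 1L || col > diff$n) stop("`col` out of range", call. = FALSE)
  Av <- diff$A[, col]
  vals <- sort(Av[!is.na(Av)], decreasing = TRUE)
  if (length(vals) == 0L) {
    warning("column ", col, " has no defined neighborhood means")
    return(list(q_row = NA_integer_, m_th = NA_real_))
  }
  k <- max(1L, floor(alpha * diff$m))
  m_th <- vals[min(k, length(vals))]

  dfc <- diff$df[, col]
  admf <- abs(dfc)
  up <- c(NA_real_, admf[-diff$m])
  dn <- c(admf[-1L], NA_real_)
  lm <- admf >= up & admf >= dn
  lm[is.na(lm)] <- FALSE
  above2 <- c(NA_real_, NA_real_, Av[seq_len(diff$m - 2L)])  # A[i - 2, col]
  cond <- lm & !is.na(dfc) & dfc < 0 & !is.na(above2) & above2 >= m_th
  q_row <- if (any(cond)) max(which(cond)) else NA_integer_
  list(q_row = q_row, m_th = m_th)
}

#' Detect vessel-shadow columns
#'
#' Computes the transition row `Q_j` (see [column_transition()]) for every
#' interior column, then flags shadow columns from the change of `Q` between
#' consecutive columns. A *boundary* falls between columns `j` and `j + 1`
#' when `|Q_{j+1} - Q_j| > jump_thr`, or when `Q` is present in exactly one
#' of the two columns. Boundaries partition the interior columns into runs;
#' a run is flagged as shadow when the median of its transition rows
#' deviates from the global median by more than `jump_thr` (a vessel shadow
#' displaces the transition far from its typical depth), or when the run has
#' no transitions at all but is bounded by at least one boundary (a shadow
#' deep enough to kill the transition entirely). This assumes shadows cover
#' a minority of columns, so the global median tracks the unshadowed
#' transition depth.
#'
#' @param img an [oct_image()] (typically the denoised scan).
#' @param params a [shadow_params()] object.
#' @return An object of class `shadow_profile`: a list with `q` (integer
#'   vector of length `n`, `NA` where absent/undefined), `m_th` (numeric
#'   vector of per-column cutoffs), `shadow_columns` (sorted integer vector
#'   of flagged 1-based column indices, always within the interior),
#'   `jump_thr` and `alpha`.
#' @export
detect_shadow_columns <- function(img, params = shadow_params()) {
  stopifnot(inherits(params, "shadow_params"))
  x <- unclass(img)
  m <- nrow(x)
  n <- ncol(x)
  dm <- diff_maps(x, params$a, params$b)
  jump_thr <- resolve_jump_thr(params, m)

  q <- rep(NA_integer_, n)
  m_th <- rep(NA_real_, n)
  interior <- (params$b + 1L):(n - params$b)
  for (j in interior) {
    tr <- suppressWarnings(column_transition(dm, j, params$alpha))
    q[j] <- tr$q_row
    m_th[j] <- tr$m_th
  }

  qi <- q[interior]
  nb <- length(interior)
  # boundaries between consecutive interior columns
  boundary <- logical(max(nb - 1L, 0L))
  for (p in seq_len(nb - 1L)) {
    q1 <- qi[p]; q2 <- qi[p + 1L]
    boundary[p] <- (is.na(q1) != is.na(q2)) ||
      (!is.na(q1) && !is.na(q2) && abs(q2 - q1) > jump_thr)
  }
  run_id <- c(0L, cumsum(boundary))
  baseline <- median(qi, na.rm = TRUE)
  flagged <- logical(nb)
  if (any(boundary) && !is.na(baseline)) {
    for (rid in unique(run_id)) {
      sel <- run_id == rid
      qr <- qi[sel]
      if (all(is.na(qr))) {
        flagged[sel] <- TRUE  # transition killed outright; bounded by a jump
      } else if (abs(median(qr, na.rm = TRUE) - baseline) > jump_thr) {
        flagged[sel] <- TRUE
      }
    }
  }
  structure(
    list(q = q, m_th = m_th,
         shadow_columns = interior[flagged],
         jump_thr = jump_thr, alpha = params$alpha),
    class = "shadow_profile"
  )
}

#' @export
print.shadow_profile <- function(x, ...) {
  sc <- x$shadow_columns
  cat(sprintf("<shadow_profile> alpha = %.3f, jump_thr = %g, %d shadow column(s)\n",
              x$alpha, x$jump_thr, length(sc)))
  if (length(sc) > 0L) {
    cat("  columns:", paste(range(sc), collapse = "-"),
        sprintf("(%d flagged)\n", length(sc)))
  }
  invisible(x)
}
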