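# Neighborhood-mean map and directional difference maps.
#
# All maps carry NA wherever an operand falls outside the image: the border
# is left explicitly undefined rather than padded, because padding would
# fabricate intensity transitions at the image edges.

# Shift a matrix so that out[i, j] = x[i + di, j + dj]; NA outside.
shift_mat <- function(x, di, dj) {
  m <- nrow(x)
  n <- ncol(x)
  out <- matrix(NA_real_, m, n)
  ri <- max(1L, 1L - di):min(m, m - di)
  cj <- max(1L, 1L - dj):min(n, n - dj)
  if (length(ri) > 0L && length(cj) > 0L) {
    out[ri, cj] <- x[ri + di, cj + dj, drop = FALSE]
  }
  out
}

#' Neighborhood-mean intensity map
#'
#' For every pixel `(i, j)` at which the full window fits inside the image,
#' computes the arithmetic mean of the `(2a+1) x (2b+1)` intensity window
#' centred at `(i, j)`:
#' \deqn{A^{a,b}_{i,j} = \frac{\sum_{q=j-b}^{j+b} \sum_{p=i-a}^{i+a} X_{p,q}}
#'                            {(2a+1)(2b+1)}}
#' Border pixels, where the window would overhang the image, are `NA`.
#'
#' @param img an [oct_image()] or numeric matrix.
#' @param a,b window half-height and half-width in pixels (defaults 1 and 1,
#'   i.e. a 3 x 3 window).
#' @return An `m x n` numeric matrix; `NA` on the `a`-row / `b`-column border.
#' @examples
#' A <- mean_map(oct_image(matrix(100, 10, 10)))
#' A[5, 5]  # 100
#' @export
mean_map <- function(img, a = 1L, b = 1L) {
  x <- unclass(img)
  m <- nrow(x)
  n <- ncol(x)
  if (a < 1L || b < 1L) stop("`a` and `b` must be >= 1", call. = FALSE)
  if (m <= 2 * a || n <= 2 * b) {
    stop(sprintf(
      "image too small for a %d x %d averaging window: need at least %d x %d, got %d x %d",
      2 * a + 1, 2 * b + 1, 2 * a + 1, 2 * b + 1, m, n), call. = FALSE)
  }
  # integral image: S[i+1, j+1] = sum over x[1:i, 1:j]
  S <- rbind(0, apply(x, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  ri <- (a + 1L):(m - a)
  cj <- (b + 1L):(n - b)
  A <- matrix(NA_real_, m, n)
  A[ri, cj] <- (S[ri + a + 1L, cj + b + 1L] - S[ri - a, cj + b + 1L] -
                  S[ri + a + 1L, cj - b] + S[ri - a, cj - b]) /
    ((2 * a + 1) * (2 * b + 1))
  A
}

#' Directional difference maps of the neighborhood mean
#'
#' From the mean map `A` (see [mean_map()]) computes the four directional
#' difference maps the detector and the shadow tracker consume:
#' \itemize{
#'   \item `dv[i,j] = A[i-1,j] - A[i+1,j]` — vertical change; positive where
#'     the tissue above is brighter than below (light-to-dark going down).
#'   \item `dl[i,j] = A[i-1,j-1] - A[i+1,j+1]` — change along the
#'     down-right diagonal (transition at the left side of a dark region).
#'   \item `dr[i,j] = A[i-1,j+1] - A[i+1,j-1]` — change along the
#'     down-left diagonal (transition at the right side of a dark region).
#'   \item `df[i,j] = A[i+2,j] - A[i-2,j]` — offset-2 vertical change used by
#'     the per-column shadow tracker; negative at a bottom-up dark-to-light
#'     transition.
#' }
#' Positions where any operand is undefined are `NA`.
#'
#' @inheritParams mean_map
#' @return An object of class `oct_diff_maps`: a list with elements `A`,
#'   `dv`, `dl`, `dr`, `df` (matrices), and `a`, `b`, `m`, `n`.
#' @export
diff_maps <- function(img, a = 1L, b = 1L) {
  A <- mean_map(img, a, b)
  structure(
    list(
      A = A,
      dv = shift_mat(A, -1L, 0L) - shift_mat(A, 1L, 0L),
      dl = shift_mat(A, -1L, -1L) - shift_mat(A, 1L, 1L),
      dr = shift_mat(A, -1L, 1L) - shift_mat(A, 1L, -1L),
      df = shift_mat(A, 2L, 0L) - shift_mat(A, -2L, 0L),
      a = as.integer(a), b = as.integer(b),
      m = nrow(A), n = ncol(A)
    ),
    class = "oct_diff_maps"
  )
}

#' @export
print.oct_diff_maps <- function(x, ...) {
  cat(sprintf("<oct_diff_maps> %d x %d (a = %d, b = %d)\n",
              x$m, x$n, x$a, x$b))
  invisible(x)
}

# neighbor offsets for each local-max comparison direction
.lm_offsets <- list(
  "vertical"        = list(c(-1L, 0L), c(1L, 0L)),
  "diag-down-right" = list(c(-1L, -1L), c(1L, 1L)),
  "diag-down-left"  = list(c(-1L, 1L), c(1L, -1L))
)

#' Directional local-maximum mask
#'
#' Marks the positions where a difference map is greater than both of its
#' neighbors along the chosen direction. `vertical` compares `(i-1,j)` and
#' `(i+1,j)`; `diag-down-right` compares `(i-1,j-1)` and `(i+1,j+1)`;
#' `diag-down-left` compares `(i-1,j+1)` and `(i+1,j-1)`.
#'
#' With `strict = TRUE` (the default, used for seed and diagonal-set
#' detection) the comparisons are strict, so plateaus of exactly tied values
#' yield no maximum. The shadow tracker uses `strict = FALSE` for the
#' magnitude of `df`, where exact two-row plateaus arise at ideal step edges.
#'
#' @param map a numeric matrix (one of the difference maps), `NA` where
#'   undefined.
#' @param direction one of `"vertical"`, `"diag-down-right"`,
#'   `"diag-down-left"`.
#' @param strict compare with `>` (default) or `>=`.
#' @return A logical matrix; `FALSE` wherever the value or either neighbor
#'   is undefined.
#' @export
local_max_mask <- function(map, direction = c("vertical", "diag-down-right",
                                              "diag-down-left"),
                           strict = TRUE) {
  direction <- match.arg(direction)
  off <- .lm_offsets[[direction]]
  n1 <- shift_mat(map, off[[1]][1], off[[1]][2])
  n2 <- shift_mat(map, off[[2]][1], off[[2]][2])
  ok <- if (strict) map > n1 & map > n2 else map >= n1 & map >= n2
  ok[is.na(ok)] <- FALSE
  ok
}
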